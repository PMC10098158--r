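Package: lglpheno
Title: Screening for T-LGL Expansions in Inclusion Body Myositis Cytometry Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and characterise expansions of CD8+ T cell large
    granular lymphocytes (T-LGLs) in inclusion body myositis from event-level
    flow cytometry. Provides a synthetic cohort generator (event-level
    fluorescence, longitudinal visits, HLA genotypes and anti-cN1A ELISA
    plates with planted ground truth), hierarchical threshold gating with
    bead-based absolute counting, a multi-criteria T-LGL_HIGH/LOW classifier
    with healthy-control-referenced cutoffs, ELISA fold-change seropositivity
    calling, HLA carriage association scans with exact tests, and the
    nonparametric statistical layer (Scheirer-Ray-Hare rank factorial test,
    Dunn's post hoc) used for group comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synth-cohort.R'
    'events-io.R'
    'gating.R'
    'classify.R'
    'serology.R'
    'hla.R'
    'cohort-stats.R'
    'pipeline.R'
    'lglpheno-package.R'
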