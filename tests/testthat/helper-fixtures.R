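# Shared fixtures, built once per test session.

# A small cohort: three groups, light event load, two visits.
smallConfig <- function(...) {
  cohortConfig(group_sizes = c(HC = 12, LOW = 10, HIGH = 8),
               events_surface = 4000, events_other = 2000, ...)
}

.fixtureEnv <- new.env(parent = emptyenv())

testCohort <- function() {
  if (is.null(.fixtureEnv$cohort))
    .fixtureEnv$cohort <- simulateCohort(smallConfig(), seed = 42)
  .fixtureEnv$cohort
}

testFeatures <- function() {
  if (is.null(.fixtureEnv$features))
    .fixtureEnv$features <- gateCohort(testCohort(), panels = "surface")
  .fixtureEnv$features
}

# a config whose HIGH %CD8+CD57+ distribution is degenerate at a point mass
degenerateHighConfig <- function(frac = 0.20, events = 50000) {
  cfg <- cohortConfig(group_sizes = c(HC = 1, LOW = 1, HIGH = 1),
                      events_surface = events)
  mp <- cfg$marker_profile
  sel <- mp$param == "frac_cd8cd57" & mp$group == "HIGH"
  mp$median[sel] <- frac
  mp$sigma[sel] <- 0
  cfg$marker_profile <- mp
  cfg
}

# hand-built one-row feature table for classifier tests
featureRow <- function(pct57 = 1, ratio = 2.8, cd5dim = 5, cd94 = 5,
                       cd56 = 5, klrg1 = 30, donor = "X1", visit = 1L,
                       date = as.Date("2020-01-01")) {
  data.frame(donor_id = donor, group = "LOW", visit = visit,
             visit_date = date,
             pct_cd8cd57_of_lymph = pct57, cd4_cd8_ratio = ratio,
             pct_cd5dim_cd857 = cd5dim, pct_cd94_cd857 = cd94,
             pct_cd56_cd857 = cd56, pct_klrg1_cd857 = klrg1,
             stringsAsFactors = FALSE)
}

# thresholds fixed by hand so classifier tests do not depend on gating
fixedThresholds <- function(cd5dim = 15, cd94 = 20, cd56 = 20, klrg1 = 65) {
  methods::new("ThresholdSet", pctCd8Cd57Cutoff = 3, ratioCutoff = 1.5,
               aberrancyCutoffs = c(pct_cd5dim_cd857 = cd5dim,
                                    pct_cd94_cd857 = cd94,
                                    pct_cd56_cd857 = cd56,
                                    pct_klrg1_cd857 = klrg1),
               hcPercentile95 = numeric(0),
               provenance = "fixed_from_paper", nHC = 56L)
}

# minimal hand-built CytoSample
manualSample <- function(mat, panel = "surface", bead = NULL) {
  if (is.null(bead)) bead <- rep(FALSE, nrow(mat))
  methods::new("CytoSample", sampleId = "manual", donorId = "manual",
               visit = 1L, visitDate = as.Date("2020-01-01"), panel = panel,
               exprs = mat, isBead = bead, truth = data.frame())
}
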