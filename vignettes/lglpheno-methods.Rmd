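---
title: "Screening for T-LGL expansions in IBM: models and methods"
author: "lglpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for T-LGL expansions in IBM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lglpheno)
```

## The problem

Inclusion body myositis (IBM) is a progressive inflammatory myopathy in
which CD8+ T cells infiltrate skeletal muscle. A subset of patients carries
a systemic expansion of T cell large granular lymphocytes (T-LGLs):
highly differentiated cytotoxic CD8+ T cells marked by CD57 and KLRG1
expression, reduced CD5, and variable CD94/CD56. Identifying these
patients from blood immunophenotyping matters because the expansion tracks
with disease severity, but no per-donor data accompany the published
cohort; everything downstream of the raw cytometry must therefore be
testable on simulated data with known ground truth. `lglpheno` provides
that simulation, the gating and classification machinery, and the serology,
HLA and nonparametric statistical layers, each testable against planted
truth or independent oracles.

## The classification rule

A patient is labelled T-LGL_HIGH when at least three of four criteria are
met:

1. **Expansion**: CD8+CD57+ cells exceed 3% of lymphocytes (the 3% cutoff
   corresponds to mean + 2 SD of the healthy-control cohort).
2. **Inverted ratio**: CD4:CD8 ratio below 1.5.
3. **Aberrant immunophenotype**: within CD8+CD57+ cells, the CD5-dim
   frequency exceeds its healthy-control cutoff *and* at least one other
   NK-cell-associated receptor (CD94, CD56 or KLRG1) exceeds its cutoff.
   Cutoffs are healthy-control mean + 2 x sample SD per feature.
4. **Persistence**: criteria 1 and 3 hold at two visits at least 183 days
   (six months) apart.

Design choices where the rule is underdetermined:

* **Indeterminate criteria** (e.g. persistence with a single visit) are
  excluded from the 3-of-4 count rather than scored as failures, so a
  single-visit patient meeting criteria 1-3 classifies HIGH. Persistence is
  treated as confirmatory, not gatekeeping.
* **Strict inequalities** at every cutoff ("greater than 3%", "< 1.5").
* **mean + 2 SD vs the 95th percentile.** For a normal distribution
  mean + 2 SD sits near the 97.7th percentile, so equating it with the 95th
  percentile is only approximate and breaks down for skewed features.
  `deriveThresholds()` computes both and stores the empirical 95th
  percentiles as a diagnostic; the mean + 2 SD value (sample SD, n - 1) is
  the operative cutoff. Which convention produced the published 3% value is
  unknowable from the summary statistics alone.
* **"CD5 dim"** is operationalised as the middle stratum of a three-way
  partition of the CD5 channel (negative / dim / bright); the frequency of
  CD5-dim cells is what enters criterion 3, not a fluorescence-intensity
  shift.
* Whether persistence requires the full criterion set at both visits is
  unstated; we require the expansion and aberrancy criteria (1 and 3) at
  both ends of the window.

The leukemia-range absolute count (0.5e9/L) is not part of the rule;
absolute counts are reported so users can flag such patients themselves.

## The synthetic cohort generator

`simulateCohort()` plants donor-level parameters and `simulateEvents()`
materialises event-level samples on demand from a per-sample seed, so a
141-donor cohort with 50,000-event samples never has to be held in memory
at once and any single sample is reproducible in isolation.

**Group structure.** Defaults: 56 healthy controls, 51 T-LGL_LOW and 34
T-LGL_HIGH donors; two visits separated by a uniform 210-960 day gap
(bracketing the reported ~600-day average follow-up); group membership is
planted as stable across visits.

**Per-donor fractions are logit-normal.** Published group summaries give
medians, 95th percentiles and ranges but no distributional form; the
strong right skew of the expansion fractions motivates a logit-normal
model. For the pivotal %CD8+CD57+ of lymphocytes, both parameters are
identified exactly from two printed quantiles via
`logitnormFromQuantiles()`: location = logit(median), scale set so the
distribution's 95th percentile equals the printed one (HC 1.10/3.0 ->
sigma 0.62; LOW 1.23/2.4 -> sigma 0.41; HIGH 9.12/14.8 -> sigma 0.33, on
the logit scale). We deliberately calibrate to the printed 95th percentile
rather than the printed range: a range is an extreme order statistic whose
expectation depends on n, while a quantile is a distribution property.
This choice also makes the healthy-control 95th percentile of the
simulated expansion fraction land at ~3%, consistent with the 3% cutoff's
published provenance. Remaining marker fractions (NK-receptor
co-expression within CD57+ subsets, IFN-g/perforin content, Ki67 strata)
use the published group medians where printed (e.g. CD4+ CD57+KLRG1+
0.24/0.36/3.08%; CD8+ IFN-g 19.5/47.1/57.1%; perforin 17.8/28.3/54.6%) and
otherwise medians chosen once to reproduce the published group contrasts,
with logit-scale sigma 0.3-0.5.

**Event model.** Events are drawn from a donor-specific lineage mixture
(CD4/CD8/double-negative/double-positive alpha-beta T cells, gamma-delta
T cells, non-T lymphocytes, non-lymphocyte debris); marker positivity is
drawn per event conditional on lineage and CD57 state; fluorescence is a
two-component log-normal mixture per marker (10-fold separation between
component medians, sdlog 0.3), with CD5 three-state to support CD5
downregulation. Scatter channels are Gaussian clusters (lymphocyte,
debris, bead). Count beads are appended at a rate implied by the planted
lymphocyte concentration and the configured bead concentration (50
beads/uL), mirroring bead-based count normalisation; because no bead
product constants are published, absolute counts are defined only up to
this configured constant. When a planted expansion is too large for the
baseline CD8 compartment, the CD8 (and if needed T cell) share grows so
that CD57+ cells stay below 80% of CD8 — a large T-LGL expansion enlarges
the CD8 pool, which is also why the HIGH group's lymphocyte concentration
is calibrated higher (1240 vs 980/880 per uL).

**What the generator does not emulate:** spectral spillover and
compensation, doublets, acquisition-time drift, muscle-digestion yield,
and manual gate placement variability. Tests passing on this generator
therefore certify the analysis arithmetic and its statistical behaviour
under the planted model, not robustness to instrument artefacts.

**HLA.** Genotypes (two G-group alleles per locus, 10 loci) are drawn per
patient from group-conditional allele frequencies shipped in
`inst/extdata/hla_group_frequencies.csv` (the published per-group
frequency table), with a pooled `<locus>*other` allele absorbing the
remaining mass. Under this independent-draw model, carriage probability is
1 - (1 - f)^2, which the tests verify.

**Serology.** ELISA plates are generated in long format with duplicate
wells, blanks, a healthy-pool control, a positive control and a synthetic
190-sample healthy reference. Seronegative fold changes are log-normal
around the pool (sdlog 0.35); seropositive donors have strongly shifted
panIgG/M/A and IgG responses (median 6-fold) and elevated minor isotypes
with probability 0.3. Planted seropositive probabilities are 13/34 (HIGH)
and 16/51 (LOW).

## Gating

Gates are one-dimensional thresholds arranged in a hierarchy
(`GatingSpec`), applied with strict parent containment. Because manual
GUI gating is not reproducible, default cutpoints are fixed at the
geometric midpoints of the known fluorescence mixtures; `fitCutpoint()`
additionally offers quantile and valley (minimum KDE density between the
two largest modes, modes below 10% of the peak ignored) methods for data
whose mixture parameters are unknown. The gamma-delta subset is gated as
CD3+TCRab- — the published surrogate — and the generator retains true
gamma-delta lineage labels so the surrogate's validity is assertable
(event-level agreement >= 99%, cross-donor frequency correlation > 0.99).
Features with empty denominators (e.g. CD4:CD8 ratio in an all-CD4
sample) are `NA`, never 0, and are excluded listwise per feature
downstream, matching how partially measured markers (KLRG1) are handled.

## Serology processing

Duplicates are averaged; the average blank is subtracted from sample and
pool; the fold change is their ratio, floored at 0. Cutoffs are the
empirical 99th percentile of healthy-reference *fold changes* (not raw
ODs — fold changes are invariant to plate-level rescaling, which is why we
compute the reference cutoff on that scale), using linear interpolation
between order statistics (R type 7); the method is recorded in the
output. A patient is seropositive when any isotype strictly exceeds its
cutoff. Duplicate CV above 20% flags the well without dropping it.

## HLA association

Allele frequency is occurrence count / (2 x patients typed at the locus).
Alleles at total frequency strictly above 2% are retained; a display rule
(>= 5% in either group) is available for reporting. Odds ratios are
computed on **carriage** (patients with >= 1 copy, homozygotes counted
once): carriage reproduces the published top-ranked odds ratio exactly
((7x40)/(22x3) = 4.24) where an allele-count odds ratio (3.80) does not.
The p-value is the two-sided conditional hypergeometric exact test,
implemented directly and verified against exhaustive enumeration over all
2x2 tables with N <= 60. Zero cells get a Haldane-Anscombe 0.5 correction
for the odds ratio only (the exact p needs none), flagged in the output.
The published interval column ("95th percentile") is interpreted as the
upper confidence limit of the odds ratio; we report the upper bound of the
90% exact conditional interval, whose upper end sits at the 95th
percentile, and note the published interval method is unstated. Raw p
values are the headline (as published); a Benjamini-Hochberg column is
provided but not used for calls.

## Nonparametric statistics

**Scheirer-Ray-Hare.** All N observations are ranked jointly (mid-ranks
for ties); factorial ANOVA sums of squares are computed on the ranks from
the margin and cell means; each term's H is SS / (N(N+1)/12), divided by
the tie-correction factor 1 - sum(t^3 - t)/(N^3 - N); p-values use the
chi-square reference with the term's ANOVA df. Using the *nominal* total
mean square N(N+1)/12 together with the explicit tie factor is
algebraically identical to dividing by the observed rank variance, and
makes the single-factor reduction exact: with one factor the H statistic
equals the tie-corrected Kruskal-Wallis H to machine precision (tested).
The interaction is computed only for complete designs (every cell
occupied); the intended use — marker subset x donor group — is complete.
The chi-square reference is asymptotic, so the simulation calibration uses
N = 60 (3 x 2 cells of 10), where the empirical type-I error at alpha =
0.05 is within Monte-Carlo error of nominal over 10,000 replicates.

**Dunn's post hoc.** Pairwise z on mean ranks with the tie-corrected
variance (N(N+1)/12 - tie term)(1/n_i + 1/n_j); two-sided normal p,
optionally Bonferroni-multiplied (capped at 1). Because the published
factorial analyses quote a "Tukey post hoc" without a procedure, a
studentized-range option (`adjust = "tukey"`, referring |z| sqrt(2) to the
range distribution with k groups) is provided alongside Bonferroni; the
rank-Tukey variant is the default after the factorial test.

**Paired blood/muscle comparison.** With two or three biopsy donors the
exact one-tailed signed-rank p cannot go below 0.5^n, so
`pairedTissueCompare()` annotates every p with that floor (0.125 at
n = 3). Note a published P = 0.25 quoted for an n = 3 one-tailed
comparison exceeds this floor; the package reports exact values and the
annotation rather than matching the quoted figure.

**Dispatch.** `compareGroups()` maps the declared design onto the
standard tests (Mann-Whitney, Kruskal-Wallis + Dunn, exact Wilcoxon
signed rank, Friedman, Scheirer-Ray-Hare); Shapiro-Wilk normality is
reported for information only — the nonparametric branch is always the one
run, mirroring the study's analysis plan. `pcaSummary()` performs
correlation-matrix PCA (constant features dropped with a warning) and
reports variance shares, e.g. the share explained by the first two
components of the CD8+CD57+ NK-receptor profile.

## The pipeline and its interface

`runPipeline()` chains simulate -> gate -> classify -> serology -> HLA ->
statistics and emits demographics, T-LGL summary, HLA scan and serology
tables plus a classification manifest; with `outDir` set, every artifact
carries the seed and a config checksum in its header, and a rerun with the
same seed is byte-identical (tested). The package's interface is its
functions and this vignette; configuration is an R list
(`cohortConfig()`) with every fixed constant of the analysis (3%, 1.5,
2%, the 99th percentile, the 183-day window, bead concentration) surfaced
as data rather than code. The event-table interchange format is plain CSV
(one header row of channel names plus an `is_bead` column); the binary
FCS container is intentionally out of scope.

## Problem sizes and numerical choices

Unit tests run on cohorts of 12/10/8 donors at 4,000 events per sample,
where binomial feature noise is still small relative to the planted group
contrasts; planted-recovery tests use 3-binomial-SE bands. The end-to-end
recovery check and the acceptance script use the full default cohort
(56/51/34 donors, 50,000 events). With 34 HIGH donors and logit-scale
sigma 0.333, the sampling 95% band for the group median expansion is
roughly 8.0-10.4%, which is the tolerance the end-to-end test asserts;
simulation calibrations use 10,000 replicates with fixed seeds and
1.5-Monte-Carlo-SE bands. Ties in rank tests are handled by mid-ranks
plus the explicit tie factors above; exact signed-rank p-values are used
whenever there are no ties and n < 50.

## Known limitations

* Fluorescence realism is limited to well-separated log-normal mixtures;
  gating accuracy claims (>= 99% truth agreement) hold at the default
  10-fold separation and degrade if components overlap.
* Absolute counts are calibrated only up to the configured bead constant.
* The generator plants stable group membership; it cannot exercise
  re-classification dynamics across visits.
* The HLA model draws alleles independently within and across loci — no
  Hardy-Weinberg deviation, linkage disequilibrium or haplotype structure.
* Demographics are generated for reporting realism, not calibrated joint
  distributions; only the marginal medians and proportions match the
  published cohort.
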