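## ---------------------------------------------------------------------------
## Synthetic cohort generator: donor-level planted parameters, event-level
## cytometry for three staining panels, longitudinal visits, HLA genotypes
## and ELISA plates. Ground truth is retained at both the donor level
## (planted fractions, columns p_*) and the event level (CytoSample@truth).
## ---------------------------------------------------------------------------

## Default per-group distribution of donor-level positive fractions.
## Distributions are logit-normal (fractions) or log-normal (ratios,
## concentrations). The %CD8+CD57+ of lymphocytes is calibrated from the
## published group median and 95th percentile (HC 1.10/3.0, LOW 1.23/2.4,
## HIGH 9.12/14.8, in percent); the remaining medians are chosen to emulate
## the published group contrasts (see the methods vignette).
.profileRow <- function(param, dist, hc, low, high, sigma) {
  data.frame(param = param, dist = dist,
             group = c("HC", "LOW", "HIGH"),
             median = c(hc, low, high),
             sigma = rep_len(sigma, 3L))
}

markerProfileDefaults <- function() {
  sig57 <- c(
    logitnormFromQuantiles(0.0110, 0.030)[["scale"]],
    logitnormFromQuantiles(0.0123, 0.024)[["scale"]],
    logitnormFromQuantiles(0.0912, 0.148)[["scale"]])
  rbind(
    .profileRow("frac_cd8cd57",   "logitnorm", 0.0110, 0.0123, 0.0912, sig57),
    .profileRow("cd4cd8_ratio",   "lognorm",   2.8,    2.2,    1.0,    c(0.55, 0.50, 0.35)),
    .profileRow("lymph_conc_uL",  "lognorm",   980,    880,    1240,   0.5),
    .profileRow("t_frac",         "logitnorm", 0.58,   0.58,   0.58,   0.30),
    .profileRow("gd_frac_of_t",   "logitnorm", 0.05,   0.05,   0.05,   0.40),
    .profileRow("cd57_in_cd4",    "logitnorm", 0.020,  0.020,  0.060,  0.5),
    .profileRow("cd57_in_gd",     "logitnorm", 0.10,   0.12,   0.25,   0.5),
    .profileRow("cd5dim_57pos_cd8", "logitnorm", 0.08, 0.09,   0.45,   0.5),
    .profileRow("cd94_57pos_cd8",   "logitnorm", 0.12, 0.13,   0.35,   0.5),
    .profileRow("cd56_57pos_cd8",   "logitnorm", 0.10, 0.11,   0.28,   0.5),
    .profileRow("klrg1_57pos_cd8",  "logitnorm", 0.45, 0.48,   0.80,   0.5),
    .profileRow("cd5dim_57pos_cd4", "logitnorm", 0.05, 0.05,   0.15,   0.5),
    .profileRow("cd94_57pos_cd4",   "logitnorm", 0.03, 0.03,   0.08,   0.5),
    .profileRow("cd56_57pos_cd4",   "logitnorm", 0.04, 0.04,   0.10,   0.5),
    .profileRow("klrg1_57pos_cd4",  "logitnorm", 0.12, 0.18,   0.51,   0.5),
    .profileRow("cd5dim_57pos_gd",  "logitnorm", 0.08, 0.09,   0.35,   0.5),
    .profileRow("cd94_57pos_gd",    "logitnorm", 0.15, 0.16,   0.35,   0.5),
    .profileRow("cd56_57pos_gd",    "logitnorm", 0.12, 0.13,   0.30,   0.5),
    .profileRow("klrg1_57pos_gd",   "logitnorm", 0.35, 0.40,   0.70,   0.5),
    .profileRow("klrg1_57neg_cd8",  "logitnorm", 0.12, 0.15,   0.30,   0.4),
    .profileRow("klrg1_57neg_cd4",  "logitnorm", 0.05, 0.06,   0.10,   0.4),
    .profileRow("klrg1_57neg_gd",   "logitnorm", 0.10, 0.12,   0.25,   0.4),
    .profileRow("ifng_cd8",         "logitnorm", 0.195, 0.471, 0.571,  0.4),
    .profileRow("perf_cd8",         "logitnorm", 0.178, 0.283, 0.546,  0.4),
    .profileRow("dual_cd8",         "logitnorm", 0.120, 0.220, 0.450,  0.4),
    .profileRow("ifng_cd4",         "logitnorm", 0.073, 0.118, 0.176,  0.4),
    .profileRow("perf_cd4",         "logitnorm", 0.0222, 0.021, 0.069, 0.4),
    .profileRow("dual_cd4",         "logitnorm", 0.015, 0.015,  0.050, 0.4),
    .profileRow("ra_frac_cd8",      "logitnorm", 0.50,  0.50,   0.50,  0.3),
    .profileRow("ra_frac_cd4",      "logitnorm", 0.45,  0.45,   0.45,  0.3),
    .profileRow("ki67_cd8_57n_k1n", "logitnorm", 0.025, 0.030,  0.0405, 0.3),
    .profileRow("ki67_cd8_57n_k1p", "logitnorm", 0.020, 0.025,  0.030,  0.3),
    .profileRow("ki67_cd8_57p_k1p", "logitnorm", 0.018, 0.020,  0.0218, 0.3))
}

## Two-component log-normal fluorescence model per marker channel; CD5 is
## three-state (neg / dim / bright) to support CD5 downregulation. Default
## 10-fold separation between component medians.
fluorModelDefaults <- function() {
  two <- function(neg = 50, fold = 10, sdlog = 0.3)
    list(meanlogs = log(c(neg = neg, pos = neg * fold)), sdlog = sdlog)
  list(
    CD3    = two(), CD4 = two(), CD8 = two(), TCRab = two(),
    CD56   = two(), CD57 = two(), CD94 = two(), KLRG1 = two(),
    CD45RA = two(), IFNg = two(), Perforin = two(), Ki67 = two(),
    CD5    = list(meanlogs = log(c(neg = 50, dim = 500, bright = 5000)),
                  sdlog = 0.3),
    scatter = list(lymph_fsc = c(1.0e5, 1.2e4), lymph_ssc = c(5.0e4, 8.0e3),
                   debris_fsc = c(3.5e4, 8e3),  debris_ssc = c(1.2e5, 2.0e4),
                   bead_fsc  = c(2.0e4, 1.0e3), bead_ssc  = c(1.0e4, 8.0e2)),
    bead_meanlog = log(8000), bead_sdlog = 0.05)
}

#' Default HLA allele model calibrated to the published group frequencies
#'
#' Reads the per-group G-group allele frequency table shipped with the
#' package (class I and II alleles with printed frequencies in the HIGH and
#' LOW patient groups) and adds, per locus, a pooled `<locus>*other` allele
#' absorbing the remaining frequency mass, so that two alleles can be drawn
#' per patient per locus.
#'
#' @return `data.frame` with columns `locus`, `allele`, `freq_high`,
#'   `freq_low` (fractions summing to 1 within each locus and group).
#' @export
hlaModelDefaults <- function() {
  path <- system.file("extdata", "hla_group_frequencies.csv",
                      package = "lglpheno", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref$freq_high <- ref$pct_high / 100
  ref$freq_low <- ref$pct_low / 100
  out <- do.call(rbind, lapply(split(ref, ref$locus), function(d) {
    filler <- data.frame(locus = d$locus[1],
                         allele = paste0(d$locus[1], "*other"),
                         freq_high = max(0, 1 - sum(d$freq_high)),
                         freq_low = max(0, 1 - sum(d$freq_low)))
    rbind(d[c("locus", "allele", "freq_high", "freq_low")], filler)
  }))
  rownames(out) <- NULL
  out
}

serologyModelDefaults <- function() {
  list(isotypes = c("panIgGMA", "IgG", "IgM", "IgA"),
       # planted seropositive probability per group (HIGH 13/34, LOW 16/51)
       seropos_prob = c(HC = 0.01, LOW = 16 / 51, HIGH = 13 / 34),
       # fold-change distributions (log scale): seronegative centred on the
       # healthy pool; seropositive strongly shifted on panIgGMA / IgG
       neg_meanlog = 0, neg_sdlog = 0.35,
       pos_meanlog = log(6), pos_sdlog = 0.4,
       minor_isotype_pos_prob = 0.3,   # IgM / IgA elevated in some positives
       pool_adj_od = 0.45, blank_od = 0.05, duplicate_cv = 0.05,
       n_reference = 190)
}

demographicsDefaults <- function() {
  list(age_hc = c(mean = 68, sd = 9, min = 45, max = 90),
       onset_age = c(LOW = 60, HIGH = 64.5), onset_sd = 8,
       duration_median = c(LOW = 8, HIGH = 11), duration_sdlog = 0.6,
       male_prob = c(HC = 27 / 56, LOW = 47 / 85, HIGH = 47 / 85),
       mobility_prob = c(HC = 0, LOW = 0.38, HIGH = 0.75))
}

#' Generator configuration for a synthetic T-LGL cytometry cohort
#'
#' Builds the full configuration consumed by [simulateCohort()]. Defaults
#' are calibrated to the published cohort: group sizes 56 healthy controls
#' (HC), 51 T-LGL_LOW and 34 T-LGL_HIGH patients; per-group %CD8+CD57+
#' distributions matching the published medians and 95th percentiles; two
#' visits separated by 210-960 days; HLA allele frequencies per group from
#' the shipped reference table; and ELISA seropositive probabilities of
#' 13/34 (HIGH) and 16/51 (LOW).
#'
#' @param group_sizes named integer vector (`HC`, `LOW`, `HIGH`).
#' @param events_surface non-bead events per surface-panel sample.
#' @param events_other non-bead events per intracellular / Ki67 sample.
#' @param beads_per_uL count-bead concentration (beads per microliter).
#' @param marker_profile per group x parameter distribution table, columns
#'   `param`, `dist` (`"logitnorm"` or `"lognorm"`), `group`, `median`,
#'   `sigma`; see [markerProfileDefaults()].
#' @param fluor_model per-channel fluorescence mixture parameters.
#' @param visit_model list with `n_visits` and `gap_days` (uniform range).
#' @param hla_model per-locus allele frequency table, see
#'   [hlaModelDefaults()].
#' @param serology_model ELISA generator parameters.
#' @param demographics demographic generator parameters.
#' @return a validated configuration list of class `lgl_config`.
#' @examples
#' cfg <- cohortConfig(group_sizes = c(HC = 5, LOW = 4, HIGH = 3),
#'                     events_surface = 2000)
#' @export
cohortConfig <- function(group_sizes = c(HC = 56, LOW = 51, HIGH = 34),
                         events_surface = 50000,
                         events_other = 20000,
                         beads_per_uL = 50,
                         marker_profile = markerProfileDefaults(),
                         fluor_model = fluorModelDefaults(),
                         visit_model = list(n_visits = 2L,
                                            gap_days = c(210, 960)),
                         hla_model = hlaModelDefaults(),
                         serology_model = serologyModelDefaults(),
                         demographics = demographicsDefaults()) {
  cfg <- list(group_sizes = group_sizes, events_surface = events_surface,
              events_other = events_other, beads_per_uL = beads_per_uL,
              marker_profile = marker_profile, fluor_model = fluor_model,
              visit_model = visit_model, hla_model = hla_model,
              serology_model = serology_model, demographics = demographics)
  validateConfig(cfg)
  class(cfg) <- c("lgl_config", "list")
  cfg
}

#' Validate a generator configuration
#'
#' Checks group sizes, distribution parameters, per-locus allele frequency
#' conservation and probability ranges; errors name the offending field.
#'
#' @param cfg a configuration list as built by [cohortConfig()].
#' @return `TRUE` invisibly; otherwise an error naming the field.
#' @export
validateConfig <- function(cfg) {
  gs <- cfg$group_sizes
  if (!all(c("HC", "LOW", "HIGH") %in% names(gs)) || any(gs < 1))
    stop("config field 'group_sizes': must name HC, LOW, HIGH with sizes >= 1")
  mp <- cfg$marker_profile
  if (any(mp$sigma < 0))
    stop("config field 'marker_profile': sigma must be >= 0")
  if (any(mp$median < 0) ||
      any(mp$median[mp$dist == "logitnorm"] >= 1))
    stop("config field 'marker_profile': logit-normal medians must lie in [0, 1)")
  if (cfg$events_surface < 1 || cfg$events_other < 1)
    stop("config field 'events_surface'/'events_other': must be >= 1")
  if (cfg$beads_per_uL <= 0)
    stop("config field 'beads_per_uL': must be > 0")
  gaps <- cfg$visit_model$gap_days
  if (length(gaps) != 2 || gaps[1] > gaps[2] || gaps[1] < 0)
    stop("config field 'visit_model$gap_days': need an increasing range")
  hm <- cfg$hla_model
  byloc <- vapply(split(hm, hm$locus),
                  function(d) c(sum(d$freq_high), sum(d$freq_low)),
                  numeric(2))
  if (any(abs(byloc - 1) > 1e-6))
    stop("config field 'hla_model': per-locus frequencies must sum to 1")
  sp <- cfg$serology_model$seropos_prob
  if (any(sp < 0 | sp > 1))
    stop("config field 'serology_model$seropos_prob': probabilities in [0,1]")
  invisible(TRUE)
}

## one draw per donor from a (param, group) profile row
.drawParam <- function(mp, param, group, n) {
  row <- mp[mp$param == param & mp$group == group, ]
  if (nrow(row) != 1)
    stop("marker_profile is missing parameter '", param, "' for group ", group)
  if (row$dist == "lognorm")
    return(stats::rlnorm(n, log(row$median), row$sigma))
  if (row$median <= 0) return(rep(0, n))
  rlogitnorm(n, logit(row$median), row$sigma)
}

#' Simulate a complete synthetic cohort
#'
#' Draws donor-level planted parameters (group label, demographics, visit
#' dates, per-subset positive-cell fractions, lymphocyte concentration),
#' HLA genotypes for the patient groups and ELISA serology plates. Event-
#' level cytometry is *not* materialised here; call [simulateEvents()] (or
#' [gateCohort()]) which regenerates any sample deterministically from a
#' per-sample seed.
#'
#' @param config configuration from [cohortConfig()].
#' @param seed integer master seed; identical config + seed give identical
#'   cohorts (and identical downstream events).
#' @return an \linkS4class{LGLCohort}.
#' @examples
#' cohort <- simulateCohort(cohortConfig(group_sizes = c(HC = 4, LOW = 3, HIGH = 3),
#'                                       events_surface = 1000), seed = 1)
#' table(donors(cohort)$group)
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L) {
  validateConfig(config)
  seed <- as.integer(seed)
  set.seed(seed)
  gs <- config$group_sizes
  groups <- rep(c("HC", "LOW", "HIGH"), times = gs[c("HC", "LOW", "HIGH")])
  n <- length(groups)
  donorsDf <- data.frame(
    donor_id = sprintf("D%03d", seq_len(n)),
    group = groups, stringsAsFactors = FALSE)

  donorsDf <- cbind(donorsDf, .simulateDemographics(groups, config))
  vm <- config$visit_model
  donorsDf$n_visits <- as.integer(vm$n_visits)
  donorsDf$visit1_date <- as.Date("2019-01-01") +
    sample.int(365L, n, replace = TRUE)
  donorsDf$visit_gap_days <- round(stats::runif(n, vm$gap_days[1],
                                                vm$gap_days[2]))

  mp <- config$marker_profile
  for (param in unique(mp$param)) {
    col <- paste0("p_", param)
    donorsDf[[col]] <- NA_real_
    for (g in c("HC", "LOW", "HIGH")) {
      idx <- groups == g
      donorsDf[[col]][idx] <- .drawParam(mp, param, g, sum(idx))
    }
  }
  donorsDf$serostatus_true <- stats::rbinom(
    n, 1, config$serology_model$seropos_prob[groups]) == 1

  genotypesDf <- .simulateGenotypes(donorsDf, config)
  serologyDf <- .simulateSerology(donorsDf, config)

  methods::new("LGLCohort", donors = donorsDf, genotypes = genotypesDf,
               serology = serologyDf, config = unclass(config), seed = seed)
}

.simulateDemographics <- function(groups, config) {
  d <- config$demographics
  n <- length(groups)
  onset <- dur <- rep(NA_real_, n)
  age <- rep(NA_real_, n)
  hc <- groups == "HC"
  age[hc] <- pmin(pmax(round(stats::rnorm(sum(hc), d$age_hc["mean"],
                                          d$age_hc["sd"])),
                       d$age_hc["min"]), d$age_hc["max"])
  for (g in c("LOW", "HIGH")) {
    idx <- groups == g
    onset[idx] <- round(stats::rnorm(sum(idx), d$onset_age[g], d$onset_sd))
    dur[idx] <- round(stats::rlnorm(sum(idx), log(d$duration_median[g]),
                                    d$duration_sdlog), 1)
    age[idx] <- pmin(round(onset[idx] + dur[idx]), 96)
  }
  sex <- ifelse(stats::rbinom(n, 1, d$male_prob[groups]) == 1, "M", "F")
  aids <- c("stick", "frame", "wheelchair")
  mob <- ifelse(stats::rbinom(n, 1, d$mobility_prob[groups]) == 1,
                sample(aids, n, replace = TRUE), "none")
  data.frame(age = age, sex = sex, onset_age = onset,
             symptom_duration = dur, mobility_aid = mob,
             stringsAsFactors = FALSE)
}

.simulateGenotypes <- function(donorsDf, config) {
  hm <- config$hla_model
  pat <- donorsDf[donorsDf$group %in% c("LOW", "HIGH"), ]
  if (!nrow(pat)) return(data.frame())
  out <- vector("list", length(unique(hm$locus)))
  loci <- unique(hm$locus)
  for (j in seq_along(loci)) {
    d <- hm[hm$locus == loci[j], ]
    freqs <- cbind(LOW = d$freq_low, HIGH = d$freq_high)
    a1 <- a2 <- character(nrow(pat))
    for (i in seq_len(nrow(pat))) {
      f <- freqs[, pat$group[i]]
      picks <- sample(d$allele, 2L, replace = TRUE, prob = f)
      a1[i] <- picks[1]; a2[i] <- picks[2]
    }
    out[[j]] <- data.frame(patient_id = pat$donor_id, group = pat$group,
                           locus = loci[j], allele1 = a1, allele2 = a2,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.simulateSerology <- function(donorsDf, config) {
  sm <- config$serology_model
  iso <- sm$isotypes
  rows <- list()
  mkod <- function(fc, n) {
    # duplicate wells: blank + fold-change on the adjusted-pool scale,
    # with multiplicative duplicate noise
    sm$blank_od + fc * sm$pool_adj_od *
      exp(stats::rnorm(n, 0, sm$duplicate_cv))
  }
  for (i in seq_len(nrow(donorsDf))) {
    pos <- donorsDf$serostatus_true[i]
    for (k in iso) {
      strong <- k %in% c("panIgGMA", "IgG")
      elevated <- pos && (strong ||
        stats::runif(1) < sm$minor_isotype_pos_prob)
      fc <- if (elevated)
        stats::rlnorm(1, sm$pos_meanlog, sm$pos_sdlog)
      else stats::rlnorm(1, sm$neg_meanlog, sm$neg_sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = donorsDf$donor_id[i], role = "patient",
        group = donorsDf$group[i], isotype = k, replicate = 1:2,
        od = mkod(fc, 2), stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(sm$n_reference)) {
    for (k in iso) {
      fc <- stats::rlnorm(1, sm$neg_meanlog, sm$neg_sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("REF%03d", r), role = "reference",
        group = NA_character_, isotype = k, replicate = 1:2,
        od = mkod(fc, 2), stringsAsFactors = FALSE)
    }
  }
  for (k in iso) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = "BLANK", role = "blank", group = NA_character_,
      isotype = k, replicate = 1:2,
      od = sm$blank_od * exp(stats::rnorm(2, 0, sm$duplicate_cv)),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = "POOL", role = "pool", group = NA_character_,
      isotype = k, replicate = 1:2, od = mkod(1, 2),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = "POSCTRL", role = "positive_control",
      group = NA_character_, isotype = k, replicate = 1:2,
      od = mkod(stats::rlnorm(1, sm$pos_meanlog, sm$pos_sdlog), 2),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## ---------------------------------------------------------------------------
## Event-level simulation
## ---------------------------------------------------------------------------

## donor-specific event composition over non-bead events; clamps keep the
## planted %CD8+CD57+ realisable: a large T-LGL expansion enlarges the CD8
## compartment (cells remain <= 80% CD57+ within CD8)
.donorComposition <- function(p, debrisFrac = 0.05) {
  lymph <- 1 - debrisFrac
  tfrac <- p[["p_t_frac"]]
  gd <- p[["p_gd_frac_of_t"]]
  ratio <- p[["p_cd4cd8_ratio"]]
  frac57 <- p[["p_frac_cd8cd57"]]      # of lymphocytes
  dn <- 0.02; dp <- 0.01
  cd8InAb <- (1 - dn - dp) / (1 + ratio)
  cd8OfLymph <- tfrac * (1 - gd) * cd8InAb
  need <- if (frac57 > 0) frac57 / 0.8 else 0
  if (cd8OfLymph < need) {
    cd8InAb <- min(need / max(tfrac * (1 - gd), 1e-9), 0.9 * (1 - dn - dp))
    cd8OfLymph <- tfrac * (1 - gd) * cd8InAb
    if (cd8OfLymph < need) {              # also grow the T compartment
      tfrac <- min(need / ((1 - gd) * cd8InAb), 0.95)
      cd8OfLymph <- tfrac * (1 - gd) * cd8InAb
    }
  }
  cd4InAb <- (1 - dn - dp) - cd8InAb
  cd57InCd8 <- if (cd8OfLymph > 0) min(frac57 / cd8OfLymph, 0.98) else 0
  ab <- lymph * tfrac * (1 - gd)
  comp <- c(cd4T = ab * cd4InAb, cd8T = ab * cd8InAb, dnT = ab * dn,
            dpT = ab * dp, gdT = lymph * tfrac * gd,
            nkb = lymph * (1 - tfrac), debris = debrisFrac)
  list(comp = comp / sum(comp), cd57InCd8 = cd57InCd8)
}

## intensity draw for a two-state marker channel
.fluorDraw <- function(model, positive) {
  n <- length(positive)
  meanlog <- ifelse(positive, model$meanlogs[["pos"]], model$meanlogs[["neg"]])
  stats::rlnorm(n, meanlog, model$sdlog)
}

#' Simulate event-level cytometry for one donor visit
#'
#' Regenerates the events of a single acquisition deterministically from the
#' cohort's master seed, the donor index, visit and panel. Per-event ground
#' truth (lineage and marker positivity) is carried in the returned object's
#' `truth` slot; count beads are appended with `isBead = TRUE`.
#'
#' @param cohort an \linkS4class{LGLCohort}.
#' @param donorId donor identifier from `donors(cohort)`.
#' @param visit visit index (1-based, up to `n_visits`).
#' @param panel `"surface"`, `"intracellular"` or `"ki67"`. The two
#'   stimulation panels are only acquired for the patient groups, matching
#'   the study design.
#' @param nEvents optional override of the configured non-bead event count.
#' @return a \linkS4class{CytoSample}.
#' @export
simulateEvents <- function(cohort, donorId, visit = 1L,
                           panel = c("surface", "intracellular", "ki67"),
                           nEvents = NULL) {
  panel <- match.arg(panel)
  dd <- donors(cohort)
  i <- match(donorId, dd$donor_id)
  if (is.na(i)) stop("unknown donor: ", donorId)
  if (visit > dd$n_visits[i]) stop("donor ", donorId, " has no visit ", visit)
  if (panel != "surface" && dd$group[i] == "HC")
    stop("panel '", panel, "' is only acquired for patient groups")
  cfg <- cohort@config
  nEv <- if (is.null(nEvents)) {
    if (panel == "surface") cfg$events_surface else cfg$events_other
  } else as.integer(nEvents)
  panelIdx <- match(panel, c("surface", "intracellular", "ki67"))
  set.seed(.sampleSeed(cohort@seed, i, as.integer(visit), panelIdx))
  p <- as.list(dd[i, grepl("^p_", names(dd))])
  visitDate <- dd$visit1_date[i] +
    (as.integer(visit) - 1L) * dd$visit_gap_days[i]
  sampleId <- sprintf("%s_v%d_%s", donorId, visit, panel)
  builder <- switch(panel, surface = .surfaceEvents,
                    intracellular = .intracellularEvents,
                    ki67 = .ki67Events)
  ev <- builder(p, nEv, cfg)
  nBead <- .appendBeads(p, nEv, cfg)
  mat <- rbind(ev$exprs, nBead$exprs[, colnames(ev$exprs), drop = FALSE])
  bead <- c(rep(FALSE, nrow(ev$exprs)), rep(TRUE, nrow(nBead$exprs)))
  truth <- ev$truth
  if (nrow(nBead$exprs)) {
    pad <- truth[rep(NA_integer_, nrow(nBead$exprs)), , drop = FALSE]
    truth <- rbind(truth, pad)
  }
  rownames(truth) <- NULL
  methods::new("CytoSample", sampleId = sampleId, donorId = donorId,
               visit = as.integer(visit), visitDate = visitDate,
               panel = panel, exprs = mat, isBead = bead, truth = truth)
}

.appendBeads <- function(p, nEv, cfg) {
  conc <- p[["p_lymph_conc_uL"]]
  # expected lymphocyte-gate events per bead follows from the planted
  # concentration and the configured bead concentration
  lam <- nEv * 0.95 * cfg$beads_per_uL / conc
  nBead <- stats::rpois(1, lam)
  fm <- cfg$fluor_model
  sc <- fm$scatter
  chans <- c("FSC-A", "SSC-A")
  mat <- cbind(`FSC-A` = stats::rnorm(nBead, sc$bead_fsc[1], sc$bead_fsc[2]),
               `SSC-A` = stats::rnorm(nBead, sc$bead_ssc[1], sc$bead_ssc[2]))
  fluorChans <- setdiff(
    c("CD3", "CD4", "CD5", "CD8", "CD56", "CD57", "CD94", "TCRab", "KLRG1",
      "CD45RA", "IFNg", "Perforin", "Ki67"), character(0))
  for (ch in fluorChans)
    mat <- cbind(mat, stats::rlnorm(nBead, fm$bead_meanlog, fm$bead_sdlog))
  colnames(mat) <- c(chans, fluorChans)
  mat[mat < 1] <- 1
  list(exprs = mat)
}

.scatterDraw <- function(lineage, sc) {
  n <- length(lineage)
  debris <- lineage == "debris"
  fsc <- ifelse(debris, stats::rnorm(n, sc$debris_fsc[1], sc$debris_fsc[2]),
                stats::rnorm(n, sc$lymph_fsc[1], sc$lymph_fsc[2]))
  ssc <- ifelse(debris, stats::rnorm(n, sc$debris_ssc[1], sc$debris_ssc[2]),
                stats::rnorm(n, sc$lymph_ssc[1], sc$lymph_ssc[2]))
  cbind(`FSC-A` = pmax(fsc, 1), `SSC-A` = pmax(ssc, 1))
}

.surfaceEvents <- function(p, nEv, cfg) {
  fm <- cfg$fluor_model
  dc <- .donorComposition(p)
  lineage <- sample(names(dc$comp), nEv, replace = TRUE, prob = dc$comp)
  isT <- lineage %in% c("cd4T", "cd8T", "dnT", "dpT", "gdT")
  isAb <- lineage %in% c("cd4T", "cd8T", "dnT", "dpT")

  p57 <- c(cd4T = p[["p_cd57_in_cd4"]], cd8T = dc$cd57InCd8,
           dnT = 0.05, dpT = 0.05, gdT = p[["p_cd57_in_gd"]],
           nkb = 0.20, debris = 0.01)
  # when all positivity is switched off (zero-fraction configs), background
  # subsets go dark too
  if (p[["p_frac_cd8cd57"]] == 0 && p[["p_cd57_in_cd4"]] == 0 &&
      p[["p_cd57_in_gd"]] == 0)
    p57[] <- 0
  cd57 <- stats::rbinom(nEv, 1, p57[lineage]) == 1

  subsetOf <- function(l) switch(l, cd4T = "cd4", cd8T = "cd8", gdT = "gd", NA)
  condProb <- function(marker, lineage, cd57) {
    # per-event probability of an NK-receptor marker given subset and CD57
    pr <- numeric(length(lineage))
    for (l in c("cd4T", "cd8T", "gdT")) {
      s <- subsetOf(l)
      posKey <- paste0("p_", marker, "_57pos_", s)
      idx <- lineage == l
      if (marker == "klrg1") {
        negKey <- paste0("p_klrg1_57neg_", s)
        pr[idx] <- ifelse(cd57[idx], p[[posKey]], p[[negKey]])
      } else {
        base <- if (p[[posKey]] == 0) 0 else 0.03
        pr[idx] <- ifelse(cd57[idx], p[[posKey]], base)
      }
    }
    bg <- switch(marker, cd56 = 0.8, cd94 = 0.3, klrg1 = 0.2, cd5dim = 0)
    if (p[["p_frac_cd8cd57"]] == 0) bg <- 0   # zero-fraction configs
    pr[lineage == "nkb"] <- bg
    pr[lineage %in% c("dnT", "dpT")] <- if (p[["p_frac_cd8cd57"]] == 0) 0 else 0.05
    pr
  }
  cd5dim <- stats::rbinom(nEv, 1, condProb("cd5dim", lineage, cd57)) == 1
  cd94 <- stats::rbinom(nEv, 1, condProb("cd94", lineage, cd57)) == 1
  cd56 <- stats::rbinom(nEv, 1, condProb("cd56", lineage, cd57)) == 1
  klrg1 <- stats::rbinom(nEv, 1, condProb("klrg1", lineage, cd57)) == 1

  cd5state <- ifelse(!isT, "neg", ifelse(cd5dim, "dim", "bright"))
  cd5ml <- fm$CD5$meanlogs[cd5state]

  mat <- cbind(
    .scatterDraw(lineage, fm$scatter),
    CD3 = .fluorDraw(fm$CD3, isT),
    CD4 = .fluorDraw(fm$CD4, lineage %in% c("cd4T", "dpT")),
    CD5 = stats::rlnorm(nEv, cd5ml, fm$CD5$sdlog),
    CD8 = .fluorDraw(fm$CD8, lineage %in% c("cd8T", "dpT")),
    CD56 = .fluorDraw(fm$CD56, cd56),
    CD57 = .fluorDraw(fm$CD57, cd57),
    CD94 = .fluorDraw(fm$CD94, cd94),
    TCRab = .fluorDraw(fm$TCRab, isAb),
    KLRG1 = .fluorDraw(fm$KLRG1, klrg1))
  truth <- data.frame(lineage = lineage, is_lymph = lineage != "debris",
                      cd57 = cd57, cd5state = cd5state, cd94 = cd94,
                      cd56 = cd56, klrg1 = klrg1, stringsAsFactors = FALSE)
  list(exprs = mat, truth = truth)
}

.intracellularEvents <- function(p, nEv, cfg) {
  fm <- cfg$fluor_model
  dc <- .donorComposition(p)
  lineage <- sample(names(dc$comp), nEv, replace = TRUE, prob = dc$comp)
  isT <- lineage %in% c("cd4T", "cd8T", "dnT", "dpT", "gdT")

  ra <- ifng <- perf <- rep(FALSE, nEv)
  clamp <- function(x) pmin(pmax(x, 0), 0.95)
  for (s in c("cd4", "cd8")) {
    l <- paste0(s, "T")
    idx <- lineage == l
    if (!any(idx)) next
    pra <- p[[paste0("p_ra_frac_", s)]]
    ra[idx] <- stats::rbinom(sum(idx), 1, pra) == 1
    # IFN-g enriched in the CD45RA- (memory) fraction, perforin in CD45RA+
    mi <- ifelse(ra[idx], 0.6, 1.4)
    mpf <- ifelse(ra[idx], 1.5, 0.5)
    pi <- clamp(p[[paste0("p_ifng_", s)]] * mi)
    pp <- clamp(p[[paste0("p_perf_", s)]] * mpf)
    pd <- pmin(clamp(p[[paste0("p_dual_", s)]] * mi * mpf),
               0.95 * pmin(pi, pp))
    perf[idx] <- stats::rbinom(sum(idx), 1, pp) == 1
    pIfng <- ifelse(perf[idx],
                    ifelse(pp > 0, pd / pp, 0),
                    ifelse(pp < 1, (pi - pd) / (1 - pp), 0))
    ifng[idx] <- stats::rbinom(sum(idx), 1, clamp(pIfng)) == 1
  }
  other <- isT & !lineage %in% c("cd4T", "cd8T")
  ra[other] <- stats::rbinom(sum(other), 1, 0.5) == 1
  ifng[other] <- stats::rbinom(sum(other), 1, 0.1) == 1
  perf[other] <- stats::rbinom(sum(other), 1, 0.1) == 1

  mat <- cbind(
    .scatterDraw(lineage, fm$scatter),
    CD3 = .fluorDraw(fm$CD3, isT),
    CD4 = .fluorDraw(fm$CD4, lineage %in% c("cd4T", "dpT")),
    CD8 = .fluorDraw(fm$CD8, lineage %in% c("cd8T", "dpT")),
    CD45RA = .fluorDraw(fm$CD45RA, ra),
    CD56 = .fluorDraw(fm$CD56, lineage == "nkb"),
    IFNg = .fluorDraw(fm$IFNg, ifng),
    Perforin = .fluorDraw(fm$Perforin, perf))
  truth <- data.frame(lineage = lineage, is_lymph = lineage != "debris",
                      cd45ra = ra, ifng = ifng, perforin = perf,
                      stringsAsFactors = FALSE)
  list(exprs = mat, truth = truth)
}

.ki67Events <- function(p, nEv, cfg) {
  fm <- cfg$fluor_model
  dc <- .donorComposition(p)
  lineage <- sample(names(dc$comp), nEv, replace = TRUE, prob = dc$comp)
  isT <- lineage %in% c("cd4T", "cd8T", "dnT", "dpT", "gdT")
  p57 <- c(cd4T = p[["p_cd57_in_cd4"]], cd8T = dc$cd57InCd8,
           dnT = 0.05, dpT = 0.05, gdT = p[["p_cd57_in_gd"]],
           nkb = 0.20, debris = 0.01)
  cd57 <- stats::rbinom(nEv, 1, p57[lineage]) == 1
  klrg1 <- rep(FALSE, nEv)
  for (l in c("cd4T", "cd8T", "gdT")) {
    s <- switch(l, cd4T = "cd4", cd8T = "cd8", gdT = "gd")
    idx <- lineage == l
    klrg1[idx] <- stats::rbinom(sum(idx), 1,
      ifelse(cd57[idx], p[[paste0("p_klrg1_57pos_", s)]],
             p[[paste0("p_klrg1_57neg_", s)]])) == 1
  }
  ki67p <- rep(0.02, nEv)
  cd8 <- lineage == "cd8T"
  ki67p[cd8 & !cd57 & !klrg1] <- p[["p_ki67_cd8_57n_k1n"]]
  ki67p[cd8 & !cd57 & klrg1] <- p[["p_ki67_cd8_57n_k1p"]]
  ki67p[cd8 & cd57 & klrg1] <- p[["p_ki67_cd8_57p_k1p"]]
  ki67 <- stats::rbinom(nEv, 1, ki67p) == 1
  mat <- cbind(
    .scatterDraw(lineage, fm$scatter),
    CD3 = .fluorDraw(fm$CD3, isT),
    CD4 = .fluorDraw(fm$CD4, lineage %in% c("cd4T", "dpT")),
    CD8 = .fluorDraw(fm$CD8, lineage %in% c("cd8T", "dpT")),
    CD57 = .fluorDraw(fm$CD57, cd57),
    KLRG1 = .fluorDraw(fm$KLRG1, klrg1),
    Ki67 = .fluorDraw(fm$Ki67, ki67))
  truth <- data.frame(lineage = lineage, is_lymph = lineage != "debris",
                      cd57 = cd57, klrg1 = klrg1, ki67 = ki67,
                      stringsAsFactors = FALSE)
  list(exprs = mat, truth = truth)
}
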