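## ---------------------------------------------------------------------------
## Multi-criteria T-LGL_HIGH / T-LGL_LOW classification:
##  c1 expansion  : %CD8+CD57+ of lymphocytes above the expansion cutoff
##  c2 ratio      : CD4:CD8 ratio below 1.5
##  c3 aberrancy  : CD5-dim frequency above its HC-referenced cutoff AND at
##                  least one other NK receptor (CD94 / CD56 / KLRG1) above
##                  its cutoff, all within CD8+CD57+ cells
##  c4 persistence: c1 and c3 both met at two visits >= 183 days apart
## A patient is T-LGL_HIGH when at least 3 determinate criteria are met.
## ---------------------------------------------------------------------------

.aberrancyFeatures <- c("pct_cd5dim_cd857", "pct_cd94_cd857",
                        "pct_cd56_cd857", "pct_klrg1_cd857")

#' Derive classification thresholds from a healthy-control cohort
#'
#' Aberrancy cutoffs are healthy-control mean + 2 x sample SD (n - 1
#' denominator) per feature. The empirical 95th percentile of each feature
#' is recorded alongside: for normally distributed features mean + 2 SD sits
#' near the 97.7th percentile, so the two summaries coincide only
#' approximately; both are reported rather than silently reconciled. The
#' expansion cutoff is the fixed 3% of lymphocytes (raised to the derived
#' mean + 2 SD should that exceed 3) under `"fixed_from_paper"` provenance,
#' or the derived value alone under `"derived_from_HC"`.
#'
#' @param hcFeatures feature `data.frame` (one row per HC donor, first
#'   visit), as produced by [gateCohort()] / [computeFeatures()].
#' @param provenance `"fixed_from_paper"` (default) or `"derived_from_HC"`.
#' @param minDonors minimum HC donors required.
#' @return a \linkS4class{ThresholdSet}.
#' @export
deriveThresholds <- function(hcFeatures, provenance = c("fixed_from_paper",
                                                        "derived_from_HC"),
                             minDonors = 10L) {
  provenance <- match.arg(provenance)
  if (nrow(hcFeatures) < minDonors)
    stop("need at least ", minDonors, " healthy-control donors, got ",
         nrow(hcFeatures))
  meanP2SD <- function(x) {
    x <- x[!is.na(x)]
    mean(x) + 2 * stats::sd(x)
  }
  ab <- vapply(.aberrancyFeatures,
               function(f) meanP2SD(hcFeatures[[f]]), numeric(1))
  q95 <- vapply(c("pct_cd8cd57_of_lymph", .aberrancyFeatures), function(f)
    unname(stats::quantile(hcFeatures[[f]], 0.95, na.rm = TRUE, type = 7)),
    numeric(1))
  derived57 <- meanP2SD(hcFeatures$pct_cd8cd57_of_lymph)
  cut57 <- if (provenance == "fixed_from_paper") max(3.0, derived57)
           else derived57
  methods::new("ThresholdSet", pctCd8Cd57Cutoff = cut57, ratioCutoff = 1.5,
               aberrancyCutoffs = ab, hcPercentile95 = q95,
               provenance = provenance, nHC = nrow(hcFeatures))
}

#' Evaluate the cross-sectional criteria (c1-c3) for one donor visit
#'
#' Strict inequalities throughout: a feature exactly equal to its cutoff
#' does not meet the criterion. A missing feature renders its criterion
#' indeterminate (`NA`), excluding it from the later n-of-m denominator.
#'
#' @param features one-row feature `data.frame` for a donor visit.
#' @param thresholds a \linkS4class{ThresholdSet}.
#' @return named logical vector `c(c1, c2, c3)` (may contain `NA`).
#' @export
evaluateCriteria <- function(features, thresholds) {
  stopifnot(nrow(features) == 1, methods::is(thresholds, "ThresholdSet"))
  gt <- function(x, cut) if (is.na(x)) NA else x > cut
  c1 <- gt(features$pct_cd8cd57_of_lymph, thresholds@pctCd8Cd57Cutoff)
  r <- features$cd4_cd8_ratio
  c2 <- if (is.na(r)) NA else r < thresholds@ratioCutoff
  ab <- thresholds@aberrancyCutoffs
  cd5 <- gt(features$pct_cd5dim_cd857, ab[["pct_cd5dim_cd857"]])
  others <- c(gt(features$pct_cd94_cd857, ab[["pct_cd94_cd857"]]),
              gt(features$pct_cd56_cd857, ab[["pct_cd56_cd857"]]),
              gt(features$pct_klrg1_cd857, ab[["pct_klrg1_cd857"]]))
  anyOther <- if (all(is.na(others))) NA else any(others, na.rm = TRUE)
  c3 <- if (is.na(cd5) || (isTRUE(cd5) && is.na(anyOther))) NA
        else cd5 && isTRUE(anyOther)
  c(c1 = c1, c2 = c2, c3 = c3)
}

#' Assess longitudinal persistence of the expansion (criterion 4)
#'
#' `TRUE` iff some pair of visits at least `windowDays` apart both satisfy
#' the expansion (c1) and aberrancy (c3) criteria; `NA` (indeterminate)
#' when no visit pair spans the window.
#'
#' @param visitFlags `data.frame` with columns `visit_date` (Date), `c1`,
#'   `c3`, time-ordered.
#' @param windowDays minimum separation, default 183 days (six months).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
assessPersistence <- function(visitFlags, windowDays = 183) {
  stopifnot(nrow(visitFlags) >= 1)
  d <- visitFlags$visit_date
  if (is.unsorted(d)) stop("visit dates must be time-ordered")
  n <- nrow(visitFlags)
  if (n < 2) return(NA)
  anyPair <- FALSE
  windowMet <- FALSE
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (as.numeric(d[j] - d[i]) >= windowDays) {
      windowMet <- TRUE
      q <- visitFlags$c1[i] & visitFlags$c3[i] &
           visitFlags$c1[j] & visitFlags$c3[j]
      if (isTRUE(q)) anyPair <- TRUE
    }
  }
  if (!windowMet) return(NA)
  anyPair
}

#' Classify a cohort into T-LGL_HIGH and T-LGL_LOW
#'
#' Evaluates c1-c3 on each patient's first visit, persistence (c4) across
#' all visits, and labels a patient `HIGH` when at least 3 of the
#' determinate criteria are met. Indeterminate criteria (e.g. persistence
#' for single-visit patients) are excluded from the count, so a
#' single-visit patient meeting c1-c3 classifies HIGH.
#'
#' @param features feature `data.frame` with one row per donor visit
#'   (columns as from [gateCohort()]); only non-HC donors are classified
#'   when a `group` column is present.
#' @param thresholds a \linkS4class{ThresholdSet}.
#' @return `data.frame` with one row per patient: criterion flags,
#'   `n_met`, `n_determinate`, `label`, plus an attribute
#'   `"criterion_counts"` summarising per-criterion prevalence.
#' @export
classifyCohort <- function(features, thresholds) {
  f <- features
  if ("group" %in% names(f)) f <- f[f$group != "HC", , drop = FALSE]
  ids <- unique(f$donor_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- f[f$donor_id == ids[k], , drop = FALSE]
    rows <- rows[order(rows$visit), , drop = FALSE]
    perVisit <- t(vapply(seq_len(nrow(rows)), function(i)
      evaluateCriteria(rows[i, , drop = FALSE], thresholds), logical(3)))
    flags <- perVisit[1, ]
    vf <- data.frame(visit_date = rows$visit_date,
                     c1 = perVisit[, "c1"], c3 = perVisit[, "c3"])
    c4 <- assessPersistence(vf)
    all4 <- c(flags, c4 = c4)
    nDet <- sum(!is.na(all4))
    nMet <- sum(all4, na.rm = TRUE)
    out[[k]] <- data.frame(
      donor_id = ids[k],
      c1 = all4[["c1"]], c2 = all4[["c2"]], c3 = all4[["c3"]], c4 = all4[["c4"]],
      n_met = nMet, n_determinate = nDet,
      label = if (nMet >= 3) "HIGH" else "LOW",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  counts <- colSums(res[c("c1", "c2", "c3", "c4")], na.rm = TRUE)
  attr(res, "criterion_counts") <- c(counts,
                                     n_high = sum(res$label == "HIGH"),
                                     n = nrow(res))
  res
}

#' Serialise a ThresholdSet to JSON (with provenance)
#'
#' @param thresholds a \linkS4class{ThresholdSet}.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
thresholdsToJson <- function(thresholds, path = NULL) {
  x <- list(pct_cd8cd57_cutoff = thresholds@pctCd8Cd57Cutoff,
            ratio_cutoff = thresholds@ratioCutoff,
            aberrancy_cutoffs = as.list(thresholds@aberrancyCutoffs),
            hc_percentile95 = as.list(thresholds@hcPercentile95),
            provenance = thresholds@provenance, n_hc = thresholds@nHC)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
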