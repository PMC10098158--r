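## ---------------------------------------------------------------------------
## Anti-cN1A ELISA processing: blank adjustment, fold change relative to a
## healthy serum pool, 99th-percentile reference cutoffs, any-isotype
## seropositivity, and the group association summary.
## ---------------------------------------------------------------------------

#' Fold change of a sample relative to the healthy serum pool
#'
#' Duplicate optical densities are averaged; the average blank is
#' subtracted from sample and pool; the fold change is the ratio of the
#' adjusted sample to the adjusted pool. A sample falling below the blank
#' floors at 0.
#'
#' @param sampleODs,blankODs,poolODs numeric vectors of duplicate ODs.
#' @return dimensionless fold change (>= 0).
#' @examples
#' foldChange(c(0.50, 0.50), c(0.05, 0.05), c(0.15, 0.15))  # 4.5
#' @export
foldChange <- function(sampleODs, blankODs, poolODs) {
  stopifnot(all(sampleODs >= 0), all(blankODs >= 0), all(poolODs >= 0))
  adjPool <- mean(poolODs) - mean(blankODs)
  if (adjPool <= 0)
    stop("adjusted pool OD is non-positive: plate invalid")
  max(0, mean(sampleODs) - mean(blankODs)) / adjPool
}

## per (sample, isotype) fold changes from a plate long-format table;
## duplicate wells with CV > 20% are flagged, not dropped
.plateFoldChanges <- function(plate, roles = "patient") {
  need <- c("sample_id", "role", "isotype", "replicate", "od")
  if (!all(need %in% names(plate)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (iso in unique(plate$isotype)) {
    p <- plate[plate$isotype == iso, ]
    blank <- p$od[p$role == "blank"]
    pool <- p$od[p$role == "pool"]
    if (!length(blank) || !length(pool))
      stop("plate is missing blank or pool wells for isotype ", iso)
    samp <- p[p$role %in% roles, ]
    for (id in unique(samp$sample_id)) {
      ods <- samp$od[samp$sample_id == id]
      cv <- if (length(ods) > 1 && mean(ods) > 0) stats::sd(ods) / mean(ods) else 0
      out[[length(out) + 1L]] <- data.frame(
        sample_id = id, isotype = iso,
        fold_change = foldChange(ods, blank, pool),
        qc_flag = cv > 0.20, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold changes for all patient samples on a plate
#'
#' @param plate long-format plate `data.frame` with columns `sample_id`,
#'   `role` (`patient`, `reference`, `blank`, `pool`,
#'   `positive_control`), `isotype`, `replicate`, `od`.
#' @return `data.frame` with `sample_id`, `isotype`, `fold_change`,
#'   `qc_flag` (duplicate CV > 20%).
#' @export
plateFoldChanges <- function(plate) .plateFoldChanges(plate, "patient")

#' Derive per-isotype seropositivity cutoffs from a healthy reference
#'
#' The cutoff per isotype is the empirical 99th percentile of the healthy
#' reference fold changes, computed by linear interpolation between order
#' statistics (R quantile type 7); the percentile definition is recorded in
#' the result for auditability.
#'
#' @param referenceFoldChanges `data.frame` with `isotype` and
#'   `fold_change` columns (e.g. from reference wells of a plate), or a
#'   numeric vector for a single isotype.
#' @param minReference minimum reference samples per isotype (error below).
#' @param prob percentile, default 0.99.
#' @return named numeric vector of cutoffs with attribute
#'   `"percentile_method"`.
#' @examples
#' deriveSerologyCutoffs(data.frame(isotype = "IgG", fold_change = 1:100))
#' @export
deriveSerologyCutoffs <- function(referenceFoldChanges, minReference = 10L,
                                  prob = 0.99) {
  if (is.numeric(referenceFoldChanges))
    referenceFoldChanges <- data.frame(isotype = "all",
                                       fold_change = referenceFoldChanges)
  sp <- split(referenceFoldChanges$fold_change, referenceFoldChanges$isotype)
  ns <- vapply(sp, length, integer(1))
  if (any(ns < minReference))
    stop("fewer than ", minReference, " reference samples for isotype(s): ",
         paste(names(ns)[ns < minReference], collapse = ", "))
  cutoffs <- vapply(sp, function(x)
    unname(stats::quantile(x, prob, type = 7)), numeric(1))
  attr(cutoffs, "percentile_method") <-
    sprintf("empirical %.0fth percentile, linear interpolation (type 7)",
            100 * prob)
  cutoffs
}

#' Call seropositivity per patient
#'
#' A patient is seropositive when the fold change of at least one isotype
#' strictly exceeds its cutoff (borderline equality is negative).
#'
#' @param foldChanges `data.frame` from [plateFoldChanges()].
#' @param cutoffs named per-isotype cutoffs from
#'   [deriveSerologyCutoffs()].
#' @return `data.frame` with one row per patient: `sample_id`,
#'   `seropositive`, per-isotype positivity columns `pos_<isotype>`.
#' @export
callSeropositivity <- function(foldChanges, cutoffs) {
  miss <- setdiff(unique(foldChanges$isotype), names(cutoffs))
  if (length(miss))
    stop("no cutoff for isotype(s): ", paste(miss, collapse = ", "))
  ids <- unique(foldChanges$sample_id)
  isos <- unique(foldChanges$isotype)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  posMat <- matrix(FALSE, length(ids), length(isos),
                   dimnames = list(ids, isos))
  for (k in seq_len(nrow(foldChanges)))
    posMat[foldChanges$sample_id[k], foldChanges$isotype[k]] <-
      foldChanges$fold_change[k] > cutoffs[[foldChanges$isotype[k]]]
  for (iso in isos) out[[paste0("pos_", iso)]] <- unname(posMat[, iso])
  out$seropositive <- apply(posMat, 1, any)
  out
}

#' Cohort seroprevalence and group association
#'
#' Per-group seropositive counts and percentages, overall prevalence, and
#' the HIGH-vs-LOW association as a sample odds ratio with a two-sided
#' Fisher exact p. An all-zero (or degenerate) table gets a
#' Haldane-Anscombe 0.5-corrected odds ratio, flagged.
#'
#' @param calls `data.frame` with `sample_id` and `seropositive`.
#' @param groups named character vector (or `data.frame` with `donor_id`
#'   and `group`) mapping patients to `HIGH` / `LOW` (HC rows allowed and
#'   summarised but excluded from the association test).
#' @return list with `by_group` (counts / percentages), `prevalence`
#'   (patients overall, percent), `odds_ratio`, `fisher_p`,
#'   `or_corrected` flag.
#' @export
seroprevalence <- function(calls, groups) {
  if (is.data.frame(groups)) {
    g <- groups$group
    names(g) <- groups$donor_id
    groups <- g
  }
  unknown <- setdiff(unique(calls$sample_id), names(groups))
  if (length(unknown))
    stop("unknown group label for: ", paste(utils::head(unknown, 3), collapse = ", "))
  grp <- groups[calls$sample_id]
  byg <- do.call(rbind, lapply(split(calls$seropositive, grp), function(x)
    data.frame(n = length(x), positive = sum(x),
               pct = 100 * mean(x))))
  pat <- grp %in% c("HIGH", "LOW")
  prev <- data.frame(n = sum(pat), positive = sum(calls$seropositive[pat]),
                     pct = 100 * mean(calls$seropositive[pat]))
  a <- sum(calls$seropositive[grp == "HIGH"])
  n1 <- sum(grp == "HIGH")
  b <- sum(calls$seropositive[grp == "LOW"])
  n2 <- sum(grp == "LOW")
  assoc <- carriageOddsRatio(a, n1, b, n2)
  list(by_group = byg, prevalence = prev, odds_ratio = assoc$odds_ratio,
       fisher_p = assoc$fisher_p, or_corrected = assoc$corrected)
}
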