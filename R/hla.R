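## ---------------------------------------------------------------------------
## HLA carriage association scan: allele frequencies from occurrence counts,
## minor-allele filtering, carriage odds ratios with exact tests.
## ---------------------------------------------------------------------------

#' Allele frequency from an occurrence count
#'
#' Each patient carries two alleles per locus, so the frequency of an
#' allele is its occurrence count divided by twice the number of typed
#' patients.
#'
#' @param n allele occurrence count (0 <= n <= 2 * nPatients).
#' @param nPatients number of patients typed at the locus.
#' @return allele frequency as a fraction.
#' @examples
#' alleleFrequency(7, 29)   # 0.1207 -> "12.07%"
#' alleleFrequency(10, 72)  # 0.0694 -> "6.94%"
#' @export
alleleFrequency <- function(n, nPatients) {
  if (any(n < 0) || any(n > 2 * nPatients))
    stop("occurrence count out of range [0, 2 * nPatients]")
  n / (2 * nPatients)
}

#' Filter minor alleles by total frequency
#'
#' Retains alleles whose overall frequency strictly exceeds the threshold
#' (default 2%). For reporting, a display rule can additionally require at
#' least 5% frequency in either group.
#'
#' @param stats `data.frame` with a `freq_total` column (and `freq_high`,
#'   `freq_low` when `displayRule = TRUE`).
#' @param threshold retention threshold on total frequency, default 0.02.
#' @param displayRule also require `freq_high >= 0.05 | freq_low >= 0.05`.
#' @return the filtered `data.frame`.
#' @export
filterMinorAlleles <- function(stats, threshold = 0.02, displayRule = FALSE) {
  keep <- stats$freq_total > threshold
  if (displayRule)
    keep <- keep & (stats$freq_high >= 0.05 | stats$freq_low >= 0.05)
  stats[keep, , drop = FALSE]
}

#' Carriage odds ratio and Fisher exact test for a 2x2 table
#'
#' Carriage counts patients with at least one copy of the allele. The odds
#' ratio is the sample cross-product
#' `(a / (n1 - a)) / (b / (n2 - b))`; the p-value is the two-sided
#' conditional hypergeometric exact test on the carriage table. When a cell
#' is zero the odds ratio uses the Haldane-Anscombe 0.5 correction and is
#' flagged; the exact p never needs correction. The reported interval
#' upper bound is the upper limit of the 90% exact conditional interval
#' (so its upper end sits at the 95th percentile).
#'
#' @param carriersHigh,nHigh carriers and group size in the HIGH group.
#' @param carriersLow,nLow carriers and group size in the LOW group.
#' @param ci compute the exact conditional interval upper bound (skippable
#'   in bulk screens where only OR and p are needed).
#' @return list with `odds_ratio`, `ci_upper`, `fisher_p`, `corrected`.
#' @examples
#' carriageOddsRatio(7, 29, 3, 43)   # OR 4.24
#' carriageOddsRatio(10, 29, 7, 43)  # OR 2.71
#' @export
carriageOddsRatio <- function(carriersHigh, nHigh, carriersLow, nLow,
                              ci = TRUE) {
  if (nHigh <= 0 || nLow <= 0) stop("group sizes must be positive")
  if (carriersHigh > nHigh || carriersLow > nLow)
    stop("carriers cannot exceed group size")
  a <- carriersHigh; b <- nHigh - carriersHigh
  c_ <- carriersLow; d <- nLow - carriersLow
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    or <- ((a + 0.5) / (b + 0.5)) / ((c_ + 0.5) / (d + 0.5))
  } else {
    or <- (a / b) / (c_ / d)
  }
  p <- .fisherP(a, b, c_, d)
  ciU <- if (ci) tryCatch(
    stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                       conf.level = 0.90)$conf.int[2],
    error = function(e) NA_real_) else NA_real_
  list(odds_ratio = or, ci_upper = unname(ciU), fisher_p = p,
       corrected = corrected)
}

#' Scan all alleles for association with the T-LGL_HIGH label
#'
#' Computes, for every allele across all typed loci: occurrence counts and
#' allele frequencies per group (denominator: 2 x patients typed at that
#' locus), carrier counts (patients with >= 1 copy), carriage odds ratio,
#' exact-interval upper bound and Fisher exact p; filters minor alleles
#' (total frequency strictly above `minFreq`); and sorts by p. Patients
#' missing a locus are excluded from that locus's denominators.
#'
#' @param genotypes `data.frame` with columns `patient_id`, `locus`,
#'   `allele1`, `allele2`.
#' @param labels named character vector (or `data.frame` with `donor_id`,
#'   `label`) assigning `HIGH` / `LOW` to every genotyped patient.
#' @param minFreq minor-allele threshold on total frequency (default 0.02).
#' @param displayRule apply the reporting rule (>= 5% in either group).
#' @return `data.frame` sorted by `fisher_p`, one row per retained allele:
#'   `allele`, `locus`, occurrence counts, frequencies, carriers, OR,
#'   `ci_upper`, `fisher_p`, `or_corrected`.
#' @export
hlaAssociationScan <- function(genotypes, labels, minFreq = 0.02,
                               displayRule = FALSE) {
  if (is.data.frame(labels)) {
    l <- labels$label
    names(l) <- labels$donor_id
    labels <- l
  }
  miss <- setdiff(unique(genotypes$patient_id), names(labels))
  if (length(miss))
    stop("no label for patient(s): ", paste(utils::head(miss, 3), collapse = ", "))
  # G-group allele strings, plus the generator's pooled '<locus>*other'
  ok <- grepl("^[A-Z0-9]+\\*([0-9]+(:[0-9]+)*[Gi]?|other)$",
              c(genotypes$allele1, genotypes$allele2))
  if (!all(ok))
    stop("malformed allele string(s), expected GENE*NN:NN[:NN][G|i]")
  rows <- list()
  for (loc in unique(genotypes$locus)) {
    g <- genotypes[genotypes$locus == loc &
                     !is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
    lab <- labels[g$patient_id]
    nH <- sum(lab == "HIGH"); nL <- sum(lab == "LOW")
    if (nH + nL == 0) next
    alleles <- unique(c(g$allele1, g$allele2))
    for (al in alleles) {
      copies <- (g$allele1 == al) + (g$allele2 == al)
      occH <- sum(copies[lab == "HIGH"]); occL <- sum(copies[lab == "LOW"])
      carH <- sum(copies[lab == "HIGH"] > 0)
      carL <- sum(copies[lab == "LOW"] > 0)
      assoc <- carriageOddsRatio(carH, nH, carL, nL)
      rows[[length(rows) + 1L]] <- data.frame(
        allele = al, locus = loc,
        n_total = occH + occL, n_high = occH, n_low = occL,
        freq_total = alleleFrequency(occH + occL, nH + nL),
        freq_high = alleleFrequency(occH, nH),
        freq_low = alleleFrequency(occL, nL),
        carriers_high = carH, n_patients_high = nH,
        carriers_low = carL, n_patients_low = nL,
        odds_ratio = assoc$odds_ratio, ci_upper = assoc$ci_upper,
        fisher_p = assoc$fisher_p, or_corrected = assoc$corrected,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- filterMinorAlleles(res, minFreq, displayRule)
  res <- res[order(res$fisher_p, -res$odds_ratio), , drop = FALSE]
  res$p_bh <- stats::p.adjust(res$fisher_p, "BH")
  rownames(res) <- NULL
  res
}
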