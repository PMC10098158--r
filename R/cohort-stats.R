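## ---------------------------------------------------------------------------
## Nonparametric statistical layer: Scheirer-Ray-Hare rank factorial test,
## Dunn's post hoc with optional Bonferroni or studentized-range (Tukey)
## adjustment, design-dispatched group comparisons, PCA summary and the
## paired blood/muscle comparison.
## ---------------------------------------------------------------------------

## sum of (t^3 - t) over tie groups of the rank vector's source values
.tieTerm <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Scheirer-Ray-Hare rank factorial test
#'
#' Rank-based extension of the Kruskal-Wallis test to a two-factor design.
#' All N observations are ranked together (mid-ranks for ties); factorial
#' ANOVA sums of squares are computed on the ranks; each term's H statistic
#' is its SS divided by the no-tie total mean square N(N+1)/12 and by the
#' tie-correction factor 1 - sum(t^3 - t)/(N^3 - N); p-values come from the
#' chi-square distribution with the term's ANOVA degrees of freedom. With a
#' single-level second factor the first factor's H reduces exactly to the
#' tie-corrected Kruskal-Wallis H.
#'
#' @param values numeric response.
#' @param factorA,factorB factors (coerced); `NA` rows dropped listwise.
#' @return object of class `srh_result`: list with `H`, `df`, `p` (each
#'   named `A`, `B`, `interaction`), `tie_correction`, `ss` (rank sums of
#'   squares incl. `cells`, `residual`, `total`), `n`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(a = gl(3, 1), b = gl(2, 1), rep = 1:5)
#' scheirerRayHare(rnorm(nrow(d)), d$a, d$b)
#' @export
scheirerRayHare <- function(values, factorA, factorB) {
  keep <- !(is.na(values) | is.na(factorA) | is.na(factorB))
  values <- values[keep]
  A <- droplevels(as.factor(factorA[keep]))
  B <- droplevels(as.factor(factorB[keep]))
  N <- length(values)
  if (N < 3) stop("need at least 3 observations")
  r <- rank(values)
  D <- 1 - .tieTerm(r) / (N^3 - N)
  grand <- mean(r)
  ssOf <- function(f) {
    m <- tapply(r, f, mean)
    n <- tapply(r, f, length)
    sum(n * (m - grand)^2)
  }
  ssA <- if (nlevels(A) > 1) ssOf(A) else NA_real_
  ssB <- if (nlevels(B) > 1) ssOf(B) else NA_real_
  cellN <- table(A, B)
  completeDesign <- all(cellN > 0) && nlevels(A) > 1 && nlevels(B) > 1
  ssCells <- {
    cell <- interaction(A, B, drop = TRUE)
    ssOf(cell)
  }
  ssAB <- if (completeDesign) ssCells - ssA - ssB else NA_real_
  if (!completeDesign && nlevels(A) > 1 && nlevels(B) > 1)
    warning("empty cells: interaction term skipped")
  ssTotal <- sum((r - grand)^2)
  msTotal <- N * (N + 1) / 12
  H <- c(A = ssA, B = ssB, interaction = ssAB) / msTotal / D
  df <- c(A = nlevels(A) - 1L, B = nlevels(B) - 1L,
          interaction = (nlevels(A) - 1L) * (nlevels(B) - 1L))
  p <- ifelse(is.na(H) | df == 0, NA_real_,
              stats::pchisq(H, df, lower.tail = FALSE))
  structure(list(H = H, df = df, p = p, tie_correction = D,
                 ss = c(A = ssA, B = ssB, interaction = ssAB,
                        cells = ssCells,
                        residual = ssTotal - ssCells, total = ssTotal),
                 n = N),
            class = "srh_result")
}

#' @export
print.srh_result <- function(x, ...) {
  cat("Scheirer-Ray-Hare rank factorial test (n =", x$n,
      ", tie correction =", round(x$tie_correction, 4), ")\n")
  print(data.frame(H = x$H, df = x$df, p = x$p))
  invisible(x)
}

#' Dunn's post hoc rank comparisons
#'
#' Pairwise z statistics on mean ranks after a joint ranking of all
#' observations, with the tie-corrected variance
#' `(N(N+1)/12 - tie term) * (1/n_i + 1/n_j)`. P-values are two-sided
#' normal, optionally Bonferroni-multiplied (capped at 1) or referred to
#' the studentized range distribution (Tukey-style, on `|z| * sqrt(2)`
#' with `k` groups).
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 levels after NA removal).
#' @param adjust `"none"`, `"bonferroni"` or `"tukey"`.
#' @return list with matrices `z` and `p` (groups x groups; `z` is
#'   antisymmetric), `mean_ranks`, and the adjustment used.
#' @export
dunnPosthoc <- function(values, groups, adjust = c("none", "bonferroni",
                                                   "tukey")) {
  adjust <- match.arg(adjust)
  keep <- !(is.na(values) | is.na(groups))
  values <- values[keep]
  g <- droplevels(as.factor(groups[keep]))
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("empty group")
  N <- length(values)
  r <- rank(values)
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tt <- .tieTerm(r) / (12 * (N - 1))
  z <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    se <- sqrt((N * (N + 1) / 12 - tt) * (1 / n[i] + 1 / n[j]))
    # se = 0 only when every observation is tied, where mean ranks agree
    z[i, j] <- if (se == 0) 0 else (mr[i] - mr[j]) / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- NA_real_
  m <- k * (k - 1) / 2
  if (adjust == "bonferroni") p <- pmin(p * m, 1)
  if (adjust == "tukey")
    p <- stats::ptukey(abs(z) * sqrt(2), k, Inf, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(z = z, p = p, mean_ranks = mr, adjust = adjust)
}

#' Design-dispatched nonparametric group comparison
#'
#' Runs the test matching the declared design on one feature of a feature
#' table: Mann-Whitney (`two_independent`), Kruskal-Wallis with Dunn's post
#' hoc (`k_independent`), exact Wilcoxon signed rank (`two_paired`),
#' Friedman with block structure (`k_paired`), or the Scheirer-Ray-Hare
#' rank factorial test (`factorial`, with `block` as the second factor).
#' Shapiro-Wilk normality is reported for information; the nonparametric
#' branch is always the one run. Missing values are excluded listwise and
#' the per-group n reported reflects the exclusion.
#'
#' @param features `data.frame`.
#' @param feature name of the response column.
#' @param groups name of the grouping column (default `"group"`).
#' @param design one of `two_independent`, `k_independent`, `two_paired`,
#'   `k_paired`, `factorial`.
#' @param block name of the pairing / blocking / second-factor column
#'   (paired and factorial designs).
#' @param posthocAdjust adjustment for Dunn's test under `k_independent`.
#' @return list: `feature`, `design`, `test`, `statistic`, `p`,
#'   `by_group` (n / median / range), `posthoc` (or `NULL`),
#'   `shapiro_p`.
#' @export
compareGroups <- function(features, feature, groups = "group",
                          design = c("two_independent", "k_independent",
                                     "two_paired", "k_paired", "factorial"),
                          block = NULL,
                          posthocAdjust = c("bonferroni", "none", "tukey")) {
  design <- match.arg(design)
  posthocAdjust <- match.arg(posthocAdjust)
  v <- features[[feature]]
  g <- as.factor(features[[groups]])
  b <- if (!is.null(block)) features[[block]] else NULL
  keep <- !(is.na(v) | is.na(g))
  if (!is.null(b)) keep <- keep & !is.na(b)
  v <- v[keep]; g <- droplevels(g[keep])
  if (!is.null(b)) b <- as.factor(b)[keep]
  byg <- do.call(rbind, lapply(split(v, g), function(x)
    data.frame(n = length(x), median = stats::median(x),
               min = suppressWarnings(min(x)),
               max = suppressWarnings(max(x)))))
  shap <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  posthoc <- NULL
  if (design == "two_independent") {
    if (nlevels(g) != 2) stop("two_independent needs exactly 2 groups")
    # normal approximation under ties is expected with percentage data
    tst <- suppressWarnings(stats::wilcox.test(v ~ g))
    test <- "Mann-Whitney U"; statistic <- unname(tst$statistic); p <- tst$p.value
  } else if (design == "k_independent") {
    tst <- stats::kruskal.test(v, g)
    test <- "Kruskal-Wallis"; statistic <- unname(tst$statistic); p <- tst$p.value
    if (nlevels(g) >= 3) posthoc <- dunnPosthoc(v, g, posthocAdjust)
  } else if (design == "two_paired") {
    if (is.null(b)) stop("two_paired needs a block column identifying pairs")
    if (nlevels(g) != 2) stop("two_paired needs exactly 2 groups")
    lv <- levels(g)
    x <- v[g == lv[1]][order(b[g == lv[1]])]
    y <- v[g == lv[2]][order(b[g == lv[2]])]
    if (length(x) != length(y)) stop("unmatched pairs in two_paired design")
    tst <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    test <- "Wilcoxon signed rank"; statistic <- unname(tst$statistic)
    p <- tst$p.value
  } else if (design == "k_paired") {
    if (is.null(b)) stop("k_paired needs a block column")
    tst <- stats::friedman.test(v, g, b)
    test <- "Friedman"; statistic <- unname(tst$statistic); p <- tst$p.value
  } else {
    if (is.null(b)) stop("factorial design needs a block (second factor) column")
    tst <- scheirerRayHare(v, g, b)
    test <- "Scheirer-Ray-Hare"; statistic <- tst$H; p <- tst$p
    posthoc <- dunnPosthoc(v, g, posthocAdjust)
  }
  list(feature = feature, design = design, test = test,
       statistic = statistic, p = p, by_group = byg, posthoc = posthoc,
       shapiro_p = shap)
}

#' PCA variance summary of an immunophenotype feature matrix
#'
#' Standardises the features (correlation-matrix PCA), dropping constant
#' features with a warning, and reports per-component variance explained,
#' the cumulative share, orthonormal loadings and scores.
#'
#' @param x numeric matrix or data.frame (samples x features); rows with
#'   `NA` are dropped.
#' @return list: `var_explained`, `cumulative`, `loadings`, `scores`,
#'   `dropped` (names of constant features).
#' @export
pcaSummary <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3 || ncol(x) < 2)
    stop("need >= 3 complete samples and >= 2 features")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(var_explained = ve, cumulative = cumsum(ve),
       loadings = pc$rotation, scores = pc$x, dropped = dropped)
}

#' Paired blood / muscle feature comparison
#'
#' For each shared feature of donor-matched blood and muscle tables,
#' computes the paired differences (muscle - blood) and the exact
#' one-tailed Wilcoxon matched-pairs signed rank p, annotated with the
#' minimum attainable exact p for the available number of non-zero pairs
#' (0.5^n one-tailed) -- essential context at the very small n typical of
#' muscle biopsies.
#'
#' @param blood,muscle feature `data.frame`s with `donor_id` columns.
#' @param features feature columns to compare (default: shared numeric
#'   columns).
#' @param alternative `"greater"` (muscle > blood, default), `"less"` or
#'   `"two.sided"`.
#' @return `data.frame`: `feature`, `n_pairs`, `n_nonzero`,
#'   `median_diff`, `p`, `min_attainable_p`.
#' @export
pairedTissueCompare <- function(blood, muscle, features = NULL,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  ids <- intersect(blood$donor_id, muscle$donor_id)
  if (!length(ids)) stop("no matched donor ids between blood and muscle")
  b <- blood[match(ids, blood$donor_id), , drop = FALSE]
  m <- muscle[match(ids, muscle$donor_id), , drop = FALSE]
  if (is.null(features)) {
    num <- vapply(blood, is.numeric, logical(1))
    features <- setdiff(intersect(names(blood)[num], names(muscle)),
                        c("visit"))
  }
  out <- lapply(features, function(f) {
    d <- m[[f]] - b[[f]]
    d <- d[!is.na(d)]
    nz <- sum(d != 0)
    p <- if (nz == 0) 1 else suppressWarnings(
      stats::wilcox.test(d[d != 0], alternative = alternative,
                         exact = TRUE)$p.value)
    minp <- if (nz == 0) 1 else
      if (alternative == "two.sided") min(1, 2 * 0.5^nz) else 0.5^nz
    data.frame(feature = f, n_pairs = length(d), n_nonzero = nz,
               median_diff = if (length(d)) stats::median(d) else NA_real_,
               p = p, min_attainable_p = minp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
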