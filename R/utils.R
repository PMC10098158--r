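## small numeric helpers shared across modules

logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

#' Calibrate a logit-normal distribution from a median and a 95th percentile
#'
#' Per-donor positive-cell fractions are modelled as logit-normal. Published
#' cohort summaries give the group median and the 95th percentile of each
#' fraction; those two quantiles identify the two parameters exactly:
#' location = logit(median), scale = (logit(q95) - logit(median)) / z_0.95.
#'
#' @param med median fraction in (0, 1).
#' @param q95 95th percentile fraction in (med, 1).
#' @return named numeric vector with elements `location` and `scale`
#'   (logit scale).
#' @examples
#' logitnormFromQuantiles(0.0912, 0.148)
#' @export
logitnormFromQuantiles <- function(med, q95) {
  stopifnot(is.numeric(med), is.numeric(q95), med > 0, med < 1,
            q95 > med, q95 < 1)
  c(location = logit(med),
    scale = (logit(q95) - logit(med)) / stats::qnorm(0.95))
}

## draw per-donor fractions from a logit-normal(location, scale)
rlogitnorm <- function(n, location, scale) {
  invlogit(stats::rnorm(n, location, scale))
}

## deterministic per-sample seed derived from the cohort seed; kept < 2^31
.sampleSeed <- function(seed, donorIdx, visit, panelIdx) {
  (seed %% 1000003L) * 2000L + donorIdx * 7L + visit * 3L + panelIdx +
    (seed %% 7919L) * 11L
}

## two-sided Fisher exact p for a 2x2 table via the conditional
## hypergeometric distribution: sum of all table probabilities not
## exceeding that of the observed table (with the customary relative
## tolerance guarding against float ties).
.fisherP <- function(a, b, c, d) {
  m <- a + b           # row-1 total (e.g. group-1 size)
  n <- c + d
  k <- a + c           # column-1 total (e.g. carriers)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  min(1, p)
}

## stop() with the calling function's message prefix kept short
.checkFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}
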