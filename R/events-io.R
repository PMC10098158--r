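#' Write and read event tables
#'
#' Event tables are written as plain CSV: one header row of channel names,
#' one row per event, plus an `is_bead` column. Values round-trip losslessly
#' at full double precision (15 significant digits). The binary FCS format
#' is not supported by this package; requesting it raises an error.
#'
#' @param sample a \linkS4class{CytoSample}.
#' @param path output file path.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly (`writeEvents`); a \linkS4class{CytoSample}
#'   (`readEvents`). Ground-truth labels are not serialised: objects read
#'   back carry an empty `truth` slot.
#' @examples
#' cohort <- simulateCohort(cohortConfig(group_sizes = c(HC = 2, LOW = 1, HIGH = 1),
#'                                       events_surface = 200), seed = 1)
#' s <- simulateEvents(cohort, "D001")
#' f <- tempfile(fileext = ".csv")
#' writeEvents(s, f)
#' s2 <- readEvents(f, panel = "surface")
#' all.equal(intensities(s), intensities(s2))
#' @export
writeEvents <- function(sample, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (format == "fcs")
    stop("FCS output is not supported; use format = \"csv\"")
  stopifnot(methods::is(sample, "CytoSample"))
  df <- as.data.frame(intensities(sample))
  if ("is_bead" %in% names(df))
    stop("channel-name collision: 'is_bead' is reserved")
  df$is_bead <- isBead(sample)
  old <- options(digits = 15); on.exit(options(old))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @param sampleId,donorId,visit,panel metadata for the reconstructed
#'   object (CSV carries only event data).
#' @export
readEvents <- function(path, sampleId = basename(path), donorId = "unknown",
                       visit = 1L, panel = c("surface", "intracellular", "ki67")) {
  panel <- match.arg(panel)
  df <- utils::read.csv(path, check.names = FALSE)
  bead <- if ("is_bead" %in% names(df)) as.logical(df$is_bead) else
    rep(FALSE, nrow(df))
  df$is_bead <- NULL
  mat <- as.matrix(df)
  if (!nrow(mat)) mat <- matrix(numeric(0), 0, ncol(df),
                                dimnames = list(NULL, names(df)))
  methods::new("CytoSample", sampleId = sampleId, donorId = donorId,
               visit = as.integer(visit), visitDate = as.Date(NA),
               panel = panel, exprs = mat, isBead = bead,
               truth = data.frame())
}
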