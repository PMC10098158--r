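#' CytoSample: event-level flow cytometry data for one sample and panel
#'
#' Holds the per-event intensity matrix for a single acquisition (one donor,
#' one visit, one staining panel), the bead indicator used for absolute
#' counting, and -- for synthetic samples -- the hidden per-event ground-truth
#' labels retained for testing.
#'
#' @slot sampleId character scalar identifying the acquisition.
#' @slot donorId character scalar.
#' @slot visit integer visit index (1-based).
#' @slot visitDate `Date` of the draw.
#' @slot panel one of `"surface"`, `"intracellular"`, `"ki67"`.
#' @slot exprs numeric matrix, events x channels, linear fluorescence units.
#' @slot isBead logical vector flagging count-bead events.
#' @slot truth `data.frame` with one row per event of hidden class labels
#'   (zero-column when unavailable, e.g. data read from disk).
#'
#' @export
setClass("CytoSample",
  representation(sampleId = "character", donorId = "character",
                 visit = "integer", visitDate = "Date", panel = "character",
                 exprs = "matrix", isBead = "logical", truth = "data.frame"),
  prototype(visit = 1L, panel = "surface",
            truth = data.frame()))

setValidity("CytoSample", function(object) {
  msg <- NULL
  if (!object@panel %in% c("surface", "intracellular", "ki67"))
    msg <- c(msg, "panel must be surface, intracellular or ki67")
  if (nrow(object@exprs) != length(object@isBead))
    msg <- c(msg, "isBead length must equal the number of events")
  if (length(object@exprs) && !all(is.finite(object@exprs)))
    msg <- c(msg, "all intensities must be finite")
  cn <- colnames(object@exprs)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "channels must be uniquely named")
  if (nrow(object@truth) && nrow(object@truth) != nrow(object@exprs))
    msg <- c(msg, "truth must have one row per event")
  if (is.null(msg)) TRUE else msg
})

#' GatingSpec: a hierarchy of one-dimensional threshold gates
#'
#' Each gate selects events on a single channel (above / below a cutpoint, or
#' inside an interval) within its parent gate; the root parent is `"root"`.
#' The hierarchy must be acyclic with every parent defined before use.
#'
#' @slot gates `data.frame` with columns `name`, `parent`, `channel`,
#'   `min`, `max` (use `-Inf`/`Inf` for one-sided gates).
#' @export
setClass("GatingSpec", representation(gates = "data.frame"))

setValidity("GatingSpec", function(object) {
  g <- object@gates
  need <- c("name", "parent", "channel", "min", "max")
  if (!all(need %in% names(g)))
    return(paste("gates must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$name)) return("gate names must be unique")
  known <- "root"
  for (i in seq_len(nrow(g))) {
    if (!g$parent[i] %in% known)
      return(sprintf("gate '%s' references undefined parent '%s' (cycle or order)",
                     g$name[i], g$parent[i]))
    known <- c(known, g$name[i])
  }
  if (any(!is.finite(g$min) & g$min != -Inf) ||
      any(!is.finite(g$max) & g$max != Inf))
    return("cutpoints must be finite or one-sided infinite")
  TRUE
})

#' ThresholdSet: classification cutoffs referenced to healthy controls
#'
#' Cutoffs driving the multi-criteria T-LGL_HIGH call: a fixed expansion
#' cutoff on %CD8+CD57+ of lymphocytes, a fixed CD4:CD8 ratio cutoff, and
#' per-feature aberrancy cutoffs (healthy-control mean + 2 x sample SD) for
#' the NK-receptor profile within CD8+CD57+ cells. Empirical HC 95th
#' percentiles are stored alongside as a diagnostic, since for skewed data
#' mean + 2 SD and the 95th percentile differ.
#'
#' @slot pctCd8Cd57Cutoff expansion cutoff, percent of lymphocytes.
#' @slot ratioCutoff CD4:CD8 ratio cutoff (criterion met below it).
#' @slot aberrancyCutoffs named numeric, upper cutoffs per aberrancy feature.
#' @slot hcPercentile95 named numeric, empirical HC 95th percentiles
#'   (diagnostic only; includes `pct_cd8cd57_of_lymph`).
#' @slot provenance `"fixed_from_paper"` or `"derived_from_HC"`.
#' @slot nHC number of healthy-control donors used.
#' @export
setClass("ThresholdSet",
  representation(pctCd8Cd57Cutoff = "numeric", ratioCutoff = "numeric",
                 aberrancyCutoffs = "numeric", hcPercentile95 = "numeric",
                 provenance = "character", nHC = "integer"),
  prototype(pctCd8Cd57Cutoff = 3, ratioCutoff = 1.5,
            provenance = "fixed_from_paper", nHC = 0L))

setValidity("ThresholdSet", function(object) {
  msg <- NULL
  if (!object@provenance %in% c("fixed_from_paper", "derived_from_HC"))
    msg <- c(msg, "provenance must be fixed_from_paper or derived_from_HC")
  if (!all(is.finite(object@aberrancyCutoffs)))
    msg <- c(msg, "aberrancy cutoffs must be finite")
  if (!is.finite(object@pctCd8Cd57Cutoff) || !is.finite(object@ratioCutoff))
    msg <- c(msg, "fixed cutoffs must be finite")
  if (is.null(msg)) TRUE else msg
})

#' LGLCohort: a simulated cohort with planted ground truth
#'
#' Container returned by [simulateCohort()]. Donor-level planted parameters
#' (group label, per-subset positive fractions, lymphocyte concentration,
#' demographics, visit dates) are stored in `donors`; event-level data are
#' *not* stored but materialised on demand by [simulateEvents()] from a
#' per-sample seed, so cohorts of realistic size stay lightweight and every
#' sample is reproducible independently of generation order.
#'
#' @slot donors `data.frame`, one row per donor, planted parameters included.
#' @slot genotypes `data.frame` of HLA G-group genotypes (IBM donors),
#'   columns `patient_id`, `group`, `locus`, `allele1`, `allele2`.
#' @slot serology `data.frame`, ELISA plate long format (see
#'   [simulateSerologyPlates()]).
#' @slot config the generator configuration list (see [cohortConfig()]).
#' @slot seed integer master seed.
#' @export
setClass("LGLCohort",
  representation(donors = "data.frame", genotypes = "data.frame",
                 serology = "data.frame", config = "list", seed = "integer"))

setValidity("LGLCohort", function(object) {
  msg <- NULL
  if (!all(c("donor_id", "group") %in% names(object@donors)))
    msg <- c(msg, "donors must carry donor_id and group")
  if (nrow(object@genotypes)) {
    cnt <- table(object@genotypes$patient_id, object@genotypes$locus)
    if (any(cnt > 1))
      msg <- c(msg, "each patient must have one genotype row (2 alleles) per locus")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CytoSample", function(object) {
  cat("CytoSample", object@sampleId, "\n",
      " panel:", object@panel, "|", nrow(object@exprs), "events (",
      sum(object@isBead), "beads ) x", ncol(object@exprs), "channels\n",
      " channels:", paste(colnames(object@exprs), collapse = ", "), "\n")
  if (ncol(object@truth))
    cat("  ground truth columns:", paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "GatingSpec", function(object) {
  cat("GatingSpec with", nrow(object@gates), "gates\n")
  print(object@gates, row.names = FALSE)
})

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet (", object@provenance, ", n HC =", object@nHC, ")\n",
      " expansion cutoff: >", object@pctCd8Cd57Cutoff, "% CD8+CD57+ of lymphocytes\n",
      " ratio cutoff:    CD4:CD8 <", object@ratioCutoff, "\n",
      " aberrancy cutoffs (HC mean + 2 SD):\n")
  print(round(object@aberrancyCutoffs, 3))
})

setMethod("show", "LGLCohort", function(object) {
  tab <- table(object@donors$group)
  cat("LGLCohort:", nrow(object@donors), "donors (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), ")\n",
      " seed:", object@seed, "| visits per donor:",
      object@config$visit_model$n_visits, "\n",
      " genotyped patients:",
      length(unique(object@genotypes$patient_id)), "\n")
})
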