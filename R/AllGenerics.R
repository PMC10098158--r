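#' Accessors for CytoSample and friends
#'
#' `intensities()` returns the events x channels matrix, `channels()` the
#' channel names, `isBead()` the bead flags, `panelType()` the panel,
#' `eventTruth()` the hidden ground-truth labels (zero-column data.frame when
#' absent), `donors()` / `genotypes()` / `serologyPlates()` the cohort
#' tables, and `gateTable()` the gate definition table of a [GatingSpec].
#'
#' @param x a \linkS4class{CytoSample}, \linkS4class{GatingSpec} or
#'   \linkS4class{LGLCohort} object.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("isBead", function(x) standardGeneric("isBead"))
#' @rdname accessors
#' @export
setGeneric("panelType", function(x) standardGeneric("panelType"))
#' @rdname accessors
#' @export
setGeneric("eventTruth", function(x) standardGeneric("eventTruth"))
#' @rdname accessors
#' @export
setGeneric("donors", function(x) standardGeneric("donors"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("serologyPlates", function(x) standardGeneric("serologyPlates"))
#' @rdname accessors
#' @export
setGeneric("gateTable", function(x) standardGeneric("gateTable"))

#' @rdname accessors
setMethod("intensities", "CytoSample", function(x) x@exprs)
#' @rdname accessors
setMethod("channels", "CytoSample", function(x) colnames(x@exprs))
#' @rdname accessors
setMethod("isBead", "CytoSample", function(x) x@isBead)
#' @rdname accessors
setMethod("panelType", "CytoSample", function(x) x@panel)
#' @rdname accessors
setMethod("eventTruth", "CytoSample", function(x) x@truth)
#' @rdname accessors
setMethod("donors", "LGLCohort", function(x) x@donors)
#' @rdname accessors
setMethod("genotypes", "LGLCohort", function(x) x@genotypes)
#' @rdname accessors
setMethod("serologyPlates", "LGLCohort", function(x) x@serology)
#' @rdname accessors
setMethod("gateTable", "GatingSpec", function(x) x@gates)
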