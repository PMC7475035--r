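#' @include AllClasses.R
NULL

#' Accessors for tandemCNV result objects
#'
#' Small accessor generics: `copyTable()` returns the per-copy truth/
#' annotation table of a [TandemRegion-class]; `regionSequence()` its
#' genome; `anrd()`, `correctedCN()` and `cnStatus()` read a
#' [CnEstimate-class]; `vstValue()` and `vstP()` read a [VstResult-class];
#' `normalizedDepth()` reads a [DepthProfile-class].
#'
#' @param x the object.
#' @return the extracted component.
#' @name accessors
#' @aliases copyTable regionSequence anrd correctedCN cnStatus vstValue
#'   vstP normalizedDepth
NULL

#' @rdname accessors
#' @export
setGeneric("copyTable", function(x) standardGeneric("copyTable"))
#' @rdname accessors
#' @export
setGeneric("regionSequence", function(x) standardGeneric("regionSequence"))
#' @rdname accessors
#' @export
setGeneric("anrd", function(x) standardGeneric("anrd"))
#' @rdname accessors
#' @export
setGeneric("correctedCN", function(x) standardGeneric("correctedCN"))
#' @rdname accessors
#' @export
setGeneric("cnStatus", function(x) standardGeneric("cnStatus"))
#' @rdname accessors
#' @export
setGeneric("vstValue", function(x) standardGeneric("vstValue"))
#' @rdname accessors
#' @export
setGeneric("vstP", function(x) standardGeneric("vstP"))
#' @rdname accessors
#' @export
setGeneric("normalizedDepth", function(x) standardGeneric("normalizedDepth"))

#' @rdname accessors
setMethod("copyTable", "TandemRegion", function(x) {
  cp <- x@copies
  data.frame(copy = cp$copy, start = BiocGenerics::start(cp),
             end = BiocGenerics::end(cp), paratype = cp$paratype,
             orfIntact = cp$orfIntact, row.names = NULL)
})

#' @rdname accessors
setMethod("regionSequence", "TandemRegion", function(x) x@genome)

#' @rdname accessors
setMethod("anrd", "CnEstimate", function(x) x@anrd)
#' @rdname accessors
setMethod("correctedCN", "CnEstimate", function(x) x@corrected)
#' @rdname accessors
setMethod("cnStatus", "CnEstimate", function(x) x@status)
#' @rdname accessors
setMethod("vstValue", "VstResult", function(x) x@vst)
#' @rdname accessors
setMethod("vstP", "VstResult", function(x) x@p)
#' @rdname accessors
setMethod("normalizedDepth", "DepthProfile", function(x) x@normalized)

setMethod("show", "TandemRegion", function(object) {
  cat("TandemRegion with", length(object@copies), "copies,",
      "genome length", length(object@genome), "nt\n")
  if (length(object@copies)) {
    cat("  paratypes:", paste(object@copies$paratype, collapse = " "), "\n")
  }
  cat("  TE insertions:", length(object@teInsertions),
      "| conversion tracts:", nrow(object@conversions), "\n")
})

setMethod("show", "SimulatedReads", function(object) {
  cat("SimulatedReads:", length(object@sequences), "reads of length",
      object@readLength, "nt\n")
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile:", length(object@raw), "bins of", object@binSize,
      "nt over", object@refLength, "nt;", object@mapped, "reads placed,",
      object@unplaced, "unplaced\n")
})

setMethod("show", "CnEstimate", function(object) {
  cat("CnEstimate (", object@method, "): ", sep = "")
  if (object@status == "ok") {
    cat("ANRD =", format(object@anrd, digits = 4), "-> rounded",
        object@rounded, "-> corrected CN", object@corrected, "\n")
  } else {
    cat("no call (", sum(object@perReference$reliable), "of",
        nrow(object@perReference), "references reliable)\n")
  }
})

setMethod("show", "VstResult", function(object) {
  cat("V_ST =", format(object@vst, digits = 4),
      "(V_T =", format(object@vT, digits = 4),
      ", V_S =", format(object@vS, digits = 4), ")")
  if (length(object@p) && !is.na(object@p))
    cat("; Monte Carlo p =", format(object@p, digits = 3),
        "over", object@nPerm, "resamples")
  cat("\n")
})
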