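#' Accessors for core classes
#'
#' `deltaT()` returns the frame interval (s); `counts()` the count matrix;
#' `nFrames()` the number of recorded frames; `speciesLabels()` the tagged
#' proteins; `spaceDim()` the total state-space dimension (sink included);
#' `effectiveRates()` the extracted `(peff, peffStar, reff)` of a fit.
#'
#' @param object the object to query.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("deltaT", function(object) standardGeneric("deltaT"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("speciesLabels", function(object) standardGeneric("speciesLabels"))
#' @rdname accessors
#' @export
setGeneric("spaceDim", function(object) standardGeneric("spaceDim"))
#' @rdname accessors
#' @export
setGeneric("effectiveRates", function(object) standardGeneric("effectiveRates"))

#' @rdname accessors
#' @export
setMethod("deltaT", "FrameSeries", function(object) object@deltaT)
#' @rdname accessors
#' @export
setMethod("deltaT", "TransitionCounts", function(object) object@deltaT)
#' @rdname accessors
#' @export
setMethod("counts", "FrameSeries", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSeries", function(object) nrow(object@counts))
#' @rdname accessors
#' @export
setMethod("speciesLabels", "FrameSeries", function(object) object@speciesLabels)
#' @rdname accessors
#' @export
setMethod("spaceDim", "FSPStateSpace", function(object) object@dim)
#' @rdname accessors
#' @export
setMethod("spaceDim", "GeneratorMatrix", function(object) object@space@dim)
#' @rdname accessors
#' @export
setMethod("spaceDim", "PropagatorMatrix", function(object) object@space@dim)
#' @rdname accessors
#' @export
setMethod("effectiveRates", "InferenceResult",
          function(object) object@effectiveRates)

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("FrameSeries: %d frames x %s, deltaT = %g s (%.2f h total)\n",
              nFrames(object), paste(object@speciesLabels, collapse = ","),
              object@deltaT, (nFrames(object) - 1) * object@deltaT / 3600))
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions; observed: %s\n",
              length(object@species), length(object@reactions),
              paste(object@observed, collapse = ",")))
})

setMethod("show", "FSPStateSpace", function(object) {
  cat(sprintf("FSPStateSpace: %s; dim = %d (incl. sink)\n",
              paste(sprintf("%s[%d]", object@axes$name, object@axes$cardinality),
                    collapse = " x "), object@dim))
})

setMethod("show", "GeneratorMatrix", function(object) {
  cat(sprintf("GeneratorMatrix: %d x %d, %d non-zeros\n", object@space@dim,
              object@space@dim, Matrix::nnzero(object@W)))
})

setMethod("show", "PropagatorMatrix", function(object) {
  cat(sprintf("PropagatorMatrix: %d x %d over %g %s\n", object@space@dim,
              object@space@dim, object@horizon, object@unit))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult [%s/%s] logLik = %.3f, converged = %s\n",
              object@model, object@circuit, object@logLik, object@convergence))
  cat("  params: ", paste(sprintf("%s=%.4g", names(object@params),
                                  object@params), collapse = ", "), "\n")
  er <- object@effectiveRates
  cat(sprintf("  effective rates (x1e-3 / s): peff=%.2f peff*=%.2f reff=%.2f\n",
              1e3 * er[["peff"]], 1e3 * er[["peffStar"]], 1e3 * er[["reff"]]))
})
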