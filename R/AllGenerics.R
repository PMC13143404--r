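#' @describeIn GMFData number of rows (cells) and columns (genes)
#' @param x a \code{GMFData}
#' @export
setMethod("dim", "GMFData", function(x) dim(x@Y))

#' Accessors for GMFData
#'
#' @param object a \code{\link{GMFData}} object.
#' @return the requested component.
#' @name gmfdata-accessors
NULL

#' @rdname gmfdata-accessors
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))
#' @rdname gmfdata-accessors
#' @export
setMethod("responses", "GMFData", function(object) object@Y)

#' @rdname gmfdata-accessors
#' @export
setGeneric("rowCovariates", function(object) standardGeneric("rowCovariates"))
#' @rdname gmfdata-accessors
#' @export
setMethod("rowCovariates", "GMFData", function(object) object@X)

#' @rdname gmfdata-accessors
#' @export
setGeneric("colCovariates", function(object) standardGeneric("colCovariates"))
#' @rdname gmfdata-accessors
#' @export
setMethod("colCovariates", "GMFData", function(object) object@Z)

#' @rdname gmfdata-accessors
#' @export
setGeneric("observedMask", function(object) standardGeneric("observedMask"))
#' @rdname gmfdata-accessors
#' @export
setMethod("observedMask", "GMFData", function(object) object@mask)

#' @rdname gmfdata-accessors
#' @export
setGeneric("priorWeights", function(object) standardGeneric("priorWeights"))
#' @rdname gmfdata-accessors
#' @export
setMethod("priorWeights", "GMFData", function(object) object@W)

#' Accessors for fitted models and parameter blocks
#'
#' \code{factorScores} returns the latent factors \code{U} (one row per
#' cell), \code{factorLoadings} the loadings \code{V} (one row per gene),
#' \code{columnCoef} the column-effect regression block \code{B},
#' \code{rowCoef} the row-effect block \code{Gamma}, and \code{dispersion}
#' the dispersion parameter \eqn{\phi}.
#'
#' @param object a \code{\link{GMFFit}} or \code{\link{GMFParams}} object.
#' @return the requested block.
#' @name gmffit-accessors
NULL

#' @rdname gmffit-accessors
#' @export
setGeneric("factorScores", function(object) standardGeneric("factorScores"))
#' @rdname gmffit-accessors
#' @export
setMethod("factorScores", "GMFParams", function(object) object@U)
#' @rdname gmffit-accessors
#' @export
setMethod("factorScores", "GMFFit", function(object) object@params@U)

#' @rdname gmffit-accessors
#' @export
setGeneric("factorLoadings", function(object) standardGeneric("factorLoadings"))
#' @rdname gmffit-accessors
#' @export
setMethod("factorLoadings", "GMFParams", function(object) object@V)
#' @rdname gmffit-accessors
#' @export
setMethod("factorLoadings", "GMFFit", function(object) object@params@V)

#' @rdname gmffit-accessors
#' @export
setGeneric("columnCoef", function(object) standardGeneric("columnCoef"))
#' @rdname gmffit-accessors
#' @export
setMethod("columnCoef", "GMFParams", function(object) object@B)
#' @rdname gmffit-accessors
#' @export
setMethod("columnCoef", "GMFFit", function(object) object@params@B)

#' @rdname gmffit-accessors
#' @export
setGeneric("rowCoef", function(object) standardGeneric("rowCoef"))
#' @rdname gmffit-accessors
#' @export
setMethod("rowCoef", "GMFParams", function(object) object@Gamma)
#' @rdname gmffit-accessors
#' @export
setMethod("rowCoef", "GMFFit", function(object) object@params@Gamma)

#' @rdname gmffit-accessors
#' @export
setGeneric("dispersion", function(object) standardGeneric("dispersion"))
#' @rdname gmffit-accessors
#' @export
setMethod("dispersion", "GMFParams", function(object) object@phi)
#' @rdname gmffit-accessors
#' @export
setMethod("dispersion", "GMFFit", function(object) object@params@phi)

#' @rdname gmffit-accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
#' @rdname gmffit-accessors
#' @export
setMethod("objectiveTrace", "GMFFit", function(object) object@trace)

#' @rdname gmffit-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname gmffit-accessors
#' @export
setMethod("isConverged", "GMFFit", function(object) object@converged)

#' @rdname gmffit-accessors
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))
#' @rdname gmffit-accessors
#' @export
setMethod("manifest", "GMFFit", function(object) object@manifest)

setMethod("show", "GMFFamily", function(object) {
  cat(sprintf("GMFFamily: %s(link = %s)\n", object@name, object@link))
  cat(sprintf("  dispersion: %s\n", object@dispersionMode))
  if (object@name == "negbin")
    cat(sprintf("  size: %s\n",
                if (is.na(object@size)) "to be estimated" else
                  format(object@size)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})

setMethod("show", "GMFData", function(object) {
  n <- nrow(object@Y); m <- ncol(object@Y)
  cat(sprintf("GMFData: %d x %d response matrix\n", n, m))
  cat(sprintf("  row covariates: %d column(s); column covariates: %d column(s)\n",
              ncol(object@X), ncol(object@Z)))
  nobs <- sum(object@mask)
  cat(sprintf("  observed entries: %d (%.1f%%)\n", nobs, 100 * nobs / (n * m)))
  invisible(NULL)
})

setMethod("show", "GMFParams", function(object) {
  cat(sprintf("GMFParams: B %dx%d, Gamma %dx%d, U %dx%d, V %dx%d, phi = %.4g\n",
              nrow(object@B), ncol(object@B),
              nrow(object@Gamma), ncol(object@Gamma),
              nrow(object@U), ncol(object@U),
              nrow(object@V), ncol(object@V), object@phi))
  invisible(NULL)
})

setMethod("show", "GMFFit", function(object) {
  cat(sprintf("GMFFit (%s): %d x %d matrix, rank %d, %s family\n",
              object@algorithm, object@dims[1], object@dims[2],
              object@rank, object@family@name))
  cat(sprintf("  penalized objective: %.6g (lambda = %g)\n",
              object@objective, object@lambda))
  cat(sprintf("  epochs: %d; converged: %s; clipping events: %g\n",
              object@epochs, object@converged, object@clipEvents))
  invisible(NULL)
})

setMethod("show", "GMFRankSelection", function(object) {
  cat("GMF rank selection over grid:", paste(object@grid, collapse = ", "), "\n")
  for (nm in names(object@best))
    cat(sprintf("  %s: rank %d\n", nm, object@best[[nm]]))
  if (nrow(object@failures))
    cat("  non-converged fits:", nrow(object@failures), "\n")
  invisible(NULL)
})
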