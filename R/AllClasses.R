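#' @import methods
NULL

#' Exponential-dispersion family descriptor
#'
#' A \code{GMFFamily} bundles everything the fitting machinery needs to know
#' about one exponential-dispersion family: the link \eqn{g} and its first two
#' derivatives, the inverse link, the variance function \eqn{\nu(\mu)} and its
#' derivative, the unit deviance, the per-entry log-likelihood (including the
#' \eqn{c(y,\phi)} constant so that information criteria are on the standard
#' likelihood scale), the dispersion handling mode, and the valid response
#' range. Objects are created with \code{\link{gmfFamily}}.
#'
#' @slot name family identifier (\code{"gaussian"}, \code{"poisson"},
#'   \code{"binomial"}, \code{"gamma"}, \code{"negbin"},
#'   \code{"quasipoisson"}).
#' @slot link link identifier (\code{"identity"}, \code{"log"},
#'   \code{"logit"}, \code{"sqrt"}, \code{"inverse"}).
#' @slot statsFamily the corresponding \code{stats::family} object, used for
#'   GLM sub-fits during initialization.
#' @slot linkFun,linkInv link and inverse link.
#' @slot linkDeriv,linkDeriv2 first and second derivatives of the link in
#'   \eqn{\mu}.
#' @slot variance,varianceDeriv variance function \eqn{\nu(\mu)} and its
#'   derivative.
#' @slot devianceFun weighted unit deviance \code{function(y, mu, w)}.
#' @slot logLikFun per-entry log-likelihood \code{function(y, mu, phi, w)}.
#' @slot initTransform link-scale transform of the raw response used by the
#'   least-squares initialization fast path.
#' @slot dispersionMode \code{"fixed"} or \code{"estimated"}.
#' @slot size negative-binomial size parameter (\code{NA} when the size is to
#'   be estimated; irrelevant for other families).
#' @slot muLower,muUpper clip bounds for the mean scale.
#' @slot responseCheck \code{function(y)} returning \code{TRUE} for responses
#'   inside the family domain.
#' @slot canSimulate whether a generative sampler exists for the family.
#' @slot flags character vector of configuration notes (e.g. a non-standard
#'   link/domain pairing), echoed into fit manifests.
#' @export
setClass("GMFFamily", representation(
  name = "character",
  link = "character",
  statsFamily = "ANY",
  linkFun = "function",
  linkInv = "function",
  linkDeriv = "function",
  linkDeriv2 = "function",
  variance = "function",
  varianceDeriv = "function",
  devianceFun = "function",
  logLikFun = "function",
  initTransform = "function",
  dispersionMode = "character",
  size = "numeric",
  muLower = "numeric",
  muUpper = "numeric",
  responseCheck = "function",
  canSimulate = "logical",
  flags = "character"
))

setValidity("GMFFamily", function(object) {
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (length(object@link) != 1L) return("'link' must be a single string")
  if (!object@dispersionMode %in% c("fixed", "estimated"))
    return("'dispersionMode' must be 'fixed' or 'estimated'")
  TRUE
})

#' Container for the observed matrix, covariates, weights and mask
#'
#' \code{GMFData} stores the \eqn{n \times m} response matrix \code{Y}
#' (cells by genes in the single-cell setting), the row-covariate matrix
#' \code{X} (\eqn{n \times p}), the column-covariate matrix \code{Z}
#' (\eqn{m \times q}), positive prior weights, an observation mask
#' (\code{TRUE} marks an observed entry) and an optional additive offset on
#' the linear-predictor scale. Masked entries of \code{Y} are never read by
#' any fitting routine; they are replaced by model-based imputations during
#' optimization. Construct with \code{\link{gmfData}}.
#'
#' @slot Y numeric response matrix.
#' @slot X,Z covariate matrices (possibly with zero columns).
#' @slot W positive prior weights, same shape as \code{Y}.
#' @slot mask logical matrix; \code{TRUE} = observed.
#' @slot offset additive offset matrix on the linear-predictor scale.
#' @export
setClass("GMFData", representation(
  Y = "matrix",
  X = "matrix",
  Z = "matrix",
  W = "matrix",
  mask = "matrix",
  offset = "matrix"
))

setValidity("GMFData", function(object) {
  n <- nrow(object@Y); m <- ncol(object@Y)
  if (nrow(object@X) != n) return("X must have one row per row of Y")
  if (nrow(object@Z) != m) return("Z must have one row per column of Y")
  if (!identical(dim(object@W), dim(object@Y)))
    return("weights must match the shape of Y")
  if (!identical(dim(object@mask), dim(object@Y)))
    return("mask must match the shape of Y")
  if (!identical(dim(object@offset), dim(object@Y)))
    return("offset must match the shape of Y")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("at least one entry must be observed")
  if (any(!is.finite(object@Y[object@mask])))
    return("observed entries of Y must be finite")
  if (any(object@W[object@mask] <= 0))
    return("prior weights must be strictly positive")
  if (ncol(object@X) > 0L && qr(object@X)$rank < ncol(object@X))
    return("X must have full column rank")
  if (ncol(object@Z) > 0L && qr(object@Z)$rank < ncol(object@Z))
    return("Z must have full column rank")
  TRUE
})

#' Parameter blocks of a generalized matrix factorization
#'
#' Holds the column-effect coefficients \code{B} (\eqn{m \times p}; row
#' \eqn{j} multiplies the row covariates \eqn{x_i}), the row-effect
#' coefficients \code{Gamma} (\eqn{n \times q}), the latent factors \code{U}
#' (\eqn{n \times d}), the loadings \code{V} (\eqn{m \times d}) and the
#' dispersion \code{phi}. The linear predictor is
#' \eqn{\eta = X B^\top + \Gamma Z^\top + U V^\top} (plus any offset).
#'
#' @slot B,Gamma,U,V numeric matrices.
#' @slot phi positive scalar dispersion.
#' @export
setClass("GMFParams", representation(
  B = "matrix",
  Gamma = "matrix",
  U = "matrix",
  V = "matrix",
  phi = "numeric"
))

setValidity("GMFParams", function(object) {
  if (ncol(object@U) != ncol(object@V))
    return("U and V must have the same number of columns")
  if (length(object@phi) != 1L || !is.finite(object@phi) || object@phi <= 0)
    return("phi must be a single positive number")
  if (any(!is.finite(object@B)) || any(!is.finite(object@Gamma)) ||
      any(!is.finite(object@U)) || any(!is.finite(object@V)))
    return("parameter blocks must be finite")
  TRUE
})

#' Result of a generalized matrix factorization fit
#'
#' Returned by \code{\link{gmfFit}}. Contains the estimated parameter blocks
#' (projected onto the requested identifiability parametrization), the final
#' penalized objective on the observed entries, the per-epoch objective
#' trace, convergence diagnostics, the count of mean-clipping events, and a
#' manifest echoing the full configuration (seeds included) so a run can be
#' reproduced exactly.
#'
#' @slot params a \code{\link{GMFParams}} object.
#' @slot family the \code{\link{GMFFamily}} used (with any estimated
#'   negative-binomial size filled in).
#' @slot rank latent dimension.
#' @slot lambda ridge penalty on the latent blocks.
#' @slot algorithm \code{"airwls"}, \code{"newton"} or \code{"sgd"}.
#' @slot objective final penalized negative log-likelihood over observed
#'   entries.
#' @slot trace data frame with per-epoch monitored objective and relative
#'   change.
#' @slot converged logical convergence flag.
#' @slot epochs number of epochs run.
#' @slot clipEvents number of mean-domain clipping events observed.
#' @slot npar effective parameter count \eqn{pm + qn + d(n+m) + 1}.
#' @slot dims response dimensions \code{c(n, m)}.
#' @slot manifest named list: configuration echo, seeds, counters.
#' @export
setClass("GMFFit", representation(
  params = "GMFParams",
  family = "GMFFamily",
  rank = "integer",
  lambda = "numeric",
  algorithm = "character",
  objective = "numeric",
  trace = "data.frame",
  converged = "logical",
  epochs = "integer",
  clipEvents = "numeric",
  npar = "numeric",
  dims = "integer",
  manifest = "list"
))

#' Rank-selection summary
#'
#' Returned by \code{\link{cvRankSelect}}: per-rank information criteria and
#' cross-validated out-of-sample errors, together with the rank chosen by
#' each criterion.
#'
#' @slot grid candidate ranks (ascending).
#' @slot aic,bic information criteria from full-data fits.
#' @slot cvDeviance folds x ranks matrix of out-of-sample relative deviances.
#' @slot cvError folds x ranks matrix of relative logarithmic RMSEs.
#' @slot best named integer vector: selected rank per criterion.
#' @slot failures data frame recording non-converged (fold, rank) cells.
#' @export
setClass("GMFRankSelection", representation(
  grid = "integer",
  aic = "numeric",
  bic = "numeric",
  cvDeviance = "matrix",
  cvError = "matrix",
  best = "integer",
  failures = "data.frame"
))
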