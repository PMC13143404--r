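#' Fit a generalized matrix factorization model
#'
#' High-level entry point: wraps structured initialization
#' (\code{\link{gmfInit}}), one of the three estimation algorithms
#' (\code{\link{fitAIRWLS}}, \code{\link{fitNewton}}, \code{\link{fitSGD}})
#' and the identifiability projection
#' (\code{\link{projectConstraints}}).
#'
#' @param data a \code{\link{GMFData}}, or a numeric matrix (converted with
#'   default intercept covariates; \code{NA} entries are treated as
#'   unobserved).
#' @param family a \code{\link{GMFFamily}}.
#' @param rank latent dimension \eqn{d \ge 0}.
#' @param lambda nonnegative ridge penalty on the latent blocks.
#' @param algorithm \code{"airwls"}, \code{"newton"} or \code{"sgd"}.
#' @param init a \code{\link{GMFParams}} warm start, or \code{NULL} to run
#'   the structured initialization.
#' @param initMethod,initResidual passed to \code{\link{gmfInit}}.
#' @param control a \code{\link{gmfControl}} list.
#' @param parametrization identifiability normalization (\code{"B1"},
#'   \code{"B2"} or \code{"B3"}).
#' @return a \code{\link{GMFFit}}.
#' @examples
#' sim <- simulateGMF(n = 40, m = 15, d = 2, seed = 1)
#' fit <- gmfFit(sim$data, gmfFamily("poisson"), rank = 2,
#'               algorithm = "newton")
#' fit
#' @export
gmfFit <- function(data, family = gmfFamily("poisson"), rank = 2L,
                   lambda = 1, algorithm = c("airwls", "newton", "sgd"),
                   init = NULL, initMethod = c("glm", "ols"),
                   initResidual = c("deviance", "pearson"),
                   control = gmfControl(),
                   parametrization = c("B1", "B2", "B3")) {
  algorithm <- match.arg(algorithm)
  parametrization <- match.arg(parametrization)
  initMethod <- match.arg(initMethod)
  initResidual <- match.arg(initResidual)
  if (!methods::is(data, "GMFData")) data <- gmfData(as.matrix(data))
  if (lambda < 0) stopf("lambda must be nonnegative")
  fallbacks <- 0L
  if (is.null(init)) {
    init <- gmfInit(data, family, rank = rank, method = initMethod,
                    residualType = initResidual)
    fallbacks <- attr(init, "fallbacks")
  } else {
    checkConformal(data, init)
    if (ncol(init@U) != rank)
      stopf("init has rank %d but rank = %d was requested", ncol(init@U),
            rank)
  }
  fit <- switch(algorithm,
    airwls = fitAIRWLS(data, init, family, lambda, control, parametrization),
    newton = fitNewton(data, init, family, lambda, control, parametrization),
    sgd = fitSGD(data, init, family, lambda, control, parametrization))
  fit@manifest$initFallbacks <- fallbacks
  fit@manifest$initMethod <- initMethod
  fit@manifest$initResidual <- initResidual
  fit
}
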