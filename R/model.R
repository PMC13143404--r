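# Linear predictor, fitted means, penalized objective and full-batch
# derivative assembly.

#' Linear predictor of a GMF model
#'
#' Computes \eqn{\eta = X B^\top + \Gamma Z^\top + U V^\top} (plus the data
#' offset), optionally restricted to a block of rows and columns; a block
#' computation touches only the corresponding rows of \code{X},
#' \code{Gamma}, \code{U} and of \code{B}, \code{Z}, \code{V}.
#'
#' @param data a \code{\link{GMFData}}.
#' @param params a \code{\link{GMFParams}}.
#' @param rows,cols optional index subsets.
#' @return the requested predictor block.
#' @export
linearPredictor <- function(data, params, rows = NULL, cols = NULL) {
  checkConformal(data, params)
  n <- nrow(data@Y); m <- ncol(data@Y)
  if (is.null(rows)) rows <- seq_len(n)
  if (is.null(cols)) cols <- seq_len(m)
  if (any(rows < 1 | rows > n) || any(cols < 1 | cols > m))
    stopf("row/column subset out of range")
  eta <- data@offset[rows, cols, drop = FALSE]
  if (ncol(data@X) > 0L)
    eta <- eta + data@X[rows, , drop = FALSE] %*%
      t(params@B[cols, , drop = FALSE])
  if (ncol(data@Z) > 0L)
    eta <- eta + params@Gamma[rows, , drop = FALSE] %*%
      t(data@Z[cols, , drop = FALSE])
  if (ncol(params@U) > 0L)
    eta <- eta + params@U[rows, , drop = FALSE] %*%
      t(params@V[cols, , drop = FALSE])
  eta
}

# Inverse link with family-domain clipping; returns the means and the count
# of clipped entries.
meanFromEta <- function(eta, family) {
  mu <- family@linkInv(eta)
  lo <- family@muLower; hi <- family@muUpper
  nclip <- sum(!is.finite(mu) | mu < lo | mu > hi)
  mu[!is.finite(mu) & eta > 0] <- hi
  mu[!is.finite(mu)] <- lo
  mu <- pmin(pmax(mu, lo), hi)
  list(mu = mu, nclip = nclip)
}

#' Fitted means of a GMF model
#'
#' Applies the inverse link to the linear predictor, clipping to the
#' family's mean domain. The same values are used to impute unobserved
#' entries during estimation.
#'
#' @inheritParams linearPredictor
#' @param family a \code{\link{GMFFamily}}.
#' @return an \eqn{n \times m} matrix of means.
#' @export
predictMean <- function(data, params, family) {
  meanFromEta(linearPredictor(data, params), family)$mu
}

#' Penalized negative log-likelihood
#'
#' \deqn{\ell_\lambda = -\sum_{(i,j) \in \Omega} \log f(y_{ij}; \mu_{ij},
#' \phi) + \tfrac{\lambda}{2} \lVert U \rVert_F^2 + \tfrac{\lambda}{2}
#' \lVert V \rVert_F^2.}
#' The sum runs over observed entries only. The response-only constant
#' \eqn{c(y, \phi)} is included, so objectives are comparable across fits of
#' the same data and AIC/BIC are on the standard likelihood scale.
#'
#' @inheritParams predictMean
#' @param lambda nonnegative ridge penalty on the latent blocks.
#' @return a finite scalar; an error is raised on divergence.
#' @export
penalizedObjective <- function(data, params, lambda, family) {
  mu <- predictMean(data, params, family)
  obs <- data@mask
  ll <- logLikMatrix(data@Y[obs], mu[obs], family, params@phi, data@W[obs])
  obj <- -sum(ll) + 0.5 * lambda * (frob2(params@U) + frob2(params@V))
  if (!is.finite(obj))
    stopf("penalized objective is not finite: the fit has diverged")
  obj
}

# Complete-data working response: observed values, model means elsewhere.
completeResponse <- function(data, mu) {
  Yw <- data@Y
  Yw[!data@mask] <- mu[!data@mask]
  Yw
}

#' Full-batch gradient and curvature blocks
#'
#' Assembles the derivatives of the penalized objective with respect to all
#' four parameter blocks from the \eqn{\eta}-scale kernels
#' (\code{\link{etaDerivatives}}):
#' \deqn{G_U = \dot D V + \lambda U, \quad G_V = \dot D^\top U + \lambda V,
#' \quad G_B = \dot D^\top X, \quad G_\Gamma = \dot D Z,}
#' with elementwise curvatures \eqn{H_U = \ddot D (V * V) + \lambda} etc.
#' Unobserved entries contribute zero gradient (their working response is
#' the current imputation \eqn{y \leftarrow \mu}); with
#' \code{fisher = TRUE} all curvature blocks are strictly positive.
#'
#' @inheritParams penalizedObjective
#' @param fisher use expected curvature.
#' @return list with components \code{GU}, \code{HU}, \code{GV}, \code{HV},
#'   \code{GB}, \code{HB}, \code{GGamma}, \code{HGamma}.
#' @export
fullGradients <- function(data, params, lambda, family, fisher = TRUE) {
  eta <- linearPredictor(data, params)
  mf <- meanFromEta(eta, family)
  mu <- mf$mu
  Yw <- completeResponse(data, mu)
  der <- etaDerivatives(Yw, mu, family, params@phi, data@W, fisher = fisher)
  D1 <- der$deta; D2 <- der$deta2
  U <- params@U; V <- params@V
  X <- data@X; Z <- data@Z
  list(
    GU = D1 %*% V + lambda * U,
    HU = D2 %*% (V * V) + lambda,
    GV = crossprod(D1, U) + lambda * V,
    HV = crossprod(D2, U * U) + lambda,
    GB = crossprod(D1, X),
    HB = crossprod(D2, X * X),
    GGamma = D1 %*% Z,
    HGamma = D2 %*% (Z * Z),
    nclip = mf$nclip
  )
}
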