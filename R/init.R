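# Structured starting values: column-wise GLMs for B, row-wise GLMs for
# Gamma, a null-residual SVD for U, column-wise GLMs for V, with an
# ordinary-least-squares fast path on a link-transformed response.

#' Structured initialization of a GMF model
#'
#' Produces starting values by the null-residual strategy:
#' \enumerate{
#'   \item fit \eqn{m} independent column GLMs of \eqn{y_{:j}} on \eqn{X}
#'     to get \eqn{\tilde B};
#'   \item fit \eqn{n} independent row GLMs of \eqn{y_{i:}} on \eqn{Z} with
#'     offset \eqn{(X \tilde B^\top)_{i:}} to get \eqn{\tilde \Gamma};
#'   \item form deviance residuals
#'     \eqn{r^D = \mathrm{sign}(y - \tilde\mu) \sqrt{D(y, \tilde\mu)}} or
#'     Pearson residuals \eqn{r^P = (y - \tilde\mu)/\sqrt{\nu(\tilde\mu)}}
#'     at the regression-only means, with masked cells set to 0 (the
#'     null-model prediction), and take the first \eqn{d} left singular
#'     vectors, scaled by the singular values, as \eqn{U};
#'   \item fit \eqn{m} column GLMs with \eqn{U} as design and the regression
#'     offset to get \eqn{V}.
#' }
#' With \code{method = "ols"} every GLM is replaced by ordinary least
#' squares on a link-transformed response (a started log,
#' \eqn{\log(y + 0.5)}, for count families), which is exact for the
#' Gaussian-identity family. A column/row GLM that fails to converge falls
#' back to the least-squares path for that fit (counted in the attribute
#' \code{"fallbacks"}).
#'
#' Unobserved entries are excluded from every regression and never read.
#'
#' @param data a \code{\link{GMFData}}.
#' @param family a \code{\link{GMFFamily}}.
#' @param rank latent dimension \eqn{d \ge 0}.
#' @param method \code{"glm"} or \code{"ols"}.
#' @param residualType \code{"deviance"} or \code{"pearson"}.
#' @param maxit,tol IRLS control for the inner GLM fits.
#' @return a \code{\link{GMFParams}} with attributes \code{"fallbacks"}
#'   (count of GLM fits that fell back to least squares) and
#'   \code{"residualSV"} (singular values of the null-residual matrix).
#' @export
gmfInit <- function(data, family, rank = 2L,
                    method = c("glm", "ols"),
                    residualType = c("deviance", "pearson"),
                    maxit = 50L, tol = 1e-8) {
  method <- match.arg(method)
  residualType <- match.arg(residualType)
  n <- nrow(data@Y); m <- ncol(data@Y)
  d <- as.integer(rank)
  if (d > min(n, m)) stopf("rank must not exceed min(n, m)")
  p <- ncol(data@X); q <- ncol(data@Z)
  fam <- family
  if (fam@name == "negbin" && is.na(fam@size))
    fam <- setFamilySize(fam, .roughNBSize(data))
  fallbacks <- 0L

  # --- stage 1: column GLMs for B ------------------------------------------
  B <- matrix(0, m, p)
  if (p > 0L) {
    for (j in seq_len(m)) {
      obs <- data@mask[, j]
      fit <- .glmColumn(data@Y[obs, j], data@X[obs, , drop = FALSE],
                        data@W[obs, j], data@offset[obs, j], fam,
                        method, maxit, tol)
      B[j, ] <- fit$coef
      fallbacks <- fallbacks + fit$fallback
    }
  }
  etaB <- data@offset + if (p > 0L) data@X %*% t(B) else 0

  # --- stage 2: row GLMs for Gamma -----------------------------------------
  Gamma <- matrix(0, n, q)
  if (q > 0L) {
    for (i in seq_len(n)) {
      obs <- data@mask[i, ]
      fit <- .glmColumn(data@Y[i, obs], data@Z[obs, , drop = FALSE],
                        data@W[i, obs], etaB[i, obs], fam,
                        method, maxit, tol)
      Gamma[i, ] <- fit$coef
      fallbacks <- fallbacks + fit$fallback
    }
  }
  etaNull <- etaB + if (q > 0L) Gamma %*% t(data@Z) else 0

  # --- stage 3: null-residual SVD for U ------------------------------------
  muNull <- meanFromEta(etaNull, fam)$mu
  R <- matrix(0, n, m)
  obs <- data@mask
  if (method == "ols") {
    R[obs] <- fam@initTransform(data@Y[obs]) - etaNull[obs]
  } else if (residualType == "deviance") {
    dev <- devianceMatrix(data@Y[obs], muNull[obs], fam, data@W[obs])
    R[obs] <- sign(data@Y[obs] - muNull[obs]) * sqrt(pmax(dev, 0))
  } else {
    R[obs] <- (data@Y[obs] - muNull[obs]) / sqrt(fam@variance(muNull[obs]))
  }
  sv <- svd(R, nu = d, nv = d)
  U <- if (d > 0L) sv$u %*% diag(sv$d[seq_len(d)], d, d) else matrix(0, n, 0)

  # --- stage 4: column GLMs for V ------------------------------------------
  V <- matrix(0, m, d)
  if (d > 0L) {
    if (method == "ols") {
      # least-squares loadings on the link-scale residual
      for (j in seq_len(m)) {
        o <- data@mask[, j]
        V[j, ] <- lsSolve(U[o, , drop = FALSE], R[o, j])
      }
    } else {
      for (j in seq_len(m)) {
        o <- data@mask[, j]
        fit <- .glmColumn(data@Y[o, j], U[o, , drop = FALSE],
                          data@W[o, j], etaNull[o, j], fam,
                          method, maxit, tol)
        V[j, ] <- fit$coef
        fallbacks <- fallbacks + fit$fallback
      }
    }
  }

  params <- gmfParams(B = B, Gamma = Gamma, U = U, V = V, phi = 1)
  mu <- predictMean(data, params, fam)
  if (fam@dispersionMode == "estimated") {
    npar <- p * m + q * n + d * (n + m)
    nobs <- sum(obs)
    params@phi <- estimateDispersion(data@Y[obs], mu[obs], fam, data@W[obs],
                                     npar = min(npar, nobs - 1))
  }
  attr(params, "fallbacks") <- fallbacks
  attr(params, "residualSV") <- sv$d
  attr(params, "residualMatrix") <- R
  attr(params, "nbSize") <- fam@size
  params
}

# One masked GLM (or least-squares) fit of y on design A with offset.
.glmColumn <- function(y, A, w, off, family, method, maxit, tol) {
  if (ncol(A) == 0L) return(list(coef = numeric(0), fallback = 0L))
  if (method == "glm" && !is.null(family@statsFamily)) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        x = A, y = y, weights = w, offset = off,
        family = family@statsFamily,
        control = stats::glm.control(epsilon = tol, maxit = maxit))),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged && all(is.finite(fit$coefficients)))
      return(list(coef = fit$coefficients, fallback = 0L))
  }
  ystar <- family@initTransform(y) - off
  cf <- tryCatch(stats::lm.wfit(x = A, y = ystar, w = w)$coefficients,
                 error = function(e) rep(0, ncol(A)))
  cf[!is.finite(cf)] <- 0
  list(coef = cf, fallback = if (method == "glm") 1L else 0L)
}

# Crude overall NB size used only to bootstrap initialization when the size
# is to be estimated: moments against column means.
.roughNBSize <- function(data) {
  obs <- data@mask
  y <- data@Y
  colMu <- vapply(seq_len(ncol(y)), function(j) {
    o <- obs[, j]
    if (any(o)) mean(y[o, j]) else NA_real_
  }, numeric(1))
  mu <- matrix(colMu, nrow(y), ncol(y), byrow = TRUE)
  estimateNBSize(y[obs], mu[obs])
}
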