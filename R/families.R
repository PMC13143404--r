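# Exponential-dispersion families: links, variance functions, deviances,
# per-entry log-likelihoods and the eta-scale derivative kernels used by all
# three fitting algorithms.

.gmfLinks <- list(
  identity = list(
    fun = function(mu) mu,
    inv = function(eta) eta,
    d1 = function(mu) rep(1, length(mu)),
    d2 = function(mu) rep(0, length(mu))
  ),
  log = list(
    fun = function(mu) log(mu),
    inv = function(eta) exp(eta),
    d1 = function(mu) 1 / mu,
    d2 = function(mu) -1 / mu^2
  ),
  logit = list(
    fun = function(mu) log(mu / (1 - mu)),
    inv = function(eta) 1 / (1 + exp(-eta)),
    d1 = function(mu) 1 / (mu * (1 - mu)),
    d2 = function(mu) (2 * mu - 1) / (mu * (1 - mu))^2
  ),
  sqrt = list(
    fun = function(mu) sqrt(mu),
    inv = function(eta) eta^2,
    d1 = function(mu) 1 / (2 * sqrt(mu)),
    d2 = function(mu) -1 / (4 * mu^1.5)
  ),
  inverse = list(
    fun = function(mu) 1 / mu,
    inv = function(eta) 1 / eta,
    d1 = function(mu) -1 / mu^2,
    d2 = function(mu) 2 / mu^3
  )
)

.canonicalLink <- c(gaussian = "identity", poisson = "log", binomial = "logit",
                    gamma = "inverse", negbin = "log", quasipoisson = "log")

# Which links keep eta unrestricted on the family's mean domain.
.naturalLinks <- list(
  gaussian = c("identity", "log", "inverse"),
  poisson = "log", quasipoisson = "log", negbin = "log",
  binomial = "logit", gamma = c("inverse", "log")
)

.EPS_MU <- 1e-10

#' Construct an exponential-dispersion family
#'
#' Builds the \code{\link{GMFFamily}} descriptor for one of the supported
#' families: \code{"gaussian"}, \code{"poisson"}, \code{"binomial"},
#' \code{"gamma"}, \code{"negbin"} (negative binomial, NB2 variance
#' \eqn{\nu(\mu) = \mu + \mu^2/\mathrm{size}}) and \code{"quasipoisson"}
#' (Poisson variance scaled by an estimated dispersion). The link defaults to
#' the family's canonical choice (log for the negative binomial, as is
#' conventional for count factor models). The Gaussian, gamma and
#' quasi-Poisson dispersions are estimated by Pearson moments during fitting;
#' the Poisson and binomial dispersions are fixed at 1.
#'
#' For positive-mean families the inverse link is clipped to
#' \eqn{[10^{-10}, 10^{10}]} (and to \eqn{[10^{-10}, 1-10^{-10}]} for the
#' binomial) to avoid overflow; clipping events are counted in fit results.
#'
#' @param name family identifier.
#' @param link optional link identifier (\code{"identity"}, \code{"log"},
#'   \code{"logit"}, \code{"sqrt"}, \code{"inverse"}); defaults to the
#'   canonical link.
#' @param size negative-binomial size parameter. If omitted for
#'   \code{"negbin"}, the size is estimated once per epoch by method of
#'   moments during fitting.
#' @return a \code{\link{GMFFamily}} object.
#' @examples
#' gmfFamily("poisson")
#' gmfFamily("negbin", size = 10)
#' @export
gmfFamily <- function(name = c("gaussian", "poisson", "binomial", "gamma",
                               "negbin", "quasipoisson"),
                      link = NULL, size = NULL) {
  name <- match.arg(name)
  if (is.null(link)) link <- unname(.canonicalLink[name])
  if (!link %in% names(.gmfLinks))
    stopf("unknown link '%s'; available: %s", link,
          paste(names(.gmfLinks), collapse = ", "))
  lk <- .gmfLinks[[link]]
  flags <- character(0)
  if (!link %in% .naturalLinks[[name]])
    flags <- c(flags, sprintf(
      "link '%s' does not map the %s mean domain onto the whole real line; predictor-scale clipping applies",
      link, name))

  sizeVal <- NA_real_
  if (name == "negbin") {
    if (is.null(size)) {
      flags <- c(flags, "negative-binomial size to be estimated by method of moments")
    } else {
      if (!is.numeric(size) || length(size) != 1L || size <= 0)
        stopf("negative-binomial 'size' must be a positive scalar")
      sizeVal <- as.numeric(size)
    }
  } else if (!is.null(size)) {
    stopf("'size' is only meaningful for the negbin family")
  }

  poisDev <- function(y, mu, w) 2 * w * (ylogy(y, mu) - (y - mu))
  def <- switch(name,
    gaussian = list(
      variance = function(mu) rep(1, length(mu)),
      varianceDeriv = function(mu) rep(0, length(mu)),
      devianceFun = function(y, mu, w) w * (y - mu)^2,
      logLikFun = function(y, mu, phi, w)
        -0.5 * w * (y - mu)^2 / phi - 0.5 * log(2 * pi * phi / w),
      initTransform = function(y) y,
      dispersionMode = "estimated",
      muLower = -1e10, muUpper = 1e10,
      responseCheck = function(y) is.finite(y),
      statsFamily = stats::gaussian(link = .statsLinkName(link, "gaussian")),
      canSimulate = TRUE
    ),
    poisson = list(
      variance = function(mu) mu,
      varianceDeriv = function(mu) rep(1, length(mu)),
      devianceFun = poisDev,
      logLikFun = function(y, mu, phi, w) w * (y * log(mu) - mu - lgamma(y + 1)),
      initTransform = function(y) log(y + 0.5),
      dispersionMode = "fixed",
      muLower = .EPS_MU, muUpper = 1e10,
      responseCheck = function(y) is.finite(y) & y >= 0,
      statsFamily = stats::poisson(link = .statsLinkName(link, "poisson")),
      canSimulate = TRUE
    ),
    quasipoisson = list(
      variance = function(mu) mu,
      varianceDeriv = function(mu) rep(1, length(mu)),
      devianceFun = poisDev,
      # quasi-likelihood on the Poisson kernel, scaled by the dispersion
      logLikFun = function(y, mu, phi, w)
        (w / phi) * (y * log(mu) - mu - lgamma(y + 1)),
      initTransform = function(y) log(y + 0.5),
      dispersionMode = "estimated",
      muLower = .EPS_MU, muUpper = 1e10,
      responseCheck = function(y) is.finite(y) & y >= 0,
      statsFamily = stats::quasipoisson(link = .statsLinkName(link, "poisson")),
      canSimulate = FALSE
    ),
    binomial = list(
      variance = function(mu) mu * (1 - mu),
      varianceDeriv = function(mu) 1 - 2 * mu,
      devianceFun = function(y, mu, w)
        2 * w * (ylogy(y, mu) + ylogy(1 - y, 1 - mu)),
      logLikFun = function(y, mu, phi, w) {
        out <- numeric(length(y))
        out <- out + ifelse(y > 0, w * y * log(mu), 0)
        out <- out + ifelse(y < 1, w * (1 - y) * log(1 - mu), 0)
        dim(out) <- dim(y)
        out
      },
      initTransform = function(y) log((y + 0.5) / (1.5 - y)),
      dispersionMode = "fixed",
      muLower = .EPS_MU, muUpper = 1 - .EPS_MU,
      responseCheck = function(y) is.finite(y) & y >= 0 & y <= 1,
      statsFamily = stats::binomial(link = .statsLinkName(link, "binomial")),
      canSimulate = TRUE
    ),
    gamma = list(
      variance = function(mu) mu^2,
      varianceDeriv = function(mu) 2 * mu,
      devianceFun = function(y, mu, w) 2 * w * (-log(y / mu) + (y - mu) / mu),
      logLikFun = function(y, mu, phi, w) {
        a <- w / phi
        a * log(a) - a * log(mu) + (a - 1) * log(y) - a * y / mu - lgamma(a)
      },
      initTransform = function(y) log(pmax(y, .EPS_MU)),
      dispersionMode = "estimated",
      muLower = .EPS_MU, muUpper = 1e10,
      responseCheck = function(y) is.finite(y) & y > 0,
      statsFamily = stats::Gamma(link = .statsLinkName(link, "gamma")),
      canSimulate = TRUE
    ),
    negbin = {
      k <- sizeVal
      list(
        variance = function(mu) mu + mu^2 / .familySize(),
        varianceDeriv = function(mu) 1 + 2 * mu / .familySize(),
        devianceFun = function(y, mu, w) {
          kk <- .familySize()
          2 * w * (ylogy(y, mu) - (y + kk) * log((y + kk) / (mu + kk)))
        },
        logLikFun = function(y, mu, phi, w) {
          kk <- .familySize()
          w * (lgamma(y + kk) - lgamma(kk) - lgamma(y + 1) +
               kk * log(kk / (kk + mu)) + y * (log(mu) - log(kk + mu)))
        },
        initTransform = function(y) log(y + 0.5),
        dispersionMode = "fixed",
        muLower = .EPS_MU, muUpper = 1e10,
        responseCheck = function(y) is.finite(y) & y >= 0,
        statsFamily = if (is.na(k)) NULL else
          MASS::negative.binomial(theta = k, link = .statsLinkName(link, "negbin")),
        canSimulate = TRUE
      )
    }
  )

  fam <- new("GMFFamily",
    name = name, link = link,
    statsFamily = def$statsFamily,
    linkFun = lk$fun, linkInv = lk$inv,
    linkDeriv = lk$d1, linkDeriv2 = lk$d2,
    variance = def$variance, varianceDeriv = def$varianceDeriv,
    devianceFun = def$devianceFun, logLikFun = def$logLikFun,
    initTransform = def$initTransform,
    dispersionMode = def$dispersionMode,
    size = sizeVal,
    muLower = def$muLower, muUpper = def$muUpper,
    responseCheck = def$responseCheck,
    canSimulate = def$canSimulate,
    flags = flags)

  # Close the negbin kernels over the family object so that an estimated
  # size (filled in by the fitters via `setFamilySize`) is picked up.
  if (name == "negbin") fam <- setFamilySize(fam, sizeVal)
  fam
}

# The stats::family link name matching ours (stats uses "1/mu" spellings
# only for quasi; the standard families accept these strings directly).
.statsLinkName <- function(link, name) {
  if (link == "inverse") return("inverse")
  link
}

# Rebind the negative-binomial size inside the family's closures. Returns a
# new GMFFamily; other families are returned unchanged.
setFamilySize <- function(family, size) {
  if (family@name != "negbin") return(family)
  k <- as.numeric(size)
  fam <- family
  fam@size <- k
  fam@variance <- function(mu) mu + mu^2 / k
  fam@varianceDeriv <- function(mu) 1 + 2 * mu / k
  fam@devianceFun <- function(y, mu, w)
    2 * w * (ylogy(y, mu) - (y + k) * log((y + k) / (mu + k)))
  fam@logLikFun <- function(y, mu, phi, w)
    w * (lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
         k * log(k / (k + mu)) + y * (log(mu) - log(k + mu)))
  if (is.finite(k))
    fam@statsFamily <- MASS::negative.binomial(theta = k, link = fam@link)
  fam
}

# placeholder so R CMD check does not complain about the closure name used
# transiently inside gmfFamily() before setFamilySize() rebinds it
.familySize <- function() NA_real_

#' Weighted unit deviances
#'
#' Computes the elementwise weighted unit deviance
#' \eqn{D(y, \mu) = -2 \log\{f_\phi(y,\mu) / f_\phi(y,y)\}} for a family;
#' summing the result gives the total deviance. Boundary responses
#' (\eqn{y = 0} for count families, \eqn{y \in \{0, 1\}} for the binomial)
#' are handled through the \eqn{x \log x \to 0} limit.
#'
#' @param y observed responses (vector or matrix).
#' @param mu fitted means, same shape as \code{y}.
#' @param family a \code{\link{GMFFamily}}.
#' @param weights positive prior weights (recycled).
#' @return nonnegative values, same shape as \code{y}.
#' @examples
#' fam <- gmfFamily("poisson")
#' devianceMatrix(c(0, 2), c(1, 2), fam)   # 2, 0
#' @export
devianceMatrix <- function(y, mu, family, weights = 1) {
  .checkMeanDomain(mu, family)
  bad <- !family@responseCheck(y)
  if (any(bad))
    stopf("response outside the %s domain at entry %d", family@name,
          which(bad)[1])
  w <- array(weights, dim = if (is.null(dim(y))) length(y) else dim(y))
  out <- family@devianceFun(y, mu, w)
  dim(out) <- dim(y)
  out
}

.checkMeanDomain <- function(mu, family) {
  bad <- !is.finite(mu) | mu < family@muLower | mu > family@muUpper
  if (any(bad))
    stopf("mean outside the %s domain at entry %d (value %g)",
          family@name, which(bad)[1], mu[which(bad)[1]])
  invisible(TRUE)
}

#' Derivatives of the negative log-likelihood in the linear predictor
#'
#' Returns the per-entry first and second derivatives of the negative
#' log-likelihood with respect to \eqn{\eta = g(\mu)}:
#' \deqn{\dot D = -\frac{w (y - \mu)}{\phi\, \nu(\mu)\, \dot g(\mu)}, \qquad
#'       \ddot D = \frac{w\, \alpha(\mu)}{\phi\, \nu(\mu)\, \dot g(\mu)^2},}
#' with \eqn{\alpha(\mu) = 1 + (y-\mu)\{\dot\nu(\mu)/\nu(\mu) +
#' \ddot g(\mu)/\dot g(\mu)\}}. With \code{fisher = TRUE} the expected
#' curvature is used instead (\eqn{\alpha \equiv 1}), which is strictly
#' positive for all valid inputs. The sign convention makes
#' \eqn{\dot D} the gradient of the penalized objective minimized by the
#' fitters, so quasi-Newton steps \eqn{-\dot D / \ddot D} descend.
#'
#' @inheritParams devianceMatrix
#' @param phi positive dispersion.
#' @param fisher use the expected (Fisher) curvature.
#' @return list with components \code{deta} and \code{deta2}.
#' @export
etaDerivatives <- function(y, mu, family, phi = 1, weights = 1,
                           fisher = TRUE) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0)
    stopf("dispersion 'phi' must be a positive scalar")
  .checkMeanDomain(mu, family)
  w <- array(weights, dim = if (is.null(dim(y))) length(y) else dim(y))
  nu <- family@variance(mu)
  g1 <- family@linkDeriv(mu)
  if (any(nu <= 0)) stopf("nonpositive variance function value encountered")
  if (any(g1 == 0)) stopf("vanishing link derivative encountered")
  deta <- -w * (y - mu) / (phi * nu * g1)
  if (fisher) {
    alpha <- 1
  } else {
    alpha <- 1 + (y - mu) * (family@varianceDeriv(mu) / nu +
                             family@linkDeriv2(mu) / g1)
  }
  deta2 <- w * alpha / (phi * nu * g1^2)
  dim(deta) <- dim(y); dim(deta2) <- dim(y)
  list(deta = deta, deta2 = deta2)
}

#' Pearson method-of-moments dispersion estimate
#'
#' \eqn{\hat\phi = \sum_\Omega w (y-\mu)^2/\nu(\mu) \; / \; (N_{obs} - k)},
#' truncated below at \code{floor}. Used for the Gaussian, gamma and
#' quasi-Poisson families after (and during) fitting.
#'
#' @inheritParams devianceMatrix
#' @param npar effective number of parameters consumed by the fit.
#' @param floor smallest admissible value.
#' @return scalar dispersion estimate.
#' @export
estimateDispersion <- function(y, mu, family, weights = 1, npar = 0,
                               floor = 1e-8) {
  w <- rep_len(weights, length(y))
  denom <- length(y) - npar
  if (denom <= 0)
    stopf("dispersion denominator N_obs - npar = %g is not positive", denom)
  pearson <- sum(w * (y - mu)^2 / family@variance(mu))
  max(pearson / denom, floor)
}

# Aggregated method-of-moments size estimate for the negative binomial:
# matches the total Pearson variance sum to mu + mu^2/k.
estimateNBSize <- function(y, mu, weights = 1) {
  w <- rep_len(weights, length(y))
  num <- sum(w * mu^2)
  den <- sum(w * ((y - mu)^2 - mu))
  k <- if (den <= 0) 1e6 else num / den
  min(max(k, 1e-2), 1e6)
}

# Per-entry log-likelihood (including the c(y, phi) constant where defined).
logLikMatrix <- function(y, mu, family, phi = 1, weights = 1) {
  w <- array(weights, dim = if (is.null(dim(y))) length(y) else dim(y))
  out <- family@logLikFun(y, mu, phi, w)
  dim(out) <- dim(y)
  out
}
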