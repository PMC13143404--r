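test_that("canonical-link conventions and variance functions are correct", {
  pois <- gmfFamily("poisson")
  expect_identical(pois@link, "log")
  expect_equal(pois@variance(c(0.5, 2, 7)), c(0.5, 2, 7))

  gaus <- gmfFamily("gaussian")
  expect_identical(gaus@link, "identity")
  expect_equal(gaus@variance(c(-1, 3)), c(1, 1))
  expect_equal(devianceMatrix(3, 1, gaus), 4)

  # NB2 variance against the reference GLM implementation
  nb <- gmfFamily("negbin", size = 10)
  ref <- MASS::negative.binomial(theta = 10)
  mus <- c(0.3, 1, 4, 25)
  expect_equal(nb@variance(mus), ref$variance(mus))
  expect_equal(nb@variance(mus), mus + mus^2 / 10)
  expect_identical(nb@link, "log")

  expect_error(gmfFamily("poisson", link = "weird"), "unknown link")
  expect_error(gmfFamily("negbin", size = -2), "positive")
  expect_error(gmfFamily("poisson", size = 3), "negbin")
})

test_that("unit deviances match closed forms and vanish at saturation", {
  set.seed(11)
  for (fam in shippedFamilies()) {
    mu <- fam@linkInv(rnorm(30, 0, 0.5))
    mu <- pmin(pmax(mu, 0.05), if (fam@name == "binomial") 0.95 else 1e6)
    y <- drawResponse(fam, mu)
    # D(y, y) = 0 (boundary responses nudged inside the mean domain)
    ysat <- pmin(pmax(y, fam@muLower + 0.01), fam@muUpper)
    if (fam@name == "binomial") ysat <- pmin(ysat, 1 - 1e-6)
    if (fam@name == "gamma") ysat <- pmax(ysat, 0.01)
    expect_equal(devianceMatrix(ysat, ysat, fam), rep(0, 30),
                 tolerance = 1e-12)
    dev <- devianceMatrix(y, mu, fam, weights = 1.3)
    expect_true(all(dev >= -1e-12))
    # cross-check against the stats/MASS family dev.resids
    if (!is.null(fam@statsFamily))
      expect_equal(dev, fam@statsFamily$dev.resids(y, mu, rep(1.3, 30)),
                   tolerance = 1e-10)
  }
  # closed-form Poisson boundary case: y = 0, mu = 1 -> 2
  expect_equal(devianceMatrix(0, 1, gmfFamily("poisson")), 2)
  expect_error(devianceMatrix(2, -1, gmfFamily("poisson")), "domain")
  expect_error(devianceMatrix(-2, 1, gmfFamily("poisson")), "domain")
})

test_that("total deviance equals twice the log-likelihood gap to saturation", {
  set.seed(4)
  for (nm in c("gaussian", "poisson", "binomial")) {
    fam <- gmfFamily(nm)
    mu <- fam@linkInv(rnorm(50, 0, 0.4))
    y <- drawResponse(fam, mu)
    phi <- if (nm == "gaussian") 1.7 else 1
    musat <- y
    if (nm != "gaussian") musat <- pmax(musat, 1e-12)
    if (nm == "binomial") musat <- pmin(musat, 1 - 1e-12)
    llFit <- sum(gmfab:::logLikMatrix(y, mu, fam, phi))
    llSat <- sum(gmfab:::logLikMatrix(y, musat, fam, phi))
    dev <- sum(devianceMatrix(y, mu, fam)) / phi
    expect_equal(dev, -2 * (llFit - llSat), tolerance = 1e-8)
  }
})

test_that("eta derivatives match finite differences of the negative log-likelihood", {
  set.seed(7)
  for (fam in shippedFamilies()) {
    phi <- if (fam@dispersionMode == "estimated") 1.3 else 1
    for (r in 1:12) {
      eta <- rnorm(1, 0, 0.8)
      mu <- fam@linkInv(eta)
      mu <- min(max(mu, 1e-4), if (fam@name == "binomial") 1 - 1e-4 else 1e8)
      eta <- fam@linkFun(mu)
      y <- drawResponse(fam, matrix(mu))
      w <- runif(1, 0.5, 2)
      nll <- function(e) -gmfab:::logLikMatrix(y, fam@linkInv(e), fam, phi, w)
      h <- 1e-5 * max(1, abs(eta))
      gFD <- (nll(eta + h) - nll(eta - h)) / (2 * h)
      hFD <- (nll(eta + h) - 2 * nll(eta) + nll(eta - h)) / h^2
      der <- etaDerivatives(y, mu, fam, phi, w, fisher = FALSE)
      expect_equal(der$deta, gFD, tolerance = 1e-6,
                   ignore_attr = TRUE)
      expect_equal(der$deta2, hFD, tolerance = 1e-4,
                   ignore_attr = TRUE)
      # Fisher curvature is strictly positive, score vanishes at y = mu
      fis <- etaDerivatives(y, mu, fam, phi, w, fisher = TRUE)
      expect_gt(fis$deta2, 0)
      if (mu > fam@muLower) {
        sat <- etaDerivatives(mu, mu, fam, phi, w, fisher = TRUE)
        expect_equal(sat$deta, 0, ignore_attr = TRUE)
      }
    }
  }
})

test_that("derivative kernels reduce to known closed forms", {
  # Gaussian identity: quadratic loss derivatives
  g <- gmfFamily("gaussian")
  der <- etaDerivatives(c(3, -1), c(1, 1), g, phi = 1, weights = 1)
  expect_equal(der$deta, -c(2, -2))
  expect_equal(der$deta2, c(1, 1))
  # Poisson canonical: score -(y - mu), Fisher curvature mu
  p <- gmfFamily("poisson")
  der <- etaDerivatives(c(4, 0), c(2.5, 1.5), p, fisher = TRUE)
  expect_equal(der$deta, -(c(4, 0) - c(2.5, 1.5)))
  expect_equal(der$deta2, c(2.5, 1.5))
  expect_error(etaDerivatives(1, 1, p, phi = -1), "positive")
})

test_that("Pearson dispersion estimation behaves as a method of moments", {
  g <- gmfFamily("gaussian")
  expect_equal(estimateDispersion(c(1, -1, 1, -1) + 2, rep(2, 4), g), 1)
  expect_equal(estimateDispersion(rep(2, 4), rep(2, 4), g), 1e-8)
  expect_error(estimateDispersion(1:3, 1:3, g, npar = 3), "not positive")
  # quasi-Poisson on NB(size = 2) counts: phi ~ 1 + mu/2
  set.seed(21)
  mu <- 5
  y <- rnbinom(20000, size = 2, mu = mu)
  qp <- gmfFamily("quasipoisson")
  phiHat <- estimateDispersion(y, rep(mean(y), length(y)), qp)
  expect_lt(abs(phiHat - (1 + mu / 2)) / (1 + mu / 2), 0.2)
})

test_that("an estimated negative-binomial size tracks the truth", {
  set.seed(31)
  mu <- exp(rnorm(5000, 1.5, 0.5))
  y <- rnbinom(5000, size = 3, mu = mu)
  k <- gmfab:::estimateNBSize(y, mu)
  expect_lt(abs(k - 3) / 3, 0.25)
  # link-domain mismatches are flagged, not fatal
  fam <- gmfFamily("poisson", link = "identity")
  expect_true(length(fam@flags) > 0)
})
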