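# Shared fixtures: tiny seeded problems and generic oracles.

# All shipped family/link pairs exercised by the derivative checks.
shippedFamilies <- function() {
  list(
    gmfFamily("gaussian"),
    gmfFamily("gaussian", link = "log"),
    gmfFamily("poisson"),
    gmfFamily("poisson", link = "sqrt"),
    gmfFamily("binomial"),
    gmfFamily("gamma", link = "log"),
    gmfFamily("gamma"),
    gmfFamily("negbin", size = 5),
    gmfFamily("quasipoisson")
  )
}

# Draw a response inside the family domain at mean mu.
drawResponse <- function(family, mu, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- length(mu)
  y <- switch(family@name,
    gaussian = rnorm(nm, mu, 1),
    poisson = rpois(nm, mu),
    quasipoisson = rpois(nm, mu),
    binomial = rbinom(nm, 1, mu),
    gamma = rgamma(nm, shape = 2, scale = mu / 2),
    negbin = rnbinom(nm, size = family@size, mu = mu))
  dim(y) <- dim(mu)
  y
}

# A small random problem with covariates, weights and an optional mask.
tinyProblem <- function(n = 20, m = 10, d = 2, family = gmfFamily("poisson"),
                        p = 2, q = 1, maskFrac = 0, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))[, seq_len(p), drop = FALSE]
  Z <- cbind(1, matrix(rnorm(m * (q - 1)), m, q - 1))[, seq_len(q), drop = FALSE]
  B <- matrix(rnorm(m * p, 0, 0.3), m, p)
  if (family@name %in% c("poisson", "negbin", "quasipoisson", "gamma"))
    B[, 1] <- B[, 1] + 1.5
  Gamma <- matrix(rnorm(n * q, 0, 0.3), n, q)
  U <- matrix(rnorm(n * d, 0, 0.4), n, d)
  V <- matrix(rnorm(m * d, 0, 0.4), m, d)
  if (family@link == "sqrt") {
    # the sqrt link maps onto positive predictors only; keep eta away from 0
    B[, 1] <- abs(B[, 1]) + 3
    Gamma <- Gamma * 0.3; U <- U * 0.5; V <- V * 0.5
  }
  eta <- X %*% t(B) + Gamma %*% t(Z) + U %*% t(V)
  mu <- family@linkInv(eta)
  mu <- pmin(pmax(mu, family@muLower), family@muUpper)
  Y <- drawResponse(family, mu)
  mask <- NULL
  if (maskFrac > 0) {
    mask <- matrix(runif(n * m) > maskFrac, n, m)
    Y[!mask] <- NA
  }
  data <- gmfData(Y, X = X, Z = Z)
  params <- gmfParams(B = B, Gamma = Gamma, U = U, V = V, phi = 1)
  list(data = data, params = params, family = family)
}

# Central finite difference of the penalized objective in one coordinate of
# one parameter block.
fdGradient <- function(data, params, lambda, family, block, k, h = 1e-4) {
  M <- slot(params, block)
  hk <- h * max(1, abs(M[k]))
  at <- function(delta) {
    p <- params
    Md <- M; Md[k] <- M[k] + delta; slot(p, block) <- Md
    penalizedObjective(data, p, lambda, family)
  }
  # fourth-order central difference
  (at(-2 * hk) - 8 * at(-hk) + 8 * at(hk) - at(2 * hk)) / (12 * hk)
}

# Largest principal angle (radians) between the column spans of A and B.
principalAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(0, min(s))))
}

# Mean R^2 of linear probes predicting batch membership from latent scores.
batchProbeR2 <- function(U, batch) {
  D <- stats::model.matrix(~ 0 + factor(batch))
  mean(vapply(seq_len(ncol(D)), function(k)
    summary(stats::lm(D[, k] ~ U))$r.squared, numeric(1)))
}
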