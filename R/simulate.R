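# Synthetic data generators: exact-model draws for parameter-recovery tests
# and a single-cell-like negative-binomial count simulator with cell types,
# batches and library sizes.

#' Simulate from the exact GMF generative model
#'
#' Draws intercepts, latent factors and loadings, forms the linear
#' predictor \eqn{\eta = X B^\top + \Gamma Z^\top + U V^\top} and samples
#' responses from the requested family. Latent entries are scaled so that
#' \code{snr} is the marginal standard deviation of the latent part of
#' \eqn{\eta} (set \code{snr = 0} for a pure-regression signal). The
#' returned truth is projected onto the B1 parametrization, so it is
#' directly comparable with fitted parameters.
#'
#' @param n,m matrix dimensions (cells by genes).
#' @param d true latent rank.
#' @param family a \code{\link{GMFFamily}} with a generative law
#'   (quasi-Poisson has none).
#' @param snr standard deviation of the latent signal on the linear
#'   predictor scale.
#' @param phi dispersion used when sampling Gaussian or gamma responses.
#' @param seed integer seed; fixed seeds give bitwise-identical output.
#' @return list with elements \code{data} (a \code{\link{GMFData}} with
#'   intercept-only covariates) and \code{truth} (list with \code{U},
#'   \code{V}, \code{B}, \code{Gamma}, \code{mu}, \code{eta},
#'   \code{family}, \code{phi}).
#' @export
simulateGMF <- function(n, m, d = 2L, family = gmfFamily("poisson"),
                        snr = 1, phi = 1, seed = 1L) {
  if (d > min(n, m)) stopf("d must not exceed min(n, m)")
  if (!family@canSimulate)
    stopf("the %s family has no generative law; use negbin or poisson",
          family@name)
  withSeed(seed, {
    interceptLevel <- switch(family@name,
      poisson = 2, negbin = 2, gamma = 1, binomial = 0, gaussian = 0)
    B <- matrix(stats::rnorm(m, interceptLevel, 0.5), m, 1)
    Gamma <- matrix(stats::rnorm(n, 0, 0.5), n, 1)
    s <- if (snr > 0 && d > 0) (snr^2 / d)^(1 / 4) else 0
    U <- matrix(stats::rnorm(n * d, 0, 1), n, d) * s
    V <- matrix(stats::rnorm(m * d, 0, 1), m, d) * s
    X <- matrix(1, n, 1); Z <- matrix(1, m, 1)
    eta <- X %*% t(B) + Gamma %*% t(Z) + U %*% t(V)
    mu <- meanFromEta(eta, family)$mu
    Y <- switch(family@name,
      gaussian = matrix(stats::rnorm(n * m, mu, sqrt(phi)), n, m),
      poisson = matrix(stats::rpois(n * m, mu), n, m),
      binomial = matrix(stats::rbinom(n * m, 1, mu), n, m),
      gamma = matrix(stats::rgamma(n * m, shape = 1 / phi,
                                   scale = mu * phi), n, m),
      negbin = matrix(stats::rnbinom(n * m, size = family@size, mu = mu),
                      n, m))
  })
  data <- gmfData(Y)
  raw <- gmfParams(B = B, Gamma = Gamma, U = U, V = V,
                   phi = if (family@dispersionMode == "estimated") phi else 1)
  proj <- projectConstraints(data, raw, "B1")
  list(data = data,
       truth = list(U = proj@U, V = proj@V, B = proj@B, Gamma = proj@Gamma,
                    mu = mu, eta = eta, family = family, phi = phi,
                    snr = snr, d = d, seed = seed))
}

#' Simulate a single-cell-like count matrix
#'
#' Generates negative-binomial counts mimicking a droplet scRNA-seq
#' experiment with discrete cell types, batch effects and cell-specific
#' library sizes. The log-mean decomposes as
#' \deqn{\log \mu_{ij} = \log L_i + b_j + \mathrm{batch}_{b(i), j} +
#'   u_{i:}^\top v_{j:},}
#' with log-normal library sizes \eqn{L_i}, gene baselines \eqn{b_j},
#' dense per-gene batch effects (reference coding), and a latent type
#' signal built as an explicit rank-\code{nTypes} factor model: each cell's
#' latent position is its type centroid (scaled coordinate axes) plus
#' within-type spread, and each latent axis loads on a sparse random subset
#' of marker genes. The within-type spread makes the latent signal genuinely
#' \code{nTypes}-dimensional even after the gene baselines absorb the
#' across-cell mean (a pure group-mean signal would lose one dimension to
#' that centering), so the generator's nominal rank equals \code{nTypes}.
#'
#' Cell types are allocated evenly (round-robin, so \code{n} divisible by
#' \code{nTypes} gives exactly equal classes); batch labels are drawn from
#' a balanced random assignment and exported as dummy covariates in
#' \code{X}. No lineage or branching structure and no zero inflation are
#' simulated.
#'
#' @param n,m number of cells and genes.
#' @param nTypes number of cell types (latent rank of the type signal).
#' @param nBatches number of batches.
#' @param typeEffect standard deviation of marker-gene loadings (log
#'   scale).
#' @param batchEffect standard deviation of per-gene batch effects (log
#'   scale).
#' @param libsizeSdlog standard deviation of log library sizes.
#' @param nbSize negative-binomial size (inverse overdispersion).
#' @param markerFraction fraction of genes loading on each latent axis.
#' @param centroidScale distance scale of the type centroids in latent
#'   space.
#' @param withinTypeSd within-type latent standard deviation.
#' @param baselineMean,baselineSd distribution of gene log-baselines.
#' @param seed integer seed.
#' @return list with \code{data} (a \code{\link{GMFData}} whose \code{X}
#'   holds an intercept plus batch dummies) and \code{truth} (cell types,
#'   batches, library sizes, latent blocks, means).
#' @export
simulateScRNA <- function(n, m, nTypes = 5L, nBatches = 3L,
                          typeEffect = 0.5, batchEffect = 0.3,
                          libsizeSdlog = 0.4, nbSize = 2,
                          markerFraction = 0.2, centroidScale = 1.5,
                          withinTypeSd = 0.6,
                          baselineMean = 1, baselineSd = 1,
                          seed = 1L) {
  if (nbSize <= 0) stopf("nbSize must be positive")
  withSeed(seed, {
    type <- rep_len(seq_len(nTypes), n)
    batch <- sample(rep_len(seq_len(nBatches), n))
    logL <- stats::rnorm(n, 0, libsizeSdlog)
    base <- stats::rnorm(m, baselineMean, baselineSd)
    # latent factors: centroid per type plus within-type spread
    centroids <- diag(centroidScale, nTypes)
    U <- centroids[type, , drop = FALSE] +
      matrix(stats::rnorm(n * nTypes, 0, withinTypeSd), n, nTypes)
    # sparse marker loadings per latent axis
    V <- matrix(0, m, nTypes)
    nMark <- max(1L, round(markerFraction * m))
    for (k in seq_len(nTypes)) {
      mk <- sample.int(m, nMark)
      V[mk, k] <- stats::rnorm(nMark, 0, typeEffect)
    }
    # dense batch effects, reference coding (batch 1 = baseline)
    Bbatch <- if (nBatches > 1L)
      matrix(stats::rnorm(m * (nBatches - 1L), 0, batchEffect),
             m, nBatches - 1L) else matrix(0, m, 0)
    Xbatch <- matrix(0, n, max(nBatches - 1L, 0L))
    for (b in seq_len(nBatches - 1L)) Xbatch[, b] <- as.numeric(batch == b + 1L)
    eta <- matrix(logL, n, m) + matrix(base, n, m, byrow = TRUE) +
      Xbatch %*% t(Bbatch) + U %*% t(V)
    mu <- pmin(exp(eta), 1e8)
    Y <- matrix(stats::rnbinom(n * m, size = nbSize, mu = mu), n, m)
  })
  X <- cbind("(Intercept)" = 1, Xbatch)
  if (ncol(Xbatch) > 0L)
    colnames(X)[-1] <- paste0("batch", seq_len(ncol(Xbatch)) + 1L)
  data <- gmfData(Y, X = X)
  list(data = data,
       truth = list(cellType = type, batch = batch,
                    librarySize = exp(logL), logBaseline = base,
                    U = U, V = V, batchCoef = Bbatch, mu = mu, eta = eta,
                    nbSize = nbSize, family = gmfFamily("negbin",
                                                        size = nbSize),
                    seed = seed))
}
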