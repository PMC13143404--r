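# The three fitting algorithms: alternated IRWLS, diagonal quasi-Newton and
# block-wise adaptive stochastic gradient descent, plus the learning-rate
# schedule and the minibatch machinery.

#' Decaying learning-rate schedule
#'
#' \eqn{\rho_t = k_0 / (1 + k_0 k_1 t)^\tau} with \eqn{k_0, k_1 > 0} and
#' \eqn{\tau \in (1/2, 1]} (the Robbins–Monro range, so that
#' \eqn{\sum \rho_t = \infty} and \eqn{\sum \rho_t^2 < \infty}).
#'
#' @param t iteration counter (0-based).
#' @param k0 initial step size.
#' @param k1 decay rate.
#' @param tau tail exponent.
#' @return positive step size, non-increasing in \code{t}.
#' @export
learningRate <- function(t, k0, k1, tau) {
  if (!is.numeric(k0) || k0 <= 0 || !is.numeric(k1) || k1 <= 0)
    stopf("k0 and k1 must be positive")
  if (tau <= 0.5 || tau > 1)
    stopf("tau must lie in (1/2, 1] for the Robbins-Monro conditions")
  k0 / (1 + k0 * k1 * t)^tau
}

#' Balanced random partitions for minibatch subsampling
#'
#' Splits \code{1:n} into \code{R} row chunks and \code{1:m} into \code{S}
#' column chunks whose sizes differ by at most one; the partition is a
#' deterministic function of the seed.
#'
#' @param n,m matrix dimensions.
#' @param R,S number of row and column chunks.
#' @param seed integer seed.
#' @return list with elements \code{rows} and \code{cols}, each a list of
#'   index vectors forming an exact partition.
#' @export
minibatchPartition <- function(n, m, R, S, seed = 1L) {
  if (R < 1 || R > n) stopf("need 1 <= R <= n")
  if (S < 1 || S > m) stopf("need 1 <= S <= m")
  withSeed(seed, {
    rows <- split(sample.int(n), rep.int(seq_len(R), chunkSizes(n, R)))
    cols <- split(sample.int(m), rep.int(seq_len(S), chunkSizes(m, S)))
  })
  list(rows = unname(lapply(rows, sort)), cols = unname(lapply(cols, sort)))
}

#' Minibatch stochastic gradients
#'
#' Evaluates the subsampled derivative blocks on the block
#' \eqn{B = I \times J}, inflated so that they are unbiased for the
#' full-batch blocks of \code{\link{fullGradients}} when the chunk is drawn
#' uniformly from an equal-size partition:
#' \deqn{\hat G_{U,I} = (m/m^*_J)\, \dot D_B V_J + \lambda U_I, \qquad
#'       \hat G_{V,J} = (n/n^*_I)\, \dot D_B^\top U_I + \lambda V_J,}
#' and analogously for the curvatures (with \eqn{V_J * V_J},
#' \eqn{U_I * U_I}) and for the unpenalized covariate blocks
#' \eqn{B_J} (scaled by \eqn{n/n^*_I}) and \eqn{\Gamma_I} (scaled by
#' \eqn{m/m^*_J}). Masked entries inside the block are imputed at the
#' current means before differentiation.
#'
#' @inheritParams fullGradients
#' @param rows,cols index vectors defining the block.
#' @return list with \code{GU}, \code{HU} (rows \code{rows}), \code{GV},
#'   \code{HV} (rows \code{cols}), \code{GB}, \code{HB}, \code{GGamma},
#'   \code{HGamma}, and \code{nclip}.
#' @export
minibatchGradients <- function(data, params, rows, cols, lambda, family,
                               fisher = TRUE) {
  if (!length(rows) || !length(cols)) stopf("empty minibatch block")
  eta <- linearPredictor(data, params, rows, cols)
  mf <- meanFromEta(eta, family)
  mu <- mf$mu
  Yb <- data@Y[rows, cols, drop = FALSE]
  mb <- data@mask[rows, cols, drop = FALSE]
  Yb[!mb] <- mu[!mb]
  Wb <- data@W[rows, cols, drop = FALSE]
  der <- etaDerivatives(Yb, mu, family, params@phi, Wb, fisher = fisher)
  n <- nrow(data@Y); m <- ncol(data@Y)
  cI <- n / length(rows); cJ <- m / length(cols)
  UI <- params@U[rows, , drop = FALSE]
  VJ <- params@V[cols, , drop = FALSE]
  XI <- data@X[rows, , drop = FALSE]
  ZJ <- data@Z[cols, , drop = FALSE]
  list(
    GU = cJ * (der$deta %*% VJ) + lambda * UI,
    HU = cJ * (der$deta2 %*% (VJ * VJ)) + lambda,
    GV = cI * crossprod(der$deta, UI) + lambda * VJ,
    HV = cI * crossprod(der$deta2, UI * UI) + lambda,
    GB = cI * crossprod(der$deta, XI),
    HB = cI * crossprod(der$deta2, XI * XI),
    GGamma = cJ * (der$deta %*% ZJ),
    HGamma = cJ * (der$deta2 %*% (ZJ * ZJ)),
    nclip = mf$nclip
  )
}

#' Control parameters for GMF fitting
#'
#' @param maxEpochs maximum number of epochs (full sweeps for the
#'   deterministic algorithms; sweeps over all column chunks for SGD).
#' @param tol convergence tolerance on the relative change of the monitored
#'   objective, required for \code{convWindow} consecutive epochs.
#' @param convWindow consecutive small-change epochs required to declare
#'   convergence.
#' @param seed integer seed controlling every random draw inside a fit.
#' @param k0,k1,tau learning-rate schedule for SGD
#'   (\code{\link{learningRate}}).
#' @param alpha1,alpha2 exponential smoothing coefficients for the gradient
#'   and curvature accumulators.
#' @param rowChunks,colChunks number of row/column minibatch chunks for SGD;
#'   \code{NULL} picks chunk sizes of about \code{min(n, 1000)} rows and
#'   \code{min(m, 250)} columns.
#' @param stepNewton,stepAIRWLS initial step sizes of the damped
#'   quasi-Newton and AIRWLS updates.
#' @param maxHalving maximum number of step halvings on an objective
#'   increase.
#' @param airwlsInner inner Fisher-scoring iterations per AIRWLS block
#'   update.
#' @param fisher use expected (Fisher) curvature; the observed curvature is
#'   available for diagnostics but is not guaranteed positive.
#' @param monitorFraction fraction of observed entries used by the SGD
#'   convergence monitor (the deterministic fitters monitor the full
#'   objective).
#' @param hFloor positive floor applied to curvature accumulators.
#' @param divergeFactor abort when the monitored objective exceeds its
#'   initial value by this factor.
#' @return a named list of class \code{"gmfControl"}.
#' @export
gmfControl <- function(maxEpochs = 500L, tol = 1e-5, convWindow = 3L,
                       seed = 1L, k0 = 0.01, k1 = 0.01, tau = 0.75,
                       alpha1 = 0.1, alpha2 = 0.01,
                       rowChunks = NULL, colChunks = NULL,
                       stepNewton = 0.1, stepAIRWLS = 1,
                       maxHalving = 10L, airwlsInner = 1L,
                       fisher = TRUE, monitorFraction = 0.1,
                       hFloor = 1e-8, divergeFactor = 100) {
  if (tau <= 0.5 || tau > 1) stopf("tau must lie in (1/2, 1]")
  if (alpha1 <= 0 || alpha1 > 1 || alpha2 <= 0 || alpha2 > 1)
    stopf("alpha1 and alpha2 must lie in (0, 1]")
  structure(list(
    maxEpochs = as.integer(maxEpochs), tol = tol,
    convWindow = as.integer(convWindow), seed = as.integer(seed),
    k0 = k0, k1 = k1, tau = tau, alpha1 = alpha1, alpha2 = alpha2,
    rowChunks = rowChunks, colChunks = colChunks,
    stepNewton = stepNewton, stepAIRWLS = stepAIRWLS,
    maxHalving = as.integer(maxHalving),
    airwlsInner = as.integer(airwlsInner),
    fisher = isTRUE(fisher), monitorFraction = monitorFraction,
    hFloor = hFloor, divergeFactor = divergeFactor),
    class = "gmfControl")
}

# ---------------------------------------------------------------------------
# Shared fitting scaffolding

.epochDispersion <- function(data, params, family, d, smooth = NULL) {
  if (family@dispersionMode != "estimated") return(params@phi)
  obs <- data@mask
  mu <- predictMean(data, params, family)
  npar <- ncol(data@X) * ncol(data@Y) + ncol(data@Z) * nrow(data@Y) +
    d * sum(dim(data@Y))
  phi <- estimateDispersion(data@Y[obs], mu[obs], family, data@W[obs],
                            npar = min(npar, sum(obs) - 1))
  if (is.null(smooth)) phi else (1 - smooth) * params@phi + smooth * phi
}

# Re-estimate the negative-binomial size by method of moments on the
# current fitted means (called once per epoch when the size is unknown).
.updateNBSize <- function(data, params, family) {
  obs <- data@mask
  mu <- predictMean(data, params, family)
  setFamilySize(family, estimateNBSize(data@Y[obs], mu[obs], data@W[obs]))
}

# Build the returned GMFFit object.
.finishFit <- function(data, params, family, lambda, algorithm, trace,
                       converged, epochs, clipEvents, control,
                       parametrization, extra = list()) {
  d <- ncol(params@U)
  # objective achieved by the optimizer; the projection below preserves the
  # fit (eta) but redistributes latent scale, which changes the penalty term
  obj <- penalizedObjective(data, params, lambda, family)
  projected <- projectConstraints(data, params, parametrization)
  n <- nrow(data@Y); m <- ncol(data@Y)
  npar <- ncol(data@X) * m + ncol(data@Z) * n + d * (n + m) + 1
  man <- c(list(
    package = "gmfab",
    family = family@name, link = family@link,
    familyFlags = family@flags,
    nbSize = family@size,
    rank = d, lambda = lambda, algorithm = algorithm,
    parametrization = parametrization,
    seed = control$seed,
    control = unclass(control),
    dims = c(n = n, m = m, p = ncol(data@X), q = ncol(data@Z)),
    observed = sum(data@mask),
    clipEvents = clipEvents), extra)
  new("GMFFit", params = projected, family = family, rank = as.integer(d),
      lambda = lambda, algorithm = algorithm, objective = obj,
      trace = trace, converged = converged, epochs = as.integer(epochs),
      clipEvents = clipEvents, npar = npar,
      dims = as.integer(c(n, m)), manifest = man)
}

# ---------------------------------------------------------------------------
# Diagonal quasi-Newton

#' Fit a GMF model by damped diagonal quasi-Newton
#'
#' Global updates \eqn{\psi \leftarrow \psi + \rho \Delta} with
#' \eqn{\Delta = -G/H} elementwise, where \eqn{G} and \eqn{H} are the
#' full-batch gradient and (expected) diagonal curvature of the penalized
#' objective. The step is halved (up to \code{maxHalving} times) whenever
#' the objective would increase, so accepted steps are monotone.
#'
#' @param data a \code{\link{GMFData}}.
#' @param init starting \code{\link{GMFParams}} (see \code{\link{gmfInit}}).
#' @param family a \code{\link{GMFFamily}}.
#' @param lambda nonnegative latent ridge penalty.
#' @param control a \code{\link{gmfControl}} list.
#' @param parametrization identifiability normalization for the returned
#'   parameters.
#' @return a \code{\link{GMFFit}}.
#' @export
fitNewton <- function(data, init, family, lambda = 1,
                      control = gmfControl(),
                      parametrization = "B1") {
  checkConformal(data, init)
  params <- init
  d <- ncol(params@U)
  estSize <- family@name == "negbin" && is.na(family@size)
  if (estSize) family <- .updateNBSize(data, params, family)
  clip <- 0
  obj <- penalizedObjective(data, params, lambda, family)
  obj0 <- obj
  trace <- data.frame(epoch = 0L, objective = obj, change = NA_real_)
  nsmall <- 0L; converged <- FALSE; epoch <- 0L
  while (epoch < control$maxEpochs) {
    epoch <- epoch + 1L
    if (estSize) family <- .updateNBSize(data, params, family)
    gr <- fullGradients(data, params, lambda, family, fisher = control$fisher)
    clip <- clip + gr$nclip
    rho <- control$stepNewton
    accepted <- FALSE
    for (h in seq_len(control$maxHalving + 1L)) {
      cand <- params
      cand@U <- params@U - rho * gr$GU / pmax(gr$HU, control$hFloor)
      cand@V <- params@V - rho * gr$GV / pmax(gr$HV, control$hFloor)
      if (ncol(data@X) > 0L)
        cand@B <- params@B - rho * gr$GB / pmax(gr$HB, control$hFloor)
      if (ncol(data@Z) > 0L)
        cand@Gamma <- params@Gamma -
          rho * gr$GGamma / pmax(gr$HGamma, control$hFloor)
      objNew <- penalizedObjective(data, cand, lambda, family)
      if (objNew <= obj) { accepted <- TRUE; break }
      rho <- rho / 2
    }
    if (!accepted) break   # no descent direction at the smallest step
    params <- cand
    if (family@dispersionMode == "estimated")
      params@phi <- .epochDispersion(data, params, family, d)
    ch <- relChange(objNew, obj)
    obj <- objNew
    trace <- rbind(trace, data.frame(epoch = epoch, objective = obj,
                                     change = ch))
    if (obj > control$divergeFactor * abs(obj0) + abs(obj0))
      stopf("objective diverged at epoch %d", epoch)
    nsmall <- if (ch < control$tol) nsmall + 1L else 0L
    if (nsmall >= control$convWindow) { converged <- TRUE; break }
  }
  .finishFit(data, params, family, lambda, "newton", trace, converged,
             epoch, clip, control, parametrization)
}

# ---------------------------------------------------------------------------
# Alternated iterative re-weighted least squares

#' Fit a GMF model by alternated IRWLS (Fisher scoring)
#'
#' Cycles between the column-wise problems (updating \eqn{(\beta_{j:},
#' v_{j:})} against the design \eqn{[X, U]}) and the row-wise problems
#' (updating \eqn{(\gamma_{i:}, u_{i:})} against \eqn{[Z, V]}), each solved
#' by penalized weighted least squares with ridge \eqn{\lambda} on the
#' latent coordinates only. A global step-halving safeguard keeps the
#' objective non-increasing across accepted cycles.
#'
#' @inheritParams fitNewton
#' @return a \code{\link{GMFFit}}.
#' @export
fitAIRWLS <- function(data, init, family, lambda = 1,
                      control = gmfControl(),
                      parametrization = "B1") {
  checkConformal(data, init)
  params <- init
  d <- ncol(params@U)
  p <- ncol(data@X); q <- ncol(data@Z)
  estSize <- family@name == "negbin" && is.na(family@size)
  if (estSize) family <- .updateNBSize(data, params, family)
  clip <- 0
  obj <- penalizedObjective(data, params, lambda, family)
  obj0 <- obj
  trace <- data.frame(epoch = 0L, objective = obj, change = NA_real_)
  nsmall <- 0L; converged <- FALSE; epoch <- 0L
  while (epoch < control$maxEpochs) {
    epoch <- epoch + 1L
    if (estSize) family <- .updateNBSize(data, params, family)
    rho <- control$stepAIRWLS
    accepted <- FALSE
    for (h in seq_len(control$maxHalving + 1L)) {
      res <- .airwlsCycle(data, params, family, lambda, rho, control)
      objNew <- penalizedObjective(data, res$params, lambda, family)
      if (objNew <= obj) { accepted <- TRUE; break }
      rho <- rho / 2
    }
    if (!accepted) break
    params <- res$params
    clip <- clip + res$nclip
    if (family@dispersionMode == "estimated")
      params@phi <- .epochDispersion(data, params, family, d)
    ch <- relChange(objNew, obj)
    obj <- objNew
    trace <- rbind(trace, data.frame(epoch = epoch, objective = obj,
                                     change = ch))
    if (obj > control$divergeFactor * abs(obj0) + abs(obj0))
      stopf("objective diverged at epoch %d", epoch)
    nsmall <- if (ch < control$tol) nsmall + 1L else 0L
    if (nsmall >= control$convWindow) { converged <- TRUE; break }
  }
  .finishFit(data, params, family, lambda, "airwls", trace, converged,
             epoch, clip, control, parametrization)
}

# One full AIRWLS cycle (columns then rows) at relaxation rho. The Fisher
# normal matrices of all row/column problems share the same design, so the
# per-problem cross products A' diag(w) A are assembled in one matrix
# multiplication; only the K x K solves remain in the loop.
.airwlsCycle <- function(data, params, family, lambda, rho, control) {
  p <- ncol(data@X); q <- ncol(data@Z); d <- ncol(params@U)
  nclip <- 0
  # --- column problems: (B_j, V_j) against [X, U] --------------------------
  if (p + d > 0L) {
    for (k in seq_len(control$airwlsInner)) {
      eta <- linearPredictor(data, params)
      mf <- meanFromEta(eta, family); nclip <- nclip + mf$nclip
      Yw <- completeResponse(data, mf$mu)
      der <- etaDerivatives(Yw, mf$mu, family, params@phi, data@W,
                            fisher = TRUE)
      upd <- .fisherSolveAll(
        A = cbind(data@X, params@U),
        D1 = der$deta, D2 = der$deta2,
        Theta = cbind(params@B, params@V),
        pen = c(rep(0, p), rep(lambda, d)), rho = rho)
      if (p > 0L) params@B <- upd[, seq_len(p), drop = FALSE]
      if (d > 0L) params@V <- upd[, p + seq_len(d), drop = FALSE]
    }
  }
  # --- row problems: (Gamma_i, U_i) against [Z, V] -------------------------
  if (q + d > 0L) {
    for (k in seq_len(control$airwlsInner)) {
      eta <- linearPredictor(data, params)
      mf <- meanFromEta(eta, family); nclip <- nclip + mf$nclip
      Yw <- completeResponse(data, mf$mu)
      der <- etaDerivatives(Yw, mf$mu, family, params@phi, data@W,
                            fisher = TRUE)
      upd <- .fisherSolveAll(
        A = cbind(data@Z, params@V),
        D1 = t(der$deta), D2 = t(der$deta2),
        Theta = cbind(params@Gamma, params@U),
        pen = c(rep(0, q), rep(lambda, d)), rho = rho)
      if (q > 0L) params@Gamma <- upd[, seq_len(q), drop = FALSE]
      if (d > 0L) params@U <- upd[, q + seq_len(d), drop = FALSE]
    }
  }
  list(params = params, nclip = nclip)
}

# Penalized Fisher-scoring step for all problems sharing design A.
# D1, D2: (rows of A) x (number of problems); Theta: problems x K.
.fisherSolveAll <- function(A, D1, D2, Theta, pen, rho) {
  K <- ncol(A)
  # columns of AA enumerate the K x K outer-product entries of the design
  AA <- matrix(0, nrow(A), K * K)
  for (k in seq_len(K)) for (l in seq_len(K))
    AA[, (k - 1L) * K + l] <- A[, k] * A[, l]
  Hall <- crossprod(AA, D2)              # K^2 x nproblems
  Gall <- crossprod(A, D1) + t(Theta) * pen
  out <- Theta
  ridge <- diag(pen + 1e-12, K)
  for (j in seq_len(ncol(D1))) {
    H <- matrix(Hall[, j], K, K) + ridge
    delta <- tryCatch(solve(H, Gall[, j]),
                      error = function(e) Gall[, j] / diag(H))
    out[j, ] <- Theta[j, ] - rho * delta
  }
  out
}

# ---------------------------------------------------------------------------
# Block-wise adaptive stochastic gradient descent

#' Fit a GMF model by block-wise adaptive SGD
#'
#' Implements the minibatch procedure: row and column indices are split
#' into balanced chunks; each inner iteration visits one block
#' \eqn{B = I \times J}, computes the subsampled derivatives on that block,
#' refreshes exponential moving averages of the gradient and diagonal
#' curvature,
#' \deqn{\bar G \leftarrow (1 - \alpha_1) \bar G + \alpha_1 \hat G, \qquad
#'       \bar H \leftarrow (1 - \alpha_2) \bar H + \alpha_2 \hat H,}
#' and applies the partial update
#' \eqn{U_I \leftarrow U_I + \rho_t \Delta_I},
#' \eqn{\Delta_I = -\alpha_t (\bar G_I / \bar H_I)} with bias factor
#' \eqn{\alpha_t = (1 - \alpha_2^t)/(1 - \alpha_1^t)} and the decaying
#' schedule of \code{\link{learningRate}} (and likewise for \eqn{V_J} and
#' the unpenalized covariate rows \eqn{B_J}, \eqn{\Gamma_I}). Row chunks
#' are cycled without replacement and reshuffled every sweep; masked
#' entries inside a visited block are imputed at the current means.
#' Convergence is declared when the relative change of the objective on a
#' fixed monitoring subsample of observed entries stays below \code{tol}
#' for \code{convWindow} consecutive epochs.
#'
#' @inheritParams fitNewton
#' @return a \code{\link{GMFFit}}.
#' @export
fitSGD <- function(data, init, family, lambda = 1,
                   control = gmfControl(),
                   parametrization = "B1") {
  checkConformal(data, init)
  n <- nrow(data@Y); m <- ncol(data@Y)
  p <- ncol(data@X); q <- ncol(data@Z)
  params <- init
  d <- ncol(params@U)
  estSize <- family@name == "negbin" && is.na(family@size)
  if (estSize) family <- .updateNBSize(data, params, family)
  R <- if (is.null(control$rowChunks)) max(1L, ceiling(n / 1000)) else
    as.integer(control$rowChunks)
  S <- if (is.null(control$colChunks)) max(1L, ceiling(m / 250)) else
    as.integer(control$colChunks)

  # seed derivation contract: the partition uses control$seed itself, the
  # monitoring subsample control$seed + 1, the row-chunk cycling
  # control$seed + 2
  part <- minibatchPartition(n, m, R, S, seed = control$seed)
  monitor <- withSeed(control$seed + 1L, {
    obsIdx <- which(data@mask)
    nMon <- max(1L, round(control$monitorFraction * length(obsIdx)))
    sort(sample(obsIdx, nMon))
  })
  monMask <- array(FALSE, dim(data@Y)); monMask[monitor] <- TRUE

  monObjective <- function(pr) {
    mu <- predictMean(data, pr, family)
    ll <- logLikMatrix(data@Y[monitor], mu[monitor], family, pr@phi,
                       data@W[monitor])
    -sum(ll) * (sum(data@mask) / length(monitor)) +
      0.5 * lambda * (frob2(pr@U) + frob2(pr@V))
  }

  # zero-initialized smoothed accumulators
  Gu <- matrix(0, n, d); Hu <- matrix(0, n, d)
  Gv <- matrix(0, m, d); Hv <- matrix(0, m, d)
  Gb <- matrix(0, m, p); Hb <- matrix(0, m, p)
  Gg <- matrix(0, n, q); Hg <- matrix(0, n, q)

  a1 <- control$alpha1; a2 <- control$alpha2
  tUpd <- 0L
  clip <- 0
  rngState <- withSeed(control$seed + 2L,
                       get(".Random.seed", envir = globalenv()))
  rowQueue <- integer(0)
  obj <- monObjective(params)
  obj0 <- obj
  trace <- data.frame(epoch = 0L, objective = obj, change = NA_real_)
  nsmall <- 0L; converged <- FALSE; epoch <- 0L

  while (epoch < control$maxEpochs) {
    epoch <- epoch + 1L
    if (estSize) family <- .updateNBSize(data, params, family)
    for (s in seq_len(S)) {
      if (!length(rowQueue)) {
        # reshuffle the row-chunk cycle deterministically
        old <- if (exists(".Random.seed", envir = globalenv())) {
          e <- get(".Random.seed", envir = globalenv()); e
        } else NULL
        assign(".Random.seed", rngState, envir = globalenv())
        rowQueue <- sample.int(R)
        rngState <- get(".Random.seed", envir = globalenv())
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }
      r <- rowQueue[1]; rowQueue <- rowQueue[-1]
      I <- part$rows[[r]]; J <- part$cols[[s]]
      gh <- minibatchGradients(data, params, I, J, lambda, family,
                               fisher = control$fisher)
      clip <- clip + gh$nclip
      rho <- learningRate(tUpd, control$k0, control$k1, control$tau)
      tb <- tUpd + 1L
      # bias-correction factor; equals 1 identically when a1 == a2
      at <- if (a1 == a2) 1 else (1 - a2^tb) / (1 - a1^tb)
      # V-side (loadings and column coefficients, rows J)
      Gv[J, ] <- (1 - a1) * Gv[J, , drop = FALSE] + a1 * gh$GV
      Hv[J, ] <- (1 - a2) * Hv[J, , drop = FALSE] + a2 * gh$HV
      if (d > 0L) {
        deltaV <- -at * Gv[J, , drop = FALSE] /
          pmax(Hv[J, , drop = FALSE], control$hFloor)
        if (any(!is.finite(deltaV)))
          stopf("non-finite V update in block (%d, %d) at epoch %d",
                r, s, epoch)
        params@V[J, ] <- params@V[J, , drop = FALSE] + rho * deltaV
      }
      if (p > 0L) {
        Gb[J, ] <- (1 - a1) * Gb[J, , drop = FALSE] + a1 * gh$GB
        Hb[J, ] <- (1 - a2) * Hb[J, , drop = FALSE] + a2 * gh$HB
        deltaB <- -at * Gb[J, , drop = FALSE] /
          pmax(Hb[J, , drop = FALSE], control$hFloor)
        if (any(!is.finite(deltaB)))
          stopf("non-finite B update in block (%d, %d) at epoch %d",
                r, s, epoch)
        params@B[J, ] <- params@B[J, , drop = FALSE] + rho * deltaB
      }
      # U-side (factors and row coefficients, rows I), using the block
      # derivatives computed at the start of the visit
      Gu[I, ] <- (1 - a1) * Gu[I, , drop = FALSE] + a1 * gh$GU
      Hu[I, ] <- (1 - a2) * Hu[I, , drop = FALSE] + a2 * gh$HU
      if (d > 0L) {
        deltaU <- -at * Gu[I, , drop = FALSE] /
          pmax(Hu[I, , drop = FALSE], control$hFloor)
        if (any(!is.finite(deltaU)))
          stopf("non-finite U update in block (%d, %d) at epoch %d",
                r, s, epoch)
        params@U[I, ] <- params@U[I, , drop = FALSE] + rho * deltaU
      }
      if (q > 0L) {
        Gg[I, ] <- (1 - a1) * Gg[I, , drop = FALSE] + a1 * gh$GGamma
        Hg[I, ] <- (1 - a2) * Hg[I, , drop = FALSE] + a2 * gh$HGamma
        deltaG <- -at * Gg[I, , drop = FALSE] /
          pmax(Hg[I, , drop = FALSE], control$hFloor)
        if (any(!is.finite(deltaG)))
          stopf("non-finite Gamma update in block (%d, %d) at epoch %d",
                r, s, epoch)
        params@Gamma[I, ] <- params@Gamma[I, , drop = FALSE] + rho * deltaG
      }
      tUpd <- tUpd + 1L
    }
    if (family@dispersionMode == "estimated") {
      phiNew <- .epochDispersionMonitor(data, params, family, d, monitor)
      params@phi <- (1 - a2) * params@phi + a2 * phiNew
    }
    objNew <- monObjective(params)
    if (!is.finite(objNew))
      stopf("monitored objective is not finite at epoch %d", epoch)
    ch <- relChange(objNew, obj)
    obj <- objNew
    trace <- rbind(trace, data.frame(epoch = epoch, objective = obj,
                                     change = ch))
    if (obj > control$divergeFactor * abs(obj0) + abs(obj0))
      stopf("objective diverged at epoch %d", epoch)
    nsmall <- if (ch < control$tol) nsmall + 1L else 0L
    if (nsmall >= control$convWindow) { converged <- TRUE; break }
  }
  .finishFit(data, params, family, lambda, "sgd", trace, converged,
             epoch, clip, control, parametrization,
             extra = list(rowChunks = R, colChunks = S,
                          monitorSize = length(monitor)))
}

# Pearson dispersion on the monitoring subsample only.
.epochDispersionMonitor <- function(data, params, family, d, monitor) {
  mu <- predictMean(data, params, family)
  npar <- ncol(data@X) * ncol(data@Y) + ncol(data@Z) * nrow(data@Y) +
    d * sum(dim(data@Y))
  nparEff <- npar * length(monitor) / sum(data@mask)
  estimateDispersion(data@Y[monitor], mu[monitor], family, data@W[monitor],
                     npar = min(nparEff, length(monitor) - 1))
}
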