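# Rank selection: information criteria, entrywise-holdout cross-validation
# and spectral (eigengap / elbow) rules.

#' Entrywise holdout split
#'
#' Samples a fraction of matrix positions uniformly at random as a test
#' set, then repairs the split so that every row and every column keeps at
#' least one training entry (offending test entries are moved back to the
#' training set). The split is a deterministic function of the seed.
#'
#' @param n,m matrix dimensions.
#' @param fraction fraction of entries to hold out, in (0, 1).
#' @param seed integer seed.
#' @return list with logical matrices \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
holdoutMask <- function(n, m, fraction = 0.3, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stopf("fraction must lie strictly between 0 and 1")
  k <- round(fraction * n * m)
  if (k < 1) stopf("holdout fraction too small: empty test set")
  if (k >= n * m) stopf("holdout fraction too large: empty training set")
  test <- matrix(FALSE, n, m)
  withSeed(seed, {
    test[sample.int(n * m, k)] <- TRUE
    repeat {
      badRows <- which(rowSums(!test) == 0L)
      badCols <- which(colSums(!test) == 0L)
      if (!length(badRows) && !length(badCols)) break
      for (i in badRows) {
        j <- sample(which(test[i, ]), 1L)
        test[i, j] <- FALSE
      }
      for (j in badCols) {
        if (all(!test[, j])) next
        i <- sample(which(test[, j]), 1L)
        test[i, j] <- FALSE
      }
    }
  })
  if (!any(test)) stopf("retention rule removed every test entry")
  list(train = !test, test = test)
}

#' Information criteria for a fitted GMF model
#'
#' \code{AIC = 2 nll + 2k} and \code{BIC = 2 nll + k log |Omega|} with
#' \code{nll} the negative log-likelihood over observed entries (penalty
#' excluded, response-only constants included) and effective parameter
#' count \eqn{k = pm + qn + d(n+m) + 1}.
#'
#' @param fit a \code{\link{GMFFit}}.
#' @param data the \code{\link{GMFData}} the model was fitted on.
#' @return named vector with elements \code{AIC} and \code{BIC}.
#' @export
informationCriteria <- function(fit, data) {
  obs <- data@mask
  mu <- predictMean(data, fit@params, fit@family)
  nll <- -sum(logLikMatrix(data@Y[obs], mu[obs], fit@family,
                           fit@params@phi, data@W[obs]))
  k <- fit@npar
  c(AIC = 2 * nll + 2 * k, BIC = 2 * nll + k * log(sum(obs)))
}

#' Rank selection by cross-validated out-of-sample error
#'
#' For each candidate rank, fits the model on entrywise-holdout training
#' sets and scores the reconstruction on the held-out entries with the
#' relative deviance and the relative logarithmic RMSE
#' (\code{\link{relativeDeviance}}, \code{\link{relativeLogRMSE}});
#' \code{folds} independent uniform holdouts are used (repeated holdout
#' validation rather than a disjoint K-fold partition). Ranks are
#' processed in ascending order with warm starts: the previous rank's
#' parameters are padded with near-zero columns (small seeded
#' perturbations, since exactly-zero padded columns are a stationary point
#' of every update rule). Full-data fits per rank (also warm-started)
#' supply AIC and BIC. Test entries are masked before initialization, so
#' no information leaks from the holdout.
#'
#' @param data a \code{\link{GMFData}}.
#' @param family a \code{\link{GMFFamily}}.
#' @param grid candidate ranks.
#' @param folds number of independent holdout repetitions.
#' @param fraction holdout fraction per repetition.
#' @param lambda latent ridge penalty used for every fit.
#' @param algorithm fitting algorithm.
#' @param control a \code{\link{gmfControl}}; its seed drives the holdout
#'   draws and all fits.
#' @param computeIC also run full-data fits for AIC/BIC (set to
#'   \code{FALSE} to save time when only the CV curve is needed).
#' @return a \code{\link{GMFRankSelection}}.
#' @export
cvRankSelect <- function(data, family, grid = 1:5, folds = 3L,
                         fraction = 0.3, lambda = 1,
                         algorithm = c("newton", "airwls", "sgd"),
                         control = gmfControl(), computeIC = TRUE) {
  algorithm <- match.arg(algorithm)
  grid <- sort(unique(as.integer(grid)))
  n <- nrow(data@Y); m <- ncol(data@Y)
  if (any(grid < 0) || any(grid > min(n, m)))
    stopf("rank grid must lie within [0, min(n, m)]")
  nr <- length(grid)
  cvDev <- matrix(NA_real_, folds, nr,
                  dimnames = list(NULL, paste0("d", grid)))
  cvErr <- cvDev
  failures <- data.frame(fold = integer(0), rank = integer(0))

  fitter <- function(dat, init, ctl)
    switch(algorithm,
           newton = fitNewton(dat, init, family, lambda, ctl),
           airwls = fitAIRWLS(dat, init, family, lambda, ctl),
           sgd = fitSGD(dat, init, family, lambda, ctl))

  runPath <- function(dat, seedBase) {
    # ascending-rank fitting path with warm starts; returns list of fits
    fits <- vector("list", nr)
    prev <- NULL
    for (g in seq_len(nr)) {
      dg <- grid[g]
      ctl <- control
      ctl$seed <- as.integer((seedBase + g) %% .Machine$integer.max)
      init <- if (is.null(prev)) {
        gmfInit(dat, family, rank = dg)
      } else {
        padParams(prev, dg, seed = ctl$seed)
      }
      fits[[g]] <- fitter(dat, init, ctl)
      prev <- fits[[g]]@params
    }
    fits
  }

  for (f in seq_len(folds)) {
    split <- holdoutMask(n, m, fraction, seed = control$seed + 1000L * f)
    trainData <- data
    trainData@mask <- data@mask & split$train
    testMask <- data@mask & split$test
    fits <- runPath(trainData, seedBase = control$seed + 1000L * f)
    trainMean <- mean(trainData@Y[trainData@mask])
    for (g in seq_len(nr)) {
      fit <- fits[[g]]
      if (!fit@converged)
        failures <- rbind(failures,
                          data.frame(fold = f, rank = grid[g]))
      mu <- predictMean(data, fit@params, fit@family)
      cvDev[f, g] <- relativeDeviance(data@Y, mu, trainMean, testMask,
                                      fit@family, data@W)
      cvErr[f, g] <- relativeLogRMSE(data@Y, mu, trainMean, testMask)
    }
  }
  if (nrow(failures))
    warning(sprintf("%d cross-validation fits did not converge; criteria average over all fits",
                    nrow(failures)))

  aic <- rep(NA_real_, nr); bic <- rep(NA_real_, nr)
  if (computeIC) {
    fits <- runPath(data, seedBase = control$seed)
    for (g in seq_len(nr)) {
      ic <- informationCriteria(fits[[g]], data)
      aic[g] <- ic["AIC"]; bic[g] <- ic["BIC"]
    }
  }

  meanDev <- colMeans(cvDev)
  best <- c(cv = grid[which.min(meanDev)])
  if (computeIC)
    best <- c(best, aic = grid[which.min(aic)], bic = grid[which.min(bic)])
  new("GMFRankSelection", grid = grid, aic = aic, bic = bic,
      cvDeviance = cvDev, cvError = cvErr, best = best,
      failures = failures)
}

# Pad a parameter set to a higher rank with small seeded entries (exact
# zeros would be a stationary point of all three update rules).
padParams <- function(params, d, seed = 1L, scale = 1e-4) {
  d0 <- ncol(params@U)
  if (d < d0) stopf("cannot pad down from rank %d to %d", d0, d)
  if (d == d0) return(params)
  n <- nrow(params@U); m <- nrow(params@V)
  extra <- d - d0
  withSeed(seed, {
    params@U <- cbind(params@U, matrix(stats::rnorm(n * extra, 0, scale),
                                       n, extra))
    params@V <- cbind(params@V, matrix(stats::rnorm(m * extra, 0, scale),
                                       m, extra))
  })
  params
}

#' Spectral rank selection from null-model residuals
#'
#' Computes the singular-value profile of the residual matrix of the
#' regression-only model (rank-0 fit of \code{\link{gmfInit}}, deviance or
#' Pearson residuals, or link-scale residuals under the least-squares fast
#' path) and selects the rank by either the eigengap rule
#' (\eqn{\arg\max_{k \le d_{max}} \sigma_k - \sigma_{k+1}}) or the elbow
#' rule (the knee of the cumulative singular-value profile: the point with
#' maximum perpendicular distance to the chord joining the profile's
#' endpoints).
#'
#' Residual columns are mean-centered before the decomposition, so the
#' profile is the PCA spectrum of the residuals. (Deviance residuals of
#' count families are skewed: their per-gene means are non-zero even at a
#' perfect null fit, which would otherwise inject an artifactual dominant
#' component constant across cells.)
#'
#' @param data a \code{\link{GMFData}}.
#' @param family a \code{\link{GMFFamily}}.
#' @param dmax largest candidate rank (at most \eqn{\min(n,m) - 1}).
#' @param rule \code{"eigengap"} or \code{"elbow"}.
#' @param method,residualType residual construction, as in
#'   \code{\link{gmfInit}}.
#' @return list with the selected \code{rank}, the singular \code{values}
#'   (length \code{dmax + 1}) and the \code{rule} used.
#' @export
spectralRank <- function(data, family, dmax = 10L,
                         rule = c("eigengap", "elbow"),
                         method = c("glm", "ols"),
                         residualType = c("deviance", "pearson")) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  residualType <- match.arg(residualType)
  dmax <- as.integer(dmax)
  if (dmax < 1) stopf("dmax must be at least 1")
  if (dmax > min(dim(data@Y)) - 1L)
    stopf("dmax must not exceed min(n, m) - 1")
  nullFit <- gmfInit(data, family, rank = 0L, method = method,
                     residualType = residualType)
  R <- attr(nullFit, "residualMatrix")
  R <- sweep(R, 2, colMeans(R))
  sv <- svd(R, nu = 0, nv = 0)$d
  values <- sv[seq_len(dmax + 1L)]
  if (dmax == 1L) {
    warning("dmax = 1: degenerate singular-value profile")
    return(list(rank = 1L, values = values, rule = rule))
  }
  if (rule == "eigengap") {
    gaps <- values[seq_len(dmax)] - values[-1]
    rank <- which.max(gaps)
  } else {
    # knee of the cumulative profile: maximum perpendicular distance to the
    # chord joining its endpoints
    cum <- cumsum(values[seq_len(dmax)])
    k <- seq_len(dmax)
    x1 <- 1; y1 <- cum[1]; x2 <- dmax; y2 <- cum[dmax]
    dist <- abs((y2 - y1) * k - (x2 - x1) * cum +
                  x2 * y1 - y2 * x1) / sqrt((y2 - y1)^2 + (x2 - x1)^2)
    rank <- which.max(dist)
  }
  list(rank = as.integer(rank), values = values, rule = rule)
}
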