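# Out-of-sample reconstruction metrics on an entrywise holdout.

#' Relative logarithmic root mean squared error
#'
#' \deqn{\mathrm{Error} = \frac{\sum_{(i,j) \in \mathcal{V}}
#'   [\log(1+y_{ij}) - \log(1+\hat\mu_{ij})]^2}
#'   {\sum_{(i,j) \in \mathcal{V}} [\log(1+y_{ij}) -
#'   \log(1+\bar y_{\mathcal T})]^2}}
#' where \eqn{\bar y_{\mathcal T}} is the mean of the observed training
#' entries. Values below 1 indicate reconstruction better than the
#' train-mean predictor; a perfect reconstruction scores 0.
#'
#' @param y response matrix.
#' @param mu fitted mean matrix.
#' @param trainMean scalar mean of the training responses.
#' @param testMask logical matrix selecting the held-out entries.
#' @return dimensionless error ratio.
#' @export
relativeLogRMSE <- function(y, mu, trainMean, testMask) {
  v <- which(testMask)
  if (!length(v)) stopf("empty test set")
  num <- sum((log1p(y[v]) - log1p(mu[v]))^2)
  den <- sum((log1p(y[v]) - log1p(trainMean))^2)
  if (den <= 0)
    stopf("undefined metric: all test responses equal the training mean")
  num / den
}

#' Relative out-of-sample deviance
#'
#' \deqn{\mathrm{Deviance} = \frac{\sum_{(i,j) \in \mathcal{V}}
#'   D(y_{ij}, \hat\mu_{ij})}{\sum_{(i,j) \in \mathcal{V}}
#'   D(y_{ij}, \bar y_{\mathcal T})}}
#' with the family's unit deviance \eqn{D}; the Poisson case is the
#' relative Poisson deviance used to benchmark count factorizations.
#'
#' @inheritParams relativeLogRMSE
#' @param family a \code{\link{GMFFamily}}.
#' @param weights prior weights (recycled).
#' @return dimensionless deviance ratio (0 = perfect, 1 = null predictor).
#' @export
relativeDeviance <- function(y, mu, trainMean, testMask, family,
                             weights = 1) {
  v <- which(testMask)
  if (!length(v)) stopf("empty test set")
  w <- matrix(0, nrow(as.matrix(y)), ncol(as.matrix(y))); w[] <- weights
  num <- sum(devianceMatrix(y[v], mu[v], family, w[v]))
  den <- sum(devianceMatrix(y[v], rep(trainMean, length(v)), family, w[v]))
  if (den <= 0)
    stopf("undefined metric: zero null deviance on the test set")
  num / den
}
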