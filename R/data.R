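#' Assemble a GMFData object
#'
#' Wraps the response matrix together with row covariates, column covariates,
#' prior weights, an observation mask and an optional linear-predictor
#' offset. Missing (\code{NA}/\code{NaN}) entries of \code{Y} are treated as
#' unobserved and are imputed from the model during fitting; their stored
#' values are never read.
#'
#' By default both covariate matrices contain a single intercept column, so
#' the model includes gene-specific baselines \eqn{\beta_{0j}} and
#' cell-specific scale factors \eqn{\gamma_{0i}} (the latter play the role of
#' estimated library-size factors for raw counts). Pass a matrix with zero
#' columns (e.g. \code{matrix(0, n, 0)}) to drop a regression block
#' entirely.
#'
#' @param Y numeric response matrix (\eqn{n} cells by \eqn{m} genes).
#' @param X row covariates (\eqn{n \times p}); \code{NULL} for an intercept
#'   only.
#' @param Z column covariates (\eqn{m \times q}); \code{NULL} for an
#'   intercept only.
#' @param weights positive prior weights, recycled to the shape of \code{Y}.
#' @param offset additive offset on the linear-predictor scale, recycled to
#'   the shape of \code{Y}; excluded from all penalties and updates.
#' @param mask optional logical matrix, \code{TRUE} = observed; combined
#'   (logical and) with non-missingness of \code{Y}.
#' @return a \code{\link{GMFData}} object.
#' @examples
#' Y <- matrix(rpois(20, 5), 4, 5)
#' gmfData(Y)
#' @export
gmfData <- function(Y, X = NULL, Z = NULL, weights = 1, offset = 0,
                    mask = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y); m <- ncol(Y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(Z)) Z <- matrix(1, m, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X); Z <- as.matrix(Z)
  storage.mode(X) <- "double"; storage.mode(Z) <- "double"
  W <- matrix(0, n, m); W[] <- weights
  O <- matrix(0, n, m); O[] <- offset
  obs <- is.finite(Y)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(Y)))
      stopf("mask must have the same shape as Y")
    obs <- obs & mask
  }
  new("GMFData", Y = Y, X = X, Z = Z, W = W, mask = obs, offset = O)
}

#' Construct a GMFParams object
#'
#' @param B column-effect coefficients (\eqn{m \times p}).
#' @param Gamma row-effect coefficients (\eqn{n \times q}).
#' @param U latent factors (\eqn{n \times d}).
#' @param V loadings (\eqn{m \times d}).
#' @param phi positive dispersion.
#' @return a \code{\link{GMFParams}} object.
#' @export
gmfParams <- function(B, Gamma, U, V, phi = 1) {
  new("GMFParams", B = as.matrix(B), Gamma = as.matrix(Gamma),
      U = as.matrix(U), V = as.matrix(V), phi = as.numeric(phi))
}

# Zero parameter set conformal with `data` at rank d.
zeroParams <- function(data, d, phi = 1) {
  n <- nrow(data@Y); m <- ncol(data@Y)
  gmfParams(B = matrix(0, m, ncol(data@X)),
            Gamma = matrix(0, n, ncol(data@Z)),
            U = matrix(0, n, d), V = matrix(0, m, d), phi = phi)
}

# Check that params conform to data.
checkConformal <- function(data, params) {
  n <- nrow(data@Y); m <- ncol(data@Y)
  if (nrow(params@B) != m || ncol(params@B) != ncol(data@X))
    stopf("B must be %d x %d", m, ncol(data@X))
  if (nrow(params@Gamma) != n || ncol(params@Gamma) != ncol(data@Z))
    stopf("Gamma must be %d x %d", n, ncol(data@Z))
  if (nrow(params@U) != n) stopf("U must have %d rows", n)
  if (nrow(params@V) != m) stopf("V must have %d rows", m)
  invisible(TRUE)
}
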