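# Projection of an unconstrained parameter set onto the identifiability
# constraint space without changing the fitted linear predictor.

#' Project parameters onto the identifiability constraint space
#'
#' The GMF decomposition \eqn{X B^\top + \Gamma Z^\top + U V^\top} is
#' invariant under rotation, scaling and sign flips of \eqn{(U, V)} and
#' under shifts between the regression and latent blocks along the covariate
#' column spaces. This projection makes the decomposition unique while
#' leaving \eqn{\eta} unchanged:
#' \itemize{
#'   \item orthogonality: \eqn{X^\top \Gamma = 0}, \eqn{X^\top U = 0},
#'     \eqn{Z^\top V = 0} — covariate-space components are absorbed into the
#'     regression blocks by least squares;
#'   \item normalization, one of
#'     \describe{
#'       \item{B1}{\eqn{U^\top U} diagonal with decreasing positive diagonal
#'         (squared singular values of \eqn{U V^\top}), \eqn{V^\top V = I_d},
#'         first non-zero entry of each column of \eqn{V} positive — the PCA
#'         convention, standard in the RNA-seq literature;}
#'       \item{B2}{the mirror image (orthonormal \eqn{U});}
#'       \item{B3}{columns of \eqn{U} standardized to unit variance and
#'         \eqn{V} lower triangular with positive diagonal — the factor-model
#'         convention; requires an intercept in the column space of \eqn{X}.}
#'     }
#' }
#' The rotation is computed from a thin QR + SVD of \eqn{U V^\top}, so the
#' singular values of the factorization are preserved (B1/B2). "First
#' non-zero" uses threshold \code{1e-12}, ties broken by the lowest row
#' index; with exactly tied singular values the rotation within the tied
#' block is fixed only up to the sign rule (noted in fit manifests).
#'
#' @param data a \code{\link{GMFData}} (supplies \code{X} and \code{Z}).
#' @param params a \code{\link{GMFParams}}.
#' @param parametrization \code{"B1"}, \code{"B2"} or \code{"B3"}.
#' @return the projected \code{\link{GMFParams}}; the linear predictor is
#'   preserved to numerical accuracy and the map is idempotent.
#' @export
projectConstraints <- function(data, params, parametrization = c("B1", "B2", "B3")) {
  parametrization <- match.arg(parametrization)
  checkConformal(data, params)
  X <- data@X; Z <- data@Z
  B <- params@B; Gamma <- params@Gamma; U <- params@U; V <- params@V
  d <- ncol(U); p <- ncol(X); q <- ncol(Z)

  # (1) absorb the Z-column-space component of V into Gamma
  if (q > 0L && d > 0L) {
    A <- lsSolve(Z, V)                  # q x d
    Gamma <- Gamma + U %*% t(A)
    V <- V - Z %*% A
  }
  # (2) absorb the X-column-space component of Gamma into B
  if (p > 0L && q > 0L) {
    A <- lsSolve(X, Gamma)              # p x q
    B <- B + Z %*% t(A)
    Gamma <- Gamma - X %*% A
  }
  # (3) absorb the X-column-space component of U into B
  if (p > 0L && d > 0L) {
    A <- lsSolve(X, U)                  # p x d
    B <- B + V %*% t(A)
    U <- U - X %*% A
  }

  if (d > 0L) {
    rot <- .rotateFactors(U, V, parametrization, X)
    U <- rot$U; V <- rot$V
  }
  gmfParams(B = B, Gamma = Gamma, U = U, V = V, phi = params@phi)
}

.rotateFactors <- function(U, V, parametrization, X) {
  d <- ncol(U)
  if (parametrization == "B3" && !hasIntercept(X))
    stopf("parametrization B3 requires an intercept in the column space of X")
  if (parametrization %in% c("B1", "B2")) {
    qu <- qr(U); qv <- qr(V)
    M <- qr.R(qu) %*% t(qr.R(qv))
    sv <- svd(M)
    L <- qr.Q(qu) %*% sv$u
    R <- qr.Q(qv) %*% sv$v
    sig <- sv$d
    if (parametrization == "B1") {
      Unew <- sweep(L, 2, sig, "*")
      Vnew <- R
      flip <- .signFix(Vnew)
    } else {
      Unew <- L
      Vnew <- sweep(R, 2, sig, "*")
      flip <- .signFix(Unew)
    }
    Unew <- sweep(Unew, 2, flip, "*")
    Vnew <- sweep(Vnew, 2, flip, "*")
    return(list(U = Unew, V = Vnew))
  }
  # B3: unit-variance (centered) factor columns, lower-triangular loadings.
  n <- nrow(U)
  S <- crossprod(U) / n   # U is centered: X contains an intercept and XᵀU=0
  es <- eigen(S, symmetric = TRUE)
  vals <- pmax(es$values, 1e-24)
  Sinvh <- es$vectors %*% (t(es$vectors) / sqrt(vals))
  Sh <- es$vectors %*% (t(es$vectors) * sqrt(vals))
  M <- V %*% Sh
  Md <- M[seq_len(d), , drop = FALSE]
  qrm <- qr(t(Md))
  Q <- qr.Q(qrm)
  Rm <- qr.R(qrm)
  s <- sign(diag(Rm)); s[s == 0] <- 1
  Q <- sweep(Q, 2, s, "*")
  list(U = U %*% Sinvh %*% Q, V = M %*% Q)
}

# Column sign flips making the first non-zero entry positive.
.signFix <- function(M, tol = 1e-12) {
  vapply(seq_len(ncol(M)), function(k) {
    col <- M[, k]
    idx <- which(abs(col) > tol)
    if (!length(idx)) 1 else sign(col[idx[1]])
  }, numeric(1))
}
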