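# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so library calls do not perturb user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# x * log(x / y) with the x -> 0 limit evaluated as 0.
ylogy <- function(x, y) {
  out <- numeric(length(x))
  pos <- (x > 0)
  out[pos] <- x[pos] * log(x[pos] / y[pos])
  dim(out) <- dim(x)
  out
}

# Frobenius norm squared.
frob2 <- function(x) sum(x * x)

# Balanced deterministic assignment of `idx` (already shuffled) into k chunks
# whose sizes differ by at most one.
chunkSizes <- function(n, k) {
  base <- rep.int(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

# Relative change used by convergence monitors.
relChange <- function(new, old) abs(new - old) / (abs(old) + 1e-10)

# Stop with a formatted message.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Is `1` in the column space of X? (used by the B3 parametrization)
hasIntercept <- function(X) {
  if (ncol(X) == 0L) return(FALSE)
  ones <- rep(1, nrow(X))
  fit <- qr.resid(qr(X), ones)
  sqrt(sum(fit^2)) < 1e-8 * sqrt(nrow(X))
}

# Least-squares coefficient solve( t(A) A, t(A) B ) with a ridge of `eps`
# only if the cross-product is numerically singular.
lsSolve <- function(A, B) {
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  tryCatch(solve(AtA, AtB), error = function(e) {
    solve(AtA + diag(1e-10, ncol(A)), AtB)
  })
}
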