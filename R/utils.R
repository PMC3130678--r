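# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Matrix exponential of -A * t for symmetric A via eigendecomposition.
expm_sym_neg <- function(eig, t) {
  # eig: result of eigen(A, symmetric = TRUE)
  U <- eig$vectors
  U %*% (exp(-eig$values * t) * t(U))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_spd <- function(A, tol = 1e-10) {
  if (!isSymmetric(unname(A), tol = 1e-8)) return(FALSE)
  all(eigen(A, symmetric = TRUE, only.values = TRUE)$values > tol)
}
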