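# Internal numerical helpers shared across modules.

#' Solve a symmetric positive-definite linear system
#'
#' Uses the Cholesky factorization; if the matrix is not numerically positive
#' definite the Moore-Penrose pseudo-inverse is used instead, with a warning.
#' Never forms an explicit inverse on the main path.
#'
#' @param A symmetric matrix (q x q).
#' @param b vector or matrix of right-hand sides.
#' @return solution with the same number of columns as `b`.
#' @keywords internal
#' @noRd
solve_spd <- function(A, b) {
  A <- as.matrix(A)
  b <- as.matrix(b)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    warning("matrix not positive definite; falling back to pseudo-inverse ",
            "(consider lambda > 0)")
    return(MASS::ginv(A) %*% b)
  }
  backsolve(R, forwardsolve(t(R), b))
}

# Two-sided normal P-value from a Z-statistic; safe for NA.
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stream label.
# Keeps every simulation stage independently reproducible from one user seed.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562L) + 1L
}

# Half-open window index for a position given a grid anchored at `origin`.
window_index <- function(pos, origin, core_bp) {
  as.integer(floor((pos - origin) / core_bp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
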