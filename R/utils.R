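# Internal numerical helpers shared across modules.

# Relative tolerance used when deciding that a covariance matrix is
# acceptably positive semi-definite: min eigenvalue >= -psd_tol * spectral
# norm, after symmetrization.
.psd_tol <- 1e-10

# Condition-number threshold beyond which linear_fisher() switches to the
# support-restricted pseudo-inverse path.
.cond_threshold <- 1e12

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

check_finite_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || !all(is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector.", name))
  }
  invisible(x)
}

symmetrize <- function(S) (S + t(S)) / 2

# Minimum and maximum eigenvalue of a symmetric matrix.
eig_range <- function(S) {
  ev <- eigen(symmetrize(S), symmetric = TRUE, only.values = TRUE)$values
  c(min(ev), max(ev))
}

assert_psd <- function(S, what = "covariance matrix", tol = .psd_tol) {
  er <- eig_range(S)
  scale <- max(abs(er), .Machine$double.eps)
  if (er[1] < -tol * scale) {
    abort(sprintf(
      "%s is not positive semi-definite: minimum eigenvalue %.6g (spectral norm %.6g).",
      what, er[1], scale
    ))
  }
  invisible(er[1])
}

# Symmetric positive-definite solve via Cholesky; returns solution of S x = b.
chol_solve <- function(S, b) {
  R <- chol(symmetrize(S))
  backsolve(R, forwardsolve(t(R), b))
}

# PSD-safe square root factor L with L %*% t(L) = S (eigen based, clips tiny
# negative eigenvalues).
psd_factor <- function(S) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam), nrow = length(lam))
}

#' Equally spaced stimulus grid on \eqn{[0, 2\pi)}
#'
#' @param k Number of grid points.
#' @return Numeric vector of `k` angles in radians, starting at 0, excluding
#'   \eqn{2\pi}.
#' @examples
#' stimulus_grid(4)
#' @export
stimulus_grid <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer.")
  }
  seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
}

#' Derive independent sub-seeds from one run seed
#'
#' A single run seed is split hierarchically into per-stage seeds (population
#' draw, auxiliary direction, Monte Carlo sampling, ...) so that changing one
#' stage's random-number consumption does not desynchronize the others. The
#' global RNG state is left untouched.
#'
#' @param seed Integer run seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @examples
#' rng_streams(1, 3)
#' @export
rng_streams <- function(seed, n) {
  check_finite_scalar(seed, "seed")
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
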