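#' Poisson-like diagonal base covariance
#'
#' Builds the diagonal covariance \eqn{\Sigma_0} with entries equal to the
#' mean responses, \eqn{\Sigma_{0,ii} = f_i(s)}, so each neuron has Fano
#' factor 1 before any structured perturbation is added.
#'
#' @param f_values Vector of mean rates, elementwise `> 0` (the information
#'   formulas need an invertible base).
#' @return A diagonal matrix.
#' @examples
#' poisson_diagonal(c(1, 2, 3))
#' @export
poisson_diagonal <- function(f_values) {
  check_finite_vector(f_values, "f_values")
  if (any(f_values <= 0)) {
    abort("All mean responses must be > 0 to build an invertible diagonal base.")
  }
  diag(f_values, nrow = length(f_values))
}

#' Rotate the signal direction by a fixed angle within a reproducible plane
#'
#' Constructs the perturbation direction `u` used by the tilted covariance:
#' `u` has the same Euclidean norm as `f_prime` and makes an angle `theta_u`
#' with it. The rotation happens in the 2-plane spanned by `f_prime` and the
#' component of `aux` orthogonal to it; `aux` is one fixed vector per
#' experiment so the tilt plane is reproducible and varies continuously with
#' the stimulus.
#'
#' @param f_prime Signal direction \eqn{f'(s)}, non-zero.
#' @param theta_u Tilt angle in radians.
#' @param aux Auxiliary vector, not parallel to `f_prime`.
#' @return Vector `u` with `|u| = |f_prime|` and `angle(u, f_prime) = theta_u`.
#' @examples
#' u <- tilted_direction(c(1, 0, 0), pi / 2, aux = c(0, 1, 0))
#' sum(u * c(1, 0, 0)) # orthogonal
#' @export
tilted_direction <- function(f_prime, theta_u, aux) {
  check_finite_vector(f_prime, "f_prime")
  check_finite_scalar(theta_u, "theta_u")
  check_finite_vector(aux, "aux")
  nf <- sqrt(sum(f_prime^2))
  if (nf == 0) abort("`f_prime` must be non-zero.")
  fhat <- f_prime / nf
  v <- aux - sum(aux * fhat) * fhat
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12 * sqrt(sum(aux^2))) {
    abort("`aux` must not be parallel to `f_prime`.")
  }
  nf * (cos(theta_u) * fhat + sin(theta_u) * v / nv)
}

#' Diagonal base plus rank-one covariance
#'
#' Builds \eqn{\Sigma_\xi = \gamma_u \Sigma_0 + \epsilon\, u u^\top}. A
#' negative `epsilon` (synergistic codes) is allowed as long as the result
#' stays positive semi-definite; a violation is an error that names the
#' offending minimum eigenvalue.
#'
#' @param Sigma0 Diagonal positive base covariance (see [poisson_diagonal()]).
#' @param gamma_u Overall scale on the base, `> 0`.
#' @param epsilon Rank-one strength (may be negative).
#' @param u Perturbation direction (required unless `epsilon = 0`).
#' @return Symmetric PSD covariance matrix.
#' @seealso [rank1_inverse()], [normalized_rank1_covariance()]
#' @export
rank1_covariance <- function(Sigma0, gamma_u = 1, epsilon = 0, u = NULL) {
  d <- check_diag_base(Sigma0)
  check_finite_scalar(gamma_u, "gamma_u")
  check_finite_scalar(epsilon, "epsilon")
  if (gamma_u <= 0) abort("`gamma_u` must be > 0.")
  S <- diag(gamma_u * d, nrow = length(d))
  if (epsilon != 0) {
    if (is.null(u)) abort("`u` is required when `epsilon` != 0.")
    check_finite_vector(u, "u")
    S <- S + epsilon * tcrossprod(u)
  }
  S <- symmetrize(S)
  assert_psd(S, what = "rank-one covariance")
  S
}

#' Closed-form inverse of the diagonal-plus-rank-one covariance
#'
#' Sherman–Morrison inverse of \eqn{\gamma_u \Sigma_0 + \epsilon u u^\top}:
#' \deqn{\Sigma_\xi^{-1} = \frac{1}{\gamma_u}\left[\Sigma_0^{-1} -
#'   \frac{(\epsilon/\gamma_u)\,\Sigma_0^{-1} u u^\top \Sigma_0^{-1}}
#'        {1 + (\epsilon/\gamma_u)\, u^\top \Sigma_0^{-1} u}\right].}
#'
#' @inheritParams rank1_covariance
#' @return The inverse covariance matrix.
#' @export
rank1_inverse <- function(Sigma0, gamma_u = 1, epsilon = 0, u = NULL) {
  d <- check_diag_base(Sigma0)
  check_finite_scalar(gamma_u, "gamma_u")
  if (gamma_u <= 0) abort("`gamma_u` must be > 0.")
  inv0 <- diag(1 / d, nrow = length(d))
  if (epsilon == 0) {
    return(inv0 / gamma_u)
  }
  if (is.null(u)) abort("`u` is required when `epsilon` != 0.")
  check_finite_vector(u, "u")
  w <- u / d
  denom <- 1 + (epsilon / gamma_u) * sum(u * w)
  if (abs(denom) < 1e-14) {
    abort("Singular configuration: 1 + (epsilon/gamma_u) * u' Sigma0^-1 u is zero.")
  }
  (inv0 - (epsilon / gamma_u) * tcrossprod(w) / denom) / gamma_u
}

check_diag_base <- function(Sigma0) {
  if (is.matrix(Sigma0)) {
    off <- Sigma0 - diag(diag(Sigma0), nrow = nrow(Sigma0))
    if (any(abs(off) > 0)) abort("`Sigma0` must be diagonal.")
    d <- diag(Sigma0)
  } else {
    d <- Sigma0
  }
  check_finite_vector(d, "Sigma0")
  if (any(d <= 0)) abort("`Sigma0` must have strictly positive diagonal entries.")
  d
}

#' Information-preserving scale factor for a perturbed covariance
#'
#' For the normalized construction \eqn{\Sigma_\xi = \gamma_u(\Sigma_0 +
#' \epsilon_u u u^\top)}, the scale
#' \deqn{\gamma_u = \frac{1}{I_x^{\rm target}}\left[f'^\top \Sigma_0^{-1} f' -
#'   \frac{\epsilon_u (f'^\top \Sigma_0^{-1} u)^2}
#'        {1 + \epsilon_u u^\top \Sigma_0^{-1} u}\right]}
#' makes the input-layer information exactly `I_x_target`, independent of
#' `epsilon_u` and `u`. [normalized_rank1_covariance()] applies it.
#'
#' @param f_prime Signal direction.
#' @param Sigma0 Diagonal positive base covariance.
#' @param epsilon_u Rank-one strength before scaling.
#' @param u Perturbation direction.
#' @param I_x_target Target input information, `> 0` (radian^-2).
#' @return Scalar `gamma_u > 0`.
#' @export
gamma_u_normalization <- function(f_prime, Sigma0, epsilon_u, u, I_x_target) {
  d <- check_diag_base(Sigma0)
  check_finite_vector(f_prime, "f_prime")
  check_finite_scalar(epsilon_u, "epsilon_u")
  check_finite_scalar(I_x_target, "I_x_target")
  if (I_x_target <= 0) abort("`I_x_target` must be > 0.")
  I0 <- sum(f_prime^2 / d)
  if (epsilon_u == 0) {
    gamma_u <- I0 / I_x_target
  } else {
    check_finite_vector(u, "u")
    a <- sum(f_prime * u / d)^2
    b <- sum(u^2 / d)
    gamma_u <- (I0 - epsilon_u * a / (1 + epsilon_u * b)) / I_x_target
  }
  if (!is.finite(gamma_u) || gamma_u <= 0) {
    abort("Ill-posed target: the information-preserving scale gamma_u is not positive.")
  }
  gamma_u
}

#' Rank-one-perturbed covariance normalized to a fixed input information
#'
#' Builds \eqn{\Sigma_\xi = \gamma_u(\Sigma_0 + \epsilon_u u u^\top)} with
#' `gamma_u` from [gamma_u_normalization()], so that
#' [linear_fisher()]`(f_prime, Sigma)` equals `I_x_target` exactly for every
#' admissible `(epsilon_u, u)`.
#'
#' @inheritParams gamma_u_normalization
#' @return Covariance matrix with attribute `"gamma_u"`.
#' @export
normalized_rank1_covariance <- function(f_prime, Sigma0, epsilon_u, u, I_x_target) {
  gamma_u <- gamma_u_normalization(f_prime, Sigma0, epsilon_u, u, I_x_target)
  S <- rank1_covariance(Sigma0, gamma_u = gamma_u, epsilon = gamma_u * epsilon_u, u = u)
  attr(S, "gamma_u") <- gamma_u
  S
}

#' Solve the rank-one strength that matches a target input information
#'
#' With the base scale fixed at 1, solves
#' \deqn{I_0 - \frac{\epsilon_u (f'^\top\Sigma_0^{-1}u)^2}
#'   {1 + \epsilon_u u^\top \Sigma_0^{-1} u} = I_x^{\rm target}}
#' for \eqn{\epsilon_u} (linear-fractional, closed form). This is how the
#' companion ("tilted") population of the noise-robustness experiments is
#' given the same per-stimulus information as the reference population.
#'
#' @inheritParams gamma_u_normalization
#' @return Scalar `epsilon_u`; the resulting covariance
#'   `rank1_covariance(Sigma0, 1, epsilon_u, u)` is verified PSD.
#' @export
epsilon_match <- function(f_prime, Sigma0, u, I_x_target) {
  d <- check_diag_base(Sigma0)
  check_finite_vector(f_prime, "f_prime")
  check_finite_vector(u, "u")
  check_finite_scalar(I_x_target, "I_x_target")
  if (I_x_target <= 0) abort("`I_x_target` must be > 0.")
  I0 <- sum(f_prime^2 / d)
  a <- sum(f_prime * u / d)^2
  b <- sum(u^2 / d)
  dd <- I0 - I_x_target
  denom <- a - dd * b
  if (abs(denom) < .Machine$double.eps * max(a, abs(dd) * b, 1)) {
    abort("No admissible epsilon_u solves the information-matching equation.")
  }
  eps_u <- dd / denom
  # PSD feasibility: for eps_u < 0 need 1 + eps_u * b > 0.
  if (1 + eps_u * b <= 0) {
    abort("No admissible solution: the matching epsilon_u violates positive semi-definiteness.")
  }
  eps_u
}

#' Differential (information-limiting) correlations
#'
#' The rank-one covariance \eqn{\Sigma_\xi = f' f'^\top / I_x} that
#' concentrates all noise along the signal direction. It carries exactly
#' `I_x_target` of information (on its support) and is the unique covariance
#' structure that is maximally robust to downstream noise regardless of the
#' downstream circuit.
#'
#' @inheritParams gamma_u_normalization
#' @return Rank-one PSD covariance matrix.
#' @export
differential_covariance <- function(f_prime, I_x_target) {
  check_finite_vector(f_prime, "f_prime")
  check_finite_scalar(I_x_target, "I_x_target")
  if (I_x_target <= 0) abort("`I_x_target` must be > 0.")
  if (all(f_prime == 0)) abort("`f_prime` must be non-zero.")
  tcrossprod(f_prime) / I_x_target
}

#' The family of maximally robust covariance structures
#'
#' For a linear channel with effective downstream covariance
#' \eqn{\Sigma_y}, every first-layer covariance of the form
#' \deqn{\Sigma_\xi = \frac{\alpha I_\eta}{I_x} \Sigma_y +
#'       \frac{1 - \alpha}{I_x} f' f'^\top,
#'       \qquad I_\eta = f'^\top \Sigma_y^{-1} f',}
#' carries input information \eqn{I_x} and attains the maximum possible
#' output information \eqn{I_x / (1 + I_x/I_\eta)} (see [optimal_output()]).
#' `alpha = 0` gives differential correlations; `alpha = 1` gives the
#' "matched" covariance proportional to \eqn{\Sigma_y}.
#'
#' @param alpha Interpolation parameter; must leave the result PSD
#'   (all of `[0, 1]` is admissible; values outside may not be).
#' @param f_prime Signal direction.
#' @param Sigma_y Effective downstream covariance, symmetric positive definite.
#' @param I_x_target Input information carried by the member, `> 0`.
#' @return An object of class `optimal_family_member`: a list with elements
#'   `Sigma`, `alpha`, `I_x`, `I_eta`.
#' @examples
#' fp <- c(1, 2)
#' fam <- optimal_family(0.5, fp, diag(2), I_x_target = 1)
#' tidy(fam)
#' @export
optimal_family <- function(alpha, f_prime, Sigma_y, I_x_target) {
  check_finite_scalar(alpha, "alpha")
  check_finite_vector(f_prime, "f_prime")
  check_finite_scalar(I_x_target, "I_x_target")
  if (I_x_target <= 0) abort("`I_x_target` must be > 0.")
  if (all(f_prime == 0)) abort("`f_prime` must be non-zero.")
  Sigma_y <- symmetrize(Sigma_y)
  assert_psd(Sigma_y, what = "`Sigma_y`")
  I_eta <- drop(crossprod(f_prime, chol_solve(Sigma_y, f_prime)))
  S <- (alpha * I_eta / I_x_target) * Sigma_y +
    ((1 - alpha) / I_x_target) * tcrossprod(f_prime)
  S <- symmetrize(S)
  er <- eig_range(S)
  if (er[1] < -.psd_tol * max(abs(er))) {
    bound <- admissible_alpha_endpoint(alpha, f_prime, Sigma_y, I_x_target)
    abort(sprintf(
      "alpha = %.6g leaves the covariance indefinite; admissible interval endpoint near %.6g.",
      alpha, bound
    ))
  }
  structure(
    list(Sigma = S, alpha = alpha, I_x = I_x_target, I_eta = I_eta),
    class = "optimal_family_member"
  )
}

# Bisect between a known-admissible alpha (0 or 1, whichever is closer to the
# requested value) and the requested alpha for the PSD boundary.
admissible_alpha_endpoint <- function(alpha, f_prime, Sigma_y, I_x) {
  I_eta <- drop(crossprod(f_prime, chol_solve(Sigma_y, f_prime)))
  member_min_eig <- function(a) {
    S <- (a * I_eta / I_x) * Sigma_y + ((1 - a) / I_x) * tcrossprod(f_prime)
    er <- eig_range(S)
    er[1] + .psd_tol * max(abs(er))
  }
  lo <- if (alpha < 0) 0 else 1
  hi <- alpha
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (member_min_eig(mid) >= 0) lo <- mid else hi <- mid
  }
  lo
}

#' @export
print.optimal_family_member <- function(x, ...) {
  cat(sprintf(
    "<optimal_family_member> alpha = %.4g, n = %d, I_x = %.6g, I_eta = %.6g\n",
    x$alpha, nrow(x$Sigma), x$I_x, x$I_eta
  ))
  invisible(x)
}

#' @rdname optimal_family
#' @param x An `optimal_family_member`.
#' @param ... Unused.
#' @export
tidy.optimal_family_member <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    I_x = x$I_x,
    I_eta = x$I_eta,
    I_y_bound = optimal_output(x$I_x, x$I_eta)
  )
}

#' @rdname optimal_family
#' @export
glance.optimal_family_member <- function(x, ...) {
  er <- eig_range(x$Sigma)
  tibble::tibble(
    n = nrow(x$Sigma),
    alpha = x$alpha,
    min_eigenvalue = er[1],
    max_eigenvalue = er[2],
    I_y_bound = optimal_output(x$I_x, x$I_eta)
  )
}

#' Average pairwise correlation over a stimulus grid
#'
#' Mean, over all ordered neuron pairs \eqn{i \ne j} and all supplied
#' covariance matrices (one per grid stimulus), of
#' \eqn{\Sigma_{ij}/\sqrt{\Sigma_{ii}\Sigma_{jj}}}.
#'
#' @param Sigmas A covariance matrix or a list of them.
#' @return Scalar mean pairwise correlation.
#' @export
average_correlation <- function(Sigmas) {
  if (is.matrix(Sigmas)) Sigmas <- list(Sigmas)
  vals <- purrr::map_dbl(Sigmas, function(S) {
    d <- diag(S)
    if (any(d <= 0)) abort("Covariance has a non-positive variance entry.")
    R <- S / sqrt(tcrossprod(d))
    n <- nrow(S)
    (sum(R) - n) / (n * (n - 1))
  })
  mean(vals)
}

# Fast closed form of average_correlation for Sigma = diag(d) + eps * u u',
# used inside the rejection-sampling loop: corr_ij = eps*a_i*a_j with
# a_i = u_i / sqrt(d_i + eps*u_i^2).
avg_corr_rank1 <- function(d_values, epsilon, u) {
  a <- u / sqrt(d_values + epsilon * u^2)
  n <- length(a)
  epsilon * (sum(a)^2 - sum(a^2)) / (n * (n - 1))
}

#' Average Fano factor over neurons and a stimulus grid
#'
#' Mean over neurons and grid stimuli of \eqn{\Sigma_{ii}(s)/f_i(s)}: 1 for
#' the Poisson-like diagonal base, slightly above 1 for the redundant
#' rank-one-perturbed populations.
#'
#' @param Sigmas A covariance matrix or list of matrices (one per stimulus).
#' @param f_list A mean-rate vector or list of them, matching `Sigmas`.
#' @return Scalar mean Fano factor.
#' @export
average_fano <- function(Sigmas, f_list) {
  if (is.matrix(Sigmas)) Sigmas <- list(Sigmas)
  if (is.numeric(f_list)) f_list <- list(f_list)
  if (length(Sigmas) != length(f_list)) {
    abort("`Sigmas` and `f_list` must have the same length.")
  }
  vals <- purrr::map2(Sigmas, f_list, function(S, f) {
    if (any(f <= 0)) abort("Mean responses must be > 0.")
    diag(S) / f
  })
  mean(unlist(vals))
}
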