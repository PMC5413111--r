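#' Linear Fisher information
#'
#' The precision (inverse mean-squared error) of the locally optimal linear
#' stimulus estimator, \eqn{I = f'^\top \Sigma^{-1} f'}, for mean-derivative
#' vector `f_prime` and noise covariance `Sigma`. Units: radian^-2 when the
#' stimulus is an angle.
#'
#' The solve uses a symmetric Cholesky factorization. If `Sigma` is singular
#' or numerically near-singular (relative condition number above 1e12), the
#' computation falls back to the Moore–Penrose pseudo-inverse restricted to
#' the support, with a warning; if `f_prime` has a component outside the
#' support of a singular `Sigma`, the information would be infinite and an
#' error is raised.
#'
#' @param f_prime Signal direction \eqn{f'(s)}.
#' @param Sigma Symmetric PSD covariance matrix.
#' @return Non-negative scalar information.
#' @examples
#' linear_fisher(c(3, 4), 25 * diag(2)) # (9 + 16) / 25 = 1
#' @export
linear_fisher <- function(f_prime, Sigma) {
  check_finite_vector(f_prime, "f_prime")
  Sigma <- symmetrize(Sigma)
  assert_psd(Sigma, what = "`Sigma`")
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- e$values
  lmax <- max(lam)
  support <- lam > lmax / .cond_threshold
  if (all(support)) {
    return(drop(crossprod(f_prime, chol_solve(Sigma, f_prime))))
  }
  # Support-restricted pseudo-inverse path.
  coef <- drop(crossprod(e$vectors, f_prime))
  out_of_support <- sqrt(sum(coef[!support]^2))
  if (out_of_support > 1e-8 * max(sqrt(sum(f_prime^2)), .Machine$double.eps)) {
    abort(paste(
      "`f_prime` lies outside the support of a singular `Sigma`;",
      "the linear Fisher information is unbounded."
    ))
  }
  warn("`Sigma` is (near-)singular; using the support-restricted pseudo-inverse.")
  sum(coef[support]^2 / lam[support])
}

#' Information in the output layer of a noisy channel
#'
#' Linear Fisher information carried by the second layer,
#' \deqn{I_y = f'^\top\left[\Sigma_\xi +
#'   (W_{\rm eff}^\top \Sigma_{{\rm eff},\eta}^{-1} W_{\rm eff})^{-1}
#'   \right]^{-1} f',}
#' valid when \eqn{W_{\rm eff}^\top \Sigma_{{\rm eff},\eta}^{-1} W_{\rm eff}}
#' is invertible (typically the case when the second layer has at least as
#' many cells as the first). [output_information_direct()] evaluates the
#' algebraically equivalent form in output space and works for any layer
#' sizes.
#'
#' @param f_prime Signal direction in the input layer.
#' @param Sigma_xi First-layer noise covariance.
#' @param W_eff Effective feedforward weights (n_out x n_in); see
#'   [effective_weights()].
#' @param Sigma_eff_eta Effective output-noise covariance (n_out x n_out).
#' @return Scalar output information (radian^-2).
#' @examples
#' fp <- c(1, 2)
#' output_information(fp, diag(c(1, 2)), diag(2), 0.5 * diag(2))
#' @export
output_information <- function(f_prime, Sigma_xi, W_eff, Sigma_eff_eta) {
  check_finite_vector(f_prime, "f_prime")
  Sigma_xi <- symmetrize(Sigma_xi)
  inner <- crossprod(W_eff, solve(symmetrize(Sigma_eff_eta), W_eff))
  inner <- symmetrize(inner)
  ei <- eig_range(inner)
  if (ei[1] <= ei[2] / .cond_threshold) {
    abort(paste(
      "W_eff' Sigma_eff_eta^-1 W_eff is not invertible;",
      "use output_information_direct() instead."
    ))
  }
  Sigma_y <- chol_solve(inner, diag(nrow(inner)))
  drop(crossprod(f_prime, chol_solve(Sigma_xi + Sigma_y, f_prime)))
}

#' @rdname output_information
#'
#' @details `output_information_direct()` computes
#' \eqn{(W_{\rm eff} f')^\top [W_{\rm eff}\Sigma_\xi W_{\rm eff}^\top +
#' \Sigma_{{\rm eff},\eta}]^{-1} (W_{\rm eff} f')}, the information in the
#' output responses themselves; the two forms agree by the Woodbury identity
#' whenever both are defined.
#' @export
output_information_direct <- function(f_prime, Sigma_xi, W_eff, Sigma_eff_eta) {
  check_finite_vector(f_prime, "f_prime")
  signal <- drop(W_eff %*% f_prime)
  total <- symmetrize(W_eff %*% symmetrize(Sigma_xi) %*% t(W_eff) + symmetrize(Sigma_eff_eta))
  er <- eig_range(total)
  if (er[1] <= er[2] / .cond_threshold) {
    abort("Total output covariance is singular; information is not defined.")
  }
  drop(crossprod(signal, chol_solve(total, signal)))
}

#' Trial-shuffled information
#'
#' Information the population would carry with the same tuning curves and
#' single-neuron variances but no inter-neuronal correlations: all
#' off-diagonal entries of `Sigma` are zeroed before applying
#' [linear_fisher()]. Shuffled > correlated diagnoses a redundant code;
#' shuffled < correlated a synergistic one.
#'
#' @inheritParams linear_fisher
#' @return Scalar information.
#' @export
shuffled_information <- function(f_prime, Sigma) {
  d <- diag(symmetrize(Sigma))
  if (any(d <= 0)) abort("`Sigma` must have strictly positive variances.")
  sum(f_prime^2 / d)
}

#' Maximum output information attainable at fixed input information
#'
#' \deqn{I_y^{\max} = \frac{I_x}{1 + I_x / I_\eta},}
#' where \eqn{I_\eta} is the information the output layer would carry if the
#' input layer were noiseless. Every member of [optimal_family()] attains this
#' bound; it never exceeds `min(I_x, I_eta)`.
#'
#' @param I_x Input information, `>= 0`.
#' @param I_eta Downstream-noise information, `> 0` (may be `Inf` for a
#'   noiseless channel, in which case the bound is `I_x`).
#' @return Scalar bound.
#' @examples
#' optimal_output(10, 10) # 5
#' @export
optimal_output <- function(I_x, I_eta) {
  if (!is.numeric(I_x) || any(I_x < 0)) abort("`I_x` must be >= 0.")
  if (!is.numeric(I_eta) || any(I_eta <= 0)) abort("`I_eta` must be > 0.")
  I_x / (1 + I_x / I_eta)
}

#' Information from an eigen-decomposition of the noise covariance
#'
#' The spectral form
#' \deqn{I = |f'|^2 \sum_k \frac{\cos^2\theta_k}{\sigma_k^2},}
#' where \eqn{\theta_k} is the angle between \eqn{f'} and the k-th
#' eigenvector and \eqn{\sigma_k^2} the k-th eigenvalue. Equals
#' [linear_fisher()] on the reassembled covariance.
#'
#' @param f_prime Signal direction.
#' @param eigenvalues Positive eigenvalues.
#' @param eigenvectors Matrix whose columns form the corresponding orthonormal
#'   basis.
#' @return Scalar information.
#' @export
eigen_information <- function(f_prime, eigenvalues, eigenvectors) {
  check_finite_vector(f_prime, "f_prime")
  check_finite_vector(eigenvalues, "eigenvalues")
  if (any(eigenvalues <= 0)) abort("All eigenvalues must be > 0.")
  V <- eigenvectors
  gram <- crossprod(V)
  if (max(abs(gram - diag(nrow(gram)))) > 1e-8) {
    abort("`eigenvectors` must form a complete orthonormal basis.")
  }
  coef <- drop(crossprod(V, f_prime))
  sum(coef^2 / eigenvalues)
}

#' Two-dimensional information-transmission ratio
#'
#' For a 2-D covariance ellipse with principal standard deviations
#' `sigma1 >= sigma2`, signal direction at angle `theta` to the long axis, and
#' iid noise of variance `sigma2_added` added downstream, the fraction of
#' input information that survives is
#' \deqn{\frac{I_y}{I_x} = \frac{\cos^2\theta/(\sigma_1^2 + \sigma^2) +
#'   \sin^2\theta/(\sigma_2^2 + \sigma^2)}
#'   {\cos^2\theta/\sigma_1^2 + \sin^2\theta/\sigma_2^2}.}
#' At `theta = 0` this is \eqn{\sigma_1^2/(\sigma_1^2 + \sigma^2)} (robust:
#' noise aligned with the long axis barely lengthens it); at
#' `theta = pi/2` it is \eqn{\sigma_2^2/(\sigma_2^2 + \sigma^2)} (fragile).
#'
#' @param sigma1,sigma2 Principal axis standard deviations, `sigma1 >= sigma2 > 0`.
#' @param theta Angle between the signal direction and the long axis (radians).
#' @param sigma2_added Added iid noise variance, `>= 0`.
#' @return Ratio in `[0, 1]`.
#' @export
information_ratio_2d <- function(sigma1, sigma2, theta, sigma2_added) {
  check_finite_scalar(sigma1, "sigma1")
  check_finite_scalar(sigma2, "sigma2")
  check_finite_scalar(theta, "theta")
  check_finite_scalar(sigma2_added, "sigma2_added")
  if (sigma2 <= 0) abort("`sigma2` must be > 0.")
  if (sigma2 > sigma1) abort("Ordering convention requires sigma1 >= sigma2.")
  if (sigma2_added < 0) abort("`sigma2_added` must be >= 0.")
  num <- cos(theta)^2 / (sigma1^2 + sigma2_added) + sin(theta)^2 / (sigma2^2 + sigma2_added)
  den <- cos(theta)^2 / sigma1^2 + sin(theta)^2 / sigma2^2
  num / den
}

#' Covariance minimizing information under a trace budget
#'
#' Among all PSD covariance matrices with trace at most `trace_budget`, the
#' information \eqn{|f'|^2 \sum_k \cos^2\theta_k / \sigma_k^2} (restricted to
#' the support) is minimized by concentrating the entire budget along the
#' signal direction — i.e. by differential correlations:
#' \deqn{\Sigma_{\min} = C_0 \frac{f' f'^\top}{|f'|^2}, \qquad
#'       I_{\min} = \frac{|f'|^2}{C_0}.}
#'
#' @param f_prime Signal direction, non-zero.
#' @param trace_budget Total variance budget \eqn{C_0 > 0}.
#' @return List with `Sigma` (the minimizing covariance) and `info`
#'   (the minimal support-restricted information).
#' @export
minimum_information_covariance <- function(f_prime, trace_budget) {
  check_finite_vector(f_prime, "f_prime")
  check_finite_scalar(trace_budget, "trace_budget")
  if (trace_budget <= 0) abort("`trace_budget` must be > 0.")
  nf2 <- sum(f_prime^2)
  if (nf2 == 0) abort("`f_prime` must be non-zero.")
  list(
    Sigma = trace_budget * tcrossprod(f_prime) / nf2,
    info = nf2 / trace_budget
  )
}

#' Total information about the true stimulus under stimulus jitter
#'
#' When the encoded stimulus s deviates from the presented stimulus s0 by
#' zero-mean jitter of variance `var_ds` (the latent-noise reading of
#' differential correlations), the total Fisher information about s0 is
#' \deqn{I^{\rm tot}(s_0) = \left[{\rm Var}[\delta s] +
#'   \int ds\, P(s|s_0) / I(s)\right]^{-1},}
#' evaluated here by quadrature over a stimulus grid.
#'
#' @param var_ds Jitter variance (radian^2), `>= 0`.
#' @param info Per-stimulus information values `I(s)` on the grid; must be
#'   `> 0` wherever the weight is positive.
#' @param weights Grid weights `P(s|s0)`, non-negative, summing to 1.
#' @return Scalar total information about s0.
#' @export
total_information <- function(var_ds, info, weights) {
  check_finite_scalar(var_ds, "var_ds")
  check_finite_vector(info, "info")
  check_finite_vector(weights, "weights")
  if (var_ds < 0) abort("`var_ds` must be >= 0.")
  if (length(info) != length(weights)) abort("`info` and `weights` must have the same length.")
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  if (abs(sum(weights) - 1) > 1e-8) abort("`weights` must sum to 1 on the grid.")
  active <- weights > 0
  if (any(info[active] <= 0)) {
    abort("Zero information at a weighted stimulus: the variance term is infinite.")
  }
  1 / (var_ds + sum(weights[active] / info[active]))
}
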