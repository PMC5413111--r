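#' Gain nonlinearities for the feedforward channel
#'
#' A gain object bundles the pointwise nonlinearity `g` applied to the summed
#' drive, its derivative when it exists, and — when available in closed form —
#' the Gaussian-smoothed average slope \eqn{\bar g'(h) = \partial_h
#' E[g(h + \chi)]} for \eqn{\chi \sim N(0, sd^2)}, which defines the
#' effective weights of the linearized channel.
#'
#' * `gain_linear(slope)`: \eqn{g(x) = cx}; the smoothed slope is `slope`.
#' * `gain_step(threshold)`: Heaviside spike generation, \eqn{g(x) =
#'   1\{x \ge \theta\}}; the smoothed mean is \eqn{\Phi((h-\theta)/sd)} and
#'   the smoothed slope the Gaussian density at \eqn{h - \theta}.
#' * `gain_tanh()`: saturating nonlinearity (no closed-form smoothed slope;
#'   computed by quadrature).
#' * `gain_quadratic(a)`: \eqn{g(x) = a x^2}, handy because its excess output
#'   covariance under Gaussian input noise is known exactly.
#'
#' @param slope,threshold,a Gain parameters.
#' @return An object of class `popinfo_gain`.
#' @seealso [effective_weights()], [delta_sigma_g()]
#' @export
gain_linear <- function(slope = 1) {
  check_finite_scalar(slope, "slope")
  new_gain(
    fn = function(x) slope * x,
    deriv = function(x) rep(slope, length(x)),
    smoothed_slope = function(h, sd) rep(slope, length(h)),
    label = sprintf("linear(slope = %g)", slope)
  )
}

#' @rdname gain_linear
#' @export
gain_step <- function(threshold = 0) {
  check_finite_scalar(threshold, "threshold")
  new_gain(
    fn = function(x) as.numeric(x >= threshold),
    deriv = NULL,
    smoothed_slope = function(h, sd) dnorm(h - threshold, sd = sd),
    label = sprintf("step(threshold = %g)", threshold)
  )
}

#' @rdname gain_linear
#' @export
gain_tanh <- function() {
  new_gain(
    fn = tanh,
    deriv = function(x) 1 - tanh(x)^2,
    smoothed_slope = NULL,
    label = "tanh"
  )
}

#' @rdname gain_linear
#' @export
gain_quadratic <- function(a = 1) {
  check_finite_scalar(a, "a")
  new_gain(
    fn = function(x) a * x^2,
    deriv = function(x) 2 * a * x,
    smoothed_slope = function(h, sd) 2 * a * h,
    label = sprintf("quadratic(a = %g)", a)
  )
}

new_gain <- function(fn, deriv, smoothed_slope, label) {
  structure(
    list(fn = fn, deriv = deriv, smoothed_slope = smoothed_slope, label = label),
    class = "popinfo_gain"
  )
}

#' @export
print.popinfo_gain <- function(x, ...) {
  cat("<popinfo_gain>", x$label, "\n")
  invisible(x)
}

#' Mean drive to the second layer
#'
#' \eqn{h(s) = W f(s)}: the average summed input each output neuron receives.
#'
#' @param W Weight matrix (n_out x n_in).
#' @param f_values Mean first-layer rates \eqn{f(s)}.
#' @return Numeric vector of length n_out.
#' @export
mean_drive <- function(W, f_values) {
  check_finite_vector(f_values, "f_values")
  W <- as.matrix(W)
  if (!all(is.finite(W))) abort("`W` must be finite.")
  if (ncol(W) != length(f_values)) {
    abort(sprintf("Shape mismatch: W is %dx%d but f has length %d.",
                  nrow(W), ncol(W), length(f_values)))
  }
  drop(W %*% f_values)
}

# Average slope of the gain seen through Gaussian input noise of the given
# per-unit standard deviations. Closed form when the gain provides one;
# otherwise Gauss-Hermite quadrature of E[g'(h + sd * z)]; Monte Carlo via the
# Stein identity E[z g(h + sd z)] / sd as a last resort.
average_slope <- function(gain, h, sd_vec, mc_samples = 1e4, seed = NULL) {
  stopifnot(inherits(gain, "popinfo_gain"))
  n <- length(h)
  sd_vec <- rep_len(sd_vec, n)
  slope <- numeric(n)
  zero_sd <- sd_vec == 0
  if (any(zero_sd)) {
    if (is.null(gain$deriv)) {
      abort("Average slope undefined: zero input noise with a non-differentiable gain.")
    }
    slope[zero_sd] <- gain$deriv(h[zero_sd])
  }
  idx <- which(!zero_sd)
  if (length(idx) > 0) {
    if (!is.null(gain$smoothed_slope)) {
      slope[idx] <- gain$smoothed_slope(h[idx], sd_vec[idx])
    } else if (!is.null(gain$deriv)) {
      gh <- pracma::gaussHermite(64)
      z <- sqrt(2) * gh$x
      w <- gh$w / sqrt(pi)
      for (i in idx) {
        slope[i] <- sum(w * gain$deriv(h[i] + sd_vec[i] * z))
      }
    } else {
      if (is.null(seed)) abort("A `seed` is required for the Monte Carlo slope estimate.")
      z <- withr::with_seed(as.integer(seed), rnorm(mc_samples))
      for (i in idx) {
        slope[i] <- mean(z * gain$fn(h[i] + sd_vec[i] * z)) / sd_vec[i]
      }
    }
  }
  if (!all(is.finite(slope))) abort("Non-finite average-slope estimate.")
  slope
}

#' Effective weights of the linearized channel
#'
#' The channel \eqn{y = g(Wx + \zeta) + \eta} behaves, to first order in the
#' signal, like a linear channel with weights
#' \eqn{W_{{\rm eff},ij} = \bar g'(h_i) W_{ij}}, where \eqn{\bar g'(h_i)} is
#' the derivative of \eqn{E[g(h_i + \chi_i)]} with respect to the mean drive
#' and \eqn{\chi = W\xi + \zeta} collects all noise entering the nonlinearity.
#' Only the marginal standard deviations \eqn{\sqrt{(\Sigma_\chi)_{ii}}}
#' enter the average slope.
#'
#' @param W Weight matrix (n_out x n_in).
#' @param gain A [gain_linear()]-style gain object.
#' @param h Mean drive vector from [mean_drive()].
#' @param Sigma_chi Covariance of the noise inside the nonlinearity
#'   (\eqn{W \Sigma_\xi W^\top + \Sigma_\zeta}); a matrix, or a vector of
#'   marginal variances.
#' @param mc_samples Monte Carlo draws for gains without derivative or closed
#'   form.
#' @param seed Seed for the Monte Carlo fallback.
#' @return List with `W_eff` (scaled weights) and `G_prime` (diagonal matrix
#'   of average slopes).
#' @export
effective_weights <- function(W, gain, h, Sigma_chi, mc_samples = 1e4, seed = NULL) {
  W <- as.matrix(W)
  check_finite_vector(h, "h")
  if (nrow(W) != length(h)) abort("`h` must have one entry per output unit (row of W).")
  var_chi <- if (is.matrix(Sigma_chi)) diag(Sigma_chi) else rep_len(Sigma_chi, length(h))
  if (any(var_chi < 0)) abort("`Sigma_chi` must have non-negative variances.")
  slope <- average_slope(gain, h, sqrt(var_chi), mc_samples = mc_samples, seed = seed)
  list(
    W_eff = slope * W,
    G_prime = diag(slope, nrow = length(slope))
  )
}

#' Excess output covariance introduced by a nonlinear gain
#'
#' The covariance of \eqn{g(h + \chi)} exceeds the linearized propagation
#' \eqn{\bar G' \Sigma_\chi \bar G'} by
#' \deqn{\delta\Sigma_g = {\rm Cov}[g(h + \chi)] - \bar G' \Sigma_\chi \bar G',}
#' estimated here by Monte Carlo over Gaussian \eqn{\chi}. For a linear gain
#' it vanishes identically; for Gaussian input noise it is positive
#' semi-definite, so it acts as an additional effective noise source in
#' \eqn{\Sigma_{{\rm eff},\eta} = \bar G' \Sigma_\zeta \bar G' +
#' \delta\Sigma_g + \Sigma_\eta}.
#'
#' @param gain A gain object.
#' @param h Mean drive vector.
#' @param Sigma_chi Covariance of the Gaussian noise inside the nonlinearity
#'   (matrix, or scalar/vector of variances for independent noise).
#' @param mc_samples Number of Monte Carlo draws (at least 1000; estimates
#'   from fewer draws are too noisy to be meaningful).
#' @param seed Integer seed.
#' @param n_batches Batches used for the Monte Carlo standard error of the
#'   minimum eigenvalue.
#' @return Symmetric matrix with attributes `min_eigenvalue` and
#'   `min_eigenvalue_se`.
#' @export
delta_sigma_g <- function(gain, h, Sigma_chi, mc_samples = 1e5, seed = 1,
                          n_batches = 10) {
  stopifnot(inherits(gain, "popinfo_gain"))
  check_finite_vector(h, "h")
  if (mc_samples < 1e3) {
    abort("`mc_samples` must be at least 1000 for a meaningful estimate.")
  }
  n <- length(h)
  if (!is.matrix(Sigma_chi)) {
    Sigma_chi <- diag(rep_len(Sigma_chi, n), nrow = n)
  }
  assert_psd(Sigma_chi, what = "`Sigma_chi`")
  L <- psd_factor(Sigma_chi)
  slope <- average_slope(gain, h, sqrt(diag(Sigma_chi)), seed = seed)
  lin <- (slope %o% slope) * Sigma_chi

  m <- as.integer(mc_samples)
  G <- withr::with_seed(as.integer(seed), {
    chi <- matrix(rnorm(m * n), m, n) %*% t(L)
    gain$fn(sweep(chi, 2, h, "+"))
  })
  dim(G) <- c(m, n)
  delta <- symmetrize(cov(G) - lin)

  e <- eigen(delta, symmetric = TRUE)
  v <- e$vectors[, n]
  batch <- rep(seq_len(n_batches), length.out = m)
  per_batch <- vapply(seq_len(n_batches), function(b) {
    Gb <- G[batch == b, , drop = FALSE]
    db <- symmetrize(cov(Gb) - lin)
    drop(crossprod(v, db %*% v))
  }, numeric(1))
  attr(delta, "min_eigenvalue") <- e$values[n]
  attr(delta, "min_eigenvalue_se") <- sd(per_batch) / sqrt(n_batches)
  delta
}

#' Mean response of a dichotomized-Gaussian neuron
#'
#' A binary neuron spikes when its Gaussian input crosses threshold, so its
#' firing probability is \eqn{\mu_i = \Phi((f_i(s) - \theta_i)/\sigma_i)},
#' with \eqn{\sigma_i} the standard deviation of the total input noise.
#'
#' @param f_value Mean input(s) \eqn{f_i(s)}.
#' @param threshold Spike threshold(s) \eqn{\theta_i}.
#' @param input_sd Input noise standard deviation(s), `> 0`.
#' @return Firing probabilities in `[0, 1]`.
#' @examples
#' dg_mean(1, 1, 0.5) # at threshold: 0.5
#' @export
dg_mean <- function(f_value, threshold, input_sd) {
  if (any(input_sd <= 0)) abort("`input_sd` must be > 0.")
  pnorm((f_value - threshold) / input_sd)
}

#' Default spike thresholds for a dichotomized-Gaussian population
#'
#' Thresholds set to 3/4 of each cell's peak tuning height,
#' \eqn{\theta_i = 0.75 (\rho_i + \upsilon_i)}, so the population always
#' contains both active and silent cells.
#'
#' @param pop A `tuning_population`.
#' @return Numeric threshold vector.
#' @export
dg_thresholds <- function(pop) {
  stopifnot(inherits(pop, "tuning_population"))
  0.75 * (pop$rho + pop$upsilon)
}

#' Sample binary responses from the dichotomized-Gaussian spiking layer
#'
#' Draws latent inputs \eqn{x = f + \xi} (optionally plus iid pre-threshold
#' noise \eqn{\zeta}) and thresholds them: \eqn{y_i = 1\{x_i + \zeta_i \ge
#' \theta_i\}}. When the covariance has the structured form \eqn{\gamma
#' \Sigma_0 + \epsilon u u^\top} with \eqn{\epsilon \ge 0}, sampling uses the
#' exact decomposition \eqn{x = f + \sqrt{\gamma}\,\Sigma_0^{1/2} z +
#' \sqrt{\epsilon}\, u\, w} (z iid standard normal, w scalar standard normal)
#' instead of a dense factorization; a negative \eqn{\epsilon} falls back to
#' the dense PSD square root.
#'
#' @param f_values Mean inputs \eqn{f(s)}.
#' @param thresholds Spike thresholds (recycled; `-Inf` makes a cell always
#'   fire).
#' @param n_draws Number of trials to simulate.
#' @param seed Integer seed.
#' @param Sigma_xi Dense first-layer covariance (ignored when `structure` is
#'   supplied).
#' @param structure Optional list `list(gamma, d0, epsilon, u)` describing
#'   \eqn{\gamma\,{\rm diag}(d_0) + \epsilon u u^\top}.
#' @param sigma_zeta2 Variance of iid Gaussian pre-threshold noise (0 for
#'   none).
#' @return Binary matrix of dimension `n_draws x n`.
#' @export
dg_sample <- function(f_values, thresholds, n_draws, seed, Sigma_xi = NULL,
                      structure = NULL, sigma_zeta2 = 0) {
  check_finite_vector(f_values, "f_values")
  check_finite_scalar(sigma_zeta2, "sigma_zeta2")
  if (sigma_zeta2 < 0) abort("`sigma_zeta2` must be >= 0.")
  n <- length(f_values)
  thresholds <- rep_len(thresholds, n)
  m <- as.integer(n_draws)
  withr::with_seed(as.integer(seed), {
    if (!is.null(structure)) {
      gamma <- structure$gamma
      d0 <- structure$d0
      epsilon <- structure$epsilon
      u <- structure$u
      if (gamma <= 0 || any(d0 <= 0)) abort("Structured sampler needs gamma > 0 and d0 > 0.")
      if (epsilon >= 0) {
        x <- matrix(rnorm(m * n), m, n) *
          matrix(sqrt(gamma * d0), m, n, byrow = TRUE)
        if (epsilon > 0) x <- x + rnorm(m) %o% (sqrt(epsilon) * u)
      } else {
        S <- rank1_covariance(diag(d0, nrow = n), gamma, epsilon, u)
        x <- matrix(rnorm(m * n), m, n) %*% t(psd_factor(S))
      }
    } else {
      if (is.null(Sigma_xi)) abort("Supply either `Sigma_xi` or `structure`.")
      assert_psd(Sigma_xi, what = "`Sigma_xi`")
      x <- matrix(rnorm(m * n), m, n) %*% t(psd_factor(Sigma_xi))
    }
    x <- sweep(x, 2, f_values, "+")
    if (sigma_zeta2 > 0) {
      x <- x + matrix(rnorm(m * n, sd = sqrt(sigma_zeta2)), m, n)
    }
    (x >= matrix(thresholds, m, n, byrow = TRUE)) * 1
  })
}

#' Monte Carlo estimate of output-layer linear Fisher information
#'
#' Estimates \eqn{I_y(s) = \mu'(s)^\top {\rm Cov}(y|s)^{-1} \mu'(s)} for a
#' spiking (or otherwise analytically intractable) output layer: the mean
#' derivative comes from central finite differences of the analytic mean
#' `mu_fn`, and the covariance from `n_draws` simulated responses. The
#' covariance solve adds a ridge of `1e-9` times the mean diagonal when the
#' raw estimate is numerically singular (logged via a message). The Monte
#' Carlo standard error is estimated by batching the draws.
#'
#' @param mu_fn Function of `s` returning the analytic mean response vector
#'   (e.g. [dg_mean()] applied along the population).
#' @param sampler Function `(s, n_draws, seed)` returning an `n_draws x n`
#'   response matrix (e.g. a wrapper around [dg_sample()]).
#' @param s Stimulus at which to estimate.
#' @param ds Finite-difference step in radians.
#' @param n_draws Monte Carlo draws (at least 1e4).
#' @param seed Integer seed.
#' @param n_batches Batches for the standard-error estimate.
#' @param min_events For discrete (e.g. binary) responses: a neuron enters the
#'   covariance only if it deviates from its modal response on at least this
#'   many draws. Near-deterministic binary neurons have vanishing true
#'   information contribution but catastrophically mis-estimated variances, so
#'   they are excluded from the support rather than inverted. Columns with
#'   continuously distributed responses are never dropped by this rule.
#' @return List with `estimate`, `se`, `n_draws`, and `n_dropped` (neurons
#'   excluded from the support).
#' @export
mc_fisher <- function(mu_fn, sampler, s, ds = 1e-4, n_draws = 1e5, seed = 1,
                      n_batches = 5, min_events = 16) {
  check_finite_scalar(s, "s")
  check_finite_scalar(ds, "ds")
  if (ds <= 0) abort("`ds` must be > 0.")
  if (n_draws < 1e4) abort("`n_draws` must be at least 1e4.")
  mu_prime <- (mu_fn(s + ds) - mu_fn(s - ds)) / (2 * ds)
  Y <- sampler(s, n_draws, seed)
  batch <- rep(seq_len(n_batches), length.out = nrow(Y))

  # Support restriction: drop degenerate columns (zero variance, or two-valued
  # with too few minority events for a meaningful variance estimate). For the
  # batch-based standard error, a column must additionally be non-degenerate
  # within every batch, so no batch inverts a variance estimated from a
  # handful of events.
  minority_counts <- function(j, rows = NULL) {
    y <- if (is.null(rows)) Y[, j] else Y[rows, j]
    vals <- unique(y)
    if (length(vals) > 2L) return(Inf) # continuous-valued column: always kept
    if (length(vals) == 1L) return(0)
    min(tabulate(match(y, vals)))
  }
  keep <- vapply(seq_len(ncol(Y)), function(j) minority_counts(j) >= min_events,
                 logical(1))
  if (!any(keep)) {
    # every neuron is (near-)deterministic at this stimulus: the observable
    # responses carry no measurable information
    message("mc_fisher: all response columns are degenerate; returning 0.")
    return(list(estimate = 0, se = 0, n_draws = as.integer(n_draws),
                n_dropped = ncol(Y)))
  }
  keep_batch <- vapply(seq_len(ncol(Y)), function(j) {
    if (!keep[j]) return(FALSE)
    all(vapply(seq_len(n_batches),
               function(b) minority_counts(j, batch == b) >= 5, logical(1)))
  }, logical(1))

  info_of <- function(C, mp) {
    if (length(mp) == 0L) return(0)
    sol <- tryCatch(chol_solve(C, mp), error = function(e) NULL)
    if (is.null(sol)) {
      message("mc_fisher: regularizing a numerically singular Monte Carlo covariance.")
      ridge <- 1e-9 * mean(diag(C))
      C <- C + diag(ridge, nrow(C))
      sol <- tryCatch(chol_solve(C, mp), error = function(e) NULL)
      if (is.null(sol)) {
        # exactly collinear columns (possible for binary draws): restrict to
        # the numerically non-singular support
        e <- eigen(symmetrize(C), symmetric = TRUE)
        pos <- e$values > max(e$values) * 1e-12
        coef <- drop(crossprod(e$vectors[, pos, drop = FALSE], mp))
        return(sum(coef^2 / e$values[pos]))
      }
    }
    drop(crossprod(mp, sol))
  }
  estimate <- info_of(cov(Y[, keep, drop = FALSE]), mu_prime[keep])
  per_batch <- vapply(seq_len(n_batches), function(b) {
    info_of(cov(Y[batch == b, keep_batch, drop = FALSE]), mu_prime[keep_batch])
  }, numeric(1))
  list(
    estimate = estimate,
    se = sd(per_batch) / sqrt(n_batches),
    n_draws = as.integer(n_draws),
    n_dropped = sum(!keep)
  )
}
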