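#' Default output-noise variance grid for the linear-channel sweeps
#'
#' Twenty logarithmically spaced values from 1e-3 to 1e2.
#'
#' @return Numeric vector.
#' @export
default_sigma2_grid <- function() 10^seq(-3, 2, length.out = 20)

# Per-stimulus quantities shared by the linear-channel pipelines: tuning
# values, diagonal base, matched rank-one strengths and directions for the
# aligned ("reference") and tilted ("companion") populations.
stimulus_state <- function(pop, s, eps, theta_u, aux) {
  f <- tuning_mean(pop, s)
  fp <- tuning_deriv(pop, s)
  d <- f
  I0 <- sum(fp^2 / d)
  if (1 + eps * I0 <= 0) {
    abort(sprintf(
      "Aligned covariance is not PSD at stimulus %.4f: 1 + eps * I_0 = %.3g <= 0.",
      s, 1 + eps * I0
    ))
  }
  I_x <- I0 / (1 + eps * I0) # aligned population, u = f'
  u <- tilted_direction(fp, theta_u, aux)
  eps_u <- epsilon_match(fp, d, u, I_x)
  list(f = f, fp = fp, d = d, I0 = I0, I_x = I_x, u = u, eps_u = eps_u)
}

# All stimulus states for one population draw, or NULL when the construction
# is infeasible somewhere on the grid (indefinite aligned covariance, or no
# admissible matching eps_u). Infeasible draws are rejected and redrawn by
# the sampling loop: the paired-covariance construction is only defined on
# draws where both matrices are PSD at every grid stimulus.
draw_states <- function(pop, s_grid, eps, theta_u, aux) {
  tryCatch(
    purrr::map(s_grid, ~ stimulus_state(pop, .x, eps, theta_u, aux)),
    error = function(e) NULL
  )
}

#' Draw a tuning population whose two covariance models have matched average
#' correlations
#'
#' Repeatedly samples populations until the population-averaged pairwise
#' correlation of the aligned covariance (\eqn{\Sigma_0 + \epsilon f'f'^\top})
#' and of the tilted, information-matched covariance (\eqn{\Sigma_0 +
#' \epsilon_u u u^\top}) differ by less than `tol`, so that robustness
#' differences between the two codes cannot be attributed to different overall
#' correlation levels.
#'
#' @param n Population size.
#' @param eps Rank-one strength of the aligned population.
#' @param theta_u Tilt angle of the companion direction (radians).
#' @param n_stimuli Stimulus grid size used for the correlation averages.
#' @param tol Acceptance tolerance on the absolute correlation gap.
#' @param max_attempts Attempt budget before giving up.
#' @param seed Integer run seed.
#' @param ranges Tuning parameter ranges ([tuning_ranges()]).
#' @return List with the accepted `pop`, the fixed auxiliary tilt-plane vector
#'   `aux`, both average correlations, the per-stimulus `eps_u` values, and the
#'   number of `attempts` used.
#' @export
sample_matched_population <- function(n = 100, eps = 1e-3, theta_u = 1 / 8,
                                      n_stimuli = 100, tol = 1e-5,
                                      max_attempts = 1e4, seed = 1,
                                      ranges = tuning_ranges()) {
  streams <- rng_streams(seed, 2)
  aux <- withr::with_seed(streams[1], rnorm(n))
  pop_seeds <- withr::with_seed(streams[2],
                                sample.int(.Machine$integer.max - 1L, max_attempts))
  s_grid <- stimulus_grid(n_stimuli)
  best_gap <- Inf
  for (attempt in seq_len(max_attempts)) {
    pop <- sample_tuning_population(n, ranges = ranges, seed = pop_seeds[attempt])
    states <- draw_states(pop, s_grid, eps, theta_u, aux)
    if (is.null(states)) next # infeasible draw: construction undefined, redraw
    corr_aligned <- mean(purrr::map_dbl(states, ~ avg_corr_rank1(.x$d, eps, .x$fp)))
    corr_tilted <- mean(purrr::map_dbl(states, ~ avg_corr_rank1(.x$d, .x$eps_u, .x$u)))
    gap <- abs(corr_aligned - corr_tilted)
    best_gap <- min(best_gap, gap)
    if (gap < tol) {
      return(list(
        pop = pop, aux = aux,
        avg_corr_aligned = corr_aligned,
        avg_corr_tilted = corr_tilted,
        eps_u = purrr::map_dbl(states, "eps_u"),
        attempts = attempt
      ))
    }
  }
  abort(sprintf(
    "Correlation matching failed after %d attempts; best |gap| achieved was %.3g (tolerance %.3g).",
    max_attempts, best_gap, tol
  ))
}

#' Robustness of two equally informative codes to added output noise
#'
#' Builds one heterogeneous tuning population and two covariance models with
#' identical per-stimulus input information: an *aligned* population with
#' noise concentrated along the signal direction (\eqn{\Sigma_0 + \epsilon
#' f'f'^\top}) and a *tilted* companion whose rank-one noise direction makes
#' an angle `theta_u` with \eqn{f'} (\eqn{\Sigma_0 + \epsilon_u u u^\top},
#' with \eqn{\epsilon_u} solved per stimulus so the information matches).
#' Both codes are then corrupted by iid output noise of variance
#' \eqn{\sigma^2} through an identity-weight linear channel, and the
#' stimulus-averaged output information is recorded for every \eqn{\sigma^2}.
#'
#' A positive `eps` produces redundant codes (trial-shuffled information
#' exceeds the correlated information); a negative `eps` produces synergistic
#' ones — see [run_synergistic_sweep()].
#'
#' @inheritParams sample_matched_population
#' @param sigma2_grid Output noise variances to sweep (may include 0).
#' @param match_correlations If `TRUE`, use [sample_matched_population()]
#'   rejection sampling so both codes have the same average correlation.
#' @param tol,max_attempts Matching controls, passed through.
#' @return A tibble of class `popinfo_noise_sweep` with one row per
#'   (population, sigma2): columns `population` (`"aligned"`/`"tilted"`),
#'   `sigma2`, `I_y`, `I_x`, `I_shuffled`, `fano`, `avg_corr`, `eps_u_mean`.
#'   All information columns are stimulus averages. Attributes `eps_u`
#'   (per-stimulus values) and `config`.
#' @examples
#' \donttest{
#' res <- run_noise_sweep(n = 20, n_stimuli = 10, sigma2_grid = c(0, 1),
#'                        match_correlations = FALSE, seed = 1)
#' glance(res)
#' }
#' @export
run_noise_sweep <- function(n = 100, eps = 1e-3, theta_u = 1 / 8,
                            n_stimuli = 100,
                            sigma2_grid = default_sigma2_grid(),
                            seed = 1, match_correlations = TRUE,
                            tol = 1e-5, max_attempts = 1e4,
                            ranges = tuning_ranges()) {
  check_finite_vector(sigma2_grid, "sigma2_grid")
  if (any(sigma2_grid < 0)) abort("`sigma2_grid` must be non-negative.")
  # When correlation matching is off the rejection loop still runs with an
  # infinite tolerance: it accepts the first draw on which the paired
  # construction is feasible at every grid stimulus.
  drawn <- sample_matched_population(
    n = n, eps = eps, theta_u = theta_u, n_stimuli = n_stimuli,
    tol = if (match_correlations) tol else Inf,
    max_attempts = max_attempts, seed = seed, ranges = ranges
  )
  pop <- drawn$pop
  aux <- drawn$aux
  s_grid <- stimulus_grid(n_stimuli)
  states <- purrr::map(s_grid, ~ stimulus_state(pop, .x, eps, theta_u, aux))

  per_pop <- function(label) {
    Sig <- purrr::map(states, function(st) {
      if (label == "aligned") {
        rank1_covariance(diag(st$d, nrow = n), 1, eps, st$fp)
      } else {
        rank1_covariance(diag(st$d, nrow = n), 1, st$eps_u, st$u)
      }
    })
    I_x_s <- purrr::map_dbl(seq_along(states), function(i) {
      linear_fisher(states[[i]]$fp, Sig[[i]])
    })
    shuf <- purrr::map_dbl(seq_along(states), function(i) {
      shuffled_information(states[[i]]$fp, Sig[[i]])
    })
    fano <- average_fano(Sig, purrr::map(states, "f"))
    corr <- average_correlation(Sig)
    I_y <- purrr::map_dbl(sigma2_grid, function(s2) {
      mean(purrr::map_dbl(seq_along(states), function(i) {
        drop(crossprod(states[[i]]$fp,
                       chol_solve(Sig[[i]] + diag(s2, n), states[[i]]$fp)))
      }))
    })
    eps_u_mean <- if (label == "aligned") eps else mean(purrr::map_dbl(states, "eps_u"))
    tibble::tibble(
      population = label,
      sigma2 = sigma2_grid,
      I_y = I_y,
      I_x = mean(I_x_s),
      I_shuffled = mean(shuf),
      fano = fano,
      avg_corr = corr,
      eps_u_mean = eps_u_mean
    )
  }

  out <- dplyr::bind_rows(per_pop("aligned"), per_pop("tilted"))

  # Matching contract: identical input information per stimulus.
  target <- purrr::map_dbl(states, "I_x")
  tilt_I <- purrr::map_dbl(states, function(st) {
    drop(crossprod(st$fp, rank1_inverse(diag(st$d, nrow = n), 1, st$eps_u, st$u) %*% st$fp))
  })
  if (max(abs(tilt_I - target) / target) > 1e-6) {
    abort("Internal error: information matching between populations failed.")
  }

  attr(out, "eps_u") <- purrr::map_dbl(states, "eps_u")
  attr(out, "config") <- list(
    n = n, eps = eps, theta_u = theta_u, n_stimuli = n_stimuli,
    seed = seed, match_correlations = match_correlations
  )
  class(out) <- c("popinfo_noise_sweep", class(out))
  out
}

#' Synergistic-code variant of the noise-robustness sweep
#'
#' Same construction as [run_noise_sweep()] but with a negative rank-one
#' strength (`eps = -5e-4`) and a larger tilt (`theta_u = 1/4` radian), which
#' makes both codes synergistic: the correlated populations carry *more*
#' information than their trial-shuffled controls.
#'
#' @inheritParams run_noise_sweep
#' @return See [run_noise_sweep()].
#' @export
run_synergistic_sweep <- function(n = 100, eps = -5e-4, theta_u = 1 / 4,
                                  n_stimuli = 100,
                                  sigma2_grid = default_sigma2_grid(),
                                  seed = 1, match_correlations = TRUE,
                                  tol = 1e-5, max_attempts = 1e4,
                                  ranges = tuning_ranges()) {
  run_noise_sweep(
    n = n, eps = eps, theta_u = theta_u, n_stimuli = n_stimuli,
    sigma2_grid = sigma2_grid, seed = seed,
    match_correlations = match_correlations, tol = tol,
    max_attempts = max_attempts, ranges = ranges
  )
}

#' @export
glance.popinfo_noise_sweep <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$population),
    I_x = .data$I_x[1],
    I_shuffled = .data$I_shuffled[1],
    fano = .data$fano[1],
    avg_corr = .data$avg_corr[1],
    eps_u_mean = .data$eps_u_mean[1],
    .groups = "drop"
  )
}

#' Information through the spiking layer as correlation structure varies
#'
#' Sweeps the rank-one noise strength `eps_u` (at fixed input information,
#' via the [gamma_u_normalization()] scale) and the tilt angle `theta_u` of
#' the noise direction, pushing each configuration through the
#' dichotomized-Gaussian spiking layer and estimating the output information
#' by Monte Carlo ([mc_fisher()]). `theta_u = 0` is the differential-
#' correlation direction; `sigma_zeta2_set` adds iid Gaussian noise before the
#' threshold (0 means the noise-free spiking channel).
#'
#' @inheritParams run_noise_sweep
#' @param eps_u_grid Rank-one strengths to sweep.
#' @param theta_u_set Tilt angles (radians).
#' @param sigma_zeta2_set Pre-threshold noise variances.
#' @param mc_draws Monte Carlo draws per stimulus.
#' @param ds Finite-difference step for the mean derivative (radians).
#' @return A tibble of class `popinfo_dg_sweep` with one row per
#'   (sigma_zeta2, theta_u, eps_u): columns `I_y_mean` (stimulus-averaged
#'   output information), `mc_se`, `I_x_target_mean`, and
#'   `I_x_max_rel_dev` (worst relative deviation of the realized input
#'   information from its target, a check on the normalization).
#' @export
run_dg_sweep <- function(n = 30,
                         eps_u_grid = 10^seq(-4, -1, length.out = 8),
                         theta_u_set = c(0, 0.1),
                         sigma_zeta2_set = 0,
                         n_stimuli = 20, mc_draws = 1e5, ds = 1e-4,
                         seed = 1, ranges = tuning_ranges()) {
  check_finite_vector(eps_u_grid, "eps_u_grid")
  streams <- rng_streams(seed, 3)
  pop <- sample_tuning_population(n, ranges = ranges, seed = streams[1])
  aux <- withr::with_seed(streams[2], rnorm(n))
  thresholds <- dg_thresholds(pop)
  s_grid <- stimulus_grid(n_stimuli)
  conditions <- tidyr::expand_grid(
    sigma_zeta2 = sigma_zeta2_set,
    theta_u = theta_u_set,
    eps_u = eps_u_grid
  )
  cond_seeds <- withr::with_seed(
    streams[3],
    matrix(sample.int(.Machine$integer.max - 1L, nrow(conditions) * n_stimuli),
           nrow(conditions), n_stimuli)
  )

  # Covariance of the first-layer noise at stimulus s for a given condition,
  # normalized so the input information equals I_0(s) (its eps_u = 0 value).
  sigma_xi_at <- function(s, theta_u, eps_u) {
    f <- tuning_mean(pop, s)
    fp <- tuning_deriv(pop, s)
    I0 <- sum(fp^2 / f)
    u <- if (theta_u == 0) fp else tilted_direction(fp, theta_u, aux)
    gamma <- gamma_u_normalization(fp, f, eps_u, u, I_x_target = I0)
    list(f = f, fp = fp, u = u, gamma = gamma, I0 = I0,
         diag = gamma * (f + eps_u * u^2))
  }

  rows <- purrr::map(seq_len(nrow(conditions)), function(ci) {
    sz2 <- conditions$sigma_zeta2[ci]
    th <- conditions$theta_u[ci]
    eu <- conditions$eps_u[ci]
    per_stim <- purrr::map(seq_along(s_grid), function(si) {
      s <- s_grid[si]
      mu_fn <- function(ss) {
        st <- sigma_xi_at(ss, th, eu)
        dg_mean(st$f, thresholds, sqrt(st$diag + sz2))
      }
      st0 <- sigma_xi_at(s, th, eu)
      sampler <- function(ss, m, sd_seed) {
        st <- sigma_xi_at(ss, th, eu)
        dg_sample(st$f, thresholds, m, sd_seed,
                  structure = list(gamma = st$gamma, d0 = st$f,
                                   epsilon = st$gamma * eu, u = st$u),
                  sigma_zeta2 = sz2)
      }
      est <- mc_fisher(mu_fn, sampler, s, ds = ds, n_draws = mc_draws,
                       seed = cond_seeds[ci, si])
      # realized input information (closed form) vs its target
      I_real <- drop(crossprod(
        st0$fp,
        rank1_inverse(diag(st0$f, nrow = n), st0$gamma, st0$gamma * eu, st0$u) %*% st0$fp
      ))
      list(I_y = est$estimate, se = est$se,
           I_target = st0$I0, rel_dev = abs(I_real - st0$I0) / st0$I0)
    })
    tibble::tibble(
      sigma_zeta2 = sz2, theta_u = th, eps_u = eu,
      I_y_mean = mean(purrr::map_dbl(per_stim, "I_y")),
      mc_se = sqrt(sum(purrr::map_dbl(per_stim, "se")^2)) / length(per_stim),
      I_x_target_mean = mean(purrr::map_dbl(per_stim, "I_target")),
      I_x_max_rel_dev = max(purrr::map_dbl(per_stim, "rel_dev"))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- list(
    n = n, n_stimuli = n_stimuli, mc_draws = mc_draws, ds = ds, seed = seed
  )
  class(out) <- c("popinfo_dg_sweep", class(out))
  out
}

#' Numerically verify the invariance of the maximally robust family
#'
#' Builds the family members of [optimal_family()] over a grid of `alpha`
#' for one sampled population and a configurable downstream covariance, and
#' records the realized input and output information next to the analytic
#' bound \eqn{I_x/(1 + I_x/I_\eta)}. The output information must be constant
#' across all admissible members (relative spread at most 1e-8) and equal to
#' the bound; a violation is an error. Members whose `alpha` leaves the
#' covariance indefinite are flagged, not fatal.
#'
#' @param n Population size.
#' @param alpha_grid Family parameters to test.
#' @param sigma_y `"iid"` (identity downstream covariance) or `"random"`
#'   (a random positive-definite matrix).
#' @param I_x_target Input information of the members; defaults to
#'   \eqn{I_\eta}.
#' @param s Stimulus at which the family is constructed.
#' @param seed Integer seed.
#' @return Tibble with columns `alpha`, `admissible`, `I_x`, `I_y`,
#'   `I_y_bound`; attribute `I_eta`.
#' @export
verify_optimal_family <- function(n = 20, alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                                  sigma_y = c("iid", "random"),
                                  I_x_target = NULL, s = pi / 3, seed = 1) {
  sigma_y <- match.arg(sigma_y)
  streams <- rng_streams(seed, 2)
  pop <- sample_tuning_population(n, seed = streams[1])
  fp <- tuning_deriv(pop, s)
  Sy <- if (sigma_y == "iid") {
    diag(n)
  } else {
    A <- withr::with_seed(streams[2], matrix(rnorm(n * n), n, n))
    symmetrize(tcrossprod(A) / n + 0.1 * diag(n))
  }
  I_eta <- drop(crossprod(fp, chol_solve(Sy, fp)))
  if (is.null(I_x_target)) I_x_target <- I_eta

  rows <- purrr::map(alpha_grid, function(a) {
    member <- tryCatch(optimal_family(a, fp, Sy, I_x_target),
                       error = function(e) NULL)
    if (is.null(member)) {
      return(tibble::tibble(alpha = a, admissible = FALSE,
                            I_x = NA_real_, I_y = NA_real_,
                            I_y_bound = optimal_output(I_x_target, I_eta)))
    }
    I_x_real <- suppressWarnings(linear_fisher(fp, member$Sigma))
    I_y <- drop(crossprod(fp, chol_solve(member$Sigma + Sy, fp)))
    tibble::tibble(alpha = a, admissible = TRUE, I_x = I_x_real, I_y = I_y,
                   I_y_bound = optimal_output(I_x_target, I_eta))
  })
  out <- dplyr::bind_rows(rows)
  ok <- out$admissible
  if (any(ok)) {
    spread <- diff(range(out$I_y[ok])) / mean(out$I_y[ok])
    bound_dev <- max(abs(out$I_y[ok] - out$I_y_bound[ok]) / out$I_y_bound[ok])
    if (spread > 1e-8 || bound_dev > 1e-8) {
      abort(sprintf(
        "Family invariance violated: relative spread %.3g, bound deviation %.3g.",
        spread, bound_dev
      ))
    }
  }
  attr(out, "I_eta") <- I_eta
  out
}
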