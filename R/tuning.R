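#' Von Mises tuning curve
#'
#' Mean firing rate of a neuron with a Von Mises (circular bell-shaped) tuning
#' curve,
#' \deqn{f(s) = \rho + \upsilon \exp\{\beta(\cos(s - \phi) - 1)\},}
#' where `rho` is the baseline rate, `upsilon` the amplitude above baseline,
#' `beta` the (dimensionless) width parameter, and `phi` the preferred
#' stimulus in radians. The curve is \eqn{2\pi}-periodic in `s`, peaks at
#' `rho + upsilon` when `s = phi`, and is bounded below by `rho`.
#'
#' All arguments recycle elementwise, so a vector of parameters evaluates a
#' whole population at one stimulus, and a vector `s` traces one curve.
#'
#' @param s Stimulus angle(s) in radians.
#' @param rho Baseline rate, `>= 0`.
#' @param upsilon Amplitude, `> 0`.
#' @param beta Width parameter, `> 0`.
#' @param phi Preferred stimulus in radians.
#' @return Firing rate(s), same length as the recycled arguments.
#' @seealso [vonmises_derivative()], [sample_tuning_population()]
#' @examples
#' vonmises_curve(pi, rho = 1, upsilon = 51, beta = 6, phi = 0)
#' @export
vonmises_curve <- function(s, rho, upsilon, beta, phi) {
  validate_vonmises_params(rho, upsilon, beta, phi)
  check_finite_vector(s, "s")
  rho + upsilon * exp(beta * (cos(s - phi) - 1))
}

#' Derivative of the Von Mises tuning curve with respect to the stimulus
#'
#' Analytic derivative
#' \deqn{f'(s) = -\upsilon \beta \sin(s - \phi)\exp\{\beta(\cos(s-\phi)-1)\},}
#' in rate per radian. The vector of derivatives across a population is the
#' signal direction: the direction in which the mean population response moves
#' for a small change in the stimulus.
#'
#' @inheritParams vonmises_curve
#' @return Rate-per-radian derivative(s).
#' @examples
#' vonmises_derivative(1, rho = 0.5, upsilon = 10, beta = 2, phi = 1) # 0 at peak
#' @export
vonmises_derivative <- function(s, rho, upsilon, beta, phi) {
  validate_vonmises_params(rho, upsilon, beta, phi)
  check_finite_vector(s, "s")
  -upsilon * beta * sin(s - phi) * exp(beta * (cos(s - phi) - 1))
}

validate_vonmises_params <- function(rho, upsilon, beta, phi) {
  for (nm in c("rho", "upsilon", "beta", "phi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) < 1L || !all(is.finite(v))) {
      abort(sprintf("Tuning parameter `%s` must be finite numeric.", nm))
    }
  }
  if (any(rho < 0)) abort("Baseline `rho` must be >= 0.")
  if (any(upsilon <= 0)) abort("Amplitude `upsilon` must be > 0.")
  if (any(beta <= 0)) abort("Width `beta` must be > 0.")
  invisible(TRUE)
}

#' Parameter ranges for sampling a heterogeneous population
#'
#' Default ranges follow the heterogeneous-population recipe used throughout
#' the numerical experiments: amplitudes `upsilon` uniform on \[1, 51\],
#' widths `beta` on \[1, 6\], preferred stimuli `phi` on \[0, 2pi), and
#' baselines `rho` on \[0, 1\].
#'
#' @param upsilon,beta,phi,rho Length-2 numeric intervals `c(lo, hi)`.
#' @return A named list of validated intervals.
#' @examples
#' tuning_ranges(rho = c(0, 0.5))
#' @export
tuning_ranges <- function(upsilon = c(1, 51), beta = c(1, 6),
                          phi = c(0, 2 * pi), rho = c(0, 1)) {
  ranges <- list(upsilon = upsilon, beta = beta, phi = phi, rho = rho)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
      abort(sprintf("Range for `%s` must be a finite interval c(lo, hi) with lo <= hi.", nm))
    }
  }
  if (ranges$upsilon[1] <= 0) abort("`upsilon` range must be positive.")
  if (ranges$beta[1] <= 0) abort("`beta` range must be positive.")
  if (ranges$rho[1] < 0) abort("`rho` range must be non-negative.")
  ranges
}

#' Sample a heterogeneous Von Mises tuning population
#'
#' Draws `n` neurons with parameters independently uniform on the configured
#' ranges. Each coordinate is independent across neurons and parameters, and
#' the draw is fully reproducible from `seed`.
#'
#' @param n Number of neurons, `>= 1`.
#' @param ranges Output of [tuning_ranges()].
#' @param seed Integer seed for the draw.
#' @return A tibble of class `tuning_population` with columns `neuron_id`,
#'   `rho`, `upsilon`, `beta`, `phi`.
#' @examples
#' pop <- sample_tuning_population(5, seed = 1)
#' tuning_mean(pop, pi / 3)
#' @export
sample_tuning_population <- function(n, ranges = tuning_ranges(), seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  ranges <- do.call(tuning_ranges, ranges)
  draw <- withr::with_seed(as.integer(seed), {
    tibble::tibble(
      neuron_id = seq_len(n),
      rho = runif(n, ranges$rho[1], ranges$rho[2]),
      upsilon = runif(n, ranges$upsilon[1], ranges$upsilon[2]),
      beta = runif(n, ranges$beta[1], ranges$beta[2]),
      phi = runif(n, ranges$phi[1], ranges$phi[2])
    )
  })
  new_tuning_population(draw)
}

new_tuning_population <- function(df) {
  needed <- c("neuron_id", "rho", "upsilon", "beta", "phi")
  if (!all(needed %in% names(df))) {
    abort(sprintf("A tuning population needs columns: %s.", paste(needed, collapse = ", ")))
  }
  validate_vonmises_params(df$rho, df$upsilon, df$beta, df$phi)
  df <- tibble::tibble(
    neuron_id = as.integer(df$neuron_id),
    rho = as.double(df$rho),
    upsilon = as.double(df$upsilon),
    beta = as.double(df$beta),
    phi = as.double(df$phi)
  )
  tibble::new_tibble(df, class = "tuning_population")
}

#' Evaluate a population's mean responses and their stimulus derivatives
#'
#' `tuning_mean()` returns the n-vector \eqn{f(s)} of mean rates;
#' `tuning_deriv()` returns the signal direction \eqn{f'(s)}.
#'
#' @param pop A `tuning_population` tibble.
#' @param s A single stimulus angle in radians.
#' @return Numeric vector of length `nrow(pop)`.
#' @export
tuning_mean <- function(pop, s) {
  check_finite_scalar(s, "s")
  vonmises_curve(s, pop$rho, pop$upsilon, pop$beta, pop$phi)
}

#' @rdname tuning_mean
#' @export
tuning_deriv <- function(pop, s) {
  check_finite_scalar(s, "s")
  vonmises_derivative(s, pop$rho, pop$upsilon, pop$beta, pop$phi)
}

#' Read or write a tuning population as plain CSV
#'
#' The on-disk format is a CSV with columns `neuron_id, rho, upsilon, beta,
#' phi`, so an experiment can pin one sampled population to a file.
#'
#' @param pop A `tuning_population`.
#' @param path File path.
#' @return `write_population()` returns `path` invisibly; `read_population()`
#'   returns a `tuning_population` tibble.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "tuning_population"))
  readr::write_csv(tibble::as_tibble(pop), path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_tuning_population(df)
}
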