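# Experiment configuration, validation, fixtures and result I/O.

config_schema <- function(experiment) {
  common <- list(
    n = "numeric", n_stimuli = "numeric", seed = "numeric"
  )
  extra <- switch(experiment,
    noise_sweep = ,
    synergy = list(
      epsilon = "numeric", theta_u = "numeric", sigma2_grid = "numeric",
      match_correlations = "logical", tol = "numeric", max_attempts = "numeric"
    ),
    dg = list(
      eps_u_grid = "numeric", theta_u_set = "numeric",
      sigma_zeta2_set = "numeric", mc_draws = "numeric", ds = "numeric"
    ),
    family = list(
      alpha_grid = "numeric", sigma_y = "character", I_x_target = "numeric",
      s = "numeric"
    ),
    abort(sprintf("Unknown experiment `%s`.", experiment))
  )
  c(common, extra)
}

config_defaults <- function(experiment) {
  switch(experiment,
    noise_sweep = list(
      n = 100, n_stimuli = 100, seed = 1, epsilon = 1e-3, theta_u = 1 / 8,
      sigma2_grid = default_sigma2_grid(), match_correlations = TRUE,
      tol = 1e-5, max_attempts = 1e4
    ),
    synergy = list(
      n = 100, n_stimuli = 100, seed = 1, epsilon = -5e-4, theta_u = 1 / 4,
      sigma2_grid = default_sigma2_grid(), match_correlations = TRUE,
      tol = 1e-5, max_attempts = 1e4
    ),
    dg = list(
      n = 100, n_stimuli = 20, seed = 1,
      eps_u_grid = 10^seq(-4, -1, length.out = 8),
      theta_u_set = c(0, 0.05, 0.1, 0.2), sigma_zeta2_set = 0,
      mc_draws = 1e6, ds = 1e-4
    ),
    family = list(
      n = 20, n_stimuli = 1, seed = 1,
      alpha_grid = c(0, 0.25, 0.5, 0.75, 1), sigma_y = "random",
      I_x_target = NULL, s = pi / 3
    ),
    abort(sprintf("Unknown experiment `%s`.", experiment))
  )
}

#' Build a validated experiment configuration
#'
#' Fills defaults for the named experiment, validates every supplied field
#' against the experiment's schema, and rejects unknown keys.
#'
#' @param experiment One of `"noise_sweep"`, `"synergy"`, `"dg"`, `"family"`.
#' @param ... Named overrides of the experiment's parameters.
#' @return A list of class `experiment_config`.
#' @examples
#' cfg <- experiment_config("noise_sweep", n = 30, seed = 7)
#' cfg$epsilon
#' @export
experiment_config <- function(experiment, ...) {
  if (!is.character(experiment) || length(experiment) != 1L) {
    abort("`experiment` must be a single string.")
  }
  schema <- config_schema(experiment)
  cfg <- config_defaults(experiment)
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("All configuration overrides must be named.")
  }
  unknown <- setdiff(names(overrides), names(schema))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration keys for experiment `%s`: %s.",
                  experiment, paste(unknown, collapse = ", ")))
  }
  for (key in names(overrides)) {
    val <- overrides[[key]]
    if (is.null(val)) {
      cfg[key] <- list(NULL)
      next
    }
    type <- schema[[key]]
    ok <- switch(type,
      numeric = is.numeric(val) && all(is.finite(val)),
      logical = is.logical(val) && length(val) == 1L && !is.na(val),
      character = is.character(val) && length(val) == 1L
    )
    if (!ok) {
      abort(sprintf("Configuration key `%s` must be %s; got `%s`.",
                    key, type, paste(format(val), collapse = ", ")))
    }
    cfg[[key]] <- val
  }
  structure(c(list(experiment = experiment), cfg), class = "experiment_config")
}

#' Load and write experiment configurations as YAML
#'
#' `load_experiment_config()` parses a YAML file, requires an `experiment`
#' key, validates all other keys against the experiment schema (unknown keys
#' are an error), and fills defaults. `write_experiment_config()` writes a
#' resolved configuration back; a write-then-load round trip is the identity.
#'
#' @param path YAML file path.
#' @param config An `experiment_config`.
#' @return `load_experiment_config()` returns an `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$experiment)) {
    abort("The config file must contain an `experiment` key.")
  }
  experiment <- raw$experiment
  raw$experiment <- NULL
  # YAML numbers may arrive as integers or lists; normalize vectors.
  raw <- purrr::map(raw, function(v) if (is.list(v)) unlist(v) else v)
  do.call(experiment_config, c(list(experiment = experiment), raw))
}

#' @rdname load_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the experiment described by a configuration
#'
#' Dispatches to [run_noise_sweep()], [run_synergistic_sweep()],
#' [run_dg_sweep()] or [verify_optimal_family()].
#'
#' @param config An `experiment_config`.
#' @return The experiment's results tibble.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  with(config, switch(config$experiment,
    noise_sweep = run_noise_sweep(
      n = n, eps = epsilon, theta_u = theta_u, n_stimuli = n_stimuli,
      sigma2_grid = sigma2_grid, seed = seed,
      match_correlations = match_correlations, tol = tol,
      max_attempts = max_attempts
    ),
    synergy = run_synergistic_sweep(
      n = n, eps = epsilon, theta_u = theta_u, n_stimuli = n_stimuli,
      sigma2_grid = sigma2_grid, seed = seed,
      match_correlations = match_correlations, tol = tol,
      max_attempts = max_attempts
    ),
    dg = run_dg_sweep(
      n = n, eps_u_grid = eps_u_grid, theta_u_set = theta_u_set,
      sigma_zeta2_set = sigma_zeta2_set, n_stimuli = n_stimuli,
      mc_draws = mc_draws, ds = ds, seed = seed
    ),
    family = verify_optimal_family(
      n = n, alpha_grid = alpha_grid, sigma_y = sigma_y,
      I_x_target = I_x_target, s = s, seed = seed
    )
  ))
}

#' Deterministic miniature instances for tests and examples
#'
#' @param kind One of `"population"` (5-neuron-style tuning population),
#'   `"covariance"` (random positive-definite matrix, eigenvalues reported),
#'   `"channel"` (identity-weight linear channel spec), `"dg"` (two
#'   correlated binary neurons whose joint firing probabilities can be
#'   checked by 2-D quadrature).
#' @param size Instance size (neurons / matrix dimension).
#' @param seed Integer seed; the same seed reproduces the same fixture.
#' @return The fixture; structure depends on `kind`.
#' @export
make_fixture <- function(kind, size = 5, seed = 1) {
  switch(kind,
    population = sample_tuning_population(size, seed = seed),
    covariance = {
      A <- withr::with_seed(as.integer(seed), matrix(rnorm(size * size), size, size))
      S <- symmetrize(tcrossprod(A) / size + 0.5 * diag(size))
      list(Sigma = S, eigenvalues = eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    },
    channel = list(
      W = diag(size),
      gain = gain_linear(1),
      Sigma_eta = withr::with_seed(as.integer(seed), {
        v <- runif(size, 0.5, 1.5)
        diag(v, nrow = size)
      })
    ),
    dg = withr::with_seed(as.integer(seed), {
      rho <- runif(1, -0.5, 0.5)
      f <- runif(2, 0.5, 1.5)
      list(
        f = f,
        Sigma = matrix(c(1, rho, rho, 1), 2, 2),
        thresholds = runif(2, 0.5, 1.5),
        correlation = rho
      )
    }),
    abort(sprintf("Unknown fixture kind `%s`.", kind))
  )
}

#' Write and read experiment result tables
#'
#' `write_results()` writes a CSV with a header row at full (round-trip safe)
#' float precision; non-finite values in numeric columns are rejected, since
#' information values must be finite. `read_results()` reads it back.
#'
#' @param table A data frame of results.
#' @param path CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()` a
#'   tibble.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table)) abort("`table` must be a data frame.")
  for (col in names(table)) {
    v <- table[[col]]
    if (is.numeric(v) && length(v) > 0 && any(!is.finite(v))) {
      abort(sprintf("Column `%s` contains non-finite values; results must be finite.", col))
    }
  }
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
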