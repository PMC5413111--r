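test_that("mean drive is the matrix-vector product", {
  f <- c(1, 2, 3)
  expect_equal(mean_drive(diag(3), f), f)
  expect_equal(mean_drive(matrix(0, 2, 3), f), c(0, 0))
  withr::with_seed(31, W <- matrix(rnorm(12), 4, 3))
  naive <- vapply(1:4, function(i) sum(W[i, ] * f), numeric(1))
  expect_equal(mean_drive(W, f), naive)
  expect_error(mean_drive(diag(2), f), "mismatch")
})

test_that("effective weights reduce to exact closed forms", {
  h <- c(0.2, -1, 2)
  W <- matrix(1, 3, 3)
  # linear gain: W_eff = c * W regardless of the noise
  ew <- effective_weights(W, gain_linear(2.5), h, Sigma_chi = c(1, 2, 3))
  expect_equal(ew$W_eff, 2.5 * W)
  expect_equal(diag(ew$G_prime), rep(2.5, 3))
  # identity gain, any noise: unit average slope
  ew1 <- effective_weights(W, gain_linear(1), h, Sigma_chi = diag(3))
  expect_equal(diag(ew1$G_prime), rep(1, 3))
  # step gain: smoothed slope is the Gaussian density at (h - theta)
  theta <- 0.5
  sds <- c(0.4, 1, 2)
  ews <- effective_weights(W, gain_step(theta), h, Sigma_chi = sds^2)
  expect_equal(diag(ews$G_prime), dnorm(h - theta, sd = sds))
  # the step slope equals the derivative of the smoothed mean Phi((h-theta)/sd)
  num <- fd_central(function(x) pnorm((x - theta) / sds[1]), h[1])
  expect_equal(diag(ews$G_prime)[1], num, tolerance = 1e-6)
})

test_that("a differentiable gain without closed form uses quadrature correctly", {
  # tanh: compare against brute-force numerical integration of E[g'(h + sd z)]
  h <- c(-0.5, 0.8)
  sds <- c(0.6, 1.2)
  ew <- effective_weights(diag(2), gain_tanh(), h, Sigma_chi = sds^2)
  for (i in 1:2) {
    expected <- integrate(function(z) dnorm(z) * (1 - tanh(h[i] + sds[i] * z)^2),
                          -9, 9, rel.tol = 1e-10)$value
    expect_equal(diag(ew$G_prime)[i], expected, tolerance = 1e-6)
  }
})

test_that("delta_sigma_g vanishes for linear gains and matches the quadratic closed form", {
  h <- c(0.3, -0.7, 1.1)
  Schi <- random_spd(3, seed = 32)
  dlin <- delta_sigma_g(gain_linear(1.7), h, Schi, mc_samples = 2e4, seed = 33)
  expect_lt(max(abs(dlin)), 0.05 * max(abs(Schi)))
  # 1-D quadratic gain under Gaussian noise: delta = 2 a^2 sigma^4 exactly
  a <- 0.8
  sigma <- 1.3
  dq <- delta_sigma_g(gain_quadratic(a), h = 0.4, Sigma_chi = sigma^2,
                      mc_samples = 4e5, seed = 34)
  expect_equal(dq[1, 1], 2 * a^2 * sigma^4, tolerance = 0.02)
  expect_error(delta_sigma_g(gain_linear(1), h, Schi, mc_samples = 100), "1000")
})

test_that("delta_sigma_g is PSD to Monte Carlo error for a tanh gain with Gaussian noise", {
  h <- c(-1, -0.2, 0.4, 1, 2)
  Schi <- random_spd(5, seed = 35)
  d <- delta_sigma_g(gain_tanh(), h, Schi, mc_samples = 1e5, seed = 36)
  expect_gte(attr(d, "min_eigenvalue"), -3 * attr(d, "min_eigenvalue_se"))
})

test_that("dichotomized-Gaussian means follow the normal CDF", {
  expect_equal(dg_mean(1, 1, 0.5), 0.5)
  expect_equal(dg_mean(2, 1, 1), pnorm(1))
  expect_equal(dg_mean(0, 2, 1), pnorm(-2))
  expect_error(dg_mean(1, 1, 0), "> 0")
})

test_that("dg_sample matches its analytic means and orthant probabilities", {
  # thresholds at -Inf: every neuron always fires
  y <- dg_sample(c(0.5, 1), c(-Inf, -Inf), 1000, seed = 37, Sigma_xi = diag(2))
  expect_true(all(y == 1))
  # independent neurons: column means within 4 binomial standard errors
  f <- c(0.8, 1.5, 2.2)
  v <- c(0.9, 1.4, 0.6)
  th <- c(1, 1, 3)
  m <- 1e5
  y <- dg_sample(f, th, m, seed = 38, Sigma_xi = diag(v))
  mu <- dg_mean(f, th, sqrt(v))
  se <- sqrt(mu * (1 - mu) / m)
  expect_true(all(abs(colMeans(y) - mu) < 4 * se))
  # two correlated neurons: joint firing probability vs 2-D quadrature
  fx <- make_fixture("dg", seed = 39)
  yy <- dg_sample(fx$f, fx$thresholds, 2e5, seed = 40, Sigma_xi = fx$Sigma)
  p11 <- mean(yy[, 1] == 1 & yy[, 2] == 1)
  p_true <- orthant_prob(fx$f, fx$Sigma, fx$thresholds)
  expect_lt(abs(p11 - p_true), 4 * sqrt(p_true * (1 - p_true) / 2e5))
})

test_that("structured and dense samplers agree in their moments", {
  d0 <- c(1, 2, 1.5, 0.8)
  u <- c(2, -1, 0.5, 1)
  gamma <- 0.7
  eps <- 0.3
  f <- c(0, 0, 0, 0)
  th <- c(0.2, 0.2, 0.2, 0.2)
  m <- 1e5
  S <- rank1_covariance(diag(d0), gamma, eps, u)
  y1 <- dg_sample(f, th, m, seed = 41, structure = list(gamma = gamma, d0 = d0,
                                                        epsilon = eps, u = u))
  y2 <- dg_sample(f, th, m, seed = 42, Sigma_xi = S)
  mu <- dg_mean(f, th, sqrt(diag(S)))
  se <- sqrt(mu * (1 - mu) / m)
  expect_true(all(abs(colMeans(y1) - mu) < 4 * se))
  expect_true(all(abs(colMeans(y1) - colMeans(y2)) < 5 * se))
  cov_gap <- abs(cov(y1) - cov(y2))
  expect_lt(max(cov_gap), 0.02)
})

test_that("mc_fisher recovers closed-form information for tractable channels", {
  # linear-Gaussian sanity channel: analytic value f' Sigma^-1 f'
  pop <- sample_tuning_population(4, seed = 43)
  s <- 1.2
  Sxi <- random_spd(4, seed = 44, jitter = 1)
  L <- t(chol(Sxi))
  sampler <- function(ss, m, sd_seed) {
    f <- tuning_mean(pop, ss)
    withr::with_seed(sd_seed, {
      sweep(matrix(rnorm(m * 4), m, 4) %*% t(L), 2, f, "+")
    })
  }
  est <- mc_fisher(function(ss) tuning_mean(pop, ss), sampler, s,
                   n_draws = 5e4, seed = 45)
  truth <- linear_fisher(tuning_deriv(pop, s), Sxi)
  expect_lt(abs(est$estimate - truth), 4 * est$se + 1e-8)

  # two independent binary neurons (thresholds near the operating point so
  # both cells fire at intermediate rates): sum of mu'^2 / (mu (1 - mu))
  pop2 <- sample_tuning_population(2, seed = 46)
  th2 <- tuning_mean(pop2, 0.9) - c(0.4, 0.8)
  v2 <- c(1.5, 2.5)
  mu_fn <- function(ss) dg_mean(tuning_mean(pop2, ss), th2, sqrt(v2))
  sampler2 <- function(ss, m, sd_seed) {
    dg_sample(tuning_mean(pop2, ss), th2, m, sd_seed, Sigma_xi = diag(v2))
  }
  est2 <- mc_fisher(mu_fn, sampler2, s = 0.9, n_draws = 2e5, seed = 47)
  mu <- mu_fn(0.9)
  dmu <- (mu_fn(0.9 + 1e-4) - mu_fn(0.9 - 1e-4)) / 2e-4
  truth2 <- sum(dmu^2 / (mu * (1 - mu)))
  expect_lt(abs(est2$estimate - truth2), 4 * est2$se + 0.02 * truth2)
})

test_that("mc_fisher validates its preconditions", {
  expect_error(mc_fisher(identity, identity, 1, ds = 0), "> 0")
  expect_error(mc_fisher(identity, identity, 1, n_draws = 100), "1e4")
})
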