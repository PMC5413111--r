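test_that("linear Fisher information matches simple closed forms", {
  expect_equal(linear_fisher(c(1, 0), diag(2)), 1)
  expect_equal(linear_fisher(c(3, 4), 25 * diag(2)), 1)
})

test_that("linear Fisher information equals the inverse variance of the best linear estimator", {
  withr::with_seed(21, fp <- rnorm(50))
  S <- random_spd(50, seed = 22)
  expect_equal(linear_fisher(fp, S), fisher_by_estimator_variance(fp, S),
               tolerance = 1e-8)
})

test_that("singular covariances use the support or fail loudly", {
  fp <- c(2, 1)
  S <- differential_covariance(fp, 4) # rank one, fp inside the support
  expect_warning(val <- linear_fisher(fp, S), "pseudo-inverse")
  expect_equal(val, 4, tolerance = 1e-10)
  S2 <- matrix(c(1, 0, 0, 0), 2, 2) # fp has a component outside the support
  expect_error(linear_fisher(c(1, 1), S2), "unbounded")
})

test_that("the two output-information forms agree and reduce correctly", {
  # noiseless channel (direct form): all input information survives
  fp <- c(1, -2, 0.5)
  Sxi <- random_spd(3, seed = 23)
  expect_equal(output_information_direct(fp, Sxi, diag(3), matrix(0, 3, 3)),
               linear_fisher(fp, Sxi))
  # diagonal closed form
  v <- c(1, 2, 3)
  s2 <- 0.7
  expect_equal(
    output_information(fp, diag(v), diag(3), s2 * diag(3)),
    sum(fp^2 / (v + s2))
  )
  # no weights, no signal
  expect_equal(output_information_direct(fp, Sxi, matrix(0, 3, 3), diag(3)), 0)
  # zero first-layer noise: reduces to the output-layer information
  Seta <- random_spd(3, seed = 24)
  expect_equal(output_information_direct(fp, matrix(0, 3, 3), diag(3), Seta),
               linear_fisher(fp, Seta))
})

test_that("Woodbury equivalence holds on random full-rank instances", {
  withr::with_seed(25, {
    for (i in 1:50) {
      n_in <- sample(2:20, 1)
      n_out <- n_in + sample(0:10, 1)
      fp <- rnorm(n_in)
      Sxi <- random_spd(n_in, seed = 1000 + i)
      W <- matrix(rnorm(n_out * n_in), n_out, n_in)
      Seta <- random_spd(n_out, seed = 2000 + i)
      a <- output_information(fp, Sxi, W, Seta)
      b <- output_information_direct(fp, Sxi, W, Seta)
      expect_equal(a, b, tolerance = 1e-8)
    }
  })
})

test_that("shuffling removes correlations only", {
  S <- diag(c(1, 2, 4))
  fp <- c(1, 1, 1)
  expect_equal(shuffled_information(fp, S), linear_fisher(fp, S))
  Sc <- random_spd(3, seed = 26)
  expect_equal(shuffled_information(fp, Sc), sum(fp^2 / diag(Sc)))
})

test_that("the optimal output bound has its closed-form values and limits", {
  expect_equal(optimal_output(10, 10), 5)
  expect_equal(optimal_output(3, Inf), 3)
  expect_equal(optimal_output(100, 1), 100 / 101)
  expect_lte(optimal_output(7, 2), min(7, 2))
  expect_error(optimal_output(-1, 1), ">= 0")
})

test_that("the spectral information form matches reconstruction", {
  withr::with_seed(27, fp <- rnorm(8))
  S <- random_spd(8, seed = 28)
  e <- eigen(S, symmetric = TRUE)
  expect_equal(eigen_information(fp, e$values, e$vectors), linear_fisher(fp, S),
               tolerance = 1e-10)
  # aligned with one eigenvector
  v0 <- e$vectors[, 1]
  expect_equal(eigen_information(2 * v0, e$values, e$vectors), 4 / e$values[1])
  # isotropic spectrum
  expect_equal(eigen_information(fp, rep(2, 8), diag(8)), sum(fp^2) / 2)
  expect_error(eigen_information(fp, e$values, e$vectors * 2), "orthonormal")
})

test_that("the 2-D transmission ratio matches its closed-form limits", {
  expect_equal(information_ratio_2d(2, 1, 0, 1), 4 / 5)
  expect_equal(information_ratio_2d(10, 1, pi / 2, 1), 1 / 2)
  expect_equal(information_ratio_2d(3, 0.5, 1.1, 0), 1)
  expect_error(information_ratio_2d(1, 2, 0, 1), "sigma1 >= sigma2")
})

test_that("the minimum-information construction scales and attains the bound", {
  r <- minimum_information_covariance(c(1, 0), 1)
  expect_equal(r$Sigma, matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(r$info, 1)
  withr::with_seed(29, fp <- rnorm(6))
  expect_equal(minimum_information_covariance(fp, 4)$info,
               minimum_information_covariance(fp, 2)$info / 2)
})

test_that("total information reduces correctly and matches adaptive quadrature", {
  expect_equal(total_information(0, rep(5, 4), rep(0.25, 4)), 5)
  expect_equal(total_information(0.1, rep(5, 4), rep(0.25, 4)), 1 / (0.1 + 1 / 5))
  # Gaussian jitter kernel over a fine grid with a smooth information profile
  s0 <- pi
  sd_j <- 0.15
  info_fn <- function(s) 40 + 10 * s
  grid <- seq(s0 - 6 * sd_j, s0 + 6 * sd_j, length.out = 4001)
  w <- dnorm(grid, s0, sd_j)
  w <- w / sum(w)
  got <- total_information(sd_j^2, info_fn(grid), w)
  integ <- integrate(function(s) dnorm(s, s0, sd_j) / info_fn(s),
                     s0 - 8 * sd_j, s0 + 8 * sd_j, rel.tol = 1e-10)$value
  expect_equal(got, 1 / (sd_j^2 + integ), tolerance = 1e-6)
  expect_error(total_information(0, c(0, 1), c(0.5, 0.5)), "Zero information")
})

test_that("adding PSD noise through an identity linear channel never increases information", {
  withr::with_seed(30, {
    for (i in 1:20) {
      n <- sample(3:12, 1)
      fp <- rnorm(n)
      Sxi <- random_spd(n, seed = 3000 + i)
      Sadd <- random_spd(n, seed = 4000 + i)
      I_x <- linear_fisher(fp, Sxi)
      I_y <- output_information_direct(fp, Sxi, diag(n), Sadd)
      expect_lte(I_y, I_x + 1e-10)
    }
  })
})
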