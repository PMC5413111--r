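test_that("the Poisson-like diagonal base has unit Fano factors", {
  S <- poisson_diagonal(c(1, 2, 3))
  expect_equal(S, diag(c(1, 2, 3)))
  f <- c(0.5, 4, 9)
  expect_equal(diag(poisson_diagonal(f)) / f, rep(1, 3))
  expect_error(poisson_diagonal(c(1, 0, 2)), "> 0")
})

test_that("tilted_direction preserves the norm and realizes the requested angle", {
  withr::with_seed(5, {
    fp <- rnorm(40)
    aux <- rnorm(40)
  })
  expect_equal(tilted_direction(fp, 0, aux), fp)
  u90 <- tilted_direction(fp, pi / 2, aux)
  expect_equal(sum(u90 * fp), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(u90^2)), sqrt(sum(fp^2)))
  u <- tilted_direction(fp, 1 / 8, aux)
  cosang <- sum(u * fp) / (sqrt(sum(u^2)) * sqrt(sum(fp^2)))
  expect_equal(cosang, cos(1 / 8), tolerance = 1e-12)
  expect_error(tilted_direction(rep(0, 4), 0.1, c(1, 0, 0, 0)), "non-zero")
  expect_error(tilted_direction(c(1, 0), 0.1, c(2, 0)), "parallel")
})

test_that("rank1_covariance builds the stated matrix and rejects indefinite ones", {
  S0 <- poisson_diagonal(c(2, 3, 5))
  expect_equal(rank1_covariance(S0, 1, 0), S0)
  fp <- c(1, -2, 4)
  Sb <- rank1_covariance(S0, 1, 1e-3, fp)
  expect_equal(diag(Sb), c(2, 3, 5) + 1e-3 * fp^2)
  expect_equal(Sb, t(Sb))
  # a rank-one positive update cannot lower any eigenvalue below the base
  withr::with_seed(8, {
    for (i in 1:20) {
      d <- runif(6, 0.5, 4)
      u <- rnorm(6)
      g <- runif(1, 0.5, 2)
      S <- rank1_covariance(diag(d), g, runif(1, 0, 2), u)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), g * min(d) - 1e-10)
    }
  })
  expect_error(rank1_covariance(diag(2), 1, -2, c(1, 0)),
               "minimum eigenvalue")
})

test_that("rank1_inverse matches dense inversion and inverts its constructor", {
  S0 <- diag(3)
  expect_equal(rank1_inverse(S0, 2, 0), diag(3) / 2)
  Si <- rank1_inverse(diag(4), 1, 1, c(1, 0, 0, 0))
  expect_equal(Si, diag(c(1 / 2, 1, 1, 1)))
  withr::with_seed(9, {
    for (i in 1:20) {
      d <- runif(8, 0.5, 4)
      u <- rnorm(8)
      g <- runif(1, 0.5, 2.5)
      eps <- runif(1, -0.05, 0.5)
      S <- tryCatch(rank1_covariance(diag(d), g, eps, u), error = function(e) NULL)
      if (is.null(S)) next
      Si <- rank1_inverse(diag(d), g, eps, u)
      expect_lt(max(abs(Si - solve(S))), 1e-8)
      expect_lt(max(abs(Si %*% S - diag(8))), 1e-8)
    }
  })
})

test_that("gamma_u normalization pins the input information to its target", {
  withr::with_seed(10, {
    d <- runif(30, 0.5, 5)
    fp <- rnorm(30, sd = 3)
    aux <- rnorm(30)
  })
  I0 <- sum(fp^2 / d)
  expect_equal(gamma_u_normalization(fp, d, 0, NULL, I_x_target = 2), I0 / 2)
  # u = f': algebraic simplification
  eps <- 0.02
  expect_equal(gamma_u_normalization(fp, d, eps, fp, I_x_target = 5),
               I0 / (5 * (1 + eps * I0)))
  # defining property for random tilts and strengths
  withr::with_seed(11, {
    for (i in 1:10) {
      theta <- runif(1, 0, 0.4)
      eps_u <- runif(1, 0, 0.2)
      u <- tilted_direction(fp, theta, aux)
      S <- normalized_rank1_covariance(fp, d, eps_u, u, I_x_target = 7)
      expect_equal(linear_fisher(fp, S), 7, tolerance = 1e-8)
    }
  })
  expect_error(gamma_u_normalization(fp, d, 0, NULL, I_x_target = -1), "> 0")
})

test_that("epsilon_match recovers the aligned strength and the unperturbed limit", {
  withr::with_seed(12, {
    d <- runif(25, 0.5, 5)
    fp <- rnorm(25, sd = 2)
    aux <- rnorm(25)
  })
  I0 <- sum(fp^2 / d)
  eps <- 1e-3
  expect_equal(epsilon_match(fp, d, fp, I0 / (1 + eps * I0)), eps, tolerance = 1e-10)
  expect_equal(epsilon_match(fp, d, fp, I0), 0, tolerance = 1e-12)
  # matching property with a tilted direction
  u <- tilted_direction(fp, 1 / 8, aux)
  target <- I0 / (1 + eps * I0)
  eps_u <- epsilon_match(fp, d, u, target)
  S <- rank1_covariance(diag(d), 1, eps_u, u)
  expect_equal(linear_fisher(fp, S), target, tolerance = 1e-8)
})

test_that("differential correlations are rank one and carry the target information", {
  S <- differential_covariance(c(1, 0), 1)
  expect_equal(S, matrix(c(1, 0, 0, 0), 2, 2))
  withr::with_seed(13, fp <- rnorm(12))
  Sd <- differential_covariance(fp, 3.5)
  expect_equal(qr(Sd)$rank, 1L)
  expect_equal(pinv_quadform(fp, Sd), 3.5, tolerance = 1e-10)
  expect_error(differential_covariance(rep(0, 3), 1), "non-zero")
})

test_that("the optimal family interpolates between differential and matched covariances", {
  withr::with_seed(14, fp <- rnorm(20, sd = 2))
  Sy <- random_spd(20, seed = 15)
  m0 <- optimal_family(0, fp, Sy, I_x_target = 4)
  expect_equal(m0$Sigma, differential_covariance(fp, 4))
  m1 <- optimal_family(1, fp, Sy, I_x_target = 4)
  ratio <- m1$Sigma / Sy
  expect_equal(max(ratio), min(ratio), tolerance = 1e-12) # proportional to Sigma_y
  td <- tidy(m1)
  expect_equal(td$I_y_bound, optimal_output(td$I_x, td$I_eta))
})

test_that("all admissible family members transmit identical output information", {
  Sy <- random_spd(20, seed = 16)
  withr::with_seed(17, fp <- rnorm(20, sd = 2))
  I_x <- 10
  I_y <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    m <- optimal_family(a, fp, Sy, I_x)
    output_information_direct(fp, m$Sigma, diag(20), Sy)
  }, numeric(1))
  expect_lt(diff(range(I_y)) / mean(I_y), 1e-8)
})

test_that("an inadmissible alpha is rejected with an interval endpoint", {
  fp <- c(3, 1, 0.5)
  Sy <- diag(3)
  # negative alpha flips the sign of the Sigma_y term off the signal direction
  expect_error(optimal_family(-0.5, fp, Sy, I_x_target = 1), "admissible interval")
})

test_that("average correlation and Fano behave on known matrices", {
  expect_equal(average_correlation(diag(c(1, 2, 3))), 0)
  expect_equal(average_correlation(matrix(c(1, 0.3, 0.3, 1), 2, 2)), 0.3)
  f <- c(1, 2, 3)
  S0 <- poisson_diagonal(f)
  expect_equal(average_fano(S0, f), 1)
  expect_equal(average_fano(2 * S0, f), 2)
  expect_error(average_correlation(matrix(c(0, 0, 0, 1), 2, 2)), "variance")
})

test_that("the fast rank-one correlation average matches the generic computation", {
  withr::with_seed(18, {
    for (i in 1:5) {
      d <- runif(15, 0.5, 5)
      u <- rnorm(15)
      eps <- runif(1, 0, 0.01)
      S <- rank1_covariance(diag(d), 1, eps, u)
      expect_equal(popinfo:::avg_corr_rank1(d, eps, u), average_correlation(S),
                   tolerance = 1e-12)
    }
  })
})
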