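# Independent oracles used across the test files. These deliberately avoid
# the code paths they check.

# Central finite difference of a scalar function.
fd_central <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Random symmetric positive-definite matrix.
random_spd <- function(n, seed, jitter = 0.1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * n), n, n)
    (tcrossprod(A) / n + jitter * diag(n) + t(tcrossprod(A) / n + jitter * diag(n))) / 2
  })
}

# Estimator-variance oracle for linear Fisher information: the information is
# the inverse variance of the minimum-variance unbiased *linear* estimator,
# found from first principles as the solution of the KKT system
#   minimize w' S w  subject to  w' fp = 1.
fisher_by_estimator_variance <- function(fp, S) {
  n <- length(fp)
  K <- rbind(cbind(2 * S, -fp), c(fp, 0))
  sol <- solve(K, c(rep(0, n), 1))
  w <- sol[seq_len(n)]
  1 / drop(crossprod(w, S %*% w))
}

# Moore-Penrose pseudo-inverse quadratic form f' S^+ f via eigen-decomposition.
pinv_quadform <- function(fp, S, tol = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  coef <- drop(crossprod(e$vectors[, keep, drop = FALSE], fp))
  sum(coef^2 / e$values[keep])
}

# Bivariate-normal upper-orthant probability P(X1 >= a1, X2 >= a2) by 1-D
# adaptive quadrature over the conditional distribution.
orthant_prob <- function(mu, Sigma, a) {
  s1 <- sqrt(Sigma[1, 1])
  s2 <- sqrt(Sigma[2, 2])
  rho <- Sigma[1, 2] / (s1 * s2)
  integrand <- function(x1) {
    cond_mean <- mu[2] + rho * s2 / s1 * (x1 - mu[1])
    cond_sd <- s2 * sqrt(1 - rho^2)
    dnorm(x1, mu[1], s1) * pnorm((a[2] - cond_mean) / cond_sd, lower.tail = FALSE)
  }
  integrate(integrand, a[1], Inf, rel.tol = 1e-10)$value
}
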