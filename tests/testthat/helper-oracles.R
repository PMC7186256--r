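# Independent oracles and fixture generators used across the suite.

# Brute-force HC0 covariance: (X'X)^{-1} X' diag(e^2) X (X'X)^{-1},
# accumulated with an explicit per-observation loop.
hc0_brute_force <- function(X, e) {
  meat <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    meat <- meat + e[i]^2 * tcrossprod(xi)
  }
  bread <- solve(crossprod(X))
  bread %*% meat %*% bread
}

# Sample skewness (method-of-moments).
sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}

# Random least-squares instance with heteroskedastic errors.
random_ols_instance <- function(n = NULL, m = NULL) {
  if (is.null(n)) n <- sample(20:200, 1)
  if (is.null(m)) m <- sample(2:6, 1)
  X <- cbind(1, matrix(rnorm(n * (m - 1)), n, m - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(m - 1)))
  theta <- rnorm(m)
  y <- drop(X %*% theta) + rnorm(n) * (0.5 + abs(X[, m]))
  list(X = X, y = y,
       data = data.frame(y = y, X[, -1, drop = FALSE]))
}

ols_problem <- function(inst) {
  covs <- setdiff(names(inst$data), "y")
  estimating_problem(inst$data, outcome = "y",
                     nuisance = covs[-length(covs)],
                     target = covs[length(covs)],
                     family = "linear")
}

# Two-group dataset with exact group sizes n*pi1 and n*(1 - pi1).
two_group_data <- function(n, delta, sd1 = 1, sd0 = 1, pi1 = 0.5) {
  n1 <- round(n * pi1)
  g <- c(rep(1, n1), rep(0, n - n1))
  y <- ifelse(g == 1, delta + sd1 * rnorm(n), sd0 * rnorm(n))
  data.frame(y = y, g = g)
}
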