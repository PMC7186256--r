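test_that("solve_theta recovers closed-form solutions", {
  # intercept-only least squares is the sample mean
  d <- data.frame(y = c(0, 1, 2), one = c(1, 1, 1))
  prob <- estimating_problem(d, "y", target = "one", intercept = FALSE)
  expect_equal(unname(solve_theta(prob)), 1)

  # exactly linear outcome: interpolating line, zero residuals
  d2 <- data.frame(x = 1:10)
  d2$y <- 2 + 3 * d2$x
  prob2 <- estimating_problem(d2, "y", target = "x")
  th <- solve_theta(prob2)
  expect_equal(unname(th), c(2, 3), tolerance = 1e-10)
  expect_equal(sum((d2$y - th[1] - th[2] * d2$x)^2), 0, tolerance = 1e-16)
})

test_that("logistic Newton solver matches the IRLS oracle", {
  set.seed(42)
  n <- 200
  x <- rnorm(n)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x - 0.5 * z))
  d <- data.frame(y = y, x = x, z = z)
  prob <- estimating_problem(d, "y", nuisance = "z", target = "x",
                             family = "logistic")
  th <- solve_theta(prob)
  oracle <- coef(glm(y ~ z + x, data = d, family = binomial))
  expect_equal(unname(th), unname(oracle[c("(Intercept)", "z", "x")]),
               tolerance = 1e-6)
})

test_that("solver failures are reported, not silent", {
  d <- data.frame(y = rnorm(20), a = rnorm(20))
  d$b <- 2 * d$a  # collinear
  prob <- estimating_problem(d, "y", nuisance = "a", target = "b")
  expect_error(solve_theta(prob), "rank deficient.*b")
  expect_error(
    estimating_problem(d[1:3, ], "y", nuisance = "a", target = "b"),
    "n > m"
  )
})

test_that("bread matrix matches closed forms and finite differences", {
  set.seed(7)
  inst <- random_ols_instance(n = 60, m = 4)
  prob <- ols_problem(inst)
  theta <- solve_theta(prob)
  J <- estimate_J(prob, theta)
  expect_equal(J, crossprod(prob$X) / prob$n, ignore_attr = TRUE,
               tolerance = 1e-12)

  # numeric fallback (family stripped of its Hessian) agrees with analytic
  fam_fd <- resi_family("linear-fd",
                        score = prob$family$score,
                        objective = prob$family$objective)
  prob_fd <- prob
  prob_fd$family <- fam_fd
  expect_equal(estimate_J(prob_fd, theta), unname(J), ignore_attr = TRUE,
               tolerance = 1e-6)

  # intercept-only least squares: J = 1
  d <- data.frame(y = rnorm(10), one = rep(1, 10))
  p1 <- estimating_problem(d, "y", target = "one", intercept = FALSE)
  expect_equal(estimate_J(p1, solve_theta(p1)), matrix(1, 1, 1),
               ignore_attr = TRUE)

  # two-means score has unit bread
  d2 <- two_group_data(40, delta = 1)
  p2 <- estimating_problem(d2, "y", target = "g", family = "two-means",
                           pi1 = 0.5)
  expect_equal(estimate_J(p2, solve_theta(p2)), matrix(1, 1, 1),
               ignore_attr = TRUE)
})

test_that("meat matrix is the empirical score outer product", {
  set.seed(8)
  inst <- random_ols_instance(n = 50, m = 3)
  prob <- ols_problem(inst)
  theta <- solve_theta(prob)
  e <- inst$y - drop(prob$X %*% theta)
  # brute-force loop oracle for the HC0 meat
  meat <- matrix(0, prob$m, prob$m)
  for (i in seq_len(prob$n)) {
    meat <- meat + e[i]^2 * tcrossprod(prob$X[i, ])
  }
  expect_equal(estimate_K(prob, theta), meat / prob$n, ignore_attr = TRUE,
               tolerance = 1e-12)

  # exact fit: zero meat
  d <- data.frame(x = 1:8)
  d$y <- 1 + 2 * d$x
  pe <- estimating_problem(d, "y", target = "x")
  expect_equal(estimate_K(pe, solve_theta(pe)), matrix(0, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-18)
})

test_that("information equality holds in the homoskedastic Gaussian limit", {
  set.seed(9)
  n <- 1e4
  x <- rnorm(n)
  sigma <- 0.7
  d <- data.frame(y = 1 + 0.5 * x + sigma * rnorm(n), x = x)
  prob <- estimating_problem(d, "y", target = "x")
  theta <- solve_theta(prob)
  J <- estimate_J(prob, theta)
  K <- estimate_K(prob, theta)
  # entries of K - sigma^2 J are mean-zero averages with O(1/sqrt(n)) noise
  expect_lt(max(abs(K - sigma^2 * J)), 10 / sqrt(n))
})

test_that("sandwich covariance reproduces HC0 and the two-group closed form", {
  set.seed(10)
  for (rep in 1:10) {
    inst <- random_ols_instance()
    prob <- ols_problem(inst)
    sw <- sandwich_covariance(prob)
    e <- inst$y - drop(prob$X %*% sw$theta_hat)
    oracle <- hc0_brute_force(prob$X, e)
    expect_equal(sw$Sigma_hat / prob$n, oracle, ignore_attr = TRUE,
                 tolerance = 1e-8)
  }

  # exact fit: zero covariance
  d <- data.frame(x = 1:8)
  d$y <- 1 + 2 * d$x
  pe <- estimating_problem(d, "y", target = "x")
  expect_equal(sandwich_covariance(pe)$Sigma_hat, matrix(0, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # heteroskedastic two-group Example-1 score: scalar pi1^-1 s1^2 + pi0^-1 s0^2
  set.seed(11)
  d2 <- two_group_data(2e4, delta = 1, sd1 = sqrt(3), sd0 = 1, pi1 = 0.5)
  p2 <- estimating_problem(d2, "y", target = "g", family = "two-means",
                           pi1 = 0.5)
  sw2 <- sandwich_covariance(p2)
  expect_equal(drop(sw2$Sigma_hat), 3 / 0.5 + 1 / 0.5, tolerance = 0.1)
})

test_that("sandwich agrees with the sandwich package HC0 estimator", {
  skip_if_not_installed("sandwich")
  set.seed(12)
  inst <- random_ols_instance(n = 150, m = 4)
  prob <- ols_problem(inst)
  sw <- sandwich_covariance(prob)
  fit <- lm(y ~ ., data = inst$data)
  oracle <- sandwich::vcovHC(fit, type = "HC0")
  expect_equal(sw$Sigma_hat / prob$n, oracle,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("Wald statistic has the defining algebra", {
  mk <- function(theta, Sigma_beta, n, m0, m1, beta0 = rep(0, m1)) {
    structure(list(theta_hat = theta, Sigma_beta = Sigma_beta, n = n,
                   m = m0 + m1, m0 = m0, m1 = m1, beta0 = beta0,
                   family = "linear"),
              class = "sandwich_estimate")
  }
  # beta_hat = beta0 -> 0
  expect_equal(wald_statistic(mk(c(1, 0.3), matrix(2), 50, 1, 1,
                                 beta0 = 0.3)), 0)
  # identity covariance, unit displacement, n = 100 -> 100
  expect_equal(wald_statistic(mk(c(0, 1, 0), diag(2), 100, 1, 2)), 100)
  # scalar: n (b/sigma)^2 * sigma^2... 25 * 4 / 4 = 25
  expect_equal(wald_statistic(mk(c(0, 2), matrix(4), 25, 1, 1)), 25)
  # permutation of target coordinates leaves T^2 unchanged
  Sb <- matrix(c(2, 0.5, 0.5, 1), 2)
  b <- c(0.4, -0.2)
  t2a <- wald_statistic(mk(c(0, b), Sb, 80, 1, 2))
  t2b <- wald_statistic(mk(c(0, rev(b)), Sb[2:1, 2:1], 80, 1, 2))
  expect_equal(t2a, t2b, tolerance = 1e-12)
  # singular covariance fails loudly
  expect_error(wald_statistic(mk(c(0, 1, 1), matrix(1, 2, 2), 10, 1, 2)),
               "positive definite")
})

test_that("affine equivariance: covariate rescaling inverts the coefficient, T^2 invariant", {
  set.seed(13)
  inst <- random_ols_instance(n = 80, m = 3)
  prob <- ols_problem(inst)
  fit1 <- estimate_from_data(prob)
  c_ <- 3.7
  d2 <- inst$data
  tgt <- setdiff(names(d2), "y")[length(setdiff(names(d2), "y"))]
  d2[[tgt]] <- d2[[tgt]] * c_
  covs <- setdiff(names(d2), "y")
  prob2 <- estimating_problem(d2, "y", nuisance = covs[-length(covs)],
                              target = tgt)
  fit2 <- estimate_from_data(prob2)
  expect_equal(unname(fit2$beta_hat), unname(fit1$beta_hat) / c_,
               tolerance = 1e-8)
  expect_equal(fit2$T2, fit1$T2, tolerance = 1e-8)
})

test_that("score matches the numerical objective gradient for built-in families", {
  set.seed(14)
  d <- data.frame(y = rnorm(40), x = rnorm(40), z = rnorm(40))
  expect_true(check_score_consistency(
    estimating_problem(d, "y", nuisance = "z", target = "x")))
  db <- data.frame(y = rbinom(60, 1, 0.5), x = rnorm(60))
  expect_true(check_score_consistency(
    estimating_problem(db, "y", target = "x", family = "logistic")))
})
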