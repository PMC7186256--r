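#' Robust effect size index (population form)
#'
#' The index is the standardized, unitless distance of the target parameter
#' from its reference value, \eqn{S = \sqrt{(\beta - \beta_0)'
#' \Sigma_\beta^{-1} (\beta - \beta_0)}}, where \eqn{\Sigma_\beta} is the
#' asymptotic (sandwich) covariance of \eqn{\sqrt{n}\,\hat\beta}. It is zero
#' iff \eqn{\beta = \beta_0} and is the square root of the per-observation
#' noncentrality of the robust Wald statistic.
#'
#' @param beta Target parameter vector.
#' @param beta0 Reference value (same length); defaults to zero.
#' @param Sigma_beta Positive-definite covariance of the target block.
#' @return The nonnegative index.
#' @examples
#' resi_parameter(c(2, 1), c(0, 0), diag(c(4, 1)))  # sqrt(2)
#' @export
resi_parameter <- function(beta, beta0 = rep(0, length(beta)), Sigma_beta) {
  stopifnot(length(beta) == length(beta0), all(is.finite(beta)),
            all(is.finite(beta0)))
  sqrt(quad_form_inv(Sigma_beta, beta - beta0, label = "Sigma_beta"))
}

#' Truncated index estimator
#'
#' Converts the robust Wald statistic into the index estimate
#' \eqn{\hat S = \sqrt{\max\{0, (T^2 - m)/(n - m)\}}}. Subtracting the total
#' number of estimated parameters m recenters the chi-squared statistic, and
#' the (n - m) divisor accounts for their estimation; truncation at zero
#' keeps the estimate in the parameter space (the index is nonnegative),
#' which induces a small positive bias near the null.
#'
#' @param T2 Nonnegative Wald chi-squared statistic.
#' @param n Sample size (must exceed `m`).
#' @param m Total number of estimated parameters.
#' @param m1 Optional target-block dimension (degrees of freedom of `T2`),
#'   recorded for reporting.
#' @return An object of class `"resi_estimate"` with elements `S`, `T2`,
#'   `n`, `m`, `m1`, `truncated`.
#' @examples
#' resi_estimate(T2 = 100, n = 100, m = 5)  # S = 1
#' @export
resi_estimate <- function(T2, n, m, m1 = NULL) {
  stopifnot(is.numeric(T2), length(T2) == 1L, is.finite(T2), T2 >= 0,
            m >= 1)
  if (n <= m) {
    stop(sprintf("need n > m to estimate the index: n = %d, m = %d", n, m),
         call. = FALSE)
  }
  structure(
    list(S = sqrt(max(0, (T2 - m) / (n - m))), T2 = T2,
         n = as.integer(n), m = as.integer(m),
         m1 = if (is.null(m1)) NULL else as.integer(m1),
         truncated = T2 < m),
    class = "resi_estimate"
  )
}

#' @export
print.resi_estimate <- function(x, ...) {
  cat(sprintf("Robust effect size index: S_hat = %.4f (%s)\n",
              x$S, as.character(classify_effect_size(x$S))))
  cat(sprintf("  T2 = %.4f on %s df, n = %d, m = %d%s\n",
              x$T2, if (is.null(x$m1)) "?" else x$m1, x$n, x$m,
              if (isTRUE(x$truncated)) " [truncated at 0]" else ""))
  invisible(x)
}

#' Estimate the robust effect size index from data
#'
#' Full pipeline: solve the estimating equation, form the sandwich
#' covariance, compute the robust Wald statistic against the problem's
#' reference value, and convert it to the truncated index estimate. All
#' intermediates are retained on the returned object.
#'
#' @param problem An [estimating_problem()].
#' @return An object of class `c("resi_fit", "resi_estimate")`: the
#'   [resi_estimate()] fields plus `beta_hat` and the full
#'   `"sandwich_estimate"` under `$sandwich`.
#' @examples
#' set.seed(1)
#' d <- data.frame(g = rbinom(200, 1, 0.5))
#' d$y <- 0.5 * d$g + rnorm(200)
#' fit <- estimate_from_data(
#'   estimating_problem(d, outcome = "y", target = "g")
#' )
#' fit$S
#' @export
estimate_from_data <- function(problem) {
  stopifnot(inherits(problem, "estimating_problem"))
  theta <- solve_theta(problem)
  sw <- sandwich_covariance(problem, theta)
  T2 <- wald_statistic(sw)
  est <- resi_estimate(T2, n = problem$n, m = problem$m, m1 = problem$m1)
  est$beta_hat <- theta[seq.int(problem$m0 + 1L, problem$m)]
  est$sandwich <- sw
  class(est) <- c("resi_fit", "resi_estimate")
  est
}

#' Two-group mean-difference index (closed form)
#'
#' Population index for a difference in means with possibly unequal group
#' variances and unequal sampling proportions:
#' \deqn{S = \sqrt{(\mu_1-\mu_0)^2 / (\pi_1^{-1}\sigma_1^2 +
#' \pi_0^{-1}\sigma_0^2)}.}
#' With equal variances and \eqn{\pi_1 = 1/2} this is proportional to
#' Cohen's d; unlike d it also reflects variance heterogeneity and the
#' design's group balance, i.e. everything that drives the power of the
#' two-group test.
#'
#' @param mu1,mu0 Group means.
#' @param sigma1_sq,sigma0_sq Positive group variances.
#' @param pi1 Group-1 population proportion in (0, 1).
#' @return The nonnegative index.
#' @examples
#' two_sample_s(1, 0, 1, 1, 0.5)  # 0.5
#' @export
two_sample_s <- function(mu1, mu0, sigma1_sq, sigma0_sq, pi1) {
  stop_if_not_scalar_prob(pi1, "pi1")
  stopifnot(sigma1_sq > 0, sigma0_sq > 0, is.finite(mu1), is.finite(mu0))
  sqrt((mu1 - mu0)^2 / (sigma1_sq / pi1 + sigma0_sq / (1 - pi1)))
}

#' Simple-linear-regression index (closed form)
#'
#' Population index for the slope of a simple linear regression with
#' possibly covariate-dependent residual variance:
#' \eqn{S = |\beta| \sqrt{\sigma_x^4 / \sigma_{xy}^2}}, where
#' \eqn{\sigma_{xy}^2 = E[(X-\mu_x)^2 (Y - \alpha - X\beta)^2]} couples the
#' covariate to the conditional variance. Under homoskedasticity
#' \eqn{\sigma_{xy}^2 = \sigma_x^2 \sigma^2} and the index reduces to
#' \eqn{|\beta| \sigma_x / \sigma}.
#'
#' @param beta Slope, or a moments list as returned by [linreg_moments()]
#'   (in which case the other arguments are taken from it).
#' @param sigma_x_sq Covariate variance.
#' @param sigma_xy_sq Covariate-weighted residual second moment
#'   \eqn{\sigma_{xy}^2}; when `NULL`, computed as
#'   `sigma_x_sq * sigma_sq` (homoskedastic case).
#' @param sigma_sq Residual variance, used only when `sigma_xy_sq` is `NULL`.
#' @return The nonnegative index.
#' @examples
#' linreg_s(0.3, sigma_x_sq = 1, sigma_sq = 1)       # 0.3
#' linreg_s(0.5, sigma_x_sq = 1, sigma_xy_sq = 4)    # 0.25
#' @export
linreg_s <- function(beta, sigma_x_sq, sigma_xy_sq = NULL, sigma_sq = NULL) {
  if (is.list(beta)) {
    m <- beta
    return(linreg_s(m$beta, m$sigma_x_sq, m$sigma_xy_sq))
  }
  stopifnot(is.finite(beta), sigma_x_sq > 0)
  if (is.null(sigma_xy_sq)) {
    if (is.null(sigma_sq)) {
      stop("supply either `sigma_xy_sq` or `sigma_sq`", call. = FALSE)
    }
    stopifnot(sigma_sq > 0)
    sigma_xy_sq <- sigma_x_sq * sigma_sq
  }
  stopifnot(sigma_xy_sq > 0)
  sqrt(sigma_x_sq^2 / sigma_xy_sq) * abs(beta)
}

#' Empirical moments for the simple-linear-regression index
#'
#' Plug-in moments from a sample, using divide-by-n averages throughout (the
#' same averaging convention as the empirical bread/meat matrices): the OLS
#' line, the residual variance \eqn{\sigma^2}, and the covariate-weighted
#' residual moments \eqn{\mu_{xy}} and \eqn{\sigma_{xy}^2}.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A list with `mu_x`, `sigma_x_sq`, `sigma_sq`, `mu_xy`,
#'   `sigma_xy_sq`, `alpha`, `beta`, suitable for [linreg_s()].
#' @export
linreg_moments <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  mu_x <- mean(x)
  sigma_x_sq <- mean((x - mu_x)^2)
  if (sigma_x_sq <= 0) stop("covariate has zero variance", call. = FALSE)
  beta <- mean((x - mu_x) * (y - mean(y))) / sigma_x_sq
  alpha <- mean(y) - beta * mu_x
  r <- y - alpha - beta * x
  list(mu_x = mu_x, sigma_x_sq = sigma_x_sq, sigma_sq = mean(r^2),
       mu_xy = mean(x * r^2), sigma_xy_sq = mean((x - mu_x)^2 * r^2),
       alpha = alpha, beta = beta)
}

#' Logistic-regression design summary
#'
#' Assembles the weighted cross-product blocks
#' \eqn{A_{k\ell}(W) = n^{-1} X_k' W X_\ell} for the logistic model, under
#' the model-implied weights \eqn{P_{ii} = p_i(1-p_i)} and (optionally) the
#' empirical weights \eqn{Q_{ii} = (y_i - p_i)^2}; the model-based
#' information block of the target parameter,
#' \eqn{I_\beta = A_{11}(P) - A_{10}(P) A_{00}(P)^{-1} A_{01}(P)}; and the
#' robust target covariance \eqn{\Sigma_\beta} assembled from the block
#' formula for the target block of \eqn{J^{-1} K J^{-1}}. When the model is
#' correctly specified the P and Q weights coincide in expectation and
#' \eqn{\Sigma_\beta = I_\beta^{-1}}; a discrepancy indicates under- or
#' over-dispersion.
#'
#' @param X0 Nuisance design matrix (n-by-m0, including any intercept
#'   column).
#' @param X1 Target design matrix (n-by-m1).
#' @param theta Full coefficient vector, nuisance coordinates first.
#' @param y Optional 0/1 outcome vector; when supplied, the empirical Q
#'   weights and the robust `Sigma_beta` are computed from it.
#' @param q Optional explicit per-observation Q weights (overrides `y`);
#'   mainly for checking the block algebra.
#' @return An object of class `"logistic_design_summary"`: the `A` blocks,
#'   `I_beta`, and `Sigma_beta` (equal to `solve(I_beta)` when no Q weights
#'   are available).
#' @seealso [logistic_s()]
#' @export
logistic_design_summary <- function(X0, X1, theta, y = NULL, q = NULL) {
  X0 <- as.matrix(X0)
  X1 <- as.matrix(X1)
  stopifnot(nrow(X0) == nrow(X1), length(theta) == ncol(X0) + ncol(X1))
  n <- nrow(X0)
  p <- plogis(drop(cbind(X0, X1) %*% theta))
  wP <- p * (1 - p)
  A <- function(w, Xa, Xb) crossprod(Xa, w * Xb) / n
  A00P <- A(wP, X0, X0)
  A01P <- A(wP, X0, X1)
  A10P <- t(A01P)
  A11P <- A(wP, X1, X1)
  if (kappa(A00P) > 1e12) {
    stop("A00(P) is computationally singular", call. = FALSE)
  }
  C <- solve(A00P, A01P)                       # A00(P)^{-1} A01(P)
  I_beta <- symmetrize(A11P - A10P %*% C)

  wQ <- q
  if (is.null(wQ) && !is.null(y)) wQ <- (y - p)^2
  if (is.null(wQ)) {
    Sigma_beta <- solve(I_beta)
  } else {
    A00Q <- A(wQ, X0, X0)
    A01Q <- A(wQ, X0, X1)
    A10Q <- t(A01Q)
    A11Q <- A(wQ, X1, X1)
    IbInv <- solve(I_beta)
    M <- (t(C) %*% A00Q %*% C - t(C) %*% A01Q) + (A11Q - A10Q %*% C)
    Sigma_beta <- symmetrize(IbInv %*% M %*% IbInv)
  }
  structure(
    list(A00P = A00P, A01P = A01P, A11P = A11P, I_beta = I_beta,
         Sigma_beta = symmetrize(Sigma_beta), n = n,
         empirical_weights = !is.null(wQ)),
    class = "logistic_design_summary"
  )
}

#' Logistic-regression index (closed form)
#'
#' The index \eqn{S = \sqrt{\beta' \Sigma_\beta^{-1} \beta}} for a logistic
#' target block, with \eqn{\Sigma_\beta} from a
#' [logistic_design_summary()]. Under correct specification this reduces to
#' \eqn{\sqrt{\beta' I_\beta \beta}}, the effect of the target variables
#' after accounting for their collinearity with the nuisance block: high
#' collinearity inflates \eqn{I_\beta^{-1}} and shrinks the index.
#'
#' @param summary A [logistic_design_summary()].
#' @param beta Target coefficient vector (length m1).
#' @param beta0 Reference value; defaults to zero.
#' @return The nonnegative index.
#' @export
logistic_s <- function(summary, beta, beta0 = rep(0, length(beta))) {
  stopifnot(inherits(summary, "logistic_design_summary"))
  resi_parameter(beta, beta0, summary$Sigma_beta)
}
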