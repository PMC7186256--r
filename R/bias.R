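#' @name bias-diagnostics
#' @title Asymptotic bias of classical effect sizes under heteroskedasticity
#'
#' @description
#' Classical effect size estimators assume a common variance. When the
#' variance differs across groups (or depends on the covariate), they
#' converge to values that differ from the robust-index-based versions.
#' These functions compute the asymptotic ratio of the classical limit to
#' the robust value; a ratio above 1 means the classical estimator
#' overstates the effect, below 1 that it understates it.
#'
#' For the pooled-SD Cohen's d with group-1 proportion `pi1` and group
#' variances \eqn{\sigma_1^2, \sigma_0^2}:
#' \deqn{d_C/d(S) = (\pi_1^{-1} + \pi_0^{-1})^{-1/2}
#'  \left(\frac{\pi_1^{-1}\sigma_1^2 + \pi_0^{-1}\sigma_0^2}
#'             {\pi_1\sigma_1^2 + \pi_0\sigma_0^2}\right)^{1/2}.}
#' The ratio is 1 when `pi1 = 1/2` or the variances are equal; d
#' overestimates when `pi1 < 1/2` and \eqn{\sigma_1^2 > \sigma_0^2}, and
#' underestimates when `pi1 < 1/2` and \eqn{\sigma_1^2 < \sigma_0^2}. In
#' (log2 variance ratio, pi1) coordinates the surface is symmetric about
#' (0, 1/2).
#'
#' For simple linear regression:
#' \deqn{R^2_C/R^2(S) = \frac{\sigma_x^4\beta^2 + \sigma_x^2\sigma_y^2}
#'  {\sigma_x^4\beta^2 + \sigma_{xy}^2},}
#' equal to 1 under homoskedasticity (\eqn{\sigma_{xy}^2 =
#' \sigma_x^2\sigma_y^2}) and strictly decreasing in \eqn{\sigma_{xy}^2}.
#'
#' @param pi1 Group-1 proportion in (0, 1).
#' @param sigma1_sq,sigma0_sq Positive group variances.
#' @param beta Regression slope.
#' @param sigma_x_sq,sigma_y_sq Positive covariate and conditional-variance
#'   moments.
#' @param sigma_xy_sq Positive covariate-weighted residual moment
#'   \eqn{\sigma_{xy}^2}.
NULL

#' @rdname bias-diagnostics
#' @return `cohens_d_bias_ratio()`: the positive ratio of the classical
#'   pooled-SD Cohen's d limit to the robust d.
#' @examples
#' cohens_d_bias_ratio(0.5, 2, 1)    # 1: balanced design, no bias
#' cohens_d_bias_ratio(0.25, 2, 1)   # ~1.18: d overstates the effect
#' @export
cohens_d_bias_ratio <- function(pi1, sigma1_sq, sigma0_sq) {
  stop_if_not_scalar_prob(pi1, "pi1")
  stopifnot(all(sigma1_sq > 0), all(sigma0_sq > 0))
  pi0 <- 1 - pi1
  sqrt((sigma1_sq / pi1 + sigma0_sq / pi0) /
         (pi1 * sigma1_sq + pi0 * sigma0_sq)) / sqrt(1 / pi1 + 1 / pi0)
}

#' @rdname bias-diagnostics
#' @return `r2_bias_ratio()`: the positive ratio of the classical R-squared
#'   limit to the robust R-squared.
#' @examples
#' r2_bias_ratio(beta = 0, sigma_x_sq = 1, sigma_y_sq = 1, sigma_xy_sq = 2)
#' @export
r2_bias_ratio <- function(beta, sigma_x_sq, sigma_y_sq, sigma_xy_sq) {
  stopifnot(all(is.finite(beta)), all(sigma_x_sq > 0), all(sigma_y_sq > 0),
            all(sigma_xy_sq > 0))
  (sigma_x_sq^2 * beta^2 + sigma_x_sq * sigma_y_sq) /
    (sigma_x_sq^2 * beta^2 + sigma_xy_sq)
}

#' Percent-bias surface for classical effect sizes
#'
#' Tabulates `100 * (ratio - 1)` over a grid. For `index = "d"` the grid is
#' (log2 variance ratio, pi1), with `sigma0_sq` fixed at 1 and `sigma1_sq =
#' 2^log2_ratio`; for `index = "r2"` it is the log2 ratio of
#' \eqn{\sigma_{xy}^2} to \eqn{\sigma_x^2 \sigma_y^2} (heteroskedasticity on
#' the log scale), with unit \eqn{\sigma_x^2, \sigma_y^2} and the supplied
#' slope.
#'
#' @param index `"d"` or `"r2"`.
#' @param log2_ratio Grid of log2 variance (or variance-moment) ratios.
#' @param pi1 Grid of group-1 proportions (index `"d"` only).
#' @param beta Slope (index `"r2"` only).
#' @return A data frame with the grid coordinates, the `ratio`, and
#'   `percent_bias`.
#' @examples
#' head(bias_surface("d", log2_ratio = -2:2, pi1 = c(0.25, 0.5)))
#' @export
bias_surface <- function(index = c("d", "r2"),
                         log2_ratio = seq(-3, 3, by = 0.25),
                         pi1 = seq(0.1, 0.9, by = 0.1),
                         beta = 0.5) {
  index <- match.arg(index)
  if (index == "d") {
    grid <- expand.grid(log2_ratio = log2_ratio, pi1 = pi1,
                        KEEP.OUT.ATTRS = FALSE)
    grid$ratio <- mapply(function(x, p) cohens_d_bias_ratio(p, 2^x, 1),
                         grid$log2_ratio, grid$pi1)
  } else {
    grid <- data.frame(log2_ratio = log2_ratio)
    grid$ratio <- vapply(log2_ratio, function(x) {
      r2_bias_ratio(beta, sigma_x_sq = 1, sigma_y_sq = 1, sigma_xy_sq = 2^x)
    }, numeric(1))
  }
  grid$percent_bias <- 100 * (grid$ratio - 1)
  grid
}
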