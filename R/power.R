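#' @name resi-power
#' @title Model-free power and sample size from the robust index
#'
#' @description
#' The robust Wald statistic is asymptotically noncentral chi-squared on
#' `df` degrees of freedom (the dimension of the target parameter) with
#' noncentrality \eqn{\lambda = n S^2}, so power for a level-`t1` test is
#' \deqn{1 - t_2 = 1 - \Phi_{df}\{\Phi_{df}^{-1}(1 - t_1; 0);\; n S^2\},}
#' where \eqn{\Phi(\cdot;\lambda)} is the noncentral chi-squared CDF. The
#' formula involves no model-specific quantity: one curve serves every model
#' whose target parameter solves an estimating equation. Any one of power,
#' sample size, or effect size is solvable from the others; the equation is
#' monotone in the noncentrality, which is found by bracketed root search
#' (tolerance 1e-10) and then mapped back to `n` or `s`. Sample size is
#' treated as continuous (asymptotic formula); use `ceiling = TRUE` for a
#' whole-number design size. No finite-sample correction is applied to the
#' noncentrality.
#'
#' @param t1 Type-I error rate in (0, 1).
#' @param df Positive integer degrees of freedom (target dimension m1).
#' @param s Robust index value, nonnegative.
#' @param n Sample size (>= 1, treated as continuous).
#' @param power Target power in `(t1, 1)` (in `[t1, 1)` for
#'   [s_from_power()]).
NULL

check_power_args <- function(t1, df) {
  stop_if_not_scalar_prob(t1, "t1")
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != round(df)) {
    stop("`df` must be a positive integer", call. = FALSE)
  }
  invisible(NULL)
}

power_from_ncp <- function(t1, df, lambda) {
  q <- qchisq(1 - t1, df)
  out <- 1 - pchisq(q, df, ncp = lambda)
  out[lambda == 0] <- t1  # central case: exactly the test level
  out
}

# Solve pchisq(q, df, ncp = lambda) = 1 - power for lambda by bracketed
# root search; monotone increasing in lambda.
solve_ncp <- function(t1, df, power) {
  if (power <= t1) return(0)
  f <- function(l) power_from_ncp(t1, df, l) - power
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e12) stop("requested power is not attainable", call. = FALSE)
  }
  uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' @rdname resi-power
#' @return `power_from_s()`: the power, in (0, 1); exactly `t1` when
#'   `s = 0`. Vectorized over `s` and `n`.
#' @examples
#' power_from_s(0.05, df = 1, s = 0.25, n = 128)
#' n_from_power(0.05, df = 1, s = 0.25, power = 0.8)
#' s_from_power(0.05, df = 1, n = 100, power = 0.8)
#' @export
power_from_s <- function(t1, df, s, n) {
  check_power_args(t1, df)
  check_nonneg(s, "s")
  if (any(n < 1)) stop("`n` must be at least 1", call. = FALSE)
  power_from_ncp(t1, df, n * s^2)
}

#' @rdname resi-power
#' @param ceiling Round the returned sample size up to a whole number?
#' @return `n_from_power()`: the smallest (continuous) sample size reaching
#'   the requested power; 1 when the power is already met at `n = 1`.
#' @export
n_from_power <- function(t1, df, s, power, ceiling = FALSE) {
  check_power_args(t1, df)
  stopifnot(length(s) == 1L, length(power) == 1L)
  if (power >= 1) stop("`power` must be below 1", call. = FALSE)
  if (s <= 0) {
    if (power > t1) {
      stop("power above t1 is unreachable when s = 0", call. = FALSE)
    }
    return(1)
  }
  check_nonneg(s, "s")
  lambda <- solve_ncp(t1, df, power)
  n <- max(1, lambda / s^2)
  if (ceiling) ceiling(n) else n
}

#' @rdname resi-power
#' @return `s_from_power()`: the index value solving the power equation;
#'   0 when `power == t1`.
#' @export
s_from_power <- function(t1, df, n, power) {
  check_power_args(t1, df)
  stopifnot(length(n) == 1L, n >= 1, length(power) == 1L)
  if (power < t1) {
    stop("`power` below the test level t1 is not attainable", call. = FALSE)
  }
  if (power >= 1) stop("`power` must be below 1", call. = FALSE)
  if (power == t1) return(0)
  sqrt(solve_ncp(t1, df, power) / n)
}

#' @rdname resi-power
#' @param n_grid Vector of sample sizes to tabulate.
#' @return `power_curve()`: a data frame with columns `n` and `power`,
#'   nondecreasing in `n`.
#' @export
power_curve <- function(t1, df, s, n_grid) {
  check_power_args(t1, df)
  stopifnot(length(s) == 1L, length(n_grid) >= 1L, all(n_grid >= 1))
  data.frame(n = n_grid, power = power_from_s(t1, df, s, n_grid))
}
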