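#' @name conversions
#' @title Conversions between the robust index and classical effect sizes
#'
#' @description
#' Conversion formulas linking the robust index S to Cohen's d (two-group
#' mean difference), Cohen's f-squared (multiple regression), and the
#' partial coefficient of determination R-squared. Under homoskedasticity
#' and correct model specification the index induces exactly the classical
#' conversion formulas, so any classical value can be rewritten as a
#' function of S and vice versa. All d/S conversions return magnitudes; the
#' caller carries the sign.
#'
#' Group proportions enter only the d conversions: `pi1` is the population
#' proportion of group 1 (`pi0 = 1 - pi1`). For the R-squared conversions
#' the unsubscripted full-model value (the R-squared or f-squared of the
#' model including all covariates) enters the denominator; the one-argument
#' convenience forms set the full-model value equal to the partial one (a
#' single target, no other covariates).
#'
#' @param d Cohen's d (sign ignored).
#' @param s Robust index value, nonnegative.
#' @param f2_beta Partial f-squared for the target, nonnegative.
#' @param f2_full Full-model f-squared; defaults to `f2_beta`.
#' @param r2_partial Partial R-squared for the target, in `[0, 1)`.
#' @param r2_full Full-model R-squared, in `[0, 1)`; defaults to
#'   `r2_partial`.
#' @param pi1 Group-1 population proportion in (0, 1); default 1/2.
#' @return The converted value (numeric, vectorized over the first
#'   argument).
#' @examples
#' s_from_d(0.2)                  # 0.1
#' d_from_s(0.25)                 # 0.5
#' f2_from_s(0.3)                 # 0.09
#' r2_from_s(0.5)                 # 0.2
#' s_from_r2(0.2)                 # 0.5
#' classify_effect_size(c(0.1, 0.3, 0.5))
NULL

pi_weight <- function(pi1) {
  stop_if_not_scalar_prob(pi1, "pi1")
  1 / pi1 + 1 / (1 - pi1)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and nonnegative", name), call. = FALSE)
  }
  invisible(x)
}

check_r2 <- function(r2_partial, r2_full) {
  if (any(r2_full >= 1)) {
    stop("full-model R-squared must be below 1", call. = FALSE)
  }
  if (any(r2_partial < 0) || any(r2_partial > r2_full)) {
    stop("need 0 <= r2_partial <= r2_full < 1", call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname conversions
#' @export
s_from_d <- function(d, pi1 = 0.5) {
  abs(d) / sqrt(pi_weight(pi1))
}

#' @rdname conversions
#' @export
d_from_s <- function(s, pi1 = 0.5) {
  check_nonneg(s, "s")
  sqrt(pi_weight(pi1)) * s
}

#' @rdname conversions
#' @export
f2_from_s <- function(s) {
  check_nonneg(s, "s")
  s^2
}

#' @rdname conversions
#' @export
s_from_f2 <- function(f2_beta) {
  check_nonneg(f2_beta, "f2_beta")
  sqrt(f2_beta)
}

#' @rdname conversions
#' @export
r2_from_s <- function(s) {
  check_nonneg(s, "s")
  s^2 / (1 + s^2)
}

#' @rdname conversions
#' @export
s_from_r2 <- function(r2_partial, r2_full = r2_partial) {
  check_r2(r2_partial, r2_full)
  sqrt(r2_partial / (1 - r2_full))
}

#' @rdname conversions
#' @export
f2_from_d <- function(d, pi1 = 0.5) {
  d^2 / pi_weight(pi1)
}

#' @rdname conversions
#' @export
d_from_f2 <- function(f2_beta, pi1 = 0.5) {
  check_nonneg(f2_beta, "f2_beta")
  sqrt(pi_weight(pi1)) * sqrt(f2_beta)
}

#' @rdname conversions
#' @export
r2_from_d <- function(d, pi1 = 0.5) {
  d^2 / (pi_weight(pi1) + d^2)
}

#' @rdname conversions
#' @export
d_from_r2 <- function(r2_partial, r2_full = r2_partial, pi1 = 0.5) {
  check_r2(r2_partial, r2_full)
  sqrt(pi_weight(pi1)) * sqrt(r2_partial / (1 - r2_full))
}

#' @rdname conversions
#' @export
r2_from_f2 <- function(f2_beta, f2_full = f2_beta) {
  check_nonneg(f2_beta, "f2_beta")
  check_nonneg(f2_full, "f2_full")
  f2_beta / (1 + f2_full)
}

#' @rdname conversions
#' @export
f2_from_r2 <- function(r2_partial, r2_full = r2_partial) {
  check_r2(r2_partial, r2_full)
  r2_partial / (1 - r2_full)
}

#' Qualitative effect size band on the S scale
#'
#' Classifies an index value into the conventional qualitative bands, mapped
#' from Cohen's d thresholds assuming equal group proportions: none-small
#' `[0, 0.1]`, small-medium `(0.1, 0.25]`, medium-large `(0.25, 0.4]`, and
#' large above 0.4. Interval endpoints are closed on the right. The top band
#' is open-ended: the tabulated thresholds stop at 0.4, so "large" is an
#' extrapolation beyond the published range.
#'
#' @param s Nonnegative index value(s).
#' @return An ordered factor with levels `none-small < small-medium <
#'   medium-large < large`.
#' @examples
#' classify_effect_size(c(0.1, 0.25, 0.4, 0.41))
#' @export
classify_effect_size <- function(s) {
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("`s` must be finite and nonnegative", call. = FALSE)
  }
  cut(s, breaks = c(-Inf, 0.1, 0.25, 0.4, Inf),
      labels = c("none-small", "small-medium", "medium-large", "large"),
      right = TRUE, ordered_result = TRUE)
}

#' Convert between effect size indices
#'
#' Dispatcher over the pairwise conversion functions: converts `value` from
#' one index (`"d"`, `"f2"`, `"r2"`, `"S"`) to another, routing through the
#' robust index. `pi1` is needed whenever `d` is involved; `full` (the
#' full-model R-squared or f-squared) whenever converting from `r2` (and for
#' `f2` to `r2`).
#'
#' @param value Numeric value of the source index.
#' @param from,to Index names, one of `"d"`, `"f2"`, `"r2"`, `"S"`.
#' @param pi1 Group-1 proportion for d conversions.
#' @param full Optional full-model value for `r2`/`f2` sources; defaults to
#'   `value` (no other covariates).
#' @return The converted value.
#' @examples
#' convert_effect_size(0.5, "d", "r2")  # 0.0588...
#' @export
convert_effect_size <- function(value, from = c("d", "f2", "r2", "S"),
                                to = c("d", "f2", "r2", "S"),
                                pi1 = 0.5, full = NULL) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (is.null(full)) full <- value
  s <- switch(from,
    d = s_from_d(value, pi1),
    f2 = s_from_f2(value),
    r2 = s_from_r2(value, full),
    S = check_nonneg(value, "value")
  )
  switch(to,
    d = d_from_s(s, pi1),
    f2 = f2_from_s(s),
    r2 = if (from == "f2") r2_from_f2(value, full) else r2_from_s(s),
    S = s
  )
}
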