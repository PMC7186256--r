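#' Estimating-equation families
#'
#' An estimating-equation family packages, for one model class, the
#' per-observation objective (a loss to be minimized), its gradient (the
#' score), and optionally an analytic Hessian and a direct solver. The
#' M-estimator is the root of the averaged score; the empirical bread and
#' meat matrices are formed from the Hessian and the score outer products.
#'
#' Built-in families:
#' * `"linear"` — least squares, loss \eqn{(y_i - x_i'\theta)^2/2}.
#' * `"logistic"` — Bernoulli negative log-likelihood with logit link.
#' * `"two-means"` — the single-parameter difference-in-means score
#'   \eqn{(2x_i-1)\pi_{x_i}^{-1} y_i - \theta} for a binary group indicator
#'   \eqn{x_i \in \{0,1\}} with group-1 probability `pi1`; the parameter is
#'   the mean difference \eqn{\mu_1 - \mu_0}.
#'
#' Custom families are accepted through the same contract: `score(theta, y,
#' X)` must return an n-by-m matrix of per-observation gradients of the loss,
#' and, if supplied, `objective(theta, y, X)` an n-vector of losses whose
#' numerical gradient matches the score.
#'
#' @param name Character label for the family.
#' @param score Function `(theta, y, X)` returning the n-by-m matrix of
#'   per-observation loss gradients.
#' @param hessian Optional function `(theta, y, X)` returning the m-by-m
#'   averaged Hessian of the loss; when absent, finite differences of the
#'   averaged score are used.
#' @param objective Optional function `(theta, y, X)` returning the n-vector
#'   of per-observation losses.
#' @param solve Optional direct solver `(y, X)` returning the root of the
#'   averaged score (used instead of Newton iteration when available).
#' @param meat Optional function `(theta, y, X)` returning the m-by-m meat
#'   matrix directly, overriding the default score outer product. Used when
#'   the score is not conditionally centered given the covariates (the index
#'   is defined conditional on the design): the two-means family centers
#'   each score at its group mean so the meat estimates the conditional
#'   variance, not the unconditional one.
#' @param design Logical; `TRUE` when `X` is a regression design matrix whose
#'   rank should be checked before solving.
#' @return An object of class `"resi_family"`.
#' @export
resi_family <- function(name, score, hessian = NULL, objective = NULL,
                        solve = NULL, meat = NULL, design = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(score))
  structure(
    list(name = name, score = score, hessian = hessian,
         objective = objective, solve = solve, meat = meat,
         design = isTRUE(design)),
    class = "resi_family"
  )
}

#' @export
print.resi_family <- function(x, ...) {
  cat("Estimating-equation family:", x$name, "\n")
  cat("  analytic Hessian:", !is.null(x$hessian),
      " direct solver:", !is.null(x$solve), "\n")
  invisible(x)
}

family_linear <- function() {
  resi_family(
    name = "linear",
    objective = function(theta, y, X) {
      0.5 * (y - drop(X %*% theta))^2
    },
    score = function(theta, y, X) {
      -X * (y - drop(X %*% theta))
    },
    hessian = function(theta, y, X) {
      crossprod(X) / nrow(X)
    },
    solve = function(y, X) {
      drop(qr.coef(qr(X), y))
    }
  )
}

family_logistic <- function() {
  resi_family(
    name = "logistic",
    objective = function(theta, y, X) {
      eta <- drop(X %*% theta)
      # -loglik, numerically stable log(1 + exp(eta))
      log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta
    },
    score = function(theta, y, X) {
      p <- plogis(drop(X %*% theta))
      X * (p - y)
    },
    hessian = function(theta, y, X) {
      p <- plogis(drop(X %*% theta))
      w <- p * (1 - p)
      crossprod(X * sqrt(w)) / nrow(X)
    }
  )
}

# pi1 = NULL means the group-1 proportion is estimated by the sample fraction
# at problem-construction time (the constructor resolves it and records the
# mode), so the family always sees a fixed numeric pi1 here.
family_two_means <- function(pi1) {
  force(pi1)
  resi_family(
    name = "two-means",
    score = function(theta, y, X) {
      x <- drop(X)
      pix <- ifelse(x == 1, pi1, 1 - pi1)
      matrix(theta - (2 * x - 1) / pix * y, ncol = 1L)
    },
    hessian = function(theta, y, X) matrix(1, 1, 1),
    solve = function(y, X) {
      x <- drop(X)
      pix <- ifelse(x == 1, pi1, 1 - pi1)
      mean((2 * x - 1) / pix * y)
    },
    # Conditionally centered meat: the index is defined conditional on the
    # design, so scores are centered at the group means before the outer
    # product, giving n^-1 sum pi_x^-2 (y - mu_x)^2 -> pi1^-1 s1^2 + pi0^-1 s0^2.
    meat = function(theta, y, X) {
      x <- drop(X)
      pix <- ifelse(x == 1, pi1, 1 - pi1)
      mu <- ifelse(x == 1, mean(y[x == 1]), mean(y[x == 0]))
      matrix(mean((y - mu)^2 / pix^2), 1, 1)
    },
    design = FALSE
  )
}

builtin_family <- function(family, pi1 = NULL) {
  switch(family,
    "linear" = family_linear(),
    "logistic" = family_logistic(),
    "two-means" = family_two_means(pi1),
    stop(sprintf("unknown family '%s'", family), call. = FALSE)
  )
}
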