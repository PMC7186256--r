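#' Define an M-estimation problem from tabular data
#'
#' Packages a data frame, a column-role assignment (outcome, nuisance
#' covariates, target covariates), an estimating-equation family, and a
#' reference value for the target parameter into a single object. Parameters
#' are ordered nuisance-first (intercept, then nuisance columns) with the
#' target block last, so the target covariance is the trailing block of the
#' sandwich covariance.
#'
#' @param data Data frame with no missing values.
#' @param outcome Name of the outcome column (numeric; 0/1 for the logistic
#'   family).
#' @param target Character vector of target covariate columns (the block the
#'   effect size is computed for).
#' @param nuisance Character vector of nuisance covariate columns (possibly
#'   empty).
#' @param family One of `"linear"`, `"logistic"`, `"two-means"`, or a custom
#'   [resi_family()] object. The two-means family takes a single 0/1 target
#'   column, no nuisance covariates, and no intercept.
#' @param beta0 Reference value for the target parameter (length `m1`);
#'   defaults to the zero vector. Larger standardized distances from `beta0`
#'   mean larger effect sizes.
#' @param intercept Include an intercept as the leading nuisance parameter?
#'   Ignored (forced off) for the two-means family.
#' @param pi1 Known group-1 probability for the two-means family. When `NULL`
#'   the sample fraction is used and the problem is flagged as having an
#'   estimated design proportion.
#' @return An object of class `"estimating_problem"` with elements `y`, `X`,
#'   `m0`, `m1`, `m`, `n`, `beta0`, `family`.
#' @seealso [estimate_from_data()] for the full pipeline.
#' @examples
#' d <- data.frame(y = rnorm(50), g = rnorm(50), z = rnorm(50))
#' prob <- estimating_problem(d, outcome = "y", nuisance = "z", target = "g")
#' estimate_from_data(prob)
#' @export
estimating_problem <- function(data, outcome, target, nuisance = character(),
                               family = c("linear", "logistic", "two-means"),
                               beta0 = NULL, intercept = TRUE, pi1 = NULL) {
  stopifnot(is.data.frame(data))
  if (anyNA(data)) stop("`data` must not contain missing values", call. = FALSE)
  cols <- c(outcome, nuisance, target)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[outcome]]
  if (!is.numeric(y)) stop("outcome column must be numeric", call. = FALSE)

  custom <- inherits(family, "resi_family")
  fam_name <- if (custom) family$name else match.arg(family)

  pi1_estimated <- FALSE
  if (fam_name == "two-means") {
    if (length(nuisance) > 0L || length(target) != 1L) {
      stop("the two-means family takes exactly one target column and no nuisance columns",
           call. = FALSE)
    }
    intercept <- FALSE
    x <- data[[target]]
    if (!all(x %in% c(0, 1))) {
      stop("the two-means group indicator must be coded 0/1", call. = FALSE)
    }
    if (is.null(pi1)) {
      pi1 <- mean(x)
      pi1_estimated <- TRUE
    }
    stop_if_not_scalar_prob(pi1, "pi1")
  }
  if (fam_name == "logistic" && !all(y %in% c(0, 1))) {
    stop("the logistic family requires a 0/1 outcome", call. = FALSE)
  }

  Xcov <- as.matrix(data[, c(nuisance, target), drop = FALSE])
  if (!is.numeric(Xcov) || !all(is.finite(Xcov))) {
    stop("covariate columns must be numeric and finite", call. = FALSE)
  }
  if (intercept) {
    X <- cbind("(Intercept)" = 1, Xcov)
  } else {
    X <- Xcov
  }
  m0 <- as.integer(intercept) + length(nuisance)
  m1 <- length(target)
  m <- m0 + m1
  n <- nrow(X)
  if (m1 < 1L) stop("at least one target column is required", call. = FALSE)
  if (n <= m) {
    stop(sprintf("need n > m: n = %d, m = %d parameters", n, m), call. = FALSE)
  }

  if (is.null(beta0)) beta0 <- rep(0, m1)
  if (length(beta0) != m1 || !all(is.finite(beta0))) {
    stop(sprintf("`beta0` must be a finite vector of length m1 = %d", m1),
         call. = FALSE)
  }

  fam <- if (custom) family else builtin_family(fam_name, pi1 = pi1)

  structure(
    list(y = y, X = X, n = n, m0 = m0, m1 = m1, m = m,
         beta0 = as.numeric(beta0), family = fam,
         outcome = outcome, nuisance = nuisance, target = target,
         pi1 = if (fam_name == "two-means") pi1 else NULL,
         pi1_estimated = pi1_estimated),
    class = "estimating_problem"
  )
}

#' @export
print.estimating_problem <- function(x, ...) {
  cat(sprintf("Estimating problem: family '%s', n = %d, m0 = %d nuisance, m1 = %d target\n",
              x$family$name, x$n, x$m0, x$m1))
  invisible(x)
}

#' Check that a family's score matches its objective
#'
#' When a family supplies a per-observation objective, its score must agree
#' with the central-difference numerical gradient of the averaged objective at
#' random probe points. Used as a self-test for built-in and custom families.
#'
#' @param problem An [estimating_problem()].
#' @param n_probe Number of random probe points.
#' @param tol Sup-norm tolerance for the gradient comparison.
#' @return Invisibly `TRUE`; errors when the check fails or is not applicable.
#' @export
check_score_consistency <- function(problem, n_probe = 5L, tol = 1e-6) {
  fam <- problem$family
  if (is.null(fam$objective)) {
    stop("family supplies no objective to check against", call. = FALSE)
  }
  obj_bar <- function(th) mean(fam$objective(th, problem$y, problem$X))
  for (k in seq_len(n_probe)) {
    th <- rnorm(problem$m, sd = 0.5)
    g_score <- colMeans(fam$score(th, problem$y, problem$X))
    h <- .Machine$double.eps^(1 / 3) * (1 + abs(th))
    g_num <- vapply(seq_along(th), function(j) {
      tp <- th; tm <- th
      tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
      (obj_bar(tp) - obj_bar(tm)) / (2 * h[j])
    }, numeric(1))
    if (sup_norm(g_score - g_num) > tol * (1 + sup_norm(g_num))) {
      stop(sprintf(
        "score differs from numerical objective gradient (sup norm %.3g at probe %d)",
        sup_norm(g_score - g_num), k), call. = FALSE)
    }
  }
  invisible(TRUE)
}

check_design_rank <- function(problem) {
  if (!problem$family$design) return(invisible(NULL))
  qrX <- qr(problem$X)
  if (qrX$rank < ncol(problem$X)) {
    bad <- colnames(problem$X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(problem$X))]]
    stop("design matrix is rank deficient; deficient columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

#' Solve the estimating equation
#'
#' Finds the M-estimator, the root of the averaged per-observation score. A
#' family-supplied direct solver is used when available (least squares uses
#' the normal equations via QR; two-means its closed form); otherwise a
#' damped Newton iteration on the averaged score is run, using the analytic
#' Hessian when the family provides one and a symmetrized central-difference
#' Jacobian otherwise.
#'
#' @param problem An [estimating_problem()].
#' @param init Optional starting value (defaults to the zero vector).
#' @param max_iter Iteration cap for the Newton solver.
#' @param tol Convergence tolerance on the sup norm of the averaged score.
#' @return The parameter estimate, an m-vector ordered nuisance-first.
#' @export
solve_theta <- function(problem, init = NULL, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(problem, "estimating_problem"))
  check_design_rank(problem)
  fam <- problem$family
  y <- problem$y
  X <- problem$X
  gbar <- function(th) colMeans(fam$score(th, y, X))

  if (!is.null(fam$solve)) {
    theta <- fam$solve(y, X)
    gn <- sup_norm(gbar(theta))
    if (!is.finite(gn) || gn > 1e-6) {
      stop(sprintf("direct solver left gradient norm %.3g", gn), call. = FALSE)
    }
    names(theta) <- colnames(X)
    return(theta)
  }

  theta <- if (is.null(init)) rep(0, problem$m) else as.numeric(init)
  g <- gbar(theta)
  gn <- sup_norm(g)
  for (iter in seq_len(max_iter)) {
    if (gn <= tol) {
      names(theta) <- colnames(X)
      return(theta)
    }
    H <- if (!is.null(fam$hessian)) fam$hessian(theta, y, X) else num_jacobian(gbar, theta)
    step <- tryCatch(solve(H, g), error = function(e) {
      stop(sprintf("Newton step failed (singular Hessian): %s",
                   conditionMessage(e)), call. = FALSE)
    })
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      gc_ <- gbar(cand)
      gnc <- sup_norm(gc_)
      if (is.finite(gnc) && gnc < gn) break
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    theta <- theta - lambda * step
    g <- gbar(theta)
    gn <- sup_norm(g)
  }
  if (gn <= tol) {
    names(theta) <- colnames(X)
    return(theta)
  }
  stop(sprintf("estimating equation did not converge in %d iterations; final gradient norm %.3g",
               max_iter, gn), call. = FALSE)
}

#' Empirical bread matrix
#'
#' The averaged Hessian of the per-observation loss at `theta` (equivalently,
#' minus the averaged Hessian of the maximized objective): the "bread" of the
#' sandwich covariance. Analytic when the family provides a Hessian,
#' otherwise central finite differences of the averaged score; the result is
#' symmetrized.
#'
#' @param problem An [estimating_problem()].
#' @param theta Parameter vector at which to evaluate.
#' @return The m-by-m bread matrix.
#' @export
estimate_J <- function(problem, theta) {
  stopifnot(inherits(problem, "estimating_problem"), all(is.finite(theta)))
  fam <- problem$family
  J <- if (!is.null(fam$hessian)) {
    fam$hessian(theta, problem$y, problem$X)
  } else {
    num_jacobian(function(th) colMeans(fam$score(th, problem$y, problem$X)), theta)
  }
  J <- symmetrize(as.matrix(J))
  kap <- kappa(J, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    stop(sprintf("bread matrix is computationally singular (condition number %.3g)", kap),
         call. = FALSE)
  }
  J
}

#' Empirical meat matrix
#'
#' The averaged outer product of per-observation scores at `theta`: the
#' "meat" of the sandwich covariance. A family may supply its own meat
#' (see [resi_family()]); the two-means family does, centering scores at
#' the group means so the meat estimates the design-conditional variance.
#'
#' @inheritParams estimate_J
#' @return The m-by-m meat matrix.
#' @export
estimate_K <- function(problem, theta) {
  stopifnot(inherits(problem, "estimating_problem"), all(is.finite(theta)))
  fam <- problem$family
  if (!is.null(fam$meat)) {
    return(as.matrix(fam$meat(theta, problem$y, problem$X)))
  }
  S <- fam$score(theta, problem$y, problem$X)
  crossprod(S) / problem$n
}

#' Sandwich covariance estimate
#'
#' Solves the estimating equation (unless `theta` is supplied), then forms
#' the empirical bread J, meat K, and the sandwich covariance
#' \eqn{\hat\Sigma = J^{-1} K J^{-1}}, the asymptotic covariance of
#' \eqn{\sqrt{n}(\hat\theta - \theta)}. The target block
#' \eqn{\hat\Sigma_\beta} is the trailing m1-by-m1 block.
#'
#' @inheritParams estimate_J
#' @param theta Optional parameter vector; solved from the data when `NULL`.
#' @return An object of class `"sandwich_estimate"` with elements
#'   `theta_hat`, `J_hat`, `K_hat`, `Sigma_hat`, `Sigma_beta`, `n`, `m`,
#'   `m0`, `m1`, `beta0`.
#' @examples
#' d <- data.frame(y = rnorm(40), x = rnorm(40))
#' prob <- estimating_problem(d, outcome = "y", target = "x")
#' sandwich_covariance(prob)
#' @export
sandwich_covariance <- function(problem, theta = NULL) {
  stopifnot(inherits(problem, "estimating_problem"))
  if (is.null(theta)) theta <- solve_theta(problem)
  J <- estimate_J(problem, theta)
  K <- estimate_K(problem, theta)
  Jinv <- solve(J)
  Sigma <- symmetrize(Jinv %*% K %*% Jinv)
  idx <- seq.int(problem$m0 + 1L, problem$m)
  structure(
    list(theta_hat = theta, J_hat = J, K_hat = K, Sigma_hat = Sigma,
         Sigma_beta = Sigma[idx, idx, drop = FALSE],
         n = problem$n, m = problem$m, m0 = problem$m0, m1 = problem$m1,
         beta0 = problem$beta0, family = problem$family$name),
    class = "sandwich_estimate"
  )
}

#' @export
print.sandwich_estimate <- function(x, ...) {
  cat(sprintf("Sandwich estimate (%s family): n = %d, m = %d (m1 = %d target)\n",
              x$family, x$n, x$m, x$m1))
  cat("theta_hat:\n")
  print(x$theta_hat)
  cat("Sigma_beta (asymptotic covariance of sqrt(n) * beta_hat):\n")
  print(x$Sigma_beta)
  invisible(x)
}

#' Robust Wald chi-squared statistic
#'
#' Computes \eqn{T^2 = n (\hat\beta - \beta_0)' \hat\Sigma_\beta^{-1}
#' (\hat\beta - \beta_0)}, approximately chi-squared on m1 degrees of freedom
#' with noncentrality \eqn{n S^2}.
#'
#' @param estimate A [sandwich_covariance()] result.
#' @param beta0 Reference value; defaults to the one recorded in the
#'   estimate.
#' @return The nonnegative Wald statistic.
#' @export
wald_statistic <- function(estimate, beta0 = NULL) {
  stopifnot(inherits(estimate, "sandwich_estimate"))
  if (is.null(beta0)) beta0 <- estimate$beta0
  beta_hat <- estimate$theta_hat[seq.int(estimate$m0 + 1L, estimate$m)]
  if (length(beta0) != estimate$m1) {
    stop(sprintf("`beta0` must have length m1 = %d", estimate$m1), call. = FALSE)
  }
  estimate$n * quad_form_inv(estimate$Sigma_beta, beta_hat - beta0,
                             label = "Sigma_beta")
}
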