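# Internal numerical helpers shared across modules.

# Quadratic form v' Sigma^{-1} v through a Cholesky factor; errors if Sigma is
# not (numerically) positive definite.
quad_form_inv <- function(Sigma, v, label = "Sigma") {
  Sigma <- as.matrix(Sigma)
  R <- tryCatch(
    chol(Sigma),
    error = function(e) {
      stop(sprintf("%s is not positive definite: %s", label, conditionMessage(e)),
           call. = FALSE)
    }
  )
  z <- backsolve(R, v, transpose = TRUE)
  sum(z^2)
}

# Central finite-difference Jacobian of a vector-valued function g at theta,
# symmetrized. Step: cube root of machine epsilon scaled by 1 + |theta_j|.
num_jacobian <- function(g, theta) {
  m <- length(theta)
  J <- matrix(0, m, m)
  h <- .Machine$double.eps^(1 / 3) * (1 + abs(theta))
  for (j in seq_len(m)) {
    tp <- theta
    tm <- theta
    tp[j] <- tp[j] + h[j]
    tm[j] <- tm[j] - h[j]
    J[, j] <- (g(tp) - g(tm)) / (2 * h[j])
  }
  (J + t(J)) / 2
}

symmetrize <- function(A) (A + t(A)) / 2

sup_norm <- function(x) max(abs(x))

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  }
  invisible(x)
}
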