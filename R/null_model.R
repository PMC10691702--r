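# Configuration model for correlation matrices: the maximum-entropy
# multivariate normal whose correlation matrix preserves each node's strength
# (row sum including the diagonal), plus a sampler for Monte-Carlo validation.
#
# The entropy of a zero-mean MVN is (up to constants) (1/2) log det C, so the
# maximizer subject to linear constraints tr(E_m C) = c_m has precision matrix
# in the span of the constraint matrices:
#   K = C^{-1} = lambda 1' + 1 lambda' + diag(d),
# with lambda enforcing the N row-sum constraints and d the unit diagonal.
# We solve the resulting KKT system rowSums(C) = s, diag(C) = 1 by a damped
# Newton iteration; all Jacobian blocks have closed forms:
#   du_i/dlambda_j = -(C_ij * sum(u) + u_i u_j),  du_i/dd_j = -C_ij u_j,
#   dC_ii/dlambda_j = -2 C_ij u_i,                dC_ii/dd_j = -C_ij^2,
# where u = C 1. The dual problem is convex, so the solution is unique and the
# fit is deterministic.

#' Fit the configuration model for a correlation matrix
#'
#' @param corr valid N x N correlation matrix.
#' @param tol convergence tolerance on the maximum absolute residual of the
#'   strength and unit-diagonal constraints.
#' @param max_iter maximum Newton iterations.
#' @param sample_size number of observations behind `corr`, stored for later
#'   use as the default sampling divisor in significance moments (optional).
#' @return An object of class `null_model_layer` with fields `null_corr`
#'   (the fitted max-entropy correlation matrix), `null_cov` (identical, since
#'   the fit is on the correlation scale), `target_strengths`,
#'   `achieved_strengths`, `convergence` (iterations, final residual) and
#'   `sample_size`.
#' @export
fit_config_model <- function(corr, tol = 1e-8, max_iter = 200,
                             sample_size = NA_integer_) {
  N <- nrow(corr)
  if (ncol(corr) != N) stop_mlc("corr must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop_mlc("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop_mlc("corr must have unit diagonal")
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop_mlc("corr is not positive semidefinite")
  s <- rowSums(corr)

  lambda <- numeric(N)
  d <- rep(1, N)
  ones <- rep(1, N)

  k_matrix <- function(lambda, d)
    outer(lambda, ones) + outer(ones, lambda) + diag(d, N)
  residual <- function(C) {
    u <- rowSums(C)
    c(u - s, diag(C) - 1)
  }

  K <- k_matrix(lambda, d)
  C <- chol2inv(chol(K))
  Fv <- residual(C)
  res <- max(abs(Fv))
  iter <- 0L
  trajectory <- res

  while (res > tol && iter < max_iter) {
    iter <- iter + 1L
    u <- rowSums(C)
    Tu <- sum(u)
    # Jacobian of (rowSums(C), diag(C)) w.r.t. (lambda, d)
    J11 <- -(C * Tu + outer(u, u))
    J12 <- -sweep(C, 2, u, `*`)
    J21 <- -2 * sweep(C, 1, u, `*`)
    J22 <- -(C^2)
    J <- rbind(cbind(J11, J12), cbind(J21, J22))
    # Levenberg-Marquardt step: the (lambda, d) parametrization can have a
    # kernel (e.g. N = 2), so ridge-regularized normal equations replace a
    # plain Newton solve
    JtJ <- crossprod(J)
    Jtf <- crossprod(J, -Fv)
    scale <- max(diag(JtJ), 1)
    improved <- FALSE
    for (ridge in scale * 10^c(-12, -8, -4, -2, 0)) {
      step <- tryCatch(solve(JtJ + ridge * diag(2 * N), Jtf),
                       error = function(e) NULL)
      if (is.null(step)) next
      alpha <- 1
      for (half in 1:30) {
        lam2 <- lambda + alpha * step[seq_len(N)]
        d2 <- d + alpha * step[N + seq_len(N)]
        K2 <- k_matrix(lam2, d2)
        ch <- tryCatch(chol(K2), error = function(e) NULL)
        if (!is.null(ch)) {
          C2 <- chol2inv(ch)
          F2 <- residual(C2)
          if (max(abs(F2)) < res) {
            lambda <- lam2; d <- d2; C <- C2; Fv <- F2
            res <- max(abs(Fv))
            improved <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (improved) break
    }
    trajectory <- c(trajectory, res)
    if (!improved) break
  }
  if (res > tol)
    stop_mlc(paste0(
      "configuration-model fit did not converge in %d iterations ",
      "(final residual %.3g; trajectory: %s)"), iter, res,
      paste(signif(utils::tail(trajectory, 5), 3), collapse = ", "))

  Cn <- (C + t(C)) / 2
  dimnames(Cn) <- dimnames(corr)
  structure(
    list(null_corr = Cn, null_cov = Cn, target_strengths = s,
         achieved_strengths = rowSums(Cn),
         convergence = list(iterations = iter, residual = res,
                            trajectory = trajectory),
         sample_size = sample_size),
    class = "null_model_layer"
  )
}

#' @export
print.null_model_layer <- function(x, ...) {
  cat(sprintf(
    "Configuration-model null: %d nodes, fit in %d iteration(s), residual %.2g\n",
    nrow(x$null_corr), x$convergence$iterations, x$convergence$residual))
  invisible(x)
}

#' Sample covariance matrix under the configuration model
#'
#' Draws `n_samples` independent observations from the zero-mean multivariate
#' normal with covariance `null_cov` and returns their sample covariance
#' (divisor `n_samples`, mean known to be zero), so that
#' `E[S] = null_cov` exactly and `Var[S_ij] = (C_ii C_jj + C_ij^2) / n`.
#'
#' @param null a `null_model_layer`.
#' @param n_samples number of draws (>= 2).
#' @param seed RNG seed for reproducibility.
#' @return N x N sample covariance matrix.
#' @export
sample_covariance <- function(null, n_samples, seed = NULL) {
  stopifnot(inherits(null, "null_model_layer"), n_samples >= 2)
  C <- null$null_cov
  R <- tryCatch(chol(C), error = function(e)
    stop_mlc("null covariance is not positive definite"))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_samples * nrow(C)), nrow = n_samples)
    X <- Z %*% R
    crossprod(X) / n_samples
  })
}

# Skewness/kurtosis diagnostic for the normality assumption behind the
# configuration model; logged, never enforced.
normality_diagnostic <- function(x) {
  x <- as.vector(x)
  m <- mean(x); s <- stats::sd(x)
  z <- (x - m) / s
  list(skewness = mean(z^3), excess_kurtosis = mean(z^4) - 3)
}
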