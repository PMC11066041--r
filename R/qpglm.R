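#' Fit a quasi-Poisson log-linear model
#'
#' Fits log E(Y) = X b by iteratively reweighted least squares under the
#' Poisson mean structure; quasi-Poisson point estimates coincide with the
#' Poisson maximum-likelihood estimates, and overdispersion enters only
#' through the Pearson dispersion phi, which rescales the
#' variance-covariance matrix: vcov = phi * (X' W X)^-1 with W = diag(mu).
#'
#' An intercept column is prepended automatically; `design` holds all other
#' terms. The named `blocks` list maps term groups (e.g. `cb`, `covariates`,
#' `seasonal`) to column indices of `design` so downstream reductions can
#' extract the cross-basis coefficient block with its matching vcov
#' sub-matrix.
#'
#' @param y Non-negative integer counts.
#' @param design Numeric matrix, rows aligned with `y` (no intercept column).
#' @param blocks Named list of integer vectors indexing columns of `design`.
#'   Defaults to a single block covering all columns.
#' @return An object of class `qp_fit`: coefficients (intercept first),
#'   vcov (dispersion-scaled), dispersion, Poisson log-likelihood, number of
#'   estimated coefficients `p`, fitted means, and a column map carrying the
#'   blocks shifted past the intercept.
#' @export
fit_quasipoisson <- function(y, design, blocks = NULL) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("fit_quasipoisson: `y` must be non-negative integers", call. = FALSE)
  }
  design <- as.matrix(design)
  if (nrow(design) != length(y)) {
    stop("fit_quasipoisson: rows of `design` must align with `y`", call. = FALSE)
  }
  if (ncol(design) > 0L && is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  if (is.null(blocks)) blocks <- list(all = seq_len(ncol(design)))
  X <- cbind(`(Intercept)` = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf(
      "fit_quasipoisson: design is rank-deficient; collinear column(s): %s",
      paste(dropped, collapse = ", ")
    ), call. = FALSE)
  }
  # IRLS via glm.fit; start at log(mean(y) + 0.5) intercept, zeros elsewhere
  start <- c(log(mean(y) + 0.5), rep(0, ncol(design)))
  fit <- stats::glm.fit(
    x = X, y = y, family = stats::poisson(link = "log"), start = start,
    control = stats::glm.control(epsilon = 1e-11, maxit = 100L)
  )
  if (!fit$converged) {
    stop(sprintf(
      "fit_quasipoisson: IRLS did not converge in %d iterations (deviance %.6g)",
      fit$iter, fit$deviance
    ), call. = FALSE)
  }
  mu <- fit$fitted.values
  n <- length(y)
  p <- ncol(X)
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / (n - p)
  degenerate <- FALSE
  if (phi < 1e-8) {
    # perfect fit: keep QAIC finite rather than dividing by ~0
    phi <- 1e-8
    degenerate <- TRUE
    warning("fit_quasipoisson: near-zero Pearson dispersion floored at 1e-8")
  }
  info <- crossprod(X * sqrt(mu)) # Fisher information for the log link
  vcov_unscaled <- chol2inv(chol(info))
  vcov <- phi * vcov_unscaled
  dimnames(vcov) <- list(colnames(X), colnames(X))
  blocks_shifted <- lapply(blocks, function(ix) as.integer(ix) + 1L)
  blocks_shifted <- c(list(intercept = 1L), blocks_shifted)
  structure(
    list(
      coefficients = stats::setNames(fit$coefficients, colnames(X)),
      vcov = vcov,
      dispersion = phi,
      dispersion_floored = degenerate,
      poisson_loglik = sum(stats::dpois(y, mu, log = TRUE)),
      p = p,
      n = n,
      fitted = mu,
      deviance = fit$deviance,
      iter = fit$iter,
      blocks = blocks_shifted
    ),
    class = "qp_fit"
  )
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf(
    "quasi-Poisson fit: n = %d, p = %d, dispersion phi = %.4g, logLik(Poisson) = %.4f\n",
    x$n, x$p, x$dispersion, x$poisson_loglik
  ))
  invisible(x)
}

#' Extract a coefficient block and its vcov sub-matrix
#'
#' @param fit A `qp_fit`.
#' @param block Name of a block declared at fit time (e.g. `"cb"`).
#' @return List with `beta` and `vcov` restricted to the block.
#' @export
coef_block <- function(fit, block) {
  stopifnot(inherits(fit, "qp_fit"))
  if (!block %in% names(fit$blocks)) {
    stop(sprintf("coef_block: no block named '%s'", block), call. = FALSE)
  }
  ix <- fit$blocks[[block]]
  list(beta = fit$coefficients[ix], vcov = fit$vcov[ix, ix, drop = FALSE])
}

#' QAIC of a quasi-Poisson fit
#'
#' Quasi-likelihood analogue of AIC: -2 * logLik(Poisson at the fitted
#' means) / phi_ref + 2 p. The reference dispersion `phi_ref` is supplied by
#' the caller so that all candidates in one model search are penalized on a
#' common dispersion scale (conventionally estimated from the most complex
#' candidate); with `phi_ref = 1` QAIC reduces to the ordinary AIC.
#'
#' @param fit A `qp_fit`.
#' @param phi_ref Positive reference dispersion.
#' @return The QAIC value.
#' @export
qaic <- function(fit, phi_ref) {
  stopifnot(inherits(fit, "qp_fit"))
  if (!is.numeric(phi_ref) || length(phi_ref) != 1L || phi_ref <= 0) {
    stop("qaic: `phi_ref` must be a single positive number", call. = FALSE)
  }
  -2 * fit$poisson_loglik / phi_ref + 2 * fit$p
}
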