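#' @keywords internal
# Accepts either a full qp_fit (cross-basis block extracted by name) or a
# bare list(beta, vcov) such as a pooled estimate.
cb_estimate <- function(estimate) {
  if (inherits(estimate, "qp_fit")) {
    coef_block(estimate, "cb")
  } else if (is.list(estimate) && all(c("beta", "vcov") %in% names(estimate))) {
    estimate[c("beta", "vcov")]
  } else {
    stop("expected a qp_fit with a 'cb' block or a list(beta, vcov)",
         call. = FALSE)
  }
}

#' @keywords internal
check_cb_dims <- function(est, cb) {
  d <- ncol(cb$matrix)
  if (length(est$beta) != d || !all(dim(est$vcov) == d)) {
    stop(sprintf(
      "cross-basis block has %d columns but estimate has %d coefficients",
      d, length(est$beta)
    ), call. = FALSE)
  }
}

#' @keywords internal
# rows: contrast vectors over the cross-basis block; returns the RR table
rr_from_contrasts <- function(D, est) {
  log_rr <- drop(D %*% est$beta)
  se <- sqrt(pmax(0, rowSums((D %*% est$vcov) * D)))
  data.frame(
    log_rr = log_rr,
    se = se,
    rr = exp(log_rr),
    rr_low = exp(log_rr - 1.96 * se),
    rr_high = exp(log_rr + 1.96 * se)
  )
}

#' Overall cumulative exposure-response association
#'
#' Reduces a fitted (or pooled) cross-basis coefficient block to the
#' cumulative log relative risk over the whole lag window 0..L, as a
#' function of exposure, relative to a reference concentration: the
#' contrast vector at exposure x is sum over lags of the Kronecker pairing
#' of the predictor basis at x with the lag basis, minus the same at x_ref.
#' Standard errors come from the delta method and intervals are 95% Wald on
#' the log scale.
#'
#' @param estimate A `qp_fit` (its `cb` block is used) or a
#'   `list(beta, vcov)` pooled estimate.
#' @param cb The `cross_basis` the coefficients refer to (provides frozen
#'   knots and the lag basis).
#' @param at Exposure grid; defaults to 100 equally spaced values over the
#'   cross-basis boundary range.
#' @param x_ref Reference exposure (e.g. the reference city's median).
#' @return An `association` data frame (kind `overall_cumulative`) with
#'   columns x, log_rr, se, rr, rr_low, rr_high; RR is exactly 1 at x_ref.
#' @export
overall_cumulative <- function(estimate, cb, at = NULL, x_ref) {
  stopifnot(inherits(cb, "cross_basis"))
  est <- cb_estimate(estimate)
  check_cb_dims(est, cb)
  if (is.null(at)) {
    at <- seq(cb$pred_boundary[1], cb$pred_boundary[2], length.out = 100L)
  }
  df_l <- ncol(cb$lag_matrix)
  df_p <- cb$spec$pred$df
  R <- pred_basis_at(cb, at)
  Rref <- pred_basis_at(cb, x_ref)
  Csum <- colSums(cb$lag_matrix)
  jcol <- rep(seq_len(df_p), each = df_l)
  kcol <- rep(seq_len(df_l), times = df_p)
  D <- (R[, jcol, drop = FALSE] -
          matrix(Rref[1, jcol], nrow = length(at), ncol = df_p * df_l, byrow = TRUE)) *
    matrix(Csum[kcol], nrow = length(at), ncol = df_p * df_l, byrow = TRUE)
  out <- cbind(data.frame(x = at), rr_from_contrasts(D, est))
  structure(out, kind = "overall_cumulative", x_ref = x_ref,
            class = c("association", "data.frame"))
}

#' Exposure-lag relative-risk surface
#'
#' The fitted bi-dimensional surface f-hat(x, l) relative to the reference
#' exposure at the same lag, exported as a long table over an exposure grid
#' and a lag grid, with delta-method standard errors per cell.
#'
#' @inheritParams overall_cumulative
#' @param lags Lag grid; defaults to the integer lags 0..L.
#' @return An `association` data frame (kind `surface`) with columns x, lag,
#'   log_rr, se, rr, rr_low, rr_high; the row at x = x_ref is exactly RR = 1
#'   for every lag.
#' @export
exposure_lag_surface <- function(estimate, cb, at = NULL, lags = NULL, x_ref) {
  stopifnot(inherits(cb, "cross_basis"))
  est <- cb_estimate(estimate)
  check_cb_dims(est, cb)
  if (is.null(at)) {
    at <- seq(cb$pred_boundary[1], cb$pred_boundary[2], length.out = 50L)
  }
  if (is.null(lags)) lags <- 0:cb$spec$max_lag
  if (any(lags < 0 | lags > cb$spec$max_lag)) {
    stop("exposure_lag_surface: lags must lie in 0..max_lag", call. = FALSE)
  }
  df_l <- ncol(cb$lag_matrix)
  df_p <- cb$spec$pred$df
  R <- pred_basis_at(cb, at)
  Rref <- pred_basis_at(cb, x_ref)
  Rdiff <- R - matrix(Rref[1, ], nrow = length(at), ncol = df_p, byrow = TRUE)
  jcol <- rep(seq_len(df_p), each = df_l)
  kcol <- rep(seq_len(df_l), times = df_p)
  grid <- expand.grid(x = at, lag = lags)
  C <- cb$lag_matrix[match(grid$lag, 0:cb$spec$max_lag), , drop = FALSE]
  D <- Rdiff[match(grid$x, at), jcol, drop = FALSE] * C[, kcol, drop = FALSE]
  out <- cbind(grid, rr_from_contrasts(D, est))
  structure(out, kind = "surface", x_ref = x_ref,
            class = c("association", "data.frame"))
}

#' Lag-specific effects at extreme exposure percentiles
#'
#' Per-lag relative risks contrasting a high quantile (default 90th) and a
#' low quantile (default 10th) of the exposure distribution against the
#' median, over lags 0..L, with 95% Wald intervals.
#'
#' @inheritParams overall_cumulative
#' @param series Exposure series from which the empirical quantiles are
#'   taken (type-7, linear interpolation).
#' @param levels Numeric triple (low, reference, high) of quantile levels.
#' @return An `association` data frame (kind `extreme`) in long format with
#'   columns lag, contrast (`high_vs_median` / `low_vs_median`), log_rr, se,
#'   rr, rr_low, rr_high; quantile values are carried in the `quantiles`
#'   attribute.
#' @export
extreme_effects <- function(estimate, cb, series,
                            levels = c(0.10, 0.50, 0.90)) {
  stopifnot(inherits(cb, "cross_basis"), length(levels) == 3L)
  est <- cb_estimate(estimate)
  check_cb_dims(est, cb)
  if (length(series) == 0L) {
    stop("extreme_effects: exposure series is empty", call. = FALSE)
  }
  if (length(unique(series)) == 1L) {
    stop("extreme_effects: degenerate exposure series; quantile contrast undefined",
         call. = FALSE)
  }
  q <- stats::quantile(series, probs = levels, type = 7, names = FALSE)
  lags <- 0:cb$spec$max_lag
  df_l <- ncol(cb$lag_matrix)
  df_p <- cb$spec$pred$df
  jcol <- rep(seq_len(df_p), each = df_l)
  kcol <- rep(seq_len(df_l), times = df_p)
  contrast_rows <- function(x_from, x_to) {
    Rd <- pred_basis_at(cb, x_from) - pred_basis_at(cb, x_to)
    matrix(Rd[1, jcol], nrow = length(lags), ncol = df_p * df_l, byrow = TRUE) *
      cb$lag_matrix[, kcol, drop = FALSE]
  }
  Dh <- contrast_rows(q[3], q[2])
  Dl <- contrast_rows(q[1], q[2])
  out <- rbind(
    cbind(data.frame(lag = lags, contrast = "high_vs_median"),
          rr_from_contrasts(Dh, est)),
    cbind(data.frame(lag = lags, contrast = "low_vs_median"),
          rr_from_contrasts(Dl, est))
  )
  structure(out, kind = "extreme",
            quantiles = stats::setNames(q, c("low", "median", "high")),
            class = c("association", "data.frame"))
}
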