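#' Hyperparameter and covariate search grid
#'
#' Defaults follow the published single-pollutant DLNM optimization setup:
#' maximum lag 7 to 31 days, 2 to 5 degrees of freedom in both the predictor
#' space and the lag dimension, and best-subset enumeration over the five
#' meteorological covariates.
#'
#' @param max_lags Ordered integer vector of candidate maximum lags (>= 1).
#' @param df_p_values,df_l_values Ordered integer vectors of candidate
#'   degrees of freedom (>= 2).
#' @param covariates Character vector of covariate column names.
#' @return An object of class `search_grid`.
#' @export
search_grid <- function(max_lags = 7:31,
                        df_p_values = 2:5,
                        df_l_values = 2:5,
                        covariates = c("tavg", "rh", "wind", "dtr", "precip")) {
  if (length(max_lags) == 0L || length(df_p_values) == 0L || length(df_l_values) == 0L) {
    stop("search_grid: grid components must be non-empty", call. = FALSE)
  }
  if (any(max_lags < 1)) stop("search_grid: max lags must be >= 1", call. = FALSE)
  if (any(df_p_values < 2) || any(df_l_values < 2)) {
    stop("search_grid: degrees of freedom must be >= 2", call. = FALSE)
  }
  structure(
    list(max_lags = as.integer(max_lags),
         df_p_values = as.integer(df_p_values),
         df_l_values = as.integer(df_l_values),
         covariates = covariates),
    class = "search_grid"
  )
}

#' Enumerate candidate model shells
#'
#' Every combination of covariate subset (mask as a binary counter over the
#' covariate list, bit 1 = first covariate) and hyperparameters
#' (lexicographic over max lag, then df_p, then df_l). With k covariates the
#' result has 2^k x |max_lags| x |df_p| x |df_l| rows in a deterministic
#' order.
#'
#' @param grid A [search_grid()].
#' @return Data frame with columns `id`, `mask_id`, `covariates`
#'   (comma-joined names, "" for none), `n_covariates`, `max_lag`, `df_p`,
#'   `df_l`.
#' @export
enumerate_candidates <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  k <- length(grid$covariates)
  masks <- 0:(2^k - 1L)
  hyper <- expand.grid(df_l = grid$df_l_values, df_p = grid$df_p_values,
                       max_lag = grid$max_lags)
  hyper <- hyper[order(hyper$max_lag, hyper$df_p, hyper$df_l), , drop = FALSE]
  n_h <- nrow(hyper)
  out <- data.frame(
    mask_id = rep(masks, each = n_h),
    max_lag = rep(hyper$max_lag, times = length(masks)),
    df_p = rep(hyper$df_p, times = length(masks)),
    df_l = rep(hyper$df_l, times = length(masks))
  )
  out$covariates <- vapply(out$mask_id, function(m) {
    if (k == 0L || m == 0L) return("")
    paste(grid$covariates[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L],
          collapse = ",")
  }, character(1))
  out$n_covariates <- vapply(out$mask_id, function(m) {
    if (k == 0L) 0L else sum(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
  }, integer(1))
  out$id <- seq_len(nrow(out))
  out[, c("id", "mask_id", "covariates", "n_covariates", "max_lag", "df_p", "df_l")]
}

#' Apply the delta-QAIC parsimony rule
#'
#' Among candidates within 2 QAIC units of the minimum, the simplest model
#' wins. Simplicity is ordered by fewer covariates, then smaller
#' df_p + df_l, then smaller maximum lag, then lower QAIC, then enumeration
#' order; the first key is the selection rule, the rest are deterministic
#' tie-breaks.
#'
#' @param candidates Data frame with columns `qaic`, `n_covariates`, `df_p`,
#'   `df_l`, `max_lag` and `id` (rows with non-finite QAIC are ignored).
#' @return The selected row of `candidates`.
#' @export
select_best <- function(candidates) {
  ok <- is.finite(candidates$qaic)
  if (!any(ok)) stop("select_best: no candidate with finite QAIC", call. = FALSE)
  cand <- candidates[ok, , drop = FALSE]
  qmin <- min(cand$qaic)
  pool <- cand[cand$qaic - qmin < 2, , drop = FALSE]
  ord <- order(pool$n_covariates, pool$df_p + pool$df_l, pool$max_lag,
               pool$qaic, pool$id)
  pool[ord[1L], , drop = FALSE]
}

#' @keywords internal
mask_names <- function(covariates_str) {
  if (identical(covariates_str, "") || is.na(covariates_str)) character(0)
  else strsplit(covariates_str, ",", fixed = TRUE)[[1]]
}

#' Fit one city at a fixed model configuration
#'
#' Builds the cross-basis at the given hyperparameters, assembles
#' cross-basis + selected covariates + Fourier seasonal terms, and fits the
#' quasi-Poisson GLM on the days with a complete lag history.
#'
#' @param panel Single-city daily panel (columns y, x and the covariates).
#' @param covariates Character vector of covariate names to include (may be
#'   empty).
#' @param max_lag,df_p,df_l Cross-basis hyperparameters.
#' @param boundary Optional frozen predictor boundary knots (e.g. the
#'   reference city's exposure range) so coefficient blocks are poolable.
#' @param K,m Seasonal harmonics and period.
#' @param window Optional 1-based row indices to fit on (defaults to all
#'   days with full lag history for `max_lag`).
#' @return List with `fit` (a `qp_fit`), `cb` (the `cross_basis`) and the
#'   configuration.
#' @export
fit_city <- function(panel, covariates, max_lag, df_p, df_l,
                     boundary = NULL, K = 6, m = 365, window = NULL) {
  n <- nrow(panel)
  cb <- build_cross_basis(panel$x, cross_basis_spec(max_lag, df_p, df_l,
                                                    boundary = boundary))
  if (is.null(window)) window <- (max_lag + 1L):n
  if (min(window) < max_lag + 1L) {
    stop("fit_city: window includes days without a full lag history",
         call. = FALSE)
  }
  cbX <- cb$matrix[window - max_lag, , drop = FALSE]
  S <- fourier_basis(0:(n - 1L), m = m, K = K)[window, , drop = FALSE]
  blocks <- list(cb = seq_len(ncol(cbX)))
  design <- cbX
  if (length(covariates)) {
    Mx <- as.matrix(panel[window, covariates, drop = FALSE])
    blocks$covariates <- ncol(design) + seq_len(ncol(Mx))
    design <- cbind(design, Mx)
  }
  blocks$seasonal <- ncol(design) + seq_len(ncol(S))
  design <- cbind(design, S)
  fit <- fit_quasipoisson(panel$y[window], design, blocks = blocks)
  list(fit = fit, cb = cb, covariates = covariates,
       max_lag = max_lag, df_p = df_p, df_l = df_l,
       boundary = cb$pred_boundary, window = window)
}

#' QAIC-based model optimization for one city
#'
#' The published optimization algorithm: enumerate every covariate subset
#' crossed with the hyperparameter grid, fit each candidate by quasi-Poisson
#' IRLS on a common usable-day window (days with full history for the
#' largest lag in the grid, so all QAICs compare the same response), rank by
#' QAIC using a single reference dispersion estimated from the most complex
#' candidate, and apply the delta-QAIC < 2 parsimony rule.
#'
#' @param panel Single-city daily panel.
#' @param grid A [search_grid()].
#' @param K,m Seasonal harmonics and period.
#' @return List with `selected` (the winning candidate row), `table` (the
#'   full QAIC table with fit status per candidate), `phi_ref`, and
#'   `refit` (the selected configuration refitted on the common window, a
#'   [fit_city()] result).
#' @export
optimize_dlnm <- function(panel, grid, K = 6, m = 365) {
  stopifnot(inherits(grid, "search_grid"))
  n <- nrow(panel)
  maxL <- max(grid$max_lags)
  if (n < maxL + 2L) {
    stop("optimize_dlnm: panel shorter than the largest lag in the grid",
         call. = FALSE)
  }
  window <- (maxL + 1L):n
  y <- panel$y[window]
  S <- fourier_basis(0:(n - 1L), m = m, K = K)[window, , drop = FALSE]
  Mall <- as.matrix(panel[window, grid$covariates, drop = FALSE])

  # cross-bases are shared across all covariate masks
  hyper_key <- function(L, df_p, df_l) paste(L, df_p, df_l, sep = "_")
  cb_cache <- new.env(parent = emptyenv())
  get_cbX <- function(L, df_p, df_l) {
    key <- hyper_key(L, df_p, df_l)
    if (is.null(cb_cache[[key]])) {
      cb <- build_cross_basis(panel$x, cross_basis_spec(L, df_p, df_l))
      cb_cache[[key]] <- cb$matrix[window - L, , drop = FALSE]
    }
    cb_cache[[key]]
  }

  fit_candidate <- function(covs, L, df_p, df_l) {
    cbX <- get_cbX(L, df_p, df_l)
    design <- cbX
    blocks <- list(cb = seq_len(ncol(cbX)))
    if (length(covs)) {
      blocks$covariates <- ncol(design) + seq_along(covs)
      design <- cbind(design, Mall[, covs, drop = FALSE])
    }
    blocks$seasonal <- ncol(design) + seq_len(ncol(S))
    design <- cbind(design, S)
    fit_quasipoisson(y, design, blocks = blocks)
  }

  # reference dispersion from the most complex candidate
  full_fit <- fit_candidate(grid$covariates, maxL,
                            max(grid$df_p_values), max(grid$df_l_values))
  phi_ref <- full_fit$dispersion

  table <- enumerate_candidates(grid)
  table$qaic <- NA_real_
  table$p <- NA_integer_
  table$status <- "ok"
  for (i in seq_len(nrow(table))) {
    covs <- mask_names(table$covariates[i])
    res <- tryCatch(
      fit_candidate(covs, table$max_lag[i], table$df_p[i], table$df_l[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      table$status[i] <- conditionMessage(res)
    } else {
      table$qaic[i] <- qaic(res, phi_ref)
      table$p[i] <- res$p
    }
  }
  if (!any(is.finite(table$qaic))) {
    stop("optimize_dlnm: every candidate fit failed", call. = FALSE)
  }
  selected <- select_best(table)
  refit <- fit_city(panel, mask_names(selected$covariates),
                    selected$max_lag, selected$df_p, selected$df_l,
                    K = K, m = m, window = window)
  list(selected = selected, table = table, phi_ref = phi_ref, refit = refit)
}
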