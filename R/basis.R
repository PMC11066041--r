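#' Natural cubic spline specification
#'
#' Describes a natural cubic spline basis with `df` degrees of freedom,
#' equally spaced interior knots and boundary knots at the observed range of
#' the variable. With `df = 1` the basis degenerates to a single linear term.
#' No intercept column is ever included; the model intercept absorbs the
#' constant.
#'
#' @param df Integer >= 1, degrees of freedom (number of basis columns).
#' @param boundary Optional length-2 numeric giving the boundary knots. When
#'   `NULL` the boundary is taken from the range of the data the basis is
#'   built on.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(df, boundary = NULL) {
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != round(df)) {
    stop("spline_spec: `df` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.null(boundary)) {
    stopifnot(is.numeric(boundary), length(boundary) == 2L, boundary[1] < boundary[2])
  }
  structure(list(df = as.integer(df), boundary = boundary), class = "spline_spec")
}

#' @keywords internal
equally_spaced_knots <- function(boundary, df) {
  # df columns (no intercept) <=> df - 1 interior knots for a natural spline
  if (df == 1L) return(numeric(0))
  seq(boundary[1], boundary[2], length.out = df + 1L)[2:df]
}

#' Evaluate a natural cubic spline basis at given values
#'
#' Internal workhorse shared by fitting and prediction: fixed knots in,
#' basis matrix out. Uses the B-spline representation of the natural cubic
#' spline space (linear beyond the boundary knots).
#' @keywords internal
ncs_eval <- function(values, knots, boundary) {
  if (length(knots) == 0L) {
    # df = 1: the natural spline space without intercept is the linear span
    m <- matrix(values, ncol = 1L)
    colnames(m) <- "ns1"
    return(m)
  }
  m <- splines::ns(values, knots = knots, Boundary.knots = boundary, intercept = FALSE)
  m <- unclass(m)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  colnames(m) <- paste0("ns", seq_len(ncol(m)))
  m
}

#' Natural cubic spline basis with equally spaced knots
#'
#' Builds an n x df basis for the natural cubic spline space of dimension
#' `df` (intercept excluded). Interior knots are equally spaced strictly
#' between the boundary knots; boundary knots default to the observed
#' min/max. The implied spline is linear beyond the boundary knots.
#'
#' @param values Numeric vector, finite.
#' @param spec A [spline_spec()].
#' @return Numeric matrix with `length(values)` rows and `spec$df` columns,
#'   carrying attributes `knots` and `boundary` for later evaluation at new
#'   values.
#' @export
natural_cubic_basis <- function(values, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (!all(is.finite(values))) {
    stop("natural_cubic_basis: `values` must be finite", call. = FALSE)
  }
  if (length(unique(values)) < spec$df + 1L) {
    stop(sprintf(
      "natural_cubic_basis: need at least df + 1 = %d distinct values, got %d",
      spec$df + 1L, length(unique(values))
    ), call. = FALSE)
  }
  boundary <- if (is.null(spec$boundary)) range(values) else spec$boundary
  knots <- equally_spaced_knots(boundary, spec$df)
  m <- ncs_eval(values, knots, boundary)
  attr(m, "knots") <- knots
  attr(m, "boundary") <- boundary
  m
}

#' Fourier basis for daily seasonality
#'
#' Pairs of sine/cosine columns sin(2*pi*k*t/m), cos(2*pi*k*t/m) for
#' harmonics k = 1..K over a period of `m` days. Column order interleaves
#' sin and cos per harmonic. Six harmonics over a 365-day period is the
#' conventional seasonal adjustment for daily admission counts.
#'
#' @param day_index Integer vector of day indices (0 = first day).
#' @param m Period in days (> 0).
#' @param K Number of harmonics (>= 1).
#' @return Numeric matrix with `2 * K` columns named `sin1, cos1, ...`.
#' @export
fourier_basis <- function(day_index, m = 365, K = 6) {
  if (!is.numeric(m) || length(m) != 1L || m <= 0) {
    stop("fourier_basis: `m` must be a positive period", call. = FALSE)
  }
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    stop("fourier_basis: `K` must be a positive integer", call. = FALSE)
  }
  out <- matrix(0, nrow = length(day_index), ncol = 2L * K)
  nm <- character(2L * K)
  for (k in seq_len(K)) {
    ang <- 2 * pi * k * day_index / m
    out[, 2L * k - 1L] <- sin(ang)
    out[, 2L * k] <- cos(ang)
    nm[2L * k - 1L] <- paste0("sin", k)
    nm[2L * k] <- paste0("cos", k)
  }
  colnames(out) <- nm
  out
}

#' Cross-basis specification
#'
#' Hyperparameters of the bi-dimensional exposure-lag basis: maximum lag `L`
#' (days), predictor-space spline with `df_p` degrees of freedom, and a
#' lag-dimension spline with `df_l` degrees of freedom over the integer lag
#' grid 0..L. The cross-basis has `df_p * df_l` columns.
#'
#' @param max_lag Integer >= 0 maximum lag in days (0 collapses to an
#'   unlagged exposure basis).
#' @param df_p Degrees of freedom of the predictor (exposure) spline.
#' @param df_l Degrees of freedom of the lag spline.
#' @param boundary Optional predictor boundary knots (length 2); defaults to
#'   the range of the exposure series the basis is built on. Freezing these
#'   to a reference city's range makes coefficient blocks poolable across
#'   cities.
#' @return An object of class `cross_basis_spec`.
#' @export
cross_basis_spec <- function(max_lag, df_p, df_l, boundary = NULL) {
  stopifnot(length(max_lag) == 1L, max_lag >= 0, max_lag == round(max_lag))
  pred <- spline_spec(df_p, boundary = boundary)
  if (max_lag == 0L) {
    lag <- NULL # degenerate: lag basis is the constant 1
  } else {
    stopifnot(df_l >= 1)
    lag <- spline_spec(df_l, boundary = c(0, max_lag))
  }
  structure(
    list(max_lag = as.integer(max_lag), pred = pred, lag = lag),
    class = "cross_basis_spec"
  )
}

#' Lag-basis matrix on the integer lag grid
#'
#' Natural cubic spline in the lag dimension evaluated at lags 0..L with
#' equally spaced knots on the untransformed lag scale. For `max_lag = 0`
#' this is the 1 x 1 constant matrix.
#' @keywords internal
lag_basis_matrix <- function(spec) {
  L <- spec$max_lag
  if (L == 0L) {
    return(matrix(1, nrow = 1L, ncol = 1L, dimnames = list(NULL, "l1")))
  }
  lags <- 0:L
  boundary <- c(0, L)
  knots <- equally_spaced_knots(boundary, spec$lag$df)
  C <- ncs_eval(lags, knots, boundary)
  colnames(C) <- paste0("l", seq_len(ncol(C)))
  C
}

#' Build the exposure-lag cross-basis
#'
#' Constructs the DLNM design block: column (j, k) at day t equals
#' sum over lags l = 0..L of R(x[t - l])_j * C(l)_k, where R is the
#' predictor natural-spline basis and C the lag natural-spline basis.
#' Only days with a complete lag history (t >= L, 0-based) are usable;
#' earlier days are dropped, not imputed.
#'
#' @param exposure Numeric exposure series (one city, consecutive days).
#' @param spec A [cross_basis_spec()].
#' @return An object of class `cross_basis`: list with `matrix`
#'   ((n - L) x (df_p * df_l)), `spec` (with predictor knots resolved),
#'   `usable` (1-based indices of days retained), `pred_knots`,
#'   `pred_boundary` and `lag_matrix`. Columns are ordered with the
#'   predictor index varying slowest: column (j - 1) * df_l + k pairs
#'   predictor column j with lag column k.
#' @export
build_cross_basis <- function(exposure, spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  L <- spec$max_lag
  n <- length(exposure)
  if (n < L + 1L) {
    stop(sprintf(
      "build_cross_basis: series of length %d is shorter than max_lag + 1 = %d",
      n, L + 1L
    ), call. = FALSE)
  }
  if (!all(is.finite(exposure))) {
    stop("build_cross_basis: exposure must be finite", call. = FALSE)
  }
  boundary <- if (is.null(spec$pred$boundary)) range(exposure) else spec$pred$boundary
  pknots <- equally_spaced_knots(boundary, spec$pred$df)
  C <- lag_basis_matrix(spec)
  df_p <- spec$pred$df
  df_l <- ncol(C)
  usable <- (L + 1L):n
  jcol <- rep(seq_len(df_p), each = df_l)
  kcol <- rep(seq_len(df_l), times = df_p)
  X <- matrix(0, nrow = length(usable), ncol = df_p * df_l)
  for (l in 0:L) {
    Rl <- ncs_eval(exposure[usable - l], pknots, boundary)
    X <- X + Rl[, jcol, drop = FALSE] *
      matrix(C[l + 1L, kcol], nrow = length(usable), ncol = df_p * df_l, byrow = TRUE)
  }
  colnames(X) <- paste0("cb", jcol, ".", kcol)
  structure(
    list(
      matrix = X,
      spec = spec,
      usable = usable,
      pred_knots = pknots,
      pred_boundary = boundary,
      lag_matrix = C
    ),
    class = "cross_basis"
  )
}

#' @export
print.cross_basis <- function(x, ...) {
  cat(sprintf(
    "cross_basis: %d usable days x %d columns (max_lag = %d, df_p = %d, df_l = %d)\n",
    nrow(x$matrix), ncol(x$matrix), x$spec$max_lag, x$spec$pred$df, ncol(x$lag_matrix)
  ))
  cat(sprintf(
    "predictor boundary knots: [%.3g, %.3g]\n",
    x$pred_boundary[1], x$pred_boundary[2]
  ))
  invisible(x)
}

#' Predictor basis evaluated at new exposure values
#'
#' Evaluates the predictor natural-spline basis of a fitted cross-basis at
#' arbitrary exposure values, using the knots frozen at build time. Values
#' outside the boundary knots are permitted (linear extrapolation) but
#' flagged with an `extrapolated` attribute.
#' @param cb A `cross_basis` object.
#' @param values Numeric vector of exposure values.
#' @keywords internal
pred_basis_at <- function(cb, values) {
  m <- ncs_eval(values, cb$pred_knots, cb$pred_boundary)
  attr(m, "extrapolated") <- values < cb$pred_boundary[1] | values > cb$pred_boundary[2]
  m
}
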