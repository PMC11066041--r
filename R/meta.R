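#' Fixed-effect multivariate meta-analysis
#'
#' Inverse-variance pooling of city-level cross-basis coefficient vectors
#' under a common-truth assumption:
#' beta_pooled = (sum_j V_j^-1)^-1 (sum_j V_j^-1 beta_j),
#' vcov_pooled = (sum_j V_j^-1)^-1, with the Cochran-type heterogeneity
#' statistic Q = sum_j (beta_j - beta_pooled)' V_j^-1 (beta_j - beta_pooled).
#' All inversions go through Cholesky factorizations; a study whose vcov is
#' numerically singular (condition number above 1e12) is rejected by name.
#'
#' @param studies List of studies, each a list with `beta` (length-d vector),
#'   `vcov` (d x d symmetric positive-definite matrix) and optionally
#'   `label`.
#' @return An object of class `pooled_estimate`: `beta` (pooled vector),
#'   `vcov` (pooled matrix), `Q` (heterogeneity), `df_Q` ((J - 1) * d) and
#'   `labels`.
#' @export
fixed_effect_mvmeta <- function(studies) {
  if (length(studies) == 0L) {
    stop("fixed_effect_mvmeta: need at least one study", call. = FALSE)
  }
  labels <- vapply(seq_along(studies), function(j) {
    if (!is.null(studies[[j]]$label)) as.character(studies[[j]]$label)
    else sprintf("study%d", j)
  }, character(1))
  d <- length(studies[[1]]$beta)
  for (j in seq_along(studies)) {
    s <- studies[[j]]
    if (length(s$beta) != d || !all(dim(as.matrix(s$vcov)) == d)) {
      stop(sprintf(
        "fixed_effect_mvmeta: dimension mismatch in %s (expected d = %d)",
        labels[j], d
      ), call. = FALSE)
    }
  }
  Sinv_sum <- matrix(0, d, d)
  Sb_sum <- numeric(d)
  Sinv_list <- vector("list", length(studies))
  for (j in seq_along(studies)) {
    V <- as.matrix(studies[[j]]$vcov)
    V <- (V + t(V)) / 2
    if (kappa(V, exact = FALSE) > 1e12) {
      stop(sprintf(
        "fixed_effect_mvmeta: vcov of %s is numerically singular", labels[j]
      ), call. = FALSE)
    }
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      stop(sprintf(
        "fixed_effect_mvmeta: vcov of %s is not positive definite", labels[j]
      ), call. = FALSE)
    }
    Sinv <- chol2inv(ch)
    Sinv_list[[j]] <- Sinv
    Sinv_sum <- Sinv_sum + Sinv
    Sb_sum <- Sb_sum + drop(Sinv %*% studies[[j]]$beta)
  }
  ch_sum <- chol(Sinv_sum)
  vcov_pooled <- chol2inv(ch_sum)
  beta_pooled <- drop(vcov_pooled %*% Sb_sum)
  Q <- 0
  for (j in seq_along(studies)) {
    r <- studies[[j]]$beta - beta_pooled
    Q <- Q + drop(crossprod(r, Sinv_list[[j]] %*% r))
  }
  names(beta_pooled) <- names(studies[[1]]$beta)
  dimnames(vcov_pooled) <- list(names(beta_pooled), names(beta_pooled))
  structure(
    list(beta = beta_pooled, vcov = vcov_pooled, Q = max(0, Q),
         df_Q = (length(studies) - 1L) * d, labels = labels),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "fixed-effect multivariate pooling of %d studies (d = %d): Q = %.3f on %d df\n",
    length(x$labels), length(x$beta), x$Q, x$df_Q
  ))
  invisible(x)
}
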