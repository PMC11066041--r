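# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Natural cubic spline basis via the truncated-power representation with
# natural (linear-beyond-boundary) constraints. Knots include the boundary;
# returns the non-intercept basis {x, N_3, ..., N_K} spanning the same
# space as a df-column natural spline basis (df = K - 1 total knots K).
oracle_ns_truncated_power <- function(x, df, boundary) {
  knots <- seq(boundary[1], boundary[2], length.out = df + 1L)
  K <- length(knots)
  if (df == 1L) return(matrix(x, ncol = 1L))
  d <- function(k) {
    (pmax(0, x - knots[k])^3 - pmax(0, x - knots[K])^3) / (knots[K] - knots[k])
  }
  cols <- list(x)
  for (k in seq_len(K - 2L)) cols[[k + 1L]] <- d(k) - d(K - 1L)
  do.call(cbind, cols)
}

# Brute-force cross-basis: naive quadruple loop over (t, l, j, k) using the
# package's spline evaluator for the marginal bases but none of its
# accumulation code.
oracle_cross_basis_bruteforce <- function(exposure, L, df_p, df_l) {
  n <- length(exposure)
  boundary <- range(exposure)
  pk <- if (df_p == 1L) numeric(0) else
    seq(boundary[1], boundary[2], length.out = df_p + 1L)[2:df_p]
  lk <- if (df_l == 1L) numeric(0) else
    seq(0, L, length.out = df_l + 1L)[2:df_l]
  R <- lagriskr:::ncs_eval(exposure, pk, boundary)
  C <- lagriskr:::ncs_eval(0:L, lk, c(0, L))
  X <- matrix(0, n - L, df_p * df_l)
  for (t in (L + 1L):n) {
    for (j in seq_len(df_p)) {
      for (k in seq_len(df_l)) {
        s <- 0
        for (l in 0:L) s <- s + R[t - l, j] * C[l + 1L, k]
        X[t - L, (j - 1L) * df_l + k] <- s
      }
    }
  }
  X
}

# Newton-Raphson Poisson maximum likelihood with quasi-Poisson standard
# errors; direct score/Hessian iteration, no IRLS, no glm.fit.
oracle_poisson_newton <- function(y, X, tol = 1e-12, maxit = 50L) {
  X <- cbind(1, X)
  b <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1L))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- exp(eta)
    score <- drop(crossprod(X, y - mu))
    H <- crossprod(X * sqrt(mu))
    step <- solve(H, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(drop(X %*% b))
  n <- length(y)
  p <- ncol(X)
  phi <- sum((y - mu)^2 / mu) / (n - p)
  vcov <- phi * solve(crossprod(X * sqrt(mu)))
  list(coefficients = b, se = sqrt(diag(vcov)), phi = phi,
       loglik = sum(dpois(y, mu, log = TRUE)))
}

# Classic scalar inverse-variance fixed-effect pooling.
oracle_scalar_meta <- function(betas, vars) {
  w <- 1 / vars
  beta <- sum(w * betas) / sum(w)
  list(beta = beta, var = 1 / sum(w), Q = sum(w * (betas - beta)^2))
}

# Minimal three-table CSV fixture written into a temp dir; returns paths.
write_toy_tables <- function(dir, dates, counts, values, city = "Seoul",
                             disease = "asthma", pollutant = "pm10") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dates)
  adm <- data.frame(date = dates, city = city, disease = disease, count = counts)
  air <- data.frame(date = dates, city = city, pollutant = pollutant, value = values)
  met <- data.frame(date = dates, city = city, tavg = rnorm(n, 12, 5),
                    rh = runif(n, 30, 90), wind = runif(n, 0.5, 5),
                    dtr = runif(n, 2, 12), precip = rexp(n, 1))
  paths <- file.path(dir, c("admissions.csv", "airquality.csv", "meteorology.csv"))
  write.csv(adm, paths[1], row.names = FALSE)
  write.csv(air, paths[2], row.names = FALSE)
  write.csv(met, paths[3], row.names = FALSE)
  paths
}
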