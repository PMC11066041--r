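test_that("natural cubic spline basis degenerates, validates, and spans the right space", {
  x <- 0:10

  # df = 1 is a single linear column (affine in the input)
  b1 <- natural_cubic_basis(x, spline_spec(1))
  expect_equal(ncol(b1), 1L)
  fit <- lm(b1[, 1] ~ x)
  expect_equal(unname(fitted(fit)), unname(b1[, 1]), tolerance = 1e-12)

  # degenerate input and bad specs are rejected
  expect_error(natural_cubic_basis(rep(2, 10), spline_spec(2)), "distinct")
  expect_error(spline_spec(0), "df")

  # df = 3: linear functions lie in the span, so y = x is reproduced exactly
  b3 <- natural_cubic_basis(x, spline_spec(3))
  expect_equal(ncol(b3), 3L)
  fit_lin <- lm(x ~ b3)
  expect_equal(unname(fitted(fit_lin)), as.numeric(x), tolerance = 1e-9)

  # span matches the independent truncated-power natural-spline construction
  set.seed(11)
  y <- rnorm(11)
  oracle <- oracle_ns_truncated_power(x, 3L, range(x))
  expect_equal(fitted(lm(y ~ b3)), fitted(lm(y ~ oracle)), tolerance = 1e-8)

  # interior knots are equally spaced and strictly inside the boundary
  k <- attr(natural_cubic_basis(x, spline_spec(4)), "knots")
  expect_equal(k, c(2.5, 5, 7.5))
})

test_that("Fourier seasonal basis has the stated shape, phase and periodicity", {
  S <- fourier_basis(0:729, m = 365, K = 6)
  expect_equal(ncol(S), 12L)
  expect_equal(unname(S[1, ]), rep(c(0, 1), 6))
  expect_equal(S[1 + 365, ], S[1, ], tolerance = 1e-12)
  expect_true(all(S >= -1 & S <= 1))
  expect_error(fourier_basis(0:10, m = -1, K = 6), "period")
  expect_error(fourier_basis(0:10, m = 365, K = 0), "integer")
})

test_that("cross-basis matches the brute-force double-sum and its collapse cases", {
  set.seed(21)
  x <- runif(50, 10, 90)

  # random spec against the naive quadruple loop
  cb <- build_cross_basis(x, cross_basis_spec(5, 3, 3))
  expect_lt(max(abs(cb$matrix - oracle_cross_basis_bruteforce(x, 5L, 3L, 3L))), 1e-10)

  # L = 0 collapses to the predictor basis at same-day exposure
  cb0 <- build_cross_basis(x, cross_basis_spec(0, 3, 2))
  pred <- natural_cubic_basis(x, spline_spec(3))
  expect_equal(unname(cb0$matrix), unname(pred[, , drop = FALSE]),
               ignore_attr = TRUE, tolerance = 1e-12)

  # constant exposure (with frozen boundary knots): every usable row is
  # identical and equals R(c)_j * sum_l C(l)_k
  cbc <- build_cross_basis(rep(30, 20), cross_basis_spec(3, 2, 2, boundary = c(10, 50)))
  expect_lt(max(apply(cbc$matrix, 2, function(col) diff(range(col)))), 1e-12)
  Rc <- lagriskr:::ncs_eval(30, attr(natural_cubic_basis(c(10, 30, 50, 20, 40),
                                                         spline_spec(2, c(10, 50))),
                                     "knots"), c(10, 50))
  Csum <- colSums(cbc$lag_matrix)
  expected <- as.numeric(t(outer(Rc[1, ], Csum, `*`))) # lag index fastest
  expect_equal(unname(cbc$matrix[1, ]), expected, tolerance = 1e-12)

  # series shorter than L + 1 fails
  expect_error(build_cross_basis(x[1:4], cross_basis_spec(5, 3, 3)), "shorter")
})

test_that("cross-basis dimension bookkeeping holds across the default grid", {
  set.seed(31)
  x <- runif(80, 5, 95)
  for (L in c(1, 7, 14)) {
    for (df_p in 2:4) {
      for (df_l in 2:4) {
        cb <- build_cross_basis(x, cross_basis_spec(L, df_p, df_l))
        expect_equal(ncol(cb$matrix), df_p * df_l)
        expect_equal(nrow(cb$matrix), length(x) - L)
        expect_equal(cb$usable, (L + 1L):length(x))
      }
    }
  }
})
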