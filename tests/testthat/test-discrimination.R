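# Incomplete-gamma Q test, degrees of freedom, Hessian and effective
# parameter counting.

test_that("gamma_q agrees with the chi-square survival function over a wide grid", {
  for (f in c(1, 2, 3, 6, 11, 22, 50)) {
    for (chi2 in c(0, 0.5, 3.13, 12.52, 38.28, 94.286, 200)) {
      expect_equal(q_value(f, chi2),
                   pgamma(chi2 / 2, f / 2, lower.tail = FALSE),
                   tolerance = 1e-10, label = sprintf("F=%g chi2=%g", f, chi2))
    }
  }
})

test_that("q_value is 1 at chi2 = 0 and strictly decreasing in chi2", {
  expect_identical(q_value(6, 0), 1)
  grid <- seq(0.5, 120, by = 0.5)
  q <- vapply(grid, function(x) q_value(7, x), 1.0)
  expect_true(all(diff(q) < 0))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("q_value reproduces the study's printed discrimination statistics", {
  # (F, chi2) pairs printed with their Q values; verified against the
  # chi-square survival function before being frozen here
  cases <- list(
    list(f = 6, chi2 = 38.28, q = 9.9e-7),    # one-pool model, whole molecules
    list(f = 4, chi2 = 3.13, q = 0.536),      # channeled model, whole molecules
    list(f = 8, chi2 = 12.52, q = 0.129),     # channeled model with fragments
    list(f = 11, chi2 = 74.9, q = 1.42e-11),  # one-pool model with fragments
    list(f = 22, chi2 = 94.286, q = 6.325e-11))  # one-pool model, joint fit
  for (cs in cases) {
    expect_equal(q_value(cs$f, cs$chi2), cs$q, tolerance = 0.01,
                 label = sprintf("Q(F=%d, chi2=%g)", cs$f, cs$chi2))
  }
})

test_that("degrees of freedom arithmetic matches the reported pairs and rejects underdetermined input", {
  expect_identical(degrees_of_freedom(22, 16), 6L)
  expect_identical(degrees_of_freedom(22, 18), 4L)
  expect_identical(degrees_of_freedom(29, 21), 8L)
  expect_identical(degrees_of_freedom(29, 18), 11L)
  expect_identical(degrees_of_freedom(46, 24), 22L)
  expect_identical(degrees_of_freedom(10, 0), 10L)
  expect_error(degrees_of_freedom(5, 6), "underdetermined")
})

test_that("verdict applies the acceptance thresholds", {
  expect_identical(verdict(0.536), "accept")
  expect_identical(verdict(9.9e-7), "reject")
  expect_identical(verdict(0.01), "marginal")
  expect_identical(verdict(0.05), "marginal")   # boundary: accept needs Q > 0.05
  expect_identical(verdict(0.001), "reject")    # boundary: reject at Q <= 0.001
})

test_that("Gauss-Newton Hessian is exact for models linear in the parameters", {
  x <- seq(0, 1, length.out = 7)
  design <- cbind(1, x, x^2)
  sd <- rep(0.2, 7)
  predict_fn <- function(a) as.vector(design %*% a)
  expected <- 2 * t(design / sd) %*% (design / sd)
  for (step in c(1e-3, 1e-5)) {
    h <- gauss_newton_hessian(predict_fn, c(a0 = 0.3, a1 = 1.2, a2 = -0.5),
                              sd, step = step)
    expect_equal(unname(h$matrix), unname(expected), tolerance = 1e-6)
  }
})

test_that("a parameter the model ignores produces a zero row and a singular Hessian", {
  predict_fn <- function(a) a[1] * c(1, 2, 3)   # a[2] unused
  h <- gauss_newton_hessian(predict_fn, c(u = 1, v = 1), sd = 1)
  expect_equal(h$matrix[2, ], c(u = 0, v = 0))
  expect_true(h$rcond < 1e-10)
  expect_null(h$covariance)
  eff <- effective_parameter_count(h)
  expect_identical(eff$p_eff, 1L)
  expect_identical(eff$selected, "u")
})

test_that("effective parameter count equals rank for constructed PSD matrices", {
  set.seed(42)
  # full-rank well-conditioned
  a <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  dimnames(a) <- list(letters[1:5], letters[1:5])
  expect_identical(effective_parameter_count(a)$p_eff, 5L)
  # duplicated column/row: two perfectly correlated parameters
  b <- a
  b[, 5] <- b[, 4]; b[5, ] <- b[4, ]; b[5, 5] <- b[4, 4]
  expect_identical(effective_parameter_count(b)$p_eff, 4L)
  # random rank-r PSD built from r outer products
  for (r in c(2, 4, 6)) {
    p <- 8
    u <- matrix(rnorm(p * r), p, r)
    m <- u %*% t(u)
    dimnames(m) <- list(paste0("p", 1:p), paste0("p", 1:p))
    expect_identical(effective_parameter_count(m)$p_eff, as.integer(r),
                     label = paste("rank", r))
  }
})

test_that("effective parameter count is invariant under parameter reordering", {
  set.seed(7)
  u <- matrix(rnorm(7 * 4), 7, 4)
  m <- u %*% t(u)
  dimnames(m) <- list(paste0("p", 1:7), paste0("p", 1:7))
  perm <- sample(7)
  m2 <- m[perm, perm]
  expect_identical(effective_parameter_count(m)$p_eff,
                   effective_parameter_count(m2)$p_eff)
})

test_that("SVD covariance matches direct inversion on well-conditioned matrices", {
  set.seed(11)
  a <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  h <- hessian_analysis(a)
  expect_equal(h$covariance, solve(a), tolerance = 1e-10)
  expect_equal(diag(h$covariance), diag(solve(a)), tolerance = 1e-10)
})

test_that("discrimination_report assembles N, P_eff, F, Q and verdicts", {
  rep1 <- discrimination_report(22, 16, 38.28, model = "one-pool")
  expect_identical(rep1$f, 6L)
  expect_identical(rep1$verdict, "reject")
  rep2 <- discrimination_report(29, 21, 12.52, model = "channeled")
  expect_identical(rep2$f, 8L)
  expect_equal(rep2$q, 0.129, tolerance = 0.01)
  expect_identical(rep2$verdict, "accept")
  td <- tidy(rep2)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$n, 29L)
})
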