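test_that("the Sobol sequence reproduces its reference values", {
  # first eight points in four dimensions, from the Joe-Kuo direction
  # numbers (verified against an independent generator)
  ref <- matrix(c(0, 0, 0, 0,
                  0.5, 0.5, 0.5, 0.5,
                  0.75, 0.25, 0.25, 0.25,
                  0.25, 0.75, 0.75, 0.75,
                  0.375, 0.375, 0.625, 0.875,
                  0.875, 0.875, 0.125, 0.375,
                  0.625, 0.125, 0.875, 0.625,
                  0.125, 0.625, 0.375, 0.125),
                ncol = 4, byrow = TRUE)
  expect_equal(sobol_sequence(8, 4), ref)
  expect_identical(sobol_sequence(8, 4), sobol_sequence(8, 4))
  expect_equal(sobol_sequence(1, 2), matrix(0, 1, 2))
  expect_equal(dim(sobol_sequence(16, 28)), c(16, 28))
})

test_that("Sobol marginals are close to uniform", {
  U <- sobol_sequence(1024, 5)
  for (j in 1:5) {
    D <- suppressWarnings(ks.test(U[, j], "punif"))$statistic
    expect_lt(unname(D), 0.02)
  }
})

test_that("designs respect their physical ranges", {
  r14 <- param_ranges("14")
  X <- sobol_design(r14, 200)
  expect_equal(dim(X), c(200, 14))
  expect_true(all(sweep(X, 2, r14$lower, ">=")))
  expect_true(all(sweep(X, 2, r14$upper, "<=")))
  expect_identical(colnames(X), r14$name)
  # normalisation round-trip
  expect_equal(scale_to_ranges(normalize_to_ranges(X, r14), r14), X)
  L <- lhs_design(r14, 50, seed = 3)
  expect_true(all(sweep(L, 2, r14$lower, ">=") &
                  sweep(L, 2, r14$upper, "<=")))
  expect_identical(lhs_design(r14, 50, seed = 3), L)
})

test_that("a linear response is captured by the mean function alone", {
  set.seed(1)
  X <- cbind(x1 = runif(40), x2 = runif(40))
  y <- 2 + 3 * X[, 1] - X[, 2]
  em <- fit_emulator(X, y, n_restarts = 2, maxit = 40)
  pr <- predict_emulator(em, X)
  expect_equal(pr$mean, y, tolerance = 1e-5)
  Xn <- cbind(x1 = runif(25), x2 = runif(25))
  prn <- predict_emulator(em, Xn)
  expect_gt(r_squared(2 + 3 * Xn[, 1] - Xn[, 2], prn$mean), 0.999)
  # extrapolation follows the linear trend
  Xe <- cbind(x1 = c(1.2, 1.5), x2 = c(-0.2, 1.3))
  pre <- predict_emulator(em, Xe)
  expect_equal(pre$mean, 2 + 3 * Xe[, 1] - Xe[, 2], tolerance = 0.05)
})

test_that("predictive variance is small at data and grows away from it", {
  set.seed(2)
  X <- cbind(x1 = runif(30), x2 = runif(30))
  y <- sin(3 * X[, 1]) + X[, 2]^2
  em <- fit_emulator(X, y, n_restarts = 3, maxit = 60)
  pr_tr <- predict_emulator(em, X)
  expect_equal(pr_tr$mean, y, tolerance = 0.15)
  # variance at a training point sits at the jitter level
  expect_lt(max(pr_tr$var), 2 * em$jitter * em$var_scale * em$sd_y^2 + 1e-8)
  # moving off the cloud along an axis inflates the variance
  line <- cbind(x1 = c(0.5, 1.2, 2, 3), x2 = 0.5)
  prl <- predict_emulator(em, line)
  expect_true(all(diff(prl$var) > 0))
})

test_that("degenerate inputs are handled per contract", {
  set.seed(3)
  X <- cbind(x1 = c(runif(20), 0.4), x2 = c(runif(20), 0.7))
  X[21, ] <- X[1, ]                      # duplicated point
  y <- X[, 1] + rnorm(21, 0, 0.01)
  y[21] <- y[1] + 0.05                   # conflicting response
  expect_s3_class(fit_emulator(X, y, n_restarts = 2, maxit = 40),
                  "la_emulator")
  expect_error(fit_emulator(X, c(y[-21], NA), n_restarts = 1), "finite")
  Xr <- X; Xr[, 2] <- 2 * Xr[, 1]        # rank-deficient design
  expect_error(fit_emulator(Xr[1:10, ], y[1:10], n_restarts = 1,
                            ranges = data.frame(name = c("x1", "x2"),
                                                lower = 0, upper = 1)),
               "rank")
})

test_that("length-scales of a known GP draw are bracketed", {
  set.seed(4)
  n <- 60
  X <- cbind(x1 = runif(n), x2 = runif(n))
  D1 <- outer(X[, 1], X[, 1], "-")^2
  D2 <- outer(X[, 2], X[, 2], "-")^2
  K <- exp(-(D1 / 0.3^2 + D2 / 0.3^2))
  y <- drop(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n))
  em <- fit_emulator(X, y, n_restarts = 4, maxit = 80, basis = "linear",
                     jitter_bounds = c(1e-8, 1))
  expect_true(all(em$delta > 0.3 / 5 & em$delta < 0.3 * 5))
})

test_that("predictions are invariant to an input-range rescaling", {
  set.seed(5)
  X <- cbind(a = runif(30, 1, 5), b = runif(30, 2, 4))
  y <- X[, 1] * 2 + sin(X[, 2])
  r1 <- data.frame(name = c("a", "b"), lower = c(1, 2), upper = c(5, 4))
  r2 <- transform(r1, lower = lower * 10, upper = upper * 10)
  em1 <- fit_emulator(X, y, ranges = r1, n_restarts = 2, maxit = 40)
  em2 <- fit_emulator(X * 10, y, ranges = r2, n_restarts = 2, maxit = 40)
  Xs <- cbind(a = runif(10, 1, 5), b = runif(10, 2, 4))
  expect_equal(predict_emulator(em1, Xs)$mean,
               predict_emulator(em2, Xs * 10)$mean, tolerance = 1e-6)
})

test_that("the log output transform reproduces a positive response", {
  set.seed(6)
  X <- cbind(x1 = runif(40), x2 = runif(40))
  y <- exp(1 + 2 * X[, 1] - X[, 2])
  em <- fit_emulator(X, y, n_restarts = 2, maxit = 40,
                     output_transform = "log")
  pr <- predict_emulator(em, X)
  expect_equal(pr$mean, y, tolerance = 0.02)
  expect_true(all(pr$var >= 0))
  expect_error(fit_emulator(X, y - 5, output_transform = "log"),
               "positive")
})

test_that("accuracy scores match their hand-computed cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_equal(ise(c(0, 0), c(0, 0), c(1, 1)), 1)
  expect_equal(ise(c(100, -100), c(0, 0), c(1e-4, 1e-4)), 0)
  expect_equal(ise(c(rep(0, 9), 10), rep(0, 10), rep(1, 10)), 0.9)
})

test_that("cross-validation folds partition the design", {
  set.seed(7)
  X <- cbind(x1 = runif(40), x2 = runif(40))
  y <- 1 + X[, 1] + 2 * X[, 2]
  cv <- cross_validate(X, y, k = 5, seed = 3, n_restarts = 2, maxit = 40)
  expect_length(cv$folds, 40)
  expect_setequal(unique(cv$folds), 1:5)
  expect_equal(as.vector(table(cv$folds)), rep(8, 5))
  expect_gt(cv$mean_R2, 0.999)
  expect_equal(cv$mean_ISE, 1)
})
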