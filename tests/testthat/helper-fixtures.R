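# Session-cached fixtures shared across test files. The 200-point
# 14-parameter design with its simulations and cross-validation reports
# is the expensive one; it is built once on first use.

.fx <- new.env(parent = emptyenv())

fx_design200 <- function() {
  if (is.null(.fx$design200)) {
    ranges <- param_ranges("14")
    X <- sobol_design(ranges, 200)
    Y <- run_design(X)
    .fx$design200 <- list(X = X, Y = Y, ranges = ranges)
  }
  .fx$design200
}

fx_cv_reports <- function() {
  if (is.null(.fx$cv)) {
    d <- fx_design200()
    eb <- feature_emulator_basis(default_anatomy())
    .fx$cv <- lapply(seq_len(ncol(d$Y)), function(j)
      cross_validate(d$X, d$Y[, j], k = 5, seed = 101, ranges = d$ranges,
                     n_restarts = 3, maxit = 60, extra_basis = eb,
                     output_transform = "log"))
    names(.fx$cv) <- colnames(d$Y)
  }
  .fx$cv
}

fx_emulators14 <- function() {
  if (is.null(.fx$em14)) {
    d <- fx_design200()
    .fx$em14 <- fit_emulators(
      d$X, d$Y, ranges = d$ranges, n_restarts = 3, maxit = 60,
      seed = 7, extra_basis = feature_emulator_basis(default_anatomy()),
      output_transform = "log")
  }
  .fx$em14
}

# small 2-d toy emulator set over an additive function, for
# history-matching plumbing tests that do not need the LA model
fx_toy_emulators <- function() {
  if (is.null(.fx$toy)) {
    ranges <- data.frame(name = c("x1", "x2"), lower = 0, upper = 1)
    X <- sobol_design(ranges, 30)
    Y <- cbind(f1 = X[, 1] + 2 * X[, 2], f2 = 3 * X[, 1] - X[, 2] + 4)
    ems <- fit_emulators(X, Y, ranges = ranges, n_restarts = 2, maxit = 40)
    .fx$toy <- list(ranges = ranges, X = X, Y = Y, emulators = ems)
  }
  .fx$toy
}
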