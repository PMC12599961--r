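#' Observation set for calibration
#'
#' Targets and observation standard deviations for the seven output
#' features, in canonical [feature_names()] order, with a provenance
#' record (ground-truth inputs, seed, noise level) when generated
#' synthetically.
#'
#' @param mu named numeric vector of feature targets
#' @param sigma named numeric vector of observation SDs (> 0)
#' @param provenance optional list recording how the observations arose
#' @return an object of class `la_observations`
#' @export
observations <- function(mu, sigma, provenance = NULL) {
  fn <- feature_names()
  mu <- unlist(mu)[fn]; sigma <- unlist(sigma)[fn]
  stopifnot(all(is.finite(mu)), all(is.finite(sigma)), all(sigma > 0))
  structure(list(mu = mu, sigma = sigma, provenance = provenance),
            class = "la_observations")
}

#' @method print la_observations
#' @export
print.la_observations <- function(x, ...) {
  cat("Observations (7 features):\n")
  print(round(rbind(mu = x$mu, sigma = x$sigma), 3))
  invisible(x)
}

#' Implausibility measure
#'
#' I(x) = max over features i of
#' |E\[f_i(x)\] - mu_i| / sqrt(Var\[f_i(x)\] + sigma_i^2),
#' the standardised discrepancy between emulator predictions and the
#' observed targets, accounting for both emulator variance and
#' observation error.
#'
#' @param pred_means,pred_vars matrices (points x features) of emulator
#'   predictions
#' @param obs an [observations()] object
#' @return numeric vector of implausibilities, one per point
#' @export
implausibility <- function(pred_means, pred_vars, obs) {
  pred_means <- as.matrix(pred_means); pred_vars <- as.matrix(pred_vars)
  stopifnot(inherits(obs, "la_observations"),
            ncol(pred_means) == length(obs$mu),
            all(dim(pred_means) == dim(pred_vars)))
  tot_var <- sweep(pred_vars, 2, obs$sigma^2, "+")
  if (any(tot_var <= 0)) stop("non-positive total variance")
  Z <- abs(sweep(pred_means, 2, obs$mu)) / sqrt(tot_var)
  apply(Z, 1, max)
}

#' Classify points as non-implausible (NROY)
#'
#' A point is retained iff its implausibility does not exceed the
#' threshold; only strict exceedance rules a point out, so the boundary
#' I = threshold is inclusive.
#'
#' @param I implausibility values
#' @param threshold positive threshold
#' @return logical mask, TRUE = retained (NROY)
#' @export
classify_nroy <- function(I, threshold) {
  stopifnot(threshold > 0)
  I <= threshold
}

#' Space-filling subsample by greedy maximin
#'
#' Selects n points from a candidate cloud maximising spread in
#' normalised coordinates: the first point is the candidate furthest
#' from the cloud centroid (ties broken by index), and each subsequent
#' point is the candidate furthest from the current selection. Fully
#' deterministic; the seed is recorded for provenance but the
#' selection does not depend on it.
#'
#' @param points candidate matrix (physical units)
#' @param n number of points to select (<= nrow(points))
#' @param seed recorded for provenance
#' @param ranges optional ranges for normalisation; defaults to the
#'   candidate cloud's column ranges
#' @return the selected rows of `points`
#' @export
diverse_subsample <- function(points, n, seed = 1L, ranges = NULL) {
  points <- as.matrix(points)
  m <- nrow(points)
  stopifnot(n >= 1, n <= m)
  if (n == m) return(points)
  if (is.null(ranges)) {
    lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  } else {
    lo <- ranges$lower; hi <- ranges$upper
  }
  U <- sweep(sweep(points, 2, lo), 2, pmax(hi - lo, 1e-12), "/")
  sel <- integer(n)
  ctr <- colMeans(U)
  sel[1] <- which.max(rowSums(sweep(U, 2, ctr)^2))
  mind <- rowSums(sweep(U, 2, U[sel[1], ])^2)
  if (n > 1) for (k in 2:n) {
    sel[k] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(U, 2, U[sel[k], ])^2))
  }
  points[sel, , drop = FALSE]
}

#' History-matching configuration
#'
#' Bundles the wave protocol: test-cloud size, per-wave simulation
#' budgets (a larger first wave that also trains the initial emulators,
#' then a fixed refill), the implausibility threshold schedule (start
#' 3.5, decrement 0.5 per wave to a floor of 3.0 per the three-sigma
#' rule, then held), the NROY-fraction convergence tolerance, and the
#' seed. Full-study defaults follow the published protocol; tests and
#' examples pass reduced budgets explicitly.
#'
#' @param n_test test-cloud size per wave
#' @param n_simul_wave1 simulations in wave 1 (emulator training set)
#' @param n_simul simulations added per subsequent wave
#' @param threshold_start,threshold_step,threshold_floor threshold
#'   schedule
#' @param convergence_tol stop when the NROY fraction of the reference
#'   cloud changes by less than this between waves
#' @param max_waves hard cap on waves
#' @param seed integer seed
#' @return list of class `hm_config`
#' @export
hm_config <- function(n_test = 100000, n_simul_wave1 = 200, n_simul = 100,
                      threshold_start = 3.5, threshold_step = 0.5,
                      threshold_floor = 3.0, convergence_tol = 0.01,
                      max_waves = 10, seed = 1L) {
  stopifnot(threshold_floor <= threshold_start, n_test > 0,
            n_simul_wave1 > 0, n_simul > 0, convergence_tol > 0)
  structure(list(n_test = n_test, n_simul_wave1 = n_simul_wave1,
                 n_simul = n_simul, threshold_start = threshold_start,
                 threshold_step = threshold_step,
                 threshold_floor = threshold_floor,
                 convergence_tol = convergence_tol,
                 max_waves = max_waves, seed = as.integer(seed)),
            class = "hm_config")
}

# Threshold for wave w under the schedule.
hm_threshold <- function(config, wave) {
  max(config$threshold_start - (wave - 1) * config$threshold_step,
      config$threshold_floor)
}

#' Refill the test cloud inside the current NROY region
#'
#' Builds the next wave's test set: fresh Latin-hypercube candidates in
#' the original box plus Gaussian jitter around the retained points
#' (jitter SD 5% of each range, clipped to the box), filtered to
#' implausibility at most `threshold` under the current emulators, and
#' truncated to `n_test`. If a capped number of proposal rounds cannot
#' produce `n_test` survivors the available ones are returned with a
#' warning.
#'
#' @param nroy_points retained points from the current wave (non-empty)
#' @param ranges the original design box
#' @param n_test target cloud size
#' @param emulators current emulator list
#' @param threshold current implausibility threshold
#' @param obs the [observations()] being matched
#' @param seed seed
#' @param max_rounds proposal-round cap
#' @return matrix of test points with attribute `composition`
#' @export
refill_test_set <- function(nroy_points, ranges, n_test, emulators,
                            threshold, obs, seed = 1L, max_rounds = 20) {
  nroy_points <- as.matrix(nroy_points)
  stopifnot(nrow(nroy_points) >= 1)
  d <- nrow(ranges)
  span <- ranges$upper - ranges$lower
  kept <- matrix(numeric(0), 0, d, dimnames = list(NULL, ranges$name))
  n_lhs_kept <- 0L
  round <- 0L
  while (nrow(kept) < n_test && round < max_rounds) {
    round <- round + 1L
    n_prop <- max(n_test, 2000L)
    half <- floor(n_prop / 2)
    Xl <- lhs_design(ranges, half, seed = seed + 31L * round)
    idx <- with_seed(seed + 131L * round,
                     sample.int(nrow(nroy_points), n_prop - half,
                                replace = TRUE))
    noise <- with_seed(seed + 257L * round,
                       matrix(stats::rnorm((n_prop - half) * d), ncol = d))
    Xj <- nroy_points[idx, , drop = FALSE] +
      sweep(noise, 2, 0.05 * span, "*")
    Xj <- pmin(pmax(Xj, matrix(ranges$lower, nrow(Xj), d, byrow = TRUE)),
               matrix(ranges$upper, nrow(Xj), d, byrow = TRUE))
    colnames(Xj) <- ranges$name
    X <- rbind(Xl, Xj)
    pr <- predict_emulators(emulators, X)
    ok <- classify_nroy(implausibility(pr$mean, pr$var, obs), threshold)
    n_lhs_kept <- n_lhs_kept + sum(ok[seq_len(half)])
    kept <- rbind(kept, X[ok, , drop = FALSE])
  }
  if (nrow(kept) < n_test)
    warning("refill produced only ", nrow(kept), " of ", n_test,
            " requested test points")
  out <- kept[seq_len(min(n_test, nrow(kept))), , drop = FALSE]
  attr(out, "composition") <- c(lhs_kept = n_lhs_kept,
                                total_kept = nrow(kept), rounds = round)
  out
}

#' Run multi-wave history matching
#'
#' The wave loop: simulate a Sobol design (wave 1), fit per-feature
#' emulators on all simulations so far, score a fixed reference cloud of
#' the original box (the measure by which NROY reduction is reported)
#' and the current test cloud, classify by the scheduled threshold,
#' record the NROY fraction, select a space-filling batch of retained
#' points, simulate them, and continue with a decremented threshold.
#' Stops when the reference-cloud NROY fraction changes by less than the
#' convergence tolerance between waves, when the wave cap is reached, or
#' with an error if the NROY set empties (model-data incompatibility).
#'
#' @param obs an [observations()] object
#' @param ranges calibration box (typically [param_ranges()] mode "9")
#' @param config an [hm_config()]
#' @param anatomy,grid forward-model setting
#' @param n_restarts,maxit emulator fitting budget per wave
#' @param extra_basis,output_transform emulator protocol passed to
#'   [fit_emulators()]; defaults are the study protocol (log output
#'   transform, physics-informed extra basis of
#'   [feature_emulator_basis()])
#' @return object of class `hm_result`: list of per-wave records
#'   (`threshold`, `nroy_fraction`, `n_train`, `nroy_test` sample,
#'   emulators of the final wave, cumulative design and features, and
#'   the convergence flag)
#' @export
run_waves <- function(obs, ranges, config = hm_config(),
                      anatomy = default_anatomy(), grid = time_grid(),
                      n_restarts = 3, maxit = 50,
                      extra_basis = feature_emulator_basis(anatomy),
                      output_transform = "log") {
  stopifnot(inherits(obs, "la_observations"), inherits(config, "hm_config"))
  X <- sobol_design(ranges, config$n_simul_wave1)
  Y <- run_design(X, anatomy, grid)
  reference <- lhs_design(ranges, config$n_test, seed = config$seed)
  test <- reference
  waves <- list()
  frac_prev <- 1
  converged <- FALSE
  emulators <- NULL
  for (w in seq_len(config$max_waves)) {
    thr <- hm_threshold(config, w)
    # refits in later waves warm-start from the previous wave's
    # hyperparameters
    emulators <- lapply(seq_len(ncol(Y)), function(j)
      fit_emulator(X, Y[, j], ranges = ranges, n_restarts = n_restarts,
                   seed = config$seed + 1000L * w + j, maxit = maxit,
                   extra_basis = extra_basis,
                   output_transform = output_transform,
                   init_theta = if (!is.null(emulators))
                     emulators[[j]]$theta))
    names(emulators) <- colnames(Y)
    pr_ref <- predict_emulators(emulators, reference)
    I_ref <- implausibility(pr_ref$mean, pr_ref$var, obs)
    frac <- mean(classify_nroy(I_ref, thr))
    if (identical(test, reference)) {
      I_test <- I_ref
    } else {
      pr_test <- predict_emulators(emulators, test)
      I_test <- implausibility(pr_test$mean, pr_test$var, obs)
    }
    keep <- classify_nroy(I_test, thr)
    if (!any(keep))
      stop("empty NROY region at wave ", w,
           ": model and observations appear incompatible")
    nroy_test <- test[keep, , drop = FALSE]
    waves[[w]] <- list(wave = w, threshold = thr, nroy_fraction = frac,
                       n_train = nrow(X), n_nroy_test = nrow(nroy_test))
    if (w > 1 && abs(frac - frac_prev) < config$convergence_tol) {
      converged <- TRUE
      break
    }
    frac_prev <- frac
    if (w == config$max_waves) break
    newX <- diverse_subsample(nroy_test, min(config$n_simul,
                                             nrow(nroy_test)),
                              seed = config$seed + w, ranges = ranges)
    newY <- run_design(newX, anatomy, grid)
    X <- rbind(X, newX)
    Y <- rbind(Y, newY)
    test <- refill_test_set(nroy_test, ranges, config$n_test, emulators,
                            hm_threshold(config, w + 1), obs,
                            seed = config$seed + 7919L * w)
  }
  structure(list(waves = waves, emulators = emulators,
                 X = X, Y = Y, nroy = nroy_test, reference = reference,
                 obs = obs, ranges = ranges, config = config,
                 converged = converged),
            class = "hm_result")
}

#' @method print hm_result
#' @export
print.hm_result <- function(x, ...) {
  cat("History matching:", length(x$waves), "waves",
      if (x$converged) "(converged)" else "(wave cap reached)", "\n")
  for (w in x$waves)
    cat(sprintf("  wave %d: threshold %.1f, NROY fraction %.3f, %d sims\n",
                w$wave, w$threshold, w$nroy_fraction, w$n_train))
  invisible(x)
}

#' Bounding box of the final NROY sample
#'
#' Per-parameter min/max of the retained test points, used as the
#' uniform prior box for posterior sampling.
#'
#' @param hm an `hm_result`
#' @return a ranges data.frame (`name`, `lower`, `upper`)
#' @export
nroy_box <- function(hm) {
  stopifnot(inherits(hm, "hm_result"))
  data.frame(name = colnames(hm$nroy),
             lower = apply(hm$nroy, 2, min),
             upper = apply(hm$nroy, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}
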