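#' Emulator-aware Gaussian log-likelihood
#'
#' Log of the product over features of normal densities with total
#' variance sigma_i^2 + Var\[f_i(x)\]:
#' sum_i \[ -0.5 log(2 pi (sigma_i^2 + Var_i)) -
#'          (mu_i - E_i)^2 / (2 (sigma_i^2 + Var_i)) \],
#' accounting for both the observation error and the emulator variance.
#'
#' @param X matrix of input points (rows) or a single named vector
#' @param emulators list of per-feature `la_emulator` objects
#' @param obs an [observations()] object
#' @return numeric vector of log-likelihoods, one per point
#' @export
log_likelihood <- function(X, emulators, obs) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  pr <- predict_emulators(emulators, X)
  gaussian_loglik(pr$mean, pr$var, obs)
}

# Log-likelihood from precomputed predictions (shared with tests'
# product-form oracle route).
gaussian_loglik <- function(pred_means, pred_vars, obs) {
  pred_means <- as.matrix(pred_means); pred_vars <- as.matrix(pred_vars)
  tot <- sweep(pred_vars, 2, obs$sigma^2, "+")
  if (any(tot <= 0)) stop("non-positive total variance")
  dev <- sweep(pred_means, 2, obs$mu)
  rowSums(-0.5 * log(2 * pi * tot) - dev^2 / (2 * tot))
}

#' Uniform log-prior on a box
#'
#' 0 (up to a constant) inside the closed box, -Inf outside.
#'
#' @param X matrix of points (rows) or a single vector
#' @param box ranges data.frame (`name`, `lower`, `upper`)
#' @return numeric vector of log-prior values
#' @export
log_prior <- function(X, box) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  inside <- apply(X, 1, function(x)
    all(x >= box$lower - 1e-12) && all(x <= box$upper + 1e-12))
  ifelse(inside, 0, -Inf)
}

# Integrated autocorrelation time of a walkers x steps matrix of one
# scalar chain quantity, following the ensemble-mean autocovariance
# approach with an adaptive window (c = 5).
integrated_autocorr_time <- function(chain_ws) {
  m <- colMeans(chain_ws)      # ensemble mean per step
  m <- m - mean(m)
  n <- length(m)
  if (n < 10 || stats::sd(m) == 0) return(NA_real_)
  ac <- stats::acf(m, lag.max = n - 1, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  rho <- ac / ac[1]
  tau <- 2 * cumsum(rho) - 1
  window <- which(seq_along(tau) >= 5 * tau)
  if (length(window) == 0) return(tau[length(tau)])
  tau[window[1]]
}

# Rank-normalised split-Rhat of a walkers x steps matrix.
split_rhat <- function(chain_ws) {
  n <- ncol(chain_ws)
  half <- floor(n / 2)
  if (half < 4) return(NA_real_)
  chains <- rbind(chain_ws[, seq_len(half), drop = FALSE],
                  chain_ws[, half + seq_len(half), drop = FALSE])
  r <- matrix(rank(chains, ties.method = "average"), nrow(chains))
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  W <- mean(apply(z, 1, stats::var))
  B <- half * stats::var(rowMeans(z))
  sqrt((half - 1) / half + B / (W * half))
}

#' Affine-invariant ensemble sampler
#'
#' Goodman-Weare stretch moves (scale parameter a = 2) over an ensemble
#' of walkers, updated in two half-ensembles so the log-posterior can be
#' evaluated on whole blocks of proposals at once. Returns thinned
#' post-burn-in samples with per-sample log-posteriors, the MAP sample,
#' acceptance statistics, and convergence diagnostics (integrated
#' autocorrelation time and rank-normalised split-Rhat per dimension).
#' If the largest autocorrelation time exceeds steps / 50 the run is
#' extended by doubling the step count, up to `max_extensions` times.
#'
#' @param log_post function taking a matrix of points (rows) and
#'   returning a vector of log-posterior values
#' @param init matrix of initial walker positions (n_walkers x d),
#'   finite log-posterior required for at least one walker
#' @param n_walkers number of walkers (>= 2 d)
#' @param n_steps steps per walker
#' @param burn_in steps discarded from the start
#' @param thin thinning stride
#' @param seed integer seed; fixed seed gives bit-identical chains
#' @param a stretch scale parameter
#' @param max_extensions maximum step-doubling rounds on non-convergence
#' @return object of class `la_posterior`
#' @export
ensemble_sample <- function(log_post, init, n_walkers = 18,
                            n_steps = 100000, burn_in = 10000, thin = 10,
                            seed = 1L, a = 2, max_extensions = 3) {
  init <- as.matrix(init)
  d <- ncol(init)
  stopifnot(nrow(init) == n_walkers, n_walkers >= 2 * d,
            burn_in < n_steps, thin >= 1)
  lp <- log_post(init)
  if (all(!is.finite(lp)))
    stop("all walkers start at zero posterior density")
  # nudge any non-finite starters onto the best starting walker
  bad <- !is.finite(lp)
  if (any(bad)) {
    init[bad, ] <- init[rep(which.max(lp), sum(bad)), , drop = FALSE]
    lp <- log_post(init)
  }

  run_chain <- function(pos, lp, n_steps, rng_seed) {
    half1 <- seq_len(floor(n_walkers / 2))
    half2 <- setdiff(seq_len(n_walkers), half1)
    stored <- array(NA_real_, c(n_walkers, n_steps, d))
    stored_lp <- matrix(NA_real_, n_walkers, n_steps)
    accept <- 0L
    set.seed(rng_seed)
    for (s in seq_len(n_steps)) {
      for (halves in list(c(1, 2), c(2, 1))) {
        mov <- if (halves[1] == 1) half1 else half2
        oth <- if (halves[1] == 1) half2 else half1
        z <- (1 + (a - 1) * stats::runif(length(mov)))^2 / a
        partners <- oth[sample.int(length(oth), length(mov),
                                   replace = TRUE)]
        prop <- pos[partners, , drop = FALSE] +
          z * (pos[mov, , drop = FALSE] - pos[partners, , drop = FALSE])
        lp_prop <- log_post(prop)
        logr <- (d - 1) * log(z) + lp_prop - lp[mov]
        acc <- log(stats::runif(length(mov))) < logr
        acc[!is.finite(lp_prop)] <- FALSE
        pos[mov[acc], ] <- prop[acc, , drop = FALSE]
        lp[mov[acc]] <- lp_prop[acc]
        accept <- accept + sum(acc)
      }
      stored[, s, ] <- pos
      stored_lp[, s] <- lp
    }
    list(pos = pos, lp = lp, stored = stored, stored_lp = stored_lp,
         accept_rate = accept / (n_steps * n_walkers))
  }

  ext <- 0L
  steps_now <- n_steps
  burn_now <- burn_in
  repeat {
    run <- run_chain(init, lp, steps_now, seed + ext)
    keep <- seq(burn_now + 1, steps_now, by = thin)
    tau <- vapply(seq_len(d), function(j)
      integrated_autocorr_time(run$stored[, , j]), numeric(1))
    rhat <- vapply(seq_len(d), function(j)
      split_rhat(run$stored[, keep, j, drop = TRUE]), numeric(1))
    if (ext >= max_extensions ||
        all(is.na(tau)) || max(tau, na.rm = TRUE) <= steps_now / 50)
      break
    ext <- ext + 1L
    steps_now <- steps_now * 2L
    burn_now <- burn_now * 2L
  }

  samples <- do.call(rbind, lapply(keep, function(s) run$stored[, s, ]))
  lps <- as.numeric(run$stored_lp[, keep])
  colnames(samples) <- colnames(init)
  map_i <- which.max(lps)
  structure(list(samples = samples, log_post = lps,
                 map = samples[map_i, ], map_log_post = lps[map_i],
                 n_walkers = n_walkers, n_steps = steps_now,
                 burn_in = burn_now, thin = thin, seed = seed,
                 extensions = ext, accept_rate = run$accept_rate,
                 tau = tau, rhat = rhat),
            class = "la_posterior")
}

#' @method print la_posterior
#' @export
print.la_posterior <- function(x, ...) {
  cat("Ensemble posterior:", nrow(x$samples), "samples (",
      x$n_walkers, "walkers x", x$n_steps, "steps, burn-in",
      x$burn_in, ", thin", x$thin, ")\n")
  cat("  acceptance:", signif(x$accept_rate, 3),
      " max tau:", signif(max(x$tau, na.rm = TRUE), 3),
      " max Rhat:", signif(max(x$rhat, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' MAP sample and nearest simulated neighbour
#'
#' The MAP is the stored sample of maximal log-posterior; the neighbour
#' is the simulated design point minimising range-normalised Euclidean
#' distance to the MAP (ties broken by first index), so a simulated
#' (rather than emulated) parameter set can be reported alongside the
#' MAP.
#'
#' @param posterior an `la_posterior`
#' @param simulated_points matrix of simulated design points
#' @param ranges optional ranges for distance normalisation; defaults to
#'   the simulated cloud's column ranges
#' @return list with `map` and `neighbour` (named vectors) and
#'   `neighbour_index`
#' @export
map_and_neighbour <- function(posterior, simulated_points, ranges = NULL) {
  stopifnot(inherits(posterior, "la_posterior"))
  S <- as.matrix(simulated_points)
  stopifnot(nrow(S) >= 1)
  if (is.null(ranges)) {
    lo <- apply(S, 2, min); hi <- apply(S, 2, max)
  } else {
    lo <- ranges$lower; hi <- ranges$upper
  }
  span <- pmax(hi - lo, 1e-12)
  D <- sweep(sweep(S, 2, posterior$map), 2, span, "/")
  i <- which.min(rowSums(D^2))
  list(map = posterior$map, neighbour = S[i, ], neighbour_index = i)
}

#' Credible intervals and corner-contour mass levels
#'
#' Equal-tailed 95% credible intervals per parameter, plus the
#' bivariate sample-mass contour levels corresponding to 0.5, 1, 1.5
#' and 2 sigma of a 2-d Gaussian, whose exact values are
#' 1 - exp(-k^2 / 2) (11.8%, 39.3%, 67.5%, 86.4%).
#'
#' @param posterior an `la_posterior` (or a samples matrix)
#' @param level interval mass (default 0.95)
#' @return list with `intervals` (data.frame: parameter, lower, median,
#'   upper, width) and `contour_levels`
#' @export
credible_summaries <- function(posterior, level = 0.95) {
  S <- if (inherits(posterior, "la_posterior")) posterior$samples
       else as.matrix(posterior)
  stopifnot(nrow(S) >= 100)
  alpha <- (1 - level) / 2
  qs <- apply(S, 2, stats::quantile, probs = c(alpha, 0.5, 1 - alpha))
  intervals <- data.frame(parameter = colnames(S) %||%
                            paste0("x", seq_len(ncol(S))),
                          lower = qs[1, ], median = qs[2, ],
                          upper = qs[3, ], width = qs[3, ] - qs[1, ],
                          row.names = NULL, stringsAsFactors = FALSE)
  k <- c(0.5, 1, 1.5, 2)
  list(intervals = intervals,
       contour_levels = stats::setNames(1 - exp(-k^2 / 2),
                                        paste0(k, "sigma")))
}
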