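test_that("the emulator-aware likelihood equals its product form", {
  toy <- fx_toy_emulators()
  obs <- structure(list(mu = c(1.5, 4.5), sigma = c(0.3, 0.5),
                        provenance = NULL), class = "la_observations")
  set.seed(21)
  Xs <- cbind(x1 = runif(5), x2 = runif(5))
  ll <- log_likelihood(Xs, toy$emulators, obs)
  pr <- predict_emulators(toy$emulators, Xs)
  # independent product-form evaluation feature by feature
  ll_oracle <- vapply(1:5, function(i)
    sum(vapply(1:2, function(j)
      stats::dnorm(obs$mu[j], pr$mean[i, j],
                   sqrt(pr$var[i, j] + obs$sigma[j]^2), log = TRUE),
      numeric(1))), numeric(1))
  expect_equal(ll, ll_oracle)
  # pulling a target away strictly lowers the likelihood
  obs_far <- obs; obs_far$mu[1] <- obs$mu[1] + 3
  expect_true(all(log_likelihood(Xs, toy$emulators, obs_far) < ll))
})

test_that("a perfectly matched single feature recovers the normal constant", {
  # emulator of a constant function predicts mu with ~zero variance
  set.seed(22)
  X <- cbind(x1 = runif(25), x2 = runif(25))
  y <- rep(2, 25) + rnorm(25, 0, 1e-9)
  em <- fit_emulator(X, y, n_restarts = 1, maxit = 30,
                     jitter_bounds = c(1e-10, 1e-8))
  obs <- structure(list(mu = 2, sigma = 1, provenance = NULL),
                   class = "la_observations")
  ll <- log_likelihood(c(x1 = 0.5, x2 = 0.5), list(em), obs)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-3)
})

test_that("the uniform prior is flat inside the closed box", {
  box <- data.frame(name = c("a", "b"), lower = c(0, -1), upper = c(1, 1))
  expect_equal(log_prior(c(0.5, 0), box), 0)
  expect_equal(log_prior(c(0, -1), box), 0)       # boundary included
  expect_equal(log_prior(c(1, 1), box), 0)
  expect_equal(log_prior(c(1.01, 0), box), -Inf)
  expect_equal(log_prior(rbind(c(0.5, 0), c(-2, 0)), box), c(0, -Inf))
})

test_that("the ensemble sampler reproduces a Gaussian target", {
  lp <- function(X) -0.5 * rowSums(X^2)
  set.seed(23)
  init <- matrix(rnorm(18 * 2, sd = 0.5), 18, 2,
                 dimnames = list(NULL, c("x1", "x2")))
  post <- ensemble_sample(lp, init, n_walkers = 18, n_steps = 4000,
                          burn_in = 500, thin = 5, seed = 2,
                          max_extensions = 0)
  expect_s3_class(post, "la_posterior")
  expect_true(post$accept_rate > 0 && post$accept_rate < 1)
  expect_lt(max(abs(colMeans(post$samples))), 0.1)
  S <- stats::cov(post$samples)
  expect_equal(diag(S), c(x1 = 1, x2 = 1), tolerance = 0.1)
  expect_lt(abs(S[1, 2]), 0.1)
  # the MAP sample carries the maximal stored log-posterior
  expect_equal(post$map_log_post, max(post$log_post))
  expect_lt(sum(post$map^2), 1)
  # a fixed seed reproduces the chains bit for bit
  post2 <- ensemble_sample(lp, init, n_walkers = 18, n_steps = 4000,
                           burn_in = 500, thin = 5, seed = 2,
                           max_extensions = 0)
  expect_identical(post$samples, post2$samples)
  # all walkers at zero density is rejected
  expect_error(ensemble_sample(function(X) rep(-Inf, nrow(X)), init,
                               n_walkers = 18, n_steps = 100,
                               burn_in = 10),
               "zero posterior")
})

test_that("MAP neighbour lookup minimises range-normalised distance", {
  post <- structure(list(map = c(x = 0.5)), class = "la_posterior")
  pts <- matrix(c(0.1, 0.45, 0.9), ncol = 1, dimnames = list(NULL, "x"))
  mn <- map_and_neighbour(post, pts)
  expect_equal(unname(mn$neighbour), 0.45)
  expect_equal(mn$neighbour_index, 2)
  # a simulated set containing the MAP returns the MAP itself
  pts2 <- rbind(pts, 0.5)
  expect_equal(unname(map_and_neighbour(post, pts2)$neighbour), 0.5)
  # per-axis rescaling leaves the choice unchanged
  post2 <- structure(list(map = c(x = 0.5, y = 500)),
                     class = "la_posterior")
  ptsa <- cbind(x = c(0.1, 0.45, 0.9), y = c(900, 480, 100))
  rg <- data.frame(name = c("x", "y"), lower = c(0, 0), upper = c(1, 1000))
  mn2 <- map_and_neighbour(post2, ptsa, ranges = rg)
  ptsb <- ptsa; ptsb[, 2] <- ptsb[, 2] / 1000
  rgb <- data.frame(name = c("x", "y"), lower = c(0, 0), upper = c(1, 1))
  post3 <- structure(list(map = c(x = 0.5, y = 0.5)),
                     class = "la_posterior")
  mn3 <- map_and_neighbour(post3, ptsb, ranges = rgb)
  expect_equal(mn2$neighbour_index, mn3$neighbour_index)
})

test_that("credible summaries report exact Gaussian contour masses", {
  set.seed(24)
  S <- cbind(a = runif(5000), b = rnorm(5000))
  cs <- credible_summaries(S)
  expect_equal(unname(cs$contour_levels),
               1 - exp(-c(0.5, 1, 1.5, 2)^2 / 2))
  expect_equal(unname(cs$contour_levels["1sigma"]), 0.3935, tolerance = 1e-4)
  expect_equal(unname(cs$contour_levels["2sigma"]), 0.8647, tolerance = 1e-4)
  iv <- cs$intervals
  expect_lt(abs(iv$lower[1] - 0.025), 0.01)
  expect_lt(abs(iv$upper[1] - 0.975), 0.01)
  expect_equal(iv$width, iv$upper - iv$lower)
  expect_error(credible_summaries(S[1:50, ]), "100")
})
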