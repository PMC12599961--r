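toy_obs <- function(mu, sigma = rep(1, 7)) {
  observations(setNames(mu, feature_names()),
               setNames(sigma, feature_names()))
}

test_that("implausibility is the max standardised discrepancy", {
  obs <- toy_obs(rep(0, 7))
  m <- matrix(0, 2, 7)
  v <- matrix(0, 2, 7)
  expect_equal(implausibility(m, v, obs), c(0, 0))
  # one feature, hand case: |E - mu| = 2, Var = 1, sigma^2 = 3 -> 1
  obs1 <- toy_obs(rep(0, 7), sigma = c(sqrt(3), rep(1, 6)))
  m1 <- matrix(c(2, rep(0, 6)), 1)
  v1 <- matrix(c(1, rep(0, 6)), 1)
  expect_equal(implausibility(m1, v1, obs1), 1)
  # adding a discrepant feature can only raise the max
  m2 <- m1; m2[1, 2] <- 5
  expect_gte(implausibility(m2, v1, obs1), implausibility(m1, v1, obs1))
  # non-positive total variance is rejected
  vneg <- v1; vneg[1, 1] <- -4
  expect_error(implausibility(m1, vneg, obs1), "variance")
})

test_that("NROY classification keeps the boundary", {
  expect_true(classify_nroy(3.0, 3))
  expect_false(classify_nroy(3.2, 3))
  expect_true(all(classify_nroy(c(0, 10, 1e6), Inf)))
  expect_equal(classify_nroy(c(2.9, 3.0, 3.1), 3),
               c(TRUE, TRUE, FALSE))
})

test_that("greedy maximin selects spread-out points", {
  line <- matrix(c(0, 1, 2), ncol = 1)
  sel <- diverse_subsample(line, 2)
  expect_setequal(as.vector(sel), c(0, 2))
  cloud <- matrix(runif(200), ncol = 2)
  expect_equal(diverse_subsample(cloud, 100), cloud)
  # the maximin selection is at least as spread as a random subset
  set.seed(31)
  for (i in 1:5) {
    cl <- matrix(runif(300), ncol = 3)
    mm <- diverse_subsample(cl, 12)
    rnd <- cl[sample.int(100, 12), ]
    mind <- function(P) min(dist(P))
    expect_gte(mind(mm), mind(rnd))
  }
})

test_that("refill concentrates the test cloud in the NROY region", {
  toy <- fx_toy_emulators()
  # observations consistent with the model at x = (0.5, 0.5)
  truth <- c(x1 = 0.5, x2 = 0.5)
  pr <- predict_emulators(toy$emulators, matrix(truth, 1,
                                                dimnames = list(NULL, c("x1", "x2"))))
  # two-feature observation set matching the toy emulators
  obs2 <- structure(list(mu = pr$mean[1, ], sigma = c(0.05, 0.05),
                         provenance = NULL), class = "la_observations")
  pr_all <- predict_emulators(toy$emulators, toy$X)
  I <- implausibility(pr_all$mean, pr_all$var, obs2)
  nroy <- toy$X[classify_nroy(I, 3), , drop = FALSE]
  cloud <- refill_test_set(nroy, toy$ranges, 500, toy$emulators,
                           threshold = 3, obs = obs2, seed = 2)
  expect_lte(nrow(cloud), 500)
  expect_gt(nrow(cloud), 100)
  pr_cloud <- predict_emulators(toy$emulators, cloud)
  expect_true(all(implausibility(pr_cloud$mean, pr_cloud$var, obs2) <= 3))
  # with an uninformative observation the cloud fills the whole box
  obs_wide <- structure(list(mu = pr$mean[1, ], sigma = c(1e6, 1e6),
                             provenance = NULL),
                        class = "la_observations")
  cloud_w <- refill_test_set(toy$X, toy$ranges, 400, toy$emulators,
                             threshold = 3, obs = obs_wide, seed = 2)
  expect_equal(nrow(cloud_w), 400)
  expect_gt(diff(range(cloud_w[, 1])), 0.9)
})

test_that("wave protocol retains a noiseless truth point", {
  r9 <- param_ranges("9")
  truth <- verification_truth()
  obs <- make_verification_observations(truth, "baseline", seed = 5,
                                        noiseless = TRUE)
  cfg <- hm_config(n_test = 2000, n_simul_wave1 = 100, n_simul = 30,
                   max_waves = 2, seed = 9)
  hm <- run_waves(obs, r9, cfg, n_restarts = 2, maxit = 40)
  expect_s3_class(hm, "hm_result")
  expect_gte(length(hm$waves), 1)
  fr <- vapply(hm$waves, `[[`, numeric(1), "nroy_fraction")
  expect_true(all(fr >= 0 & fr <= 1))
  # threshold schedule starts at 3.5 and steps down towards 3
  expect_equal(hm$waves[[1]]$threshold, 3.5)
  if (length(hm$waves) > 1) expect_equal(hm$waves[[2]]$threshold, 3.0)
  # the generating point stays non-implausible under the final emulators
  prt <- predict_emulators(hm$emulators,
                           matrix(truth, 1, dimnames = list(NULL, names(truth))))
  It <- implausibility(prt$mean, prt$var, obs)
  expect_lte(It, hm$waves[[length(hm$waves)]]$threshold)
  # the NROY bounding box still contains the truth
  box <- nroy_box(hm)
  expect_true(all(truth[box$name] >= box$lower - 1e-9 &
                  truth[box$name] <= box$upper + 1e-9))
  # emulator means over the retained cloud approach the targets
  pr_nroy <- predict_emulators(hm$emulators, hm$nroy)
  dev <- abs(colMeans(pr_nroy$mean) - obs$mu)
  expect_true(all(dev <= 3 * obs$sigma))
})
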