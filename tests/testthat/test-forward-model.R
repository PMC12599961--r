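grid40 <- time_grid()

test_that("pressure transient hits its phase landmarks", {
  p <- build_pressure_transient(4.5, 29.6, grid40)
  t <- grid40$t
  expect_equal(p[1], 0)
  expect_equal(p[which.min(abs(t - grid40$t_load))], 4.5)
  expect_equal(p[which.min(abs(t - grid40$t_ES))], 29.6)
  expect_equal(max(p), 29.6)
  expect_equal(which.max(p), which.min(abs(t - grid40$t_ES)))
  # monotone non-decreasing up to ES, constant EDP after the conduit
  expect_true(all(diff(p[t <= grid40$t_ES]) >= 0))
  expect_true(all(p[t > grid40$t_cond] == 4.5))
  expect_error(build_pressure_transient(10, 5), "EDP")
})

test_that("mitral-annulus transient is a bump peaking at ES", {
  expect_true(all(build_mv_transient(0, grid40) == 0))
  d <- build_mv_transient(8, grid40)
  t <- grid40$t
  expect_equal(max(d), 8)
  expect_equal(t[which.max(d)], grid40$t_ES)
  expect_equal(d[1], 0)
  expect_equal(d[length(d)], 0)
  expect_true(all(d[t <= grid40$t_load] == 0))
})

test_that("pericardial penalty map is thresholded and monotone", {
  expect_equal(peri_weight(1, 0.6), 1)
  expect_equal(peri_weight(0.5, 0.6), 0)
  expect_equal(peri_weight(0.6, 0.6), 0)
  expect_equal(peri_weight(0.8, 0.6), 0.5)
  # non-increasing in PTH for every region's roofness
  for (psi in default_anatomy()$psi) {
    w <- vapply(seq(0.5, 0.94, by = 0.02), peri_weight, numeric(1),
                psi = psi)
    expect_true(all(diff(w) <= 1e-12))
  }
})

test_that("regional equilibrium matches a dense-grid root scan", {
  p <- guccione_params(C = 1.7, alpha = 1)
  lam <- solve_region_equilibrium(10, R0 = 20, R_ED = 22, h = 2,
                                  params = p)
  # independent residual built from the exported energy only
  resid <- function(l) {
    dW <- (equibiaxial_energy(l + 1e-6, p) -
           equibiaxial_energy(l - 1e-6, p)) / 2e-6
    (2 * 2 / (20 * l^2)) * dW - 10 * 0.133322
  }
  grid <- seq(1.0001, 2.5, by = 1e-4)
  r <- vapply(grid, resid, numeric(1))
  i <- which(diff(sign(r)) != 0)[1]
  expect_equal(lam, grid[i], tolerance = 2e-4)
  # spring-loaded case cross-checked the same way
  lam_s <- solve_region_equilibrium(10, R0 = 20, R_ED = 20.5, h = 2,
                                    params = p, k_peri = 0.003, w = 1)
  resid_s <- function(l) resid(l) + 0.003 * 1 * pmax(0, 20 * l - 20.5) * 1000
  r_s <- vapply(grid, resid_s, numeric(1))
  i_s <- which(diff(sign(r_s)) != 0)[1]
  expect_equal(lam_s, grid[i_s], tolerance = 2e-4)
})

test_that("equilibrium stretch is monotone in pressure and stiffness", {
  p <- guccione_params()
  expect_equal(solve_region_equilibrium(0, 20, 22, 2, p), 1)
  lams <- vapply(c(2, 5, 10, 20, 30), solve_region_equilibrium,
                 numeric(1), R0 = 20, R_ED = 22, h = 2, params = p)
  expect_true(all(diff(lams) > 0))
  lama <- vapply(c(0.25, 0.5, 1, 2, 4), function(a)
    solve_region_equilibrium(10, 20, 22, 2, guccione_params(alpha = a)),
    numeric(1))
  expect_true(all(diff(lama) < 0))
})

test_that("unloading converges and reloading recovers the ED volume", {
  an <- default_anatomy()
  un <- unload(an, verification_truth())
  expect_lt(un$volume_error, 0.01)
  # near-zero pressure leaves the geometry unloaded where it stands
  un0 <- unload(an, c(verification_truth()[1:5], EDP = 0.001, ESP = 13,
                      k_peri = 0.003, PTH = 0.6))
  expect_equal(un0$R0, an$R_ED, tolerance = 1e-3)
  # error decreases monotonically over the final iterations
  tr <- un$trace
  if (length(tr) >= 3) expect_true(all(diff(tail(tr, 3)) <= 0))
})

test_that("simulated transients respond physiologically", {
  an <- default_anatomy()
  tr <- simulate_la(an, verification_truth())
  f <- extract_features(tr)
  expect_length(f, 7)
  expect_named(f, feature_names())
  expect_true(all(is.finite(f)))
  expect_true(all(f[-1] >= 0))
  # LA fills beyond ED volume when ESP exceeds EDP
  expect_gt(f[["ESV"]], cavity_volume(an))
  # stiffening only the roof lowers roof displacement, leaves pressure
  x2 <- verification_truth(); x2[["alpha_roof"]] <- 4
  tr2 <- simulate_la(an, x2)
  expect_lt(extract_features(tr2)[["d_roof"]], f[["d_roof"]])
  expect_equal(tr2$pressure, tr$pressure)
  expect_equal(tr2$R["anterior", ], tr$R["anterior", ], tolerance = 1e-3)
})

test_that("flat pressure with no annular pull gives flat transients", {
  an <- default_anatomy(A_MV = 0)
  x <- c(verification_truth()[1:5], EDP = 8, ESP = 8, k_peri = 0.003,
         PTH = 0.6)
  tr <- simulate_la(an, x)
  post <- tr$time > tr$grid$t_load
  expect_lt(diff(range(tr$volume[post])) / mean(tr$volume[post]), 1e-3)
  expect_true(all(tr$d_region[, post] < 0.2))
})

test_that("end-systole is the volume peak with earliest-index ties", {
  tr <- simulate_la(default_anatomy(), verification_truth())
  # monotone-increasing volume puts ES at the last index
  tr_up <- tr
  tr_up$volume <- seq_along(tr$volume) * 1.0
  expect_equal(extract_features(tr_up)[["ESV"]],
               tr_up$volume[length(tr_up$volume)])
  # flat volume resolves to the first post-loading index
  tr_fl <- tr
  tr_fl$volume <- rep(100, length(tr$volume))
  post <- which(tr_fl$time > tr_fl$grid$t_load)
  expect_equal(extract_features(tr_fl)[["d_global"]],
               tr_fl$d_global[post[1]])
})

test_that("feature derivatives at the design centre have the right signs", {
  r9 <- param_ranges("9")
  centre <- setNames((r9$lower + r9$upper) / 2, r9$name)
  f0 <- forward_features(centre)
  for (r in c("anterior", "posterior", "septum", "lateral", "roof")) {
    xp <- centre; nm <- paste0("alpha_", r)
    xp[[nm]] <- xp[[nm]] * 1.05
    fp <- forward_features(xp)
    expect_lt(fp[[paste0("d_", r)]], f0[[paste0("d_", r)]])
  }
  xe <- centre; xe[["ESP"]] <- xe[["ESP"]] + 1
  expect_gt(forward_features(xe)[["ESV"]], f0[["ESV"]])
})
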