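test_that("the strain-energy exponent matches hand-evaluated cases", {
  p <- guccione_params()
  expect_equal(guccione_Q(green_strain(), p), 0)
  # single fibre-strain component, default exponents
  s <- green_strain(E_ff = 0.1)
  expect_equal(guccione_Q(s, guccione_params(b_f = 8, alpha = 1)), 0.08)
  # all components engaged, computed term by term
  s2 <- green_strain(E_ff = 0.1, E_ss = -0.05, E_nn = 0.02,
                     E_fs = 0.03, E_fn = -0.01, E_sn = 0.04)
  q_hand <- 8 * 0.1^2 + 2 * 4 * (0.03^2 + 0.01^2) +
    3 * (0.05^2 + 0.02^2 + 2 * 0.04^2)
  expect_equal(guccione_Q(s2, p), q_hand)
})

test_that("alpha scales the exponent linearly and commutes with the b's", {
  set.seed(11)
  for (i in 1:20) {
    s <- green_strain(E_ff = rnorm(1, 0, 0.1), E_ss = rnorm(1, 0, 0.1),
                      E_nn = rnorm(1, 0, 0.1), E_fs = rnorm(1, 0, 0.05),
                      E_fn = rnorm(1, 0, 0.05), E_sn = rnorm(1, 0, 0.05))
    a <- runif(1, 0.2, 4)
    p1 <- guccione_params(alpha = a)
    p2 <- guccione_params(alpha = 2 * a)
    expect_equal(guccione_Q(s, p2), 2 * guccione_Q(s, p1))
    # alpha-equivalence: energy(alpha, b) == energy(1, alpha * b), up to
    # floating-point associativity
    pb <- guccione_params(alpha = 1, b_f = a * 8, b_t = a * 3, b_ft = a * 4)
    expect_equal(guccione_energy(s, p1), guccione_energy(s, pb),
                 tolerance = 1e-14)
  }
})

test_that("Guccione energy density evaluates the exponential form", {
  p <- guccione_params(C = 1.7)
  expect_equal(guccione_energy(green_strain(), p), 0)
  s <- green_strain(E_ff = 0.1)
  expect_equal(guccione_energy(s, p), 1.7 / 2 * (exp(0.08) - 1))
  expect_equal(guccione_energy(s, p), 0.0708, tolerance = 1e-2)
  # linear in C at fixed strain
  expect_equal(guccione_energy(s, guccione_params(C = 3.4)),
               2 * guccione_energy(s, p))
  # volumetric penalty appears through J
  sj <- green_strain(J = 1.1)
  expect_equal(guccione_energy(sj, p), 1000 / 2 * log(1.1)^2)
  expect_error(green_strain(J = -1), "J")
})

test_that("default material parameters are the healthy-tissue reference", {
  p <- guccione_params()
  expect_equal(p$C, 1.7)
  expect_equal(p$b_f, 8)
  expect_equal(p$b_ft, 4)
  expect_equal(p$b_t, 3)
  expect_equal(p$kappa, 1000)
  expect_equal(neo_hookean_params()$c, 7.45)
})

test_that("Neo-Hookean energy matches its closed form", {
  expect_equal(neo_hookean_energy(3, 1), 0)
  expect_equal(neo_hookean_energy(3.02, 1, neo_hookean_params(c = 7.45)),
               7.45 * 0.02)
  expect_equal(neo_hookean_energy(3.02, 1, neo_hookean_params(c = 7.45)),
               0.149, tolerance = 1e-6)
  # kappa penalty vanishes at J = 1 regardless of magnitude
  expect_equal(neo_hookean_energy(3.5, 1, neo_hookean_params(kappa = 1e6)),
               neo_hookean_energy(3.5, 1, neo_hookean_params(kappa = 1)))
  expect_error(neo_hookean_energy(3, 0), "J")
})

test_that("equibiaxial reduction agrees with the general energy", {
  p <- guccione_params()
  expect_equal(equibiaxial_energy(1, p), 0)
  for (lam in c(1.05, 1.1, 1.3, 1.5)) {
    s <- green_strain(E_ff = (lam^2 - 1) / 2, E_ss = (lam^2 - 1) / 2,
                      E_nn = (lam^-4 - 1) / 2, J = 1)
    expect_equal(equibiaxial_energy(lam, p), guccione_energy(s, p))
  }
  # strictly increasing and convex on the loading branch
  lam <- seq(1, 1.6, by = 0.01)
  W <- equibiaxial_energy(lam, p)
  expect_true(all(diff(W) > 0))
  d2 <- diff(diff(W))
  expect_true(all(d2 > 0))
})
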