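test_that("dimensionless solutions take their closed-form values", {
  for (ord in c("first", "zero")) {
    expect_equal(dimensionlessProfile(ord, 5, 0), 1)        # u(0) = 1
    expect_equal(dimensionlessProfile(ord, 0, 0.5), 1)      # no reaction
  }
  expect_equal(dimensionlessProfile("zero", sqrt(2), 1), 0) # 1 - 2 + 1
  expect_equal(dimensionlessProfile("first", 2, 1), 1 / cosh(2))
  expect_equal(55 * dimensionlessProfile("first", 2, 1), 14.62,
               tolerance = 1e-3)
  expect_error(dimensionlessProfile("first", 2, 1.2), "\\[0, 1\\]")
  expect_error(dimensionlessProfile("first", -1, 0.5), ">= 0")
  # large phi must not overflow
  expect_equal(dimensionlessProfile("first", 800, 0), 1)
  expect_gt(dimensionlessProfile("first", 800, 0.5), 0)
})

test_that("both solutions satisfy the zero-gradient bottom boundary", {
  h <- 1e-7
  # centred difference at zeta = 1 using the symmetry-free one-sided form
  du_first <- (dimensionlessProfile("first", 3, 1) -
               dimensionlessProfile("first", 3, 1 - h)) / h
  expect_equal(du_first, 0, tolerance = 1e-5)
  # quadratic: du/dzeta = phi^2 zeta - phi^2 -> 0 at zeta = 1 (phi^2 <= 2)
  du_zero <- (dimensionlessProfile("zero", 1.2, 1) -
              dimensionlessProfile("zero", 1.2, 1 - h)) / h
  expect_equal(du_zero, 0, tolerance = 1e-5)
})

test_that("thieleModulus and limitation classification", {
  expect_equal(thieleModulus(1, 1, 1), 1)
  expect_equal(thieleModulus(7.84e-3, 1, 1e-5), 28)   # sqrt(784)
  expect_equal(thieleModulus(1, 2, 1), 2 * thieleModulus(1, 1, 1))
  expect_error(thieleModulus(1, 0, 1), "> 0")
  expect_identical(classifyLimitation(28), "diffusion_limited")
  expect_identical(classifyLimitation(0.1), "reaction_limited")
  expect_identical(classifyLimitation(1), "balanced")
})

test_that("estimateFlux reproduces Fick's law on linear profiles", {
  flat <- microprofile(c(0, 100, 200), rep(40, 3), C_bulk = 40)
  expect_equal(fluxValue(estimateFlux(flat, 4.5e-5)), 0)
  # linear 55 -> 0 over 950 um; quadratic and OLS agree (zero curvature)
  z <- seq(0, 950, length.out = 20)
  lin <- microprofile(z, 55 * (1 - z / 950), C_bulk = 55)
  J_expect <- 4.5e-5 * (55 / 950) * 1e-3 * 1e4     # 2.605e-5
  expect_equal(fluxValue(estimateFlux(lin, 4.5e-5)), J_expect,
               tolerance = 1e-10)
  expect_equal(fluxValue(estimateFlux(lin, 4.5e-5, method = "linear")),
               J_expect, tolerance = 1e-10)
  expect_equal(fluxValue(estimateFlux(lin, 9e-5)), 2 * J_expect,
               tolerance = 1e-10)                  # linear in D_e
  expect_error(estimateFlux(microprofile(c(0, 1), c(5, 4), 5), 4.5e-5,
                            window = 1L), "window")
})

test_that("windowed flux converges to the closed-form surface flux", {
  m <- siteProfileModel(osp)
  J_closed <- closedFormFlux(m)
  lf_um <- m@L_f * 1e4
  for (h in c(10, 5, 2)) {
    p <- genMicroprofile(m, z_grid = seq(0, floor(lf_um / h) * h, h))
    J_hat <- fluxValue(estimateFlux(p, D_e = m@D_e))
    expect_equal(J_hat, J_closed, tolerance = 0.02)
  }
  # and the bias shrinks with the grid
  err <- vapply(c(20, 10, 5), function(h) {
    p <- genMicroprofile(m, z_grid = seq(0, floor(lf_um / h) * h, h))
    abs(fluxValue(estimateFlux(p, D_e = m@D_e)) - J_closed) / J_closed
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("fitProfile recovers the generating Thiele modulus", {
  m1 <- siteProfileModel(osp)
  p1 <- genMicroprofile(m1, z_grid = seq(0, 6000, 10))
  phi_gen <- thieleModulus(m1@rate_constant, m1@L_f, m1@D_e)
  f1 <- fitProfile(p1, order = "first", L_f = m1@L_f, D_e = m1@D_e)
  expect_equal(thiele(f1), phi_gen, tolerance = 1e-6)
  expect_equal(rateConstant(f1), m1@rate_constant, tolerance = 1e-6)
  expect_lt(f1@rmse, 1e-8)
  # zero order quadratic, phi^2 = 2
  mz <- reactionDiffusionModel("zero", rate_constant = 2 * 4.5e-5 * 55 / 0.25,
                               D_e = 4.5e-5, L_f = 0.5, C0 = 55)
  pz <- genMicroprofile(mz, z_grid = seq(0, 5000, 50))
  fz <- fitProfile(pz, order = "zero", L_f = 0.5, D_e = 4.5e-5)
  expect_equal(thiele(fz), sqrt(2), tolerance = 1e-6)
  # flat profile: no consumption
  flat <- microprofile(seq(0, 1000, 100), rep(55, 11), C_bulk = 55)
  expect_equal(thiele(fitProfile(flat, L_f = 0.1, D_e = 4.5e-5)), 0)
  expect_error(fitProfile(microprofile(c(0, 10), c(0, 0), 55),
                          L_f = 0.1, D_e = 4.5e-5), "all-zero")
})

test_that("fitProfile is invariant to rescaling C and C_bulk together", {
  m <- siteProfileModel(osp)
  p <- genMicroprofile(m, z_grid = seq(0, 6000, 20))
  p2 <- microprofile(profileDepths(p), 10 * profileConc(p),
                     C_bulk = 10 * bulkConc(p))
  expect_equal(thiele(fitProfile(p2, L_f = m@L_f, D_e = m@D_e)),
               thiele(fitProfile(p, L_f = m@L_f, D_e = m@D_e)),
               tolerance = 1e-9)
})

test_that("penetration depth interpolates the detection-limit crossing", {
  z <- seq(0, 1000, 100)
  lin <- microprofile(z, pmax(55 * (1 - z / 1000), 0), C_bulk = 55)
  expect_equal(penetrationDepth(lin), 1000 * (55 - 0.3) / 55,
               tolerance = 1e-9)                    # 994.5 um
  oxic <- microprofile(z, rep(20, length(z)), C_bulk = 55)
  expect_true(is.na(penetrationDepth(oxic)))
  expect_equal(penetrationDepth(lin, detection_limit = 5.5), 900)
})
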