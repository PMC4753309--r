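test_that("noiseless accretion series lies exactly on the exponential", {
  cfg <- siteConfig("osp", fe_x0 = 0.5, fe_k = 0.05)
  s <- genAccretionSeries(cfg, times = c(0, 35, 70))
  expect_equal(obsValues(s)[1], 0.5)                 # e^0 = 1
  expect_equal(obsValues(s)[3], 0.5 * exp(3.5))      # 16.557...
  # log-linear slope of the noiseless series recovers the configured k
  o <- loglinear_oracle(obsTimes(genAccretionSeries(osp)),
                        obsValues(genAccretionSeries(osp)))
  expect_equal(o[["k"]], osp@fe_k, tolerance = 1e-10)
})

test_that("DNA series follows (dna_x0, dna_r) with the same machinery", {
  flat <- siteConfig("osp", dna_r = 0, dna_x0 = 10)
  expect_equal(obsValues(genDnaSeries(flat, times = c(0, 10, 50))),
               rep(10, 3))
  g <- siteConfig("osp", dna_r = 0.043, dna_x0 = 1)
  expect_equal(obsValues(genDnaSeries(g, times = c(0, 25, 50)))[3],
               exp(2.15), tolerance = 1e-12)
  s <- genDnaSeries(beowulf)
  expect_equal(loglinear_oracle(obsTimes(s), obsValues(s))[["k"]],
               beowulf@dna_r, tolerance = 1e-10)
})

test_that("series generation validates inputs and censors below detection", {
  expect_error(genAccretionSeries(osp, times = numeric(0)), "non-empty")
  expect_error(genAccretionSeries(osp, times = c(-1, 5)), "non-negative")
  expect_error(genAccretionSeries(osp, times = c(5, 5)), "increasing")
  tiny <- siteConfig("osp", fe_x0 = 0.01)
  s <- genAccretionSeries(tiny, times = c(0, 7, 70), detection_limit = 0.05)
  expect_true(isCensored(s)[1])                      # 0.01 < 0.05
  expect_false(isCensored(s)[3])
})

test_that("lognormal noise is seed-reproducible and mean-preserving", {
  n1 <- noiseSpec("lognormal", 0.2, seed = 11)
  a <- genAccretionSeries(osp, noise = n1)
  b <- genAccretionSeries(osp, noise = n1)
  expect_identical(obsValues(a), obsValues(b))       # bit-reproducible
  c2 <- genAccretionSeries(osp, noise = noiseSpec("lognormal", 0.2, 12))
  expect_false(identical(obsValues(a), obsValues(c2)))
  # multiplicative factors are mean-1: large-sample average near the curve
  many <- replicate(400, {
    s <- genAccretionSeries(osp, times = c(0, 70),
      noise = noiseSpec("lognormal", 0.2, sample.int(1e6, 1)))
    obsValues(s)[2]
  })
  expect_equal(mean(many), osp@fe_x0 * exp(osp@fe_k * 70), tolerance = 0.05)
})

test_that("generated microprofiles evaluate the dimensionless solutions", {
  m <- reactionDiffusionModel("first", rate_constant = 4 * 4.5e-5 / 0.25,
                              D_e = 4.5e-5, L_f = 0.5, C0 = 55)  # phi = 2
  p <- genMicroprofile(m, z_grid = c(0, 2500, 5000))
  expect_equal(profileConc(p)[1], 55)                # u(0) = 1
  expect_equal(profileConc(p)[3], 55 / cosh(2), tolerance = 1e-12)
  mz <- reactionDiffusionModel("zero", rate_constant = 2 * 4.5e-5 * 55 / 0.25,
                               D_e = 4.5e-5, L_f = 0.5, C0 = 55) # phi^2 = 2
  pz <- genMicroprofile(mz, z_grid = c(0, 5000))
  expect_equal(profileConc(pz)[2], 0)                # 1 - 2 + 1 = 0
  expect_error(genMicroprofile(m, z_grid = c(0, 9000)), "within")
})

test_that("count fields give rate*t*area means and Poisson dispersion", {
  expect_true(all(genCountFields(0, c(5, 10), 1e-5)$count == 0))
  obs <- genCountFields(3.7e6, times = 7, field_area = 1e-5, n_fields = 1)
  expect_equal(obs$count, 259)
  expect_error(genCountFields(-1, 5, 1e-5), ">= 0")
  # Poisson mean/variance ratio -> 1 over many fields
  big <- genCountFields(3.7e6, times = 7, field_area = 1e-5,
                        n_fields = 2e4, noise = noiseSpec("poisson", seed = 3))
  expect_equal(var(big$count) / mean(big$count), 1, tolerance = 0.05)
})

test_that("community tables follow the configured succession trajectory", {
  ct <- genCommunityTable(osp, times = c(4, 70))
  a <- abundances(ct)
  expect_equal(a["Hydrogenobaculum", 1], 0.85)
  expect_equal(a["Hydrogenobaculum", 2], 0.85 - 0.66)   # 1%/day for 66 d
  expect_equal(a["M_yellowstonensis", ], c(osp_day04 = 0.15,
                                           osp_day70 = 0.15))
  expect_true(all(abs(colSums(a) - 1) < 1e-9))
  # dirichlet draws stay on the simplex and are seed-stable
  n <- noiseSpec("dirichlet", scale = 200, seed = 5)
  d1 <- genCommunityTable(osp, noise = n)
  expect_true(all(abs(colSums(abundances(d1)) - 1) < 1e-9))
  expect_identical(abundances(d1),
                   abundances(genCommunityTable(osp, noise = n)))
  expect_error(genCommunityTable(osp, times = c(4, 120)), "within")
})

test_that("extraction tables encode the configured molar ratios", {
  es <- genExtractionTable(siteConfig("beowulf", as_fe_ratio = 1),
                           times = c(14, 70))
  d <- as.data.frame(es)
  fe <- d$mg_per_L[d$element == "Fe"]
  as_ <- d$mg_per_L[d$element == "As"]
  expect_equal(as_ / fe, rep(74.922 / 55.845, 2), tolerance = 1e-12)
  # W at ratio 0.002: mass conc = 0.002 * mol(Fe) * 183.84
  esw <- genExtractionTable(beowulf, times = 14)
  dw <- as.data.frame(esw)
  expect_equal(dw$mg_per_L[dw$element == "W"] /
                 dw$mg_per_L[dw$element == "Fe"],
               0.002 * 183.84 / 55.845, tolerance = 1e-12)
  expect_error(genExtractionTable(beowulf, extraction_volume = 0), "> 0")
  expect_error(genExtractionTable(beowulf, slide_area = 0), "> 0")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); before <- .Random.seed
  invisible(genAccretionSeries(osp, noise = noiseSpec("lognormal", 0.2, 1)))
  expect_identical(.Random.seed, before)
})
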