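test_that("fitExponential matches the log-linear oracle on noiseless data", {
  t <- seq(0, 70, 7)
  s <- accretionSeries(t, 2 * exp(0.05 * t))
  f <- fitExponential(s)
  oracle <- loglinear_oracle(t, 2 * exp(0.05 * t))
  expect_equal(coef(f)[["k"]], oracle[["k"]], tolerance = 1e-6)
  expect_equal(coef(f)[["x0"]], oracle[["x0"]], tolerance = 1e-6)
  expect_true(f@converged)
  # constant series: k = 0, x0 = level
  fc <- fitExponential(accretionSeries(c(0, 10, 20, 30), rep(5, 4)))
  expect_equal(coef(fc)[["k"]], 0, tolerance = 1e-10)
  expect_equal(coef(fc)[["x0"]], 5, tolerance = 1e-10)
})

test_that("round trip with the generator recovers site defaults to 1e-6", {
  for (cfg in list(osp, beowulf)) {
    f <- fitExponential(genAccretionSeries(cfg))
    expect_equal(coef(f)[["k"]], cfg@fe_k, tolerance = 1e-6)
    fd <- fitExponential(genDnaSeries(cfg))
    expect_equal(coef(fd)[["k"]], cfg@dna_r, tolerance = 1e-6)
  }
})

test_that("fit is invariant to uniform rescaling of x", {
  t <- seq(0, 70, 7)
  x <- withr::with_seed(21, 0.5 * exp(0.05 * t) * rlnorm(length(t), 0, 0.1))
  f1 <- fitExponential(accretionSeries(t, x))
  f2 <- fitExponential(accretionSeries(t, 1000 * x))
  expect_equal(coef(f2)[["k"]], coef(f1)[["k"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["x0"]], 1000 * coef(f1)[["x0"]], tolerance = 1e-6)
})

test_that("censored points are excluded or substituted as requested", {
  t <- c(0, 7, 14, 21, 28)
  x <- 0.5 * exp(0.05 * t)
  s <- accretionSeries(t, x, censored = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  f_ex <- fitExponential(s)                      # exclusion: still exact
  expect_equal(coef(f_ex)[["k"]], 0.05, tolerance = 1e-6)
  f_sub <- fitExponential(s, censored_action = "substitute",
                          detection_limit = 0.6)
  expect_false(isTRUE(all.equal(coef(f_sub)[["k"]], 0.05, tolerance = 1e-6)))
  expect_error(fitExponential(accretionSeries(t, x, censored = rep(TRUE, 5))),
               "censored")
  expect_error(fitExponential(accretionSeries(c(0, 7), c(1, 2))), ">= 3")
})

test_that("robust (HC3) standard errors exceed iid ones under
          mean-proportional noise", {
  s <- genAccretionSeries(osp, noise = noiseSpec("lognormal", 0.2, 4))
  f_iid <- fitExponential(s)
  f_rob <- fitExponential(s, vcov = "robust")
  expect_equal(coef(f_rob), coef(f_iid))         # same point estimate
  expect_gt(f_rob@se_k, 0)
  expect_false(identical(f_rob@se_k, f_iid@se_k))
})

test_that("se_k shrinks with replication roughly as 1/sqrt(n)", {
  mean_se <- function(times) {
    mean(vapply(1:20, function(s) {
      ser <- genAccretionSeries(osp, times = times,
                                noise = noiseSpec("lognormal", 0.2, s))
      fitExponential(ser)@se_k
    }, numeric(1)))
  }
  se_coarse <- mean_se(seq(0, 70, 7))            # 11 points
  se_fine <- mean_se(seq(0, 70, 70 / 43))        # 44 points
  expect_lt(se_fine, se_coarse)
  expect_equal(se_fine / se_coarse, sqrt(11 / 44), tolerance = 0.35)
})

test_that("predict, instantaneousRate and lagTime follow the closed forms", {
  f <- new("ExponentialFit", x0 = 2, k = 0.05, se_x0 = 0, se_k = 0,
           p_value_k = 0, residual_df = 9L, converged = TRUE, units = "")
  expect_equal(predict(f, 0), 2)
  expect_equal(predict(f, 70), 2 * exp(3.5))     # 66.23
  f0 <- new("ExponentialFit", x0 = 1, k = 0, se_x0 = 0, se_k = 0,
            p_value_k = 1, residual_df = 9L, converged = TRUE, units = "")
  expect_equal(predict(f0, 100), 1)
  expect_equal(instantaneousRate(f, 70), 0.05 * 2 * exp(3.5))
  expect_equal(instantaneousRate(f0, 12), 0)
  rates <- instantaneousRate(f, c(10, 20, 40))
  expect_true(all(diff(rates) > 0))              # monotone for k > 0
  expect_equal(lagTime(f, 2), 0)                 # limit = x0
  expect_equal(lagTime(f, 2 * exp(1.5)), 30)     # ln(limit/x0)/k
  expect_true(is.na(lagTime(f0, 5)))             # k = 0, never reached
})

test_that("vertical growth rate converts mm/month to um/day", {
  expect_equal(verticalGrowthRate(1), 1000 / 30)
  expect_equal(verticalGrowthRate(0.45), 15)
  expect_equal(verticalGrowthRate(0), 0)
  expect_equal(verticalGrowthRate(1, days_per_month = 25), 40)
})

test_that("endpoint comparison reproduces the textbook Student t", {
  id <- compareEndpoints(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t_stat, 0)
  expect_equal(id$p_value, 1)
  a <- c(10, 11, 12); b <- c(16, 17, 18)
  got <- compareEndpoints(a, b)
  oracle <- student_t_oracle(a, b)
  expect_equal(got$t_stat, oracle$t)
  expect_equal(got$df, 4)
  expect_equal(got$p_value, oracle$p)
  welch <- compareEndpoints(c(1, 2, 3, 9), c(2, 2.1, 1.9), welch = TRUE)
  expect_lt(welch$df, 4)                         # Welch df < pooled df
  expect_error(compareEndpoints(1, c(1, 2)), ">= 2")
})
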