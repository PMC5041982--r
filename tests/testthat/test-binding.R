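test_that("percent-of-control normalisation", {
  expect_equal(percentOfControl(50, 50), 100)
  expect_equal(percentOfControl(0, 50), 0)
  expect_equal(percentOfControl(c(50, 25), 50), c(100, 50))
  expect_error(percentOfControl(10, 0), "positive")
  expect_error(percentOfControl(10, -5), "positive")
})

test_that("4PL fit recovers a noiseless planted curve on the assay ladder", {
  gen <- genDoseResponse(1, ic50 = 3.7e-6, noiseFrac = 0)
  fit <- fit4PL(gen$data$dose_molar, gen$data$response)
  expect_true(fit@converged)
  expect_lt(abs(fit@ic50 - 3.7e-6) / 3.7e-6, 0.001)
  # midpoint property: the model response at IC50 is halfway between
  # the plateaus
  expect_equal(hitlead:::.fourPL(fit@ic50, log10(fit@ic50), fit@hill,
                                 fit@top, fit@bottom),
               (fit@top + fit@bottom) / 2)
  expect_error(fit4PL(c(1e-6, 1e-5, 1e-4), c(90, 50, 10)), "4 distinct")
})

test_that("4PL fit is scale-equivariant in dose", {
  gen <- genDoseResponse(3, ic50 = 16.2e-6, noiseFrac = 0.03)
  f1 <- fit4PL(gen$data$dose_molar, gen$data$response)
  f2 <- fit4PL(gen$data$dose_molar * 1000, gen$data$response)
  expect_equal(f2@ic50 / f1@ic50, 1000, tolerance = 1e-4)
  expect_equal(f2@hill, f1@hill, tolerance = 1e-4)
})

test_that("4PL median recovery error stays under 10% at 5% noise", {
  errs <- vapply(1:100, function(s) {
    gen <- genDoseResponse(s, ic50 = 16.2e-6, noiseFrac = 0.05)
    fit <- fit4PL(gen$data$dose_molar, gen$data$response,
                  top = 100, bottom = 0)
    abs(fit@ic50 - 16.2e-6) / 16.2e-6
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("F_norm extraction from a fluorescence trace", {
  tt <- seq(0, 40, by = 0.1)
  flat <- rep(1000, length(tt))
  expect_equal(mstFnorm(tt, flat, laserOn = 5), 1)
  # two-level trace: 1000 up to laser-on at t = 5, 800 afterwards
  twol <- ifelse(tt <= 5, 1000, 800)
  expect_equal(mstFnorm(tt, twol, laserOn = 5), 0.8)
  # scaling the whole trace leaves the ratio unchanged
  expect_equal(mstFnorm(tt, 7.3 * twol, laserOn = 5), 0.8)
  expect_error(mstFnorm(tt, twol, laserOn = 15), "outside the trace")
  expect_error(mstFnorm(tt, twol, laserOn = 5, coldWindow = c(4, 6)),
               "before laser-on")
})

test_that("fraction bound follows the quadratic mass-action solution", {
  expect_equal(fractionBound(1e-9, 1e-9, 1e-9), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  expect_equal(fractionBound(0, 80e-9, 4.7e-9), 0)
  expect_gt(fractionBound(1e-3, 80e-9, 4.7e-9), 0.9999)  # saturation
  # monotone increasing in L, decreasing in KD, bounded in [0, 1]
  L <- 10^seq(-11, -4, length.out = 40)
  fb <- fractionBound(L, 80e-9, 4.7e-9)
  expect_true(all(diff(fb) > 0))
  expect_true(all(fb >= 0 & fb <= 1))
  expect_true(all(fractionBound(L, 80e-9, 50e-9) < fb))
  expect_error(fractionBound(1e-9, 0, 1e-9), "positive")
})

test_that("KD fit recovers the planted constant on the printed ladder", {
  gen <- genMst(2, kd = 1.1e-9, noiseFrac = 0)
  # ladder floor matches the printed series: 10,000 / 2^15 nM
  expect_equal(min(gen$data$titrant_molar) * 1e9, 0.3052, tolerance = 1e-3)
  expect_true(all(diff(gen$data$fnorm) < 0))  # monotone in the dilution
  fit <- fitKd(gen$data$titrant_molar, gen$data$fnorm)
  expect_true(fit@converged)
  expect_lt(abs(fit@kd - 1.1e-9) / 1.1e-9, 0.01)
  expect_error(fitKd(c(1, 2, 3, 4, 5) * 1e-9, rep(1, 5)), "at least 6")
  expect_error(fitKd(-1 * gen$data$titrant_molar, gen$data$fnorm),
               "non-negative")
})

test_that("KD median recovery error stays under 15% at 1% noise", {
  errs <- vapply(1:100, function(s) {
    gen <- genMst(s, kd = 4.7e-9, noiseFrac = 0.01)
    fit <- fitKd(gen$data$titrant_molar, gen$data$fnorm)
    abs(fit@kd - 4.7e-9) / 4.7e-9
  }, numeric(1))
  expect_lte(median(errs), 0.15)
})

test_that("Cheng-Prusoff conversion and its limits", {
  # printed inputs: IC50 2,500 nM, [STAT3] 200 nM, KD 1.1 nM -> 13.67 nM
  expect_equal(chengPrusoffKi(2500e-9, 200e-9, 1.1e-9) * 1e9, 13.67,
               tolerance = 1e-3)
  # KD rounded to 1.0 nM reproduces the printed 12.4 nM
  expect_equal(chengPrusoffKi(2500e-9, 200e-9, 1.0e-9) * 1e9, 12.44,
               tolerance = 1e-3)
  # vanishing competition: Ki -> IC50
  expect_equal(chengPrusoffKi(2.5e-6, 1e-15, 1e-9), 2.5e-6, tolerance = 1e-5)
  # correction always shrinks the IC50
  set.seed(77)
  for (i in 1:20) {
    ic <- runif(1, 1e-9, 1e-5); tc <- runif(1, 1e-9, 1e-6)
    kp <- runif(1, 1e-10, 1e-8)
    expect_lt(chengPrusoffKi(ic, tc, kp), ic)
  }
  expect_error(chengPrusoffKi(0, 1e-9, 1e-9), "positive")
})

test_that("tumour volume formulas", {
  expect_equal(tumorVolume(5, 2, "half"), 10)
  expect_equal(tumorVolume(1, 1, "half"), 0.5)
  expect_equal(tumorVolume(7.3, 4.1, "six_over_pi") /
               tumorVolume(7.3, 4.1, "half"), 12 / pi)
  expect_error(tumorVolume(2, 5), "short dimension")
  expect_error(tumorVolume(-1, -2), "positive")
})
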