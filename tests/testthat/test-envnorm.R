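test_that("calibration recovers known coefficients exactly in the noise-free case", {
  sp <- flatSpecs("G1"); sp$temp_coef <- 0.5
  env <- envProfile(1800, period_s = 1800)
  s <- simulateControlAir(sp, duration_h = 0.5, env = env)
  cf <- calCoefficients(fitEnvCalibration(s))
  expect_equal(cf$beta_T, 0.5, tolerance = 1e-8)
  expect_equal(cf$beta_H, 0, tolerance = 1e-8)
  expect_equal(cf$T_ref, mean(env$temp_c))
  expect_equal(cf$resid_sd, 0, tolerance = 1e-8)
})

test_that("calibration on noisy control air is within 3 SE of the generator truth", {
  env <- envProfile(7200, period_s = 7200)
  s <- simulateControlAir(gmSensorSpecs(), duration_h = 2, env = env,
                          seed = 3)
  cf <- calCoefficients(fitEnvCalibration(s))
  d <- streamData(s)
  for (i in seq_len(nrow(cf))) {
    fit <- summary(lm(d[[cf$sensor[i]]] ~ d$temp_c + d$rh_pct))$coefficients
    expect_lt(abs(cf$beta_T[i] - (-0.8)), 3 * fit[2, 2])
    expect_lt(abs(cf$beta_H[i] - 0.4), 3 * fit[3, 2])
  }
})

test_that("constant or collinear environment is a calibration error", {
  sp <- flatSpecs("G1")
  env <- data.frame(time_s = 0:399, temp_c = 25, rh_pct = 60)
  s <- simulateControlAir(sp, duration_h = 400 / 3600, env = env)
  expect_error(fitEnvCalibration(s), "collinear")
  ## T and RH perfectly collinear is equally degenerate
  env2 <- data.frame(time_s = 0:399, temp_c = seq(20, 30, length.out = 400),
                     rh_pct = 40 + 2 * seq(20, 30, length.out = 400))
  s2 <- simulateControlAir(sp, duration_h = 400 / 3600, env = env2)
  expect_error(fitEnvCalibration(s2), "collinear")
})

test_that("environmental correction subtracts the calibrated response", {
  cf <- data.frame(sensor = "G1", intercept = 1000, beta_T = 0.5,
                   beta_H = 0, T_ref = 25, H_ref = 60, n = 100,
                   resid_sd = 0)
  cal <- new("EnvCalibration", coefficients = cf)
  m <- matrix(100, 3, 1, dimnames = list(NULL, "G1"))
  ## identity at the reference point
  expect_equal(applyEnvCorrection(m, rep(25, 3), rep(60, 3), cal), m)
  ## forced arithmetic: T = T_ref + 10 with beta_T = 0.5 subtracts 5
  expect_equal(unname(applyEnvCorrection(m, rep(35, 3), rep(60, 3), cal)[, 1]),
               rep(95, 3))
  ## identity when both betas are zero
  cal0 <- new("EnvCalibration",
              coefficients = transform(cf, beta_T = 0, beta_H = 0))
  expect_equal(applyEnvCorrection(m, rnorm(3, 25), rnorm(3, 60), cal0), m)
  ## missing sensor is an error
  m2 <- matrix(1, 2, 1, dimnames = list(NULL, "G9"))
  expect_error(applyEnvCorrection(m2, 1:2, 1:2, cal), "G9")
})

test_that("corrected control air decouples from temperature and humidity", {
  env <- envProfile(14400, period_s = 14400)
  s <- simulateControlAir(gmSensorSpecs(), duration_h = 4, env = env,
                          seed = 5)
  cal <- fitEnvCalibration(s)
  corrected <- applyEnvCorrection(s, cal = cal)
  d <- streamData(corrected)
  for (sn in sensorNames(corrected)) {
    expect_lt(abs(cor(d[[sn]], d$temp_c)), 0.05)
    expect_lt(abs(cor(d[[sn]], d$rh_pct)), 0.05)
    ## residual regression slope on T within 2 SE of zero
    fit <- summary(lm(d[[sn]] ~ d$temp_c))$coefficients
    expect_lt(abs(fit[2, 1]), 2 * fit[2, 2])
  }
})

test_that("two-step normalization is anchored, dimensionless and scale-invariant", {
  expect_equal(normalizeCycle(rep(7, 5)), rep(0, 5))
  expect_equal(normalizeCycle(c(100, 110, 121)), c(0, 0.10, 0.21))
  expect_error(normalizeCycle(c(0, 1, 2)), "anchor")
  withr::with_seed(8, {
    x <- rnorm(40, 100, 5)
    for (k in runif(5, 0.1, 50))
      expect_equal(normalizeCycle(k * x), normalizeCycle(x))
  })
  ## log-ratio variant
  expect_equal(normalizeCycle(c(100, 110, 121), method = "logratio"),
               log(c(1, 1.10, 1.21)))
  ## matrix input is anchored column-wise
  m <- cbind(a = c(100, 110), b = c(200, 190))
  expect_equal(unname(normalizeCycle(m)[2, ]), c(0.10, -0.05))
})

test_that("calibration persists through CSV round trip", {
  env <- envProfile(600, period_s = 600)
  cal <- fitEnvCalibration(simulateControlAir(gmSensorSpecs(),
                                              duration_h = 600 / 3600,
                                              env = env, seed = 2))
  path <- tempfile(fileext = ".csv")
  writeCalibrationCSV(cal, path)
  cal2 <- readCalibrationCSV(path)
  expect_equal(calCoefficients(cal2), calCoefficients(cal),
               tolerance = 1e-10)
})

test_that("cycleFeatureSet stacks trimmed, normalized sampling readings", {
  sp <- flatSpecs(c("G1", "G2"), baseline = c(2000, 3000))
  src <- odorSource("durian_uninfested", amplitudes = c(G1 = 200, G2 = 300),
                    fruit_id = "f1")
  cyc <- simulateCycle(sp, src, odorModel = "saturating")
  fs <- cycleFeatureSet(cyc)
  expect_s4_class(fs, "OdorFeatureSet")
  expect_equal(dim(SummarizedExperiment::assay(fs)), c(2L, 30L))
  ## saturating noise-free response: features near A * s(t) / baseline
  a <- SummarizedExperiment::assay(fs)
  expect_true(all(abs(a["G1", ] - 200 * (1 - exp(-(70:99) / 20)) / 2000)
                  < 1e-3))
  expect_equal(unname(SummarizedExperiment::colData(fs)$class[1]),
               "durian_uninfested")
})
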