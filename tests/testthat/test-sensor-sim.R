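test_that("control-air streams follow the configured linear response model", {
  ## degenerate flat case: all coefficients and noise zero
  s <- simulateControlAir(flatSpecs(), duration_h = 100 / 3600, seed = 1)
  expect_true(all(streamData(s)$S1 == 1000))

  ## forced linear temperature response: T ramps 20 -> 30 degC
  sp <- flatSpecs(); sp$temp_coef <- 0.5
  env <- data.frame(time_s = 0:99, temp_c = seq(20, 30, length.out = 100),
                    rh_pct = 50)
  s <- simulateControlAir(sp, duration_h = 100 / 3600, env = env)
  r <- streamData(s)$S1
  expect_equal(r[100] - r[1], 5, tolerance = 1e-12)

  ## mismatched environment length is a length error
  expect_error(simulateControlAir(sp, duration_h = 1, env = env), "length")
})

test_that("identical seed and config give bit-identical streams", {
  a <- simulateControlAir(gmSensorSpecs(), duration_h = 0.1, seed = 7)
  b <- simulateControlAir(gmSensorSpecs(), duration_h = 0.1, seed = 7)
  expect_identical(streamData(a), streamData(b))
  sa <- simulateSurveyExperiment(surveyDesign(), seed = 11)
  sb <- simulateSurveyExperiment(surveyDesign(), seed = 11)
  expect_identical(sa$truth, sb$truth)
  expect_identical(streamData(sa$stream), streamData(sb$stream))
  ## and the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(simulateControlAir(gmSensorSpecs(), 0.05, seed = 3))
  expect_identical(rnorm(1), x1)
})

test_that("noisy control air recovers temperature/humidity coefficients by OLS", {
  ## OLS on generated data is the recovery oracle: coefficients within 3 SE
  hits <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    env <- envProfile(7200, period_s = 7200)
    s <- simulateControlAir(gmSensorSpecs()[1, ], duration_h = 2, env = env,
                            seed = 100 + r)
    d <- streamData(s)
    fit <- summary(lm(GM102B ~ temp_c + rh_pct, data = d))$coefficients
    okT <- abs(fit["temp_c", 1] - (-0.8)) < 3 * fit["temp_c", 2]
    okH <- abs(fit["rh_pct", 1] - 0.4) < 3 * fit["rh_pct", 2]
    hits <- hits + (okT && okH)
  }
  expect_gte(hits, ceiling(0.9 * reps))
})

test_that("cycle generator: sampling slope equals the configured target", {
  ## null odor, no noise, no warm-up: sampling-phase slope 0 for every sensor
  sp <- flatSpecs(c("A", "B"), baseline = c(1500, 2000))
  cyc <- simulateCycle(sp, odorSource("air_only"), phaseSchedule("prototype"))
  d <- streamData(cyc)
  samp <- d[d$phase == "sampling", ]
  expect_equal(olsSlope(samp$time_s, samp$A), 0)
  expect_equal(olsSlope(samp$time_s, samp$B), 0)

  ## survey measurement logic recovers a Table-2-magnitude slope exactly
  ## (warm-up disabled) ...
  sp1 <- flatSpecs("MQ7", baseline = 2100)
  src <- odorSource("durian_uninfested", slopes = c(MQ7 = 0.000152))
  sim <- simulateCycle(sp1, src, phaseSchedule("survey"))
  sl <- extractSurveySlopes(sim)
  expect_equal(sl$slope_net, 0.000152, tolerance = 1e-6)

  ## ... and the warm-up transient cancels in the room-air subtraction
  sp2 <- sp1; sp2$warmup_tau <- 20; sp2$warmup_amp <- 15
  sl2 <- extractSurveySlopes(simulateCycle(sp2, src, phaseSchedule("survey")))
  expect_equal(sl2$slope_net, 0.000152, tolerance = 1e-6)
  ## while contaminating each phase slope individually
  expect_gt(abs(sl2$slope_room), 1e-3)
  expect_equal(sl$slope_room, 0, tolerance = 1e-10)

  ## unknown group label is a validation error
  expect_error(simulateCycle(sp1, list(group = "durian_rotten")), "group")
})

test_that("noisy cycles recover the target slope without bias", {
  sp <- flatSpecs("MQ7", baseline = 2100); sp$noise_sd <- 2
  src <- odorSource("durian_uninfested", slopes = c(MQ7 = 0.02))
  slopes <- vapply(1:200, function(s) {
    extractSurveySlopes(simulateCycle(sp, src, phaseSchedule("survey"),
                                      seed = s))$slope_net
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.02), 2 * se)
})

test_that("survey generator emits the documented design", {
  sim <- simulateSurveyExperiment(surveyDesign(), seed = 2)
  d <- streamData(sim$stream)
  expect_equal(nrow(d), 10 * 200)            # 10 paired 100+100-s cycles
  expect_length(sensorNames(sim$stream), 13)
  expect_equal(nrow(sim$truth), 130)
  expect_equal(sort(unique(d$group)),
               c("durian_infested", "durian_uninfested"))
  ## phase durations match the schedule in every cycle
  expect_true(all(table(d$phase) == 1000))

  ## zero SDs, no noise, no warm-up: group means recovered exactly by the
  ## downstream extraction
  eff <- surveyEffectSizes()
  eff$sd_uninfested <- eff$sd_infested <- 0
  sp0 <- surveySensorSpecs(); sp0$warmup_tau <- 0
  sim0 <- simulateSurveyExperiment(
    surveyDesign(specs = sp0, effects = eff, noiseScale = 0), seed = 3)
  sl <- extractSurveySlopes(sim0$stream)
  mu <- tapply(sl$slope_net, list(sl$sensor, sl$group), mean)
  expect_equal(unname(mu[eff$sensor, "durian_uninfested"]),
               eff$mean_uninfested, tolerance = 1e-8)
  expect_equal(unname(mu[eff$sensor, "durian_infested"]),
               eff$mean_infested, tolerance = 1e-8)
})

test_that("outdoor generator reproduces the train/test reading counts", {
  od <- simulateOutdoorExperiment(outdoorDesign(), seed = 4)
  fsTr <- cycleFeatureSet(od$train)
  fsTe <- cycleFeatureSet(od$test)
  cls <- SummarizedExperiment::colData(fsTr)$class
  expect_equal(sum(cls != "air_only"), 900)  # 10 fruits x 3 x 30
  expect_equal(sum(cls == "air_only"), 90)   # 3 air measurements x 30
  expect_equal(ncol(fsTe), 300)              # 10 fruits x 1 x 30
  expect_equal(nrow(fsTr), 4)                # GM channels
})

test_that("indoor generator: 210 readings per fruit and day-step geometry", {
  ind <- simulateIndoorRipening(indoorDesign(), seed = 5)
  fs <- cycleFeatureSet(ind$stream)
  cd <- SummarizedExperiment::colData(fs)
  expect_true(all(table(cd$fruit_id) == 210))
  expect_true(all(table(cd$day, cd$fruit_id) == 30))

  ## step size 0 and no measurement noise: all day clouds coincide (each day
  ## repeats the same within-measurement trace), so ANOSIM by day ~ 0 (the
  ## exact duplicates across days pull it marginally negative)
  d0 <- indoorDesign(nInfested = 1, nControl = 0, stepSize = 0,
                     infestedMultiplier = 1, measurementSD = 0,
                     noiseScale = 0)
  f0 <- cycleFeatureSet(simulateIndoorRipening(d0, seed = 6)$stream)
  a0 <- anosimTest(pairwiseDistances(f0),
                   SummarizedExperiment::colData(f0)$day,
                   nPermutations = 99, seed = 1)
  expect_lt(abs(a0@statistic), 0.1)
  expect_gt(a0@p_value, 0.5)

  ## step far above noise: day structure saturates, R > 0.95
  d1 <- indoorDesign(nInfested = 1, nControl = 0, stepSize = 60)
  f1 <- cycleFeatureSet(simulateIndoorRipening(d1, seed = 7)$stream)
  a1 <- anosimTest(pairwiseDistances(f1),
                   SummarizedExperiment::colData(f1)$day,
                   nPermutations = 99, seed = 1)
  expect_gt(a1@statistic, 0.95)
})

test_that("stream container enforces its invariants", {
  d <- data.frame(time_s = c(0, 1, 1), phase = "reset", S1 = 1,
                  temp_c = 25, rh_pct = 50)
  expect_error(SensorStream(d, "S1"), "strictly increasing")
  d2 <- data.frame(time_s = 0:1, phase = "reset", S1 = 1, temp_c = 25,
                   rh_pct = c(50, 140))
  expect_error(SensorStream(d2, "S1"), "rh_pct")
  d3 <- data.frame(time_s = 0:1, phase = "warp", S1 = 1, temp_c = 25,
                   rh_pct = 50)
  expect_error(SensorStream(d3, "S1"), "phase")
})
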