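## Experiment-level generators reproducing the three study designs:
## the 13-sensor sensitivity survey, the outdoor train/test detection
## experiment, and the indoor 6-fruit x 7-day ripening experiment.

#' Design of the sensor-sensitivity survey
#'
#' @param nPerGroup fruits per infestation group (default 5: the 2024
#'   survey used 10 fruits, 5 infested and 5 uninfested).
#' @param specs sensor specification table (13-sensor array by default).
#' @param effects per-sensor group slope distributions (means/SDs) from
#'   which per-fruit net slopes are drawn; see
#'   \code{\link{surveyEffectSizes}}.
#' @param slopeDraw \code{"normal"}: per-fruit slopes are independent
#'   Gaussian draws; \code{"quantile"}: deterministic equal-probability
#'   normal quantiles (a noise-free rendering of the same group
#'   distributions).
#' @param noiseScale multiplier on sensor read noise (0 = noise-free
#'   streams).
#' @return list of class \code{"surveyDesign"}.
#' @export
surveyDesign <- function(nPerGroup = 5, specs = surveySensorSpecs(),
                         effects = surveyEffectSizes(),
                         slopeDraw = c("normal", "quantile"),
                         noiseScale = 1) {
  slopeDraw <- match.arg(slopeDraw)
  if (!.isCount(nPerGroup)) .stopf("'nPerGroup' must be a positive integer")
  .checkSpecs(specs)
  if (!all(specs$name %in% effects$sensor))
    .stopf("effects table must cover every sensor in the array")
  structure(list(nPerGroup = nPerGroup, specs = specs, effects = effects,
                 slopeDraw = slopeDraw, noiseScale = noiseScale),
            class = "surveyDesign")
}

#' Simulate the paired room-air/sample-air sensitivity survey
#'
#' For each fruit, one room-air segment (100 s) and one sample-air segment
#' (100 s) are generated; the fruit's per-sensor net emission slope is drawn
#' from the group's Normal(mean, SD) effect distribution (or placed at
#' deterministic equal-probability quantiles of it).
#'
#' @param design a \code{\link{surveyDesign}}.
#' @param seed integer seed; all fruits derive deterministically from it.
#' @return list with \code{stream} (one \code{\link{SensorStream}} of all
#'   paired cycles) and \code{truth} (data.frame of the drawn per-fruit,
#'   per-sensor net slopes).
#' @examples
#' sim <- simulateSurveyExperiment(surveyDesign(noiseScale = 0), seed = 1)
#' table(streamData(sim$stream)$group) / 200  # fruits per group
#' @export
simulateSurveyExperiment <- function(design = surveyDesign(), seed = NULL) {
  stopifnot(inherits(design, "surveyDesign"))
  specs <- design$specs
  eff <- design$effects[match(specs$name, design$effects$sensor), ]
  n <- design$nPerGroup
  schedule <- phaseSchedule("survey")
  groups <- c("durian_uninfested", "durian_infested")
  withSeed(seed, {
    streams <- list()
    truth <- list()
    t_off <- 0
    for (g in groups) {
      mu <- if (g == "durian_uninfested") eff$mean_uninfested else
        eff$mean_infested
      sd <- if (g == "durian_uninfested") eff$sd_uninfested else
        eff$sd_infested
      for (i in seq_len(n)) {
        slopes <- if (design$slopeDraw == "normal")
          rnorm(length(mu), mu, sd)
        else mu + sd * qnorm((i - 0.5) / n)
        names(slopes) <- specs$name
        fid <- sprintf("%s%02d",
                       if (g == "durian_uninfested") "U" else "I", i)
        cyc <- simulateCycle(specs, odorSource(g, slopes = slopes,
                                               fruit_id = fid),
                             schedule = schedule,
                             noiseScale = design$noiseScale,
                             t_offset = t_off)
        t_off <- t_off + sum(schedule$phases)
        streams[[fid]] <- streamData(cyc)
        truth[[fid]] <- data.frame(fruit_id = fid, group = g,
                                   sensor = specs$name, slope_true = slopes,
                                   row.names = NULL)
      }
    }
    list(stream = SensorStream(do.call(rbind, streams), specs$name),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Design of the outdoor detection experiment
#'
#' Defaults reproduce the outdoor study layout: a training set of 10 fruits
#' (5 per infestation group) measured three times each plus three pure-air
#' measurements, and a testing set of 10 further fruits measured once each;
#' 100-s sampling phases retain 30 readings after trimming, giving 900
#' durian + 90 air training readings and 300 testing readings.
#'
#' The class-conditional response amplitudes (a.u.) are configurable; the
#' defaults place pure air near zero, make the two fruit groups overlap
#' substantially, and add per-fruit random effects so that test fruits are
#' exchangeable with, but not identical to, training fruits.
#'
#' @param nTrainPerGroup,nTestPerGroup fruits per infestation group.
#' @param trainMeasurements,testMeasurements,airMeasurements measurement
#'   counts.
#' @param specs sensor specification table (4 GM channels by default).
#' @param classAmplitude matrix of per-class mean response amplitudes,
#'   rows = groups, columns = channels.
#' @param amplitudeSD between-measurement amplitude SD (a.u.).
#' @param fruitSD between-fruit random-effect SD (a.u.).
#' @param airSD amplitude SD of pure-air measurements (a.u.).
#' @param noiseScale multiplier on sensor read noise.
#' @return list of class \code{"outdoorDesign"}.
#' @export
outdoorDesign <- function(nTrainPerGroup = 5, nTestPerGroup = 5,
                          trainMeasurements = 3, testMeasurements = 1,
                          airMeasurements = 3, specs = gmSensorSpecs(),
                          classAmplitude = NULL, amplitudeSD = 60,
                          fruitSD = 15, airSD = 10, noiseScale = 1) {
  .checkSpecs(specs)
  if (is.null(classAmplitude)) {
    classAmplitude <- rbind(air_only = rep(0, nrow(specs)),
                            durian_uninfested = c(240, 260, 250, 245),
                            durian_infested = c(276, 314, 295, 281))
    colnames(classAmplitude) <- specs$name
  }
  structure(list(nTrainPerGroup = nTrainPerGroup,
                 nTestPerGroup = nTestPerGroup,
                 trainMeasurements = trainMeasurements,
                 testMeasurements = testMeasurements,
                 airMeasurements = airMeasurements, specs = specs,
                 classAmplitude = classAmplitude, amplitudeSD = amplitudeSD,
                 fruitSD = fruitSD, airSD = airSD, noiseScale = noiseScale),
            class = "outdoorDesign")
}

.simulateMeasurementSet <- function(design, fruits, groups, nMeas, t_off,
                                    amplitudes, label) {
  specs <- design$specs
  schedule <- phaseSchedule("prototype")
  streams <- list()
  truth <- list()
  for (i in seq_along(fruits)) {
    for (m in seq_len(nMeas)) {
      amp <- amplitudes[[i]] +
        rnorm(nrow(specs), 0,
              if (groups[i] == "air_only") design$airSD else
                design$amplitudeSD)
      names(amp) <- specs$name
      cyc <- simulateCycle(specs,
                           odorSource(groups[i], amplitudes = amp,
                                      fruit_id = fruits[i]),
                           schedule = schedule, odorModel = "saturating",
                           noiseScale = design$noiseScale, t_offset = t_off,
                           replicate = m)
      t_off <- t_off + sum(schedule$phases)
      key <- paste(label, fruits[i], m, sep = "_")
      streams[[key]] <- streamData(cyc)
      truth[[key]] <- data.frame(set = label, fruit_id = fruits[i],
                                 group = groups[i], replicate = m,
                                 t(amp), check.names = FALSE)
    }
  }
  list(data = do.call(rbind, streams),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       t_off = t_off)
}

#' Simulate the outdoor detection experiment (training and testing sets)
#'
#' @param design an \code{\link{outdoorDesign}}.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test}
#'   (\code{\link{SensorStream}}s of full reset/sampling/rest cycles) and
#'   \code{truth} (the latent per-measurement amplitudes).
#' @export
simulateOutdoorExperiment <- function(design = outdoorDesign(),
                                      seed = NULL) {
  stopifnot(inherits(design, "outdoorDesign"))
  specs <- design$specs
  p <- nrow(specs)
  withSeed(seed, {
    mkFruit <- function(group, ids) {
      lapply(ids, function(i)
        design$classAmplitude[group, ] + rnorm(p, 0, design$fruitSD))
    }
    trU <- sprintf("TRU%02d", seq_len(design$nTrainPerGroup))
    trI <- sprintf("TRI%02d", seq_len(design$nTrainPerGroup))
    teU <- sprintf("TEU%02d", seq_len(design$nTestPerGroup))
    teI <- sprintf("TEI%02d", seq_len(design$nTestPerGroup))
    fruitsTr <- c(trU, trI)
    groupsTr <- rep(c("durian_uninfested", "durian_infested"),
                    each = design$nTrainPerGroup)
    ampTr <- c(mkFruit("durian_uninfested", seq_along(trU)),
               mkFruit("durian_infested", seq_along(trI)))
    train <- .simulateMeasurementSet(design, fruitsTr, groupsTr,
                                     design$trainMeasurements, 0, ampTr,
                                     "train")
    air <- .simulateMeasurementSet(design, "air", "air_only",
                                   design$airMeasurements, train$t_off,
                                   list(design$classAmplitude["air_only", ]),
                                   "train")
    fruitsTe <- c(teU, teI)
    groupsTe <- rep(c("durian_uninfested", "durian_infested"),
                    each = design$nTestPerGroup)
    ampTe <- c(mkFruit("durian_uninfested", seq_along(teU)),
               mkFruit("durian_infested", seq_along(teI)))
    test <- .simulateMeasurementSet(design, fruitsTe, groupsTe,
                                    design$testMeasurements, air$t_off,
                                    ampTe, "test")
    list(train = SensorStream(rbind(train$data, air$data), specs$name),
         test = SensorStream(test$data, specs$name),
         truth = rbind(train$truth, air$truth, test$truth))
  })
}

#' Design of the indoor ripening experiment
#'
#' Defaults reproduce the indoor study layout: six fruits (three
#' mealybug-inoculated, three controls), one measurement of 30 retained
#' readings per day over 7 days (210 readings per fruit). Each fruit's
#' daily latent 4-channel response amplitude follows a directed trajectory
#' whose direction of daily displacement reverses at the fruit's cracking
#' day; infested fruits take larger daily steps.
#'
#' @param nInfested,nControl fruit counts per treatment.
#' @param days number of measurement days.
#' @param crackingDay cracking day per fruit (scalar recycled, or a vector
#'   of length \code{nInfested + nControl}).
#' @param specs sensor specification table (4 GM channels by default).
#' @param baseAmplitude day-1 mean response amplitude per channel (a.u.).
#' @param stepSize daily amplitude displacement (a.u.) for control fruits.
#' @param infestedMultiplier multiplier on \code{stepSize} for infested
#'   fruits.
#' @param directionJitterSD SD of the per-day jitter added to the
#'   displacement direction (unitless, relative to a unit vector).
#' @param measurementSD per-measurement amplitude SD (a.u.).
#' @param noiseScale multiplier on sensor read noise.
#' @return list of class \code{"indoorDesign"}.
#' @export
indoorDesign <- function(nInfested = 3, nControl = 3, days = 7,
                         crackingDay = 4, specs = gmSensorSpecs(),
                         baseAmplitude = c(300, 280, 320, 260),
                         stepSize = 20, infestedMultiplier = 2,
                         directionJitterSD = 0.15, measurementSD = 4,
                         noiseScale = 1) {
  .checkSpecs(specs)
  nFruit <- nInfested + nControl
  crackingDay <- rep(crackingDay, length.out = nFruit)
  if (any(crackingDay < 1 | crackingDay > days))
    .stopf("cracking days must lie within 1..%d", days)
  structure(list(nInfested = nInfested, nControl = nControl, days = days,
                 crackingDay = crackingDay, specs = specs,
                 baseAmplitude = rep(baseAmplitude,
                                     length.out = nrow(specs)),
                 stepSize = stepSize,
                 infestedMultiplier = infestedMultiplier,
                 directionJitterSD = directionJitterSD,
                 measurementSD = measurementSD, noiseScale = noiseScale),
            class = "indoorDesign")
}

#' Simulate the indoor 6-fruit x 7-day ripening experiment
#'
#' @param design an \code{\link{indoorDesign}}.
#' @param seed integer seed.
#' @return list with \code{stream} (all daily cycles of all fruits) and
#'   \code{truth} (per fruit-day latent amplitudes, treatment and cracking
#'   day).
#' @export
simulateIndoorRipening <- function(design = indoorDesign(), seed = NULL) {
  stopifnot(inherits(design, "indoorDesign"))
  specs <- design$specs
  p <- nrow(specs)
  schedule <- phaseSchedule("prototype")
  nFruit <- design$nInfested + design$nControl
  infested <- rep(c(TRUE, FALSE), c(design$nInfested, design$nControl))
  withSeed(seed, {
    streams <- list()
    truth <- list()
    t_off <- 0
    for (f in seq_len(nFruit)) {
      fid <- sprintf("fruit%02d", f)
      grp <- if (infested[f]) "durian_infested" else "durian_uninfested"
      step <- design$stepSize *
        if (infested[f]) design$infestedMultiplier else 1
      u <- rnorm(p); u <- u / sqrt(sum(u^2))
      A <- design$baseAmplitude + rnorm(p, 0, design$measurementSD)
      crack <- design$crackingDay[f]
      for (d in seq_len(design$days)) {
        if (d > 1) {
          dir <- (if (d <= crack) u else -u) +
            rnorm(p, 0, design$directionJitterSD)
          dir <- dir / sqrt(sum(dir^2))
          A <- A + step * dir
        }
        amp <- A + rnorm(p, 0, design$measurementSD)
        names(amp) <- specs$name
        cyc <- simulateCycle(specs,
                             odorSource(grp, amplitudes = amp, day = d,
                                        fruit_id = fid),
                             schedule = schedule, odorModel = "saturating",
                             noiseScale = design$noiseScale,
                             t_offset = t_off)
        t_off <- t_off + sum(schedule$phases)
        key <- paste(fid, d, sep = "_")
        streams[[key]] <- streamData(cyc)
        truth[[key]] <- data.frame(fruit_id = fid, group = grp, day = d,
                                   cracking_day = crack, t(amp),
                                   check.names = FALSE)
      }
    }
    list(stream = SensorStream(do.call(rbind, streams), specs$name),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}
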