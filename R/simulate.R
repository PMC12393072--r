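## Seeded generators of synthetic raw MOS-sensor streams with the statistical
## structure the downstream pipeline assumes: baseline + drift + environment
## response + odor response + warm-up transient + Gaussian read noise.

#' Sinusoidal diel environment profile
#'
#' Per-second temperature and relative-humidity series following a smooth
#' diel cycle. Temperature and humidity are phase-shifted so the two series
#' are linearly independent, which the environmental calibration fit
#' requires.
#'
#' @param duration_s length of the profile in seconds.
#' @param t_mean,t_amp temperature mean and amplitude (degC); defaults
#'   25 +/- 5.
#' @param rh_mean,rh_amp relative-humidity mean and amplitude (\%RH);
#'   defaults 60 +/- 15.
#' @param period_s diel period (s), default 86400.
#' @param rh_phase phase shift of the humidity sinusoid (radians).
#' @return data.frame with columns \code{time_s}, \code{temp_c},
#'   \code{rh_pct}; humidity clamped to [0, 100].
#' @examples
#' head(envProfile(3600))
#' @export
envProfile <- function(duration_s, t_mean = 25, t_amp = 5, rh_mean = 60,
                       rh_amp = 15, period_s = 86400, rh_phase = 2 * pi / 3) {
  if (!.isCount(duration_s)) .stopf("'duration_s' must be a positive integer")
  t <- seq_len(duration_s) - 1
  w <- 2 * pi * t / period_s
  data.frame(time_s = t,
             temp_c = t_mean + t_amp * sin(w),
             rh_pct = pmin(100, pmax(0, rh_mean + rh_amp * sin(w + rh_phase))))
}

#' Describe an odor source for cycle simulation
#'
#' @param group one of \code{"air_only"}, \code{"durian_uninfested"},
#'   \code{"durian_infested"}.
#' @param slopes named numeric vector of target net emission rates
#'   (a.u./s per sensor) for the linear-ramp odor model.
#' @param amplitudes named numeric vector of response amplitudes (a.u. per
#'   sensor) for the saturating odor model.
#' @param day integer postharvest day (indoor design) or \code{NA}.
#' @param fruit_id fruit identifier or \code{NA}.
#' @return list of class \code{"odorSource"}.
#' @export
odorSource <- function(group, slopes = NULL, amplitudes = NULL,
                       day = NA_integer_, fruit_id = NA_character_) {
  if (length(group) != 1L || !group %in% .groupLevels)
    .stopf("unknown group label '%s'; expected one of: %s",
           paste(group, collapse = ","), paste(.groupLevels, collapse = ", "))
  structure(list(group = group, slopes = slopes, amplitudes = amplitudes,
                 day = day, fruit_id = fruit_id), class = "odorSource")
}

## named per-sensor vector aligned to specs$name, defaulting to 0
.alignSensors <- function(v, specs, what) {
  out <- stats::setNames(numeric(nrow(specs)), specs$name)
  if (is.null(v)) return(out)
  if (is.null(names(v)) || !all(names(v) %in% specs$name))
    .stopf("%s names must be a subset of the array sensor names", what)
  out[names(v)] <- v
  out
}

## env covering `n` seconds: either a data.frame(time_s, temp_c, rh_pct) or
## a constant list; returns matrix-friendly vectors
.resolveEnv <- function(env, n) {
  if (is.null(env)) env <- list(temp_c = 25, rh_pct = 60)
  if (is.data.frame(env)) {
    if (nrow(env) < n)
      .stopf("environment profile (%d s) shorter than stream (%d s)",
             nrow(env), n)
    list(temp_c = env$temp_c[seq_len(n)], rh_pct = env$rh_pct[seq_len(n)])
  } else {
    list(temp_c = rep(env$temp_c, length.out = n),
         rh_pct = rep(env$rh_pct, length.out = n))
  }
}

#' Simulate continuous control-air sampling
#'
#' Generates a charcoal-filtered (odor-free) stream: per-sensor reading =
#' baseline + drift + temp_coef (T - T0) + hum_coef (RH - RH0) + Gaussian
#' noise, where T0/RH0 are the profile's initial values. This is the input
#' for \code{\link{fitEnvCalibration}}.
#'
#' @param specs sensor specification table (see
#'   \code{\link{surveySensorSpecs}}).
#' @param duration_h duration in hours (default 24).
#' @param env environment profile as from \code{\link{envProfile}}; defaults
#'   to the standard diel profile.
#' @param seed integer seed; the stream is fully reproducible from it.
#' @return A \code{\link{SensorStream}} with phase \code{"reset"}.
#' @examples
#' s <- simulateControlAir(gmSensorSpecs(), duration_h = 0.1, seed = 1)
#' s
#' @export
simulateControlAir <- function(specs, duration_h = 24, env = NULL,
                               seed = NULL) {
  .checkSpecs(specs)
  if (!is.numeric(duration_h) || duration_h <= 0)
    .stopf("'duration_h' must be > 0")
  n <- as.integer(round(duration_h * 3600))
  if (is.data.frame(env) && nrow(env) != n)
    .stopf("environment profile length (%d) does not match duration (%d s)",
           nrow(env), n)
  if (is.null(env)) env <- envProfile(n)
  e <- .resolveEnv(env, n)
  t <- seq_len(n) - 1
  withSeed(seed, {
    readings <- vapply(seq_len(nrow(specs)), function(j) {
      sp <- specs[j, ]
      sp$baseline + sp$drift_rate * t +
        sp$temp_coef * (e$temp_c - e$temp_c[1]) +
        sp$hum_coef * (e$rh_pct - e$rh_pct[1]) +
        if (sp$noise_sd > 0) rnorm(n, 0, sp$noise_sd) else 0
    }, numeric(n))
    colnames(readings) <- specs$name
    SensorStream(data.frame(time_s = t, phase = "reset",
                            as.data.frame(readings), temp_c = e$temp_c,
                            rh_pct = e$rh_pct, check.names = FALSE),
                 sensors = specs$name)
  })
}

## one acquisition phase for all sensors; returns a numeric matrix n x p.
## t0 = absolute cycle time at phase start (drives drift);
## odor: list(model, slopes, amplitudes, riseTau) or NULL;
## decayFrom: named odor level at phase start, decaying with decayTau.
.simulateSegment <- function(specs, duration, t0, env, odor = NULL,
                             warmup = FALSE, decayFrom = NULL,
                             decayTau = 30, noiseScale = 1) {
  tl <- seq_len(duration) - 1
  out <- matrix(0, duration, nrow(specs), dimnames = list(NULL, specs$name))
  for (j in seq_len(nrow(specs))) {
    sp <- specs[j, ]
    y <- sp$baseline + sp$drift_rate * (t0 + tl) +
      sp$temp_coef * (env$temp_c - env$temp_c_ref) +
      sp$hum_coef * (env$rh_pct - env$rh_pct_ref)
    if (!is.null(odor)) {
      y <- y + switch(odor$model,
        ramp = odor$slopes[[sp$name]] * tl,
        saturating = odor$amplitudes[[sp$name]] *
          (1 - exp(-tl / odor$riseTau)))
    }
    if (warmup && sp$warmup_tau > 0)
      y <- y + sp$warmup_amp * exp(-tl / sp$warmup_tau)
    if (!is.null(decayFrom))
      y <- y + decayFrom[[sp$name]] * exp(-(tl + 1) / decayTau)
    if (noiseScale > 0 && sp$noise_sd > 0)
      y <- y + rnorm(duration, 0, sp$noise_sd * noiseScale)
    out[, j] <- y
  }
  out
}

#' Simulate one measurement cycle
#'
#' Generates a single acquisition cycle following a
#' \code{\link{phaseSchedule}}. Under the prototype schedule
#' (reset/sampling/rest) the odor term appears during sampling and decays
#' back to baseline during rest; under the survey schedule
#' (room-air/sample-air) the odor appears during the sample-air phase.
#' During odor phases the noise-free reading either rises linearly at the
#' configured per-sensor slope (\code{odorModel = "ramp"}, the default: the
#' slope is the odor statistic) or saturates towards a per-sensor amplitude
#' (\code{odorModel = "saturating"}). A heating transient
#' \code{warmup_amp * exp(-t / warmup_tau)} contaminates the start of every
#' measured phase (the reason the first 70 sampling points are discarded
#' downstream); set \code{warmup_tau = 0} in the specs to disable it.
#'
#' @param specs sensor specification table.
#' @param odor an \code{\link{odorSource}}.
#' @param schedule a \code{\link{phaseSchedule}}.
#' @param env environment: constant \code{list(temp_c=, rh_pct=)} (default
#'   25 degC / 60 \%RH) or a per-second data.frame covering the cycle.
#' @param seed integer seed.
#' @param odorModel \code{"ramp"} or \code{"saturating"}.
#' @param riseTau time constant (s) of the saturating response.
#' @param noiseScale multiplier on each sensor's \code{noise_sd}; 0 gives a
#'   noise-free cycle.
#' @param t_offset absolute time (s) of the cycle start, added to
#'   \code{time_s} and driving sensor drift.
#' @param replicate replicate index stored in the stream metadata.
#' @return A \code{\link{SensorStream}} of one full cycle.
#' @examples
#' src <- odorSource("durian_uninfested", slopes = c(MQ7 = 0.000152))
#' cyc <- simulateCycle(surveySensorSpecs("MQ7"), src,
#'                      phaseSchedule("survey"), seed = 1)
#' @export
simulateCycle <- function(specs, odor, schedule = phaseSchedule("prototype"),
                          env = NULL, seed = NULL,
                          odorModel = c("ramp", "saturating"), riseTau = 20,
                          noiseScale = 1, t_offset = 0, replicate = 1L) {
  .checkSpecs(specs)
  odorModel <- match.arg(odorModel)
  if (!inherits(odor, "odorSource"))
    odor <- do.call(odorSource, odor) # validates the group label
  durations <- schedule$phases
  total <- sum(durations)
  e <- .resolveEnv(env, total)
  slopes <- .alignSensors(odor$slopes, specs, "per-sensor slope")
  amps <- .alignSensors(odor$amplitudes, specs, "per-sensor amplitude")
  odorTerm <- list(model = odorModel, slopes = as.list(slopes),
                   amplitudes = as.list(amps), riseTau = riseTau)
  withSeed(seed, {
    rows <- vector("list", length(durations))
    t0 <- 0
    for (k in seq_along(durations)) {
      ph <- names(durations)[k]
      D <- durations[[k]]
      idx <- t0 + seq_len(D)
      envk <- list(temp_c = e$temp_c[idx], rh_pct = e$rh_pct[idx],
                   temp_c_ref = e$temp_c[1], rh_pct_ref = e$rh_pct[1])
      seg <- switch(ph,
        reset = .simulateSegment(specs, D, t0, envk,
                                 noiseScale = noiseScale),
        room_air = .simulateSegment(specs, D, t0, envk, warmup = TRUE,
                                    noiseScale = noiseScale),
        sampling = ,
        sample_air = .simulateSegment(specs, D, t0, envk, odor = odorTerm,
                                      warmup = TRUE,
                                      noiseScale = noiseScale),
        rest = {
          ## odor level reached at the end of the sampling phase decays away
          S <- durations[["sampling"]]
          endLevel <- if (odorModel == "ramp") slopes * (S - 1)
                      else amps * (1 - exp(-(S - 1) / riseTau))
          .simulateSegment(specs, D, t0, envk,
                           decayFrom = as.list(endLevel),
                           noiseScale = noiseScale)
        },
        .stopf("unknown phase '%s' in schedule", ph))
      rows[[k]] <- data.frame(time_s = t_offset + t0 + seq_len(D) - 1,
                              phase = ph, as.data.frame(seg),
                              temp_c = envk$temp_c, rh_pct = envk$rh_pct,
                              check.names = FALSE)
      t0 <- t0 + D
    }
    d <- do.call(rbind, rows)
    d$fruit_id <- odor$fruit_id
    d$group <- odor$group
    d$day <- odor$day
    d$replicate <- replicate
    SensorStream(d, sensors = specs$name)
  })
}
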