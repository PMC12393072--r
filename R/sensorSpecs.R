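#' Sensor specification tables
#'
#' Parameter tables describing the simulated MOS gas-sensor arrays. The
#' survey array carries the thirteen low-cost sensors screened for
#' sensitivity to mealybug-associated volatiles (nine MQ-series units plus
#' the four channels of a Grove Multichannel Gas Sensor v2 module); the
#' prototype array carries the four GM channels retained for the deployed
#' device. All responses are in arbitrary ADC units (a.u.).
#'
#' Columns: \code{name}; \code{baseline} (a.u.); \code{drift_rate} (a.u./s,
#' slow monotone drift common to MOS elements); \code{temp_coef} (a.u./degC);
#' \code{hum_coef} (a.u./\%RH); \code{odor_gain} (a.u. per unit odor
#' concentration); \code{noise_sd} (a.u., per-second Gaussian read noise);
#' \code{warmup_tau} (s, time constant of the additive heating transient at
#' the start of a sampling phase); \code{warmup_amp} (a.u., its amplitude).
#'
#' @param names optional subset of sensor names to keep, in the given order.
#' @return data.frame of sensor specifications, one row per sensor.
#' @examples
#' surveySensorSpecs()
#' gmSensorSpecs(c("GM302B", "GM502B"))
#' @export
surveySensorSpecs <- function(names = NULL) {
  ## The survey system logs a normalized (dimensionless) signal: per-sensor
  ## slopes are relative rates of signal change, so baselines are O(1) and
  ## read noise is a few 1e-4 per second. MQ elements drift appreciably
  ## (they need frequent recalibration); the GM channels do not.
  specs <- data.frame(
    name = c("MQ2", "MQ3", "MQ4", "MQ5", "MQ6", "MQ7", "MQ8", "MQ9",
             "MQ135", "GM102B", "GM302B", "GM502B", "GM702B"),
    baseline = c(0.9, 1.1, 0.75, 0.85, 0.8, 1.05, 0.7, 0.95,
                 1.0, 1.5, 1.55, 1.45, 1.6),
    drift_rate = rep(c(2e-6, 0), c(9, 4)),
    temp_coef = rep(c(-4e-4, -3e-4), c(9, 4)),
    hum_coef = rep(c(2e-4, 1.5e-4), c(9, 4)),
    odor_gain = 1,
    noise_sd = 3e-4,
    warmup_tau = 20,
    warmup_amp = 5e-3,
    stringsAsFactors = FALSE)
  .subsetSpecs(specs, names)
}

#' @rdname surveySensorSpecs
#' @export
gmSensorSpecs <- function(names = NULL) {
  ## The prototype streams raw ADC counts from the Grove multichannel
  ## module: O(3000)-count baselines, ~1.5-count read noise, and the
  ## temperature/humidity response the 24-h calibration compensates.
  specs <- data.frame(
    name = c("GM102B", "GM302B", "GM502B", "GM702B"),
    baseline = c(3000, 3100, 2900, 3200),
    drift_rate = 0,
    temp_coef = -0.8,
    hum_coef = 0.4,
    odor_gain = 1,
    noise_sd = 1.5,
    warmup_tau = 20,
    warmup_amp = 15,
    stringsAsFactors = FALSE)
  .subsetSpecs(specs, names)
}

.subsetSpecs <- function(specs, names) {
  if (!is.null(names)) {
    unknown <- setdiff(names, specs$name)
    if (length(unknown))
      .stopf("unknown sensor(s): %s", paste(unknown, collapse = ", "))
    specs <- specs[match(names, specs$name), , drop = FALSE]
    rownames(specs) <- NULL
  }
  specs
}

.checkSpecs <- function(specs) {
  need <- c("name", "baseline", "drift_rate", "temp_coef", "hum_coef",
            "odor_gain", "noise_sd", "warmup_tau", "warmup_amp")
  if (!is.data.frame(specs) || !all(need %in% names(specs)))
    .stopf("sensor specs must be a data.frame with columns: %s",
           paste(need, collapse = ", "))
  if (anyDuplicated(specs$name)) .stopf("sensor names must be unique")
  if (any(specs$noise_sd < 0)) .stopf("noise_sd must be >= 0")
  if (any(specs$warmup_tau < 0))
    .stopf("warmup_tau must be >= 0 (0 disables the transient)")
  invisible(specs)
}

#' Survey effect sizes: per-sensor net-slope group distributions
#'
#' Per-sensor means and standard deviations (a.u./s) of the net
#' odor-emission slope for uninfested and mealybug-infested durian fruit, as
#' observed in the thirteen-sensor field survey. These are the default
#' group-level effect sizes from which the survey simulator draws per-fruit
#' slopes.
#'
#' @return data.frame with columns \code{sensor}, \code{mean_uninfested},
#'   \code{sd_uninfested}, \code{mean_infested}, \code{sd_infested}.
#' @examples
#' surveyEffectSizes()
#' @export
surveyEffectSizes <- function() {
  data.frame(
    sensor = c("MQ2", "MQ3", "MQ4", "MQ5", "MQ6", "MQ7", "MQ8", "MQ9",
               "MQ135", "GM102B", "GM302B", "GM502B", "GM702B"),
    mean_uninfested = c(-0.000001, 0.000054, -0.000013, 0.000023, 0.000026,
                        0.000152, 0.000020, 0.000020, 0.000021, -0.000008,
                        -0.000053, -0.000087, -0.000991),
    sd_uninfested = c(0.000088, 0.000117, 0.000095, 0.000112, 0.000030,
                      0.000243, 0.000025, 0.000027, 0.000054, 0.000107,
                      0.000172, 0.000208, 0.002331),
    mean_infested = c(-0.000010, -0.000042, -0.000009, -0.000049, -0.000020,
                      -0.000032, -0.000028, -0.000016, -0.000028, 0.000042,
                      0.000070, 0.000059, 0.000215),
    sd_infested = c(0.000027, 0.000032, 0.000036, 0.000046, 0.000019,
                    0.000031, 0.000026, 0.000009, 0.000021, 0.000055,
                    0.000056, 0.000061, 0.000219),
    stringsAsFactors = FALSE)
}
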