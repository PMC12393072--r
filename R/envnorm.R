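## Environmental compensation and two-step normalization of prototype
## readings. Calibration is a per-sensor multiple OLS of control-air
## readings on temperature and humidity jointly (marginal fits would be
## biased because T and RH covary diurnally).

#' Fit per-sensor temperature/humidity calibration
#'
#' Multiple OLS of each sensor's control-air (charcoal-filtered) readings on
#' temperature and relative humidity. Coefficients are stored together with
#' the calibration reference means (\code{T_ref}, \code{H_ref}) and fit
#' diagnostics.
#'
#' @param stream a control-air \code{\link{SensorStream}}, typically 24 h of
#'   continuous sampling (\code{\link{simulateControlAir}}).
#' @return An \code{\link{EnvCalibration}}.
#' @examples
#' cal <- fitEnvCalibration(simulateControlAir(gmSensorSpecs(),
#'                                             duration_h = 0.5, seed = 1))
#' calCoefficients(cal)
#' @export
fitEnvCalibration <- function(stream) {
  stopifnot(is(stream, "SensorStream"))
  d <- streamData(stream)
  X <- cbind(1, d$temp_c, d$rh_pct)
  if (qr(X)$rank < 3L)
    .stopf(paste0("calibration error: temperature and humidity are constant",
                  " or collinear; provide a richer environmental profile"))
  cf <- do.call(rbind, lapply(sensorNames(stream), function(s) {
    fit <- lm(d[[s]] ~ d$temp_c + d$rh_pct)
    b <- coef(fit)
    data.frame(sensor = s, intercept = unname(b[1]), beta_T = unname(b[2]),
               beta_H = unname(b[3]), T_ref = mean(d$temp_c),
               H_ref = mean(d$rh_pct), n = nrow(d),
               resid_sd = sqrt(sum(fit$residuals^2) /
                                 max(1, nrow(d) - 3)))
  }))
  new("EnvCalibration", coefficients = cf)
}

#' Apply environmental correction
#'
#' Subtracts the calibrated temperature and humidity response from raw
#' readings: \code{corrected = raw - beta_T (T - T_ref) - beta_H (H -
#' H_ref)}. At the calibration reference point the correction is the
#' identity.
#'
#' @param readings numeric matrix or data.frame of raw readings, one column
#'   per sensor named as in the calibration; or a
#'   \code{\link{SensorStream}}.
#' @param temp_c,rh_pct environment series matching the rows of
#'   \code{readings} (ignored for a \code{SensorStream}, which carries its
#'   own).
#' @param cal an \code{\link{EnvCalibration}} covering every sensor present.
#' @return corrected readings of the same shape (or a corrected
#'   \code{SensorStream}).
#' @export
applyEnvCorrection <- function(readings, temp_c = NULL, rh_pct = NULL, cal) {
  stopifnot(is(cal, "EnvCalibration"))
  cf <- calCoefficients(cal)
  if (is(readings, "SensorStream")) {
    d <- streamData(readings)
    d[, sensorNames(readings)] <-
      applyEnvCorrection(d[, sensorNames(readings), drop = FALSE],
                         d$temp_c, d$rh_pct, cal)
    return(SensorStream(d, sensorNames(readings)))
  }
  sens <- colnames(readings)
  miss <- setdiff(sens, cf$sensor)
  if (length(miss))
    .stopf("no calibration for sensor(s): %s", paste(miss, collapse = ", "))
  out <- as.matrix(readings)
  for (s in sens) {
    r <- cf[cf$sensor == s, ]
    out[, s] <- out[, s] - r$beta_T * (temp_c - r$T_ref) -
      r$beta_H * (rh_pct - r$H_ref)
  }
  if (is.data.frame(readings)) as.data.frame(out) else out
}

#' Two-step normalization of a sampling phase
#'
#' Step 1 divides each reading by the anchor value (by default the first
#' reading of the series, i.e. the initial value of the sampling phase);
#' step 2 re-expresses the ratio as a relative change: \code{x / anchor - 1}
#' (default) or \code{log(x / anchor)} (\code{method = "logratio"}). The
#' output is dimensionless, zero at the anchor, and invariant to rescaling
#' the raw series by any positive constant.
#'
#' @param readings numeric vector, or matrix/data.frame with one column per
#'   sensor (anchored column-wise).
#' @param method \code{"relative"} or \code{"logratio"}.
#' @param anchorValue optional explicit anchor (scalar, or one value per
#'   column); defaults to the first reading.
#' @return normalized readings, same shape as the input.
#' @examples
#' normalizeCycle(c(100, 110, 121))  # 0, 0.10, 0.21
#' @export
normalizeCycle <- function(readings, method = c("relative", "logratio"),
                           anchorValue = NULL) {
  method <- match.arg(method)
  if (is.null(dim(readings))) {
    anchor <- if (is.null(anchorValue)) readings[1] else anchorValue
    if (!is.finite(anchor) || anchor == 0)
      .stopf("normalization error: anchor value is 0 or not finite")
    ratio <- readings / anchor
    return(if (method == "relative") ratio - 1 else log(ratio))
  }
  m <- as.matrix(readings)
  anchor <- if (is.null(anchorValue)) m[1, ] else
    rep(anchorValue, length.out = ncol(m))
  if (any(!is.finite(anchor)) || any(anchor == 0))
    .stopf("normalization error: anchor value is 0 or not finite")
  out <- sweep(m, 2, anchor, "/")
  out <- if (method == "relative") out - 1 else log(out)
  if (is.data.frame(readings)) as.data.frame(out) else out
}

#' Persist / load a calibration as CSV
#'
#' @param cal an \code{\link{EnvCalibration}}.
#' @param path file path.
#' @return \code{readCalibrationCSV} returns an \code{EnvCalibration};
#'   \code{writeCalibrationCSV} returns \code{path} invisibly.
#' @export
writeCalibrationCSV <- function(cal, path) {
  stopifnot(is(cal, "EnvCalibration"))
  write.csv(calCoefficients(cal), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibrationCSV
#' @export
readCalibrationCSV <- function(path) {
  new("EnvCalibration", coefficients = read.csv(path, comment.char = "#"))
}

#' Build the multivariate feature table from prototype cycles
#'
#' Applies the full prototype preprocessing to every cycle of a stream:
#' segment into reset/sampling/rest cycles, environmentally correct the
#' sampling-phase readings, anchor the two-step normalization at the initial
#' value of the sampling phase (or at the first retained reading, see
#' \code{anchor}), trim to the last \code{keep_last} readings, and stack the
#' normalized readings into an \code{\link{OdorFeatureSet}} (one row per
#' retained reading, one column per channel).
#'
#' @param stream a prototype \code{\link{SensorStream}}.
#' @param cal optional \code{\link{EnvCalibration}}; when supplied, readings
#'   are corrected before normalization.
#' @param schedule the prototype \code{\link{phaseSchedule}}.
#' @param keep_last readings retained per sampling phase (default 30).
#' @param anchor \code{"sampling_start"} (default) anchors at the first
#'   reading of the sampling phase; \code{"trimmed_first"} at the first
#'   retained reading.
#' @param method normalization method, see \code{\link{normalizeCycle}}.
#' @return An \code{\link{OdorFeatureSet}} with per-reading labels
#'   \code{class}, \code{fruit_id}, \code{day}, \code{replicate},
#'   \code{cycle_id}.
#' @export
cycleFeatureSet <- function(stream, cal = NULL,
                            schedule = phaseSchedule("prototype"),
                            keep_last = 30,
                            anchor = c("sampling_start", "trimmed_first"),
                            method = c("relative", "logratio")) {
  anchor <- match.arg(anchor)
  method <- match.arg(method)
  sens <- sensorNames(stream)
  cycles <- segmentCycles(stream, schedule)
  if (!length(cycles)) .stopf("stream contains no complete cycle")
  values <- vector("list", length(cycles))
  labels <- vector("list", length(cycles))
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]
    samp <- cyc$data[cyc$data$phase == "sampling", , drop = FALSE]
    m <- as.matrix(samp[, sens, drop = FALSE])
    if (!is.null(cal))
      m <- applyEnvCorrection(m, samp$temp_c, samp$rh_pct, cal)
    anchorValue <- if (anchor == "sampling_start") m[1, ] else
      m[nrow(m) - keep_last + 1L, ]
    trimmed <- trimSampling(m, keep_last)
    values[[i]] <- normalizeCycle(trimmed, method, anchorValue)
    labels[[i]] <- data.frame(class = samp$group[1],
                              fruit_id = samp$fruit_id[1],
                              day = samp$day[1],
                              replicate = samp$replicate[1],
                              cycle_id = cyc$cycle_id)[rep(1, keep_last), ]
  }
  OdorFeatureSet(do.call(rbind, values),
                 do.call(rbind, c(labels, list(make.row.names = FALSE))))
}
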