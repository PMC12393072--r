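#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' SensorStream: raw per-second multichannel sensor readings
#'
#' Container for a raw electronic-nose data stream: one row per second, one
#' column per sensor channel (arbitrary units), plus acquisition phase,
#' environment (temperature, relative humidity) and sample metadata
#' (fruit id, infestation group, postharvest day, replicate).
#'
#' @slot data data.frame with columns \code{time_s}, \code{phase},
#'   \code{fruit_id}, \code{group}, \code{day}, \code{replicate}, one column
#'   per sensor, \code{temp_c}, \code{rh_pct}.
#' @slot sensors character vector of sensor column names.
#'
#' @aliases SensorStream-class
#' @exportClass SensorStream
setClass("SensorStream",
  representation(data = "data.frame", sensors = "character"))

setValidity("SensorStream", function(object) {
  d <- object@data
  msgs <- character(0)
  required <- c("time_s", "phase", "temp_c", "rh_pct")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    msgs <- c(msgs, paste("missing column(s):",
                          paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(object@sensors))
    msgs <- c(msgs, "sensor names must be unique")
  absent <- setdiff(object@sensors, names(d))
  if (length(absent))
    msgs <- c(msgs, paste("sensor column(s) absent from data:",
                          paste(absent, collapse = ", ")))
  if (!length(msgs) && nrow(d)) {
    if (any(diff(d$time_s) <= 0))
      msgs <- c(msgs, "time_s must be strictly increasing")
    if (!all(d$phase %in% .phaseLevels))
      msgs <- c(msgs, paste("unknown phase label(s):",
                            paste(setdiff(unique(d$phase), .phaseLevels),
                                  collapse = ", ")))
    rh <- d$rh_pct[is.finite(d$rh_pct)]
    if (length(rh) && (min(rh) < 0 || max(rh) > 100))
      msgs <- c(msgs, "rh_pct must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SensorStream-class constructor; metadata columns absent from
#'   \code{data} are filled with \code{NA}.
#' @param data data.frame of readings (see slots).
#' @param sensors character vector naming the sensor columns; by default all
#'   numeric columns that are not time/environment/metadata.
#' @return A \code{SensorStream}.
#' @export
SensorStream <- function(data, sensors = NULL) {
  meta <- c("time_s", "phase", "fruit_id", "group", "day", "replicate",
            "temp_c", "rh_pct")
  if (is.null(sensors))
    sensors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       meta)
  for (m in c("fruit_id", "group", "day", "replicate"))
    if (!m %in% names(data)) data[[m]] <- rep(NA, nrow(data))
  canonical <- c("time_s", "phase", "fruit_id", "group", "day",
                 "replicate", sensors, "temp_c", "rh_pct")
  extras <- setdiff(names(data), canonical) # e.g. extra field-log metadata columns
  data <- data[, c(canonical, extras), drop = FALSE]
  new("SensorStream", data = data, sensors = as.character(sensors))
}

#' EnvCalibration: per-sensor temperature/humidity response model
#'
#' Coefficients of the per-sensor multiple regression of control-air readings
#' on temperature and relative humidity, with the calibration reference means
#' and fit diagnostics. Used to subtract environment-driven signal before
#' normalization.
#'
#' @slot coefficients data.frame with columns \code{sensor},
#'   \code{intercept}, \code{beta_T} (a.u./degC), \code{beta_H} (a.u./%RH),
#'   \code{T_ref}, \code{H_ref}, \code{n}, \code{resid_sd}.
#'
#' @aliases EnvCalibration-class
#' @exportClass EnvCalibration
setClass("EnvCalibration", representation(coefficients = "data.frame"))

setValidity("EnvCalibration", function(object) {
  cf <- object@coefficients
  need <- c("sensor", "intercept", "beta_T", "beta_H", "T_ref", "H_ref",
            "n", "resid_sd")
  if (!all(need %in% names(cf)))
    return(paste("coefficients must have columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(cf$sensor)) return("duplicate sensor rows")
  if (any(cf$n < 100)) return("calibration requires n >= 100 per sensor")
  TRUE
})

#' OdorFeatureSet: corrected, normalized channel values per reading
#'
#' The multivariate analysis substrate: a
#' \linkS4class{SummarizedExperiment} whose assay \code{"odor"} holds one row
#' per sensor channel and one column per retained reading, with class /
#' fruit / day labels in \code{colData}.
#'
#' @aliases OdorFeatureSet-class
#' @exportClass OdorFeatureSet
setClass("OdorFeatureSet", contains = "SummarizedExperiment")

setValidity("OdorFeatureSet", function(object) {
  if (!"odor" %in% SummarizedExperiment::assayNames(object))
    return("assay 'odor' is required")
  a <- SummarizedExperiment::assay(object, "odor")
  if (any(!is.finite(a))) return("assay 'odor' must be finite (no NAs)")
  TRUE
})

#' @describeIn OdorFeatureSet-class constructor from a readings-by-channels
#'   matrix and per-reading labels.
#' @param values numeric matrix, rows = readings, columns = sensor channels.
#' @param labels data.frame of per-reading labels (e.g. \code{class},
#'   \code{fruit_id}, \code{day}).
#' @return An \code{OdorFeatureSet}.
#' @export
OdorFeatureSet <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("ch", seq_len(ncol(values)))
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(nrow(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(odor = t(values)),
    colData = S4Vectors::DataFrame(labels))
  new("OdorFeatureSet", se)
}

#' BMResult: Brunner-Munzel two-sample test result
#'
#' @slot sensor sensor name (may be \code{NA} for ad-hoc comparisons).
#' @slot statistic studentized Brunner-Munzel statistic.
#' @slot df Welch-type degrees of freedom.
#' @slot p_value two-sided p-value from the t reference distribution.
#' @slot p_hat estimated relative effect P(X<Y) + 0.5 P(X=Y).
#' @slot summary data.frame of per-group mean, sd and n.
#'
#' @aliases BMResult-class
#' @exportClass BMResult
setClass("BMResult",
  representation(sensor = "character", statistic = "numeric", df = "numeric",
                 p_value = "numeric", p_hat = "numeric",
                 summary = "data.frame"))

setValidity("BMResult", function(object) {
  if (object@p_hat < 0 || object@p_hat > 1) return("p_hat must be in [0,1]")
  if (!is.na(object@p_value) && (object@p_value < 0 || object@p_value > 1))
    return("p_value must be in [0,1]")
  TRUE
})

#' AnosimResult: analysis-of-similarities permutation test result
#'
#' @slot statistic ANOSIM R in [-1, 1].
#' @slot p_value permutation p-value.
#' @slot n_permutations number of random permutations used (0 when the null
#'   distribution was enumerated exactly).
#' @slot exact logical; TRUE when all distinct relabelings were enumerated.
#' @slot seed seed used for the permutation stream (NA when exact).
#'
#' @aliases AnosimResult-class
#' @exportClass AnosimResult
setClass("AnosimResult",
  representation(statistic = "numeric", p_value = "numeric",
                 n_permutations = "numeric", exact = "logical",
                 seed = "numeric"))

#' LDAModel: linear discriminant axes and class geometry
#'
#' @slot scaling matrix of axis coefficients, rows = channels, columns =
#'   discriminant axes (sign-canonicalized: largest-magnitude coefficient
#'   positive).
#' @slot centers matrix of class means in the original channel space.
#' @slot priors named numeric vector of class prior probabilities.
#' @slot channels character vector of channel names (coefficient order).
#' @slot svd eigenvalues of the discriminant problem (between/within ratios).
#'
#' @aliases LDAModel-class
#' @exportClass LDAModel
setClass("LDAModel",
  representation(scaling = "matrix", centers = "matrix", priors = "numeric",
                 channels = "character", svd = "numeric"))

setValidity("LDAModel", function(object) {
  k <- nrow(object@centers); p <- length(object@channels)
  if (k > 0 && ncol(object@scaling) > min(k - 1L, p))
    return("number of axes exceeds min(#classes - 1, #channels)")
  if (nrow(object@scaling) != p) return("scaling rows must match channels")
  TRUE
})

#' OdorConfusion: confusion matrix in predicted-by-true orientation
#'
#' @slot counts integer matrix, rows = predicted class, columns = true class.
#' @slot accuracy named numeric vector of per-class accuracy in percent
#'   (diagonal over column total).
#'
#' @aliases OdorConfusion-class
#' @exportClass OdorConfusion
setClass("OdorConfusion",
  representation(counts = "matrix", accuracy = "numeric"))

setValidity("OdorConfusion", function(object) {
  if (any(object@counts < 0)) return("counts must be nonnegative")
  acc <- object@accuracy[is.finite(object@accuracy)]
  if (length(acc) && (min(acc) < 0 || max(acc) > 100))
    return("accuracies must be percentages in [0, 100]")
  TRUE
})
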