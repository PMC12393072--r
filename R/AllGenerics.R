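#' @rdname SensorStream-class
#' @param x a \code{SensorStream}.
#' @export
setGeneric("streamData", function(x) standardGeneric("streamData"))

#' @rdname SensorStream-class
#' @export
setGeneric("sensorNames", function(x) standardGeneric("sensorNames"))

#' @rdname EnvCalibration-class
#' @param object the object.
#' @export
setGeneric("calCoefficients",
           function(object) standardGeneric("calCoefficients"))

setMethod("streamData", "SensorStream", function(x) x@data)
setMethod("sensorNames", "SensorStream", function(x) x@sensors)
setMethod("calCoefficients", "EnvCalibration",
          function(object) object@coefficients)

setMethod("show", "SensorStream", function(object) {
  d <- object@data
  cat(sprintf("SensorStream: %d readings x %d sensors\n",
              nrow(d), length(object@sensors)))
  cat("  sensors:", paste(object@sensors, collapse = ", "), "\n")
  if (nrow(d)) {
    ph <- table(d$phase)
    cat("  phases: ",
        paste(sprintf("%s(%d)", names(ph), as.integer(ph)), collapse = " "),
        "\n", sep = "")
    cat(sprintf("  time: %g..%g s\n", d$time_s[1], d$time_s[nrow(d)]))
  }
})

setMethod("show", "EnvCalibration", function(object) {
  cat(sprintf("EnvCalibration for %d sensor(s)\n",
              nrow(object@coefficients)))
  print(object@coefficients, row.names = FALSE, digits = 4)
})

setMethod("show", "BMResult", function(object) {
  cat("Brunner-Munzel test",
      if (!is.na(object@sensor)) sprintf("[%s]", object@sensor), "\n")
  cat(sprintf("  BM = %.4g, df = %.3g, p = %.4g, p-hat = %.4g\n",
              object@statistic, object@df, object@p_value, object@p_hat))
})

setMethod("show", "AnosimResult", function(object) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s)\n", object@statistic,
              object@p_value,
              if (object@exact) "exact enumeration"
              else sprintf("%d permutations, seed %s", object@n_permutations,
                           format(object@seed))))
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: %d class(es), %d axis/axes over %d channel(s)\n",
              nrow(object@centers), ncol(object@scaling),
              length(object@channels)))
  print(round(object@scaling, 6))
})

setMethod("show", "OdorConfusion", function(object) {
  cat("Confusion matrix (rows = predicted, columns = true):\n")
  print(object@counts)
  cat("Per-class accuracy (%):\n")
  print(round(object@accuracy, 1))
})
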