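## CSV stream dialect, run configuration, and output stamping.
## Stream dialect: header row mandatory, UTF-8, "." decimal separator,
## columns time_s,phase,fruit_id,group,day,replicate,<sensor...>,temp_c,rh_pct;
## extra columns are preserved as metadata. Lines starting with '#' are
## stamp/comment lines.

#' Read / write a sensor stream CSV
#'
#' @param path file path.
#' @param sensors sensor column names; by default every numeric column that
#'   is not time/environment/metadata.
#' @return \code{readStreamCSV}: a \code{\link{SensorStream}};
#'   \code{writeStreamCSV}: \code{path}, invisibly.
#' @export
readStreamCSV <- function(path, sensors = NULL) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("time_s", "phase", "temp_c", "rh_pct")
  miss <- setdiff(required, names(d))
  if (length(miss))
    .stopf("schema error: missing column(s) %s in %s",
           paste(miss, collapse = ", "), path)
  if (nrow(d) > 1 && any(diff(d$time_s) <= 0))
    .stopf("ordering error: time_s is not strictly increasing in %s (first at row %d)",
           path, which(diff(d$time_s) <= 0)[1] + 1L)
  SensorStream(d, sensors = sensors)
}

#' @rdname readStreamCSV
#' @param stream a \code{\link{SensorStream}}.
#' @param stamp optional character vector of stamp lines (written as
#'   \code{#}-prefixed comments before the header).
#' @export
writeStreamCSV <- function(stream, path, stamp = NULL) {
  stopifnot(is(stream, "SensorStream"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  write.csv(streamData(stream), con, row.names = FALSE)
  invisible(path)
}

.configDefaults <- function() list(
  mode = "outdoor",              # survey | outdoor | indoor
  seed = 1L,
  alpha = 0.05,
  n_permutations = 199L,
  metric = "euclidean",
  normalization = "relative",    # relative | logratio
  anchor = "sampling_start",     # sampling_start | trimmed_first
  coverage_level = 0.95,
  calibration_hours = 24,
  keep_last = 30L,
  out_dir = ".",
  timestamp = FALSE,
  input = NULL                   # optional path to an existing stream CSV
)

#' Read and validate a run configuration
#'
#' Configurations are flat YAML files; unknown keys are rejected, every
#' field is validated before any stage runs, and missing keys take the
#' documented defaults.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @param overrides named list applied on top of the file values (CLI
#'   flags).
#' @return named list of class \code{"runConfig"}.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .configDefaults()
  given <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(given)) .stopf("config must be a YAML mapping")
  given <- utils::modifyList(given, overrides)
  unknown <- setdiff(names(given), names(cfg))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, given)
  if (!cfg$mode %in% c("survey", "outdoor", "indoor"))
    .stopf("mode must be survey, outdoor or indoor")
  if (!is.numeric(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1)
    .stopf("alpha must be in [0, 1]")
  if (!.isCount(cfg$n_permutations))
    .stopf("n_permutations must be a positive integer")
  if (!cfg$metric %in% c("euclidean", "bray"))
    .stopf("metric must be euclidean or bray")
  if (!cfg$normalization %in% c("relative", "logratio"))
    .stopf("normalization must be relative or logratio")
  if (!cfg$anchor %in% c("sampling_start", "trimmed_first"))
    .stopf("anchor must be sampling_start or trimmed_first")
  if (!is.numeric(cfg$coverage_level) || cfg$coverage_level <= 0 ||
      cfg$coverage_level >= 1)
    .stopf("coverage_level must be in (0, 1)")
  if (!.isCount(cfg$keep_last)) .stopf("keep_last must be a positive integer")
  structure(cfg, class = c("runConfig", "list"))
}

## stamp lines embedded in every artifact: tool version + config hash (+
## optional timestamp, suppressed by default so reruns are byte-identical)
.stampLines <- function(cfg) {
  lines <- c(sprintf("durianose %s", as.character(packageVersion("durianose"))),
             sprintf("config_hash=%s seed=%d", fnv1aHash(.configString(cfg)),
                     as.integer(cfg$seed)))
  if (isTRUE(cfg$timestamp))
    lines <- c(lines, format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  lines
}

.writeStamped <- function(df, path, cfg) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", .stampLines(cfg)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
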