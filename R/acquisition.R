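## Turning raw per-second streams into per-sensor odor-emission features:
## 10-s windowed medians, OLS slopes, room-air subtraction, and the
## discard-70/keep-30 trim of prototype sampling phases.

#' Acquisition phase schedule
#'
#' Two presets of one code path: the \code{"prototype"} device runs
#' relay-controlled reset (pump on, 300 s), sampling (fan on, 100 s) and
#' rest (200 s) phases; the \code{"survey"} system measures room air for
#' 100 s followed by sample air for 100 s.
#'
#' @param preset \code{"prototype"} or \code{"survey"}.
#' @param reset_s,sampling_s,rest_s prototype phase durations (s).
#' @param room_air_s,sample_air_s survey phase durations (s).
#' @return list of class \code{"phaseSchedule"} with elements \code{preset}
#'   and \code{phases} (named durations, in acquisition order).
#' @examples
#' phaseSchedule("prototype")$phases
#' @export
phaseSchedule <- function(preset = c("prototype", "survey"), reset_s = 300,
                          sampling_s = 100, rest_s = 200, room_air_s = 100,
                          sample_air_s = 100) {
  preset <- match.arg(preset)
  phases <- switch(preset,
    prototype = c(reset = reset_s, sampling = sampling_s, rest = rest_s),
    survey = c(room_air = room_air_s, sample_air = sample_air_s))
  if (any(phases <= 0)) .stopf("all phase durations must be > 0")
  structure(list(preset = preset, phases = phases), class = "phaseSchedule")
}

#' Segment a raw stream into measurement cycles
#'
#' Splits a stream into consecutive cycles following the schedule's phase
#' grammar. Every reading is assigned to exactly one cycle; a trailing
#' partial cycle is dropped with a warning. Within a phase, up to 5\% of
#' dropped seconds are linearly interpolated; more is an error. A phase
#' sequence that violates the schedule grammar is a parse error naming the
#' offending timestamp.
#'
#' @param stream a \code{\link{SensorStream}}.
#' @param schedule a \code{\link{phaseSchedule}}.
#' @return list of cycles; each cycle is a list with \code{cycle_id}
#'   (0-based), \code{data} (the cycle's rows, gaps interpolated) and
#'   \code{schedule}. The number of original readings left unassigned is in
#'   \code{attr(, "dropped")}.
#' @export
segmentCycles <- function(stream, schedule) {
  stopifnot(is(stream, "SensorStream"), inherits(schedule, "phaseSchedule"))
  d <- streamData(stream)
  if (!nrow(d)) {
    out <- list()
    attr(out, "dropped") <- 0L
    return(out)
  }
  pattern <- names(schedule$phases)
  runs <- rle(as.character(d$phase))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nRuns <- length(runs$values)
  ## validate the phase grammar run by run
  for (k in seq_len(nRuns)) {
    expect <- pattern[(k - 1L) %% length(pattern) + 1L]
    if (runs$values[k] != expect)
      .stopf(paste0("phase sequence violates the schedule at time_s=%g: ",
                    "found '%s' where '%s' was expected"),
             d$time_s[starts[k]], runs$values[k], expect)
  }
  numCols <- names(d)[vapply(d, is.numeric, logical(1))]
  numCols <- setdiff(numCols, "time_s")
  fillRun <- function(rows, D, phase) {
    span <- rows$time_s[nrow(rows)] - rows$time_s[1] + 1
    if (span != D) return(NULL)        # partial (trailing) run
    if (nrow(rows) == D) return(rows)  # complete
    missing <- D - nrow(rows)
    if (missing > 0.05 * D)
      .stopf("phase '%s' starting at time_s=%g is missing %d of %d seconds (> 5%%)",
             phase, rows$time_s[1], missing, D)
    grid <- seq(rows$time_s[1], length.out = D)
    out <- rows[rep(1L, D), , drop = FALSE]
    out$time_s <- grid
    out$phase <- phase
    for (cc in numCols) {
      if (sum(!is.na(rows[[cc]])) < 2L) next  # constant/NA metadata column
      out[[cc]] <- stats::approx(rows$time_s, rows[[cc]], xout = grid,
                                 rule = 2)$y
    }
    rownames(out) <- NULL
    out
  }
  nCycles <- nRuns %/% length(pattern)
  cycles <- vector("list", nCycles)
  assigned <- 0L
  complete <- 0L
  for (ci in seq_len(nCycles)) {
    ks <- (ci - 1L) * length(pattern) + seq_along(pattern)
    parts <- vector("list", length(ks))
    ok <- TRUE
    for (j in seq_along(ks)) {
      k <- ks[j]
      rows <- d[starts[k]:ends[k], , drop = FALSE]
      filled <- fillRun(rows, schedule$phases[[j]], pattern[j])
      if (is.null(filled)) { ok <- FALSE; break }
      parts[[j]] <- filled
    }
    if (!ok) break
    complete <- complete + 1L
    assigned <- assigned + sum(ends[ks] - starts[ks] + 1L)
    cyc <- do.call(rbind, parts)
    rownames(cyc) <- NULL
    cycles[[ci]] <- list(cycle_id = ci - 1L, data = cyc,
                         schedule = schedule)
  }
  cycles <- cycles[seq_len(complete)]
  dropped <- nrow(d) - assigned
  if (dropped > 0L)
    .warnf("dropped %d trailing reading(s) not forming a complete cycle",
           dropped)
  attr(cycles, "dropped") <- dropped
  cycles
}

#' Windowed medians of a per-second series
#'
#' Median of every consecutive \code{window_s}-second window (half-open
#' \code{[k*w, (k+1)*w)} in 0-based sample index). Even-count windows use
#' the mean of the two central order statistics. The abscissa returned for
#' each window is its midpoint in seconds (5, 15, ..., 95 for the default
#' 100 s / 10 s), so downstream slopes are in a.u./s.
#'
#' @param values numeric series, one reading per second.
#' @param window_s window width in seconds (default 10).
#' @param t0 time of the first reading (s).
#' @return data.frame with columns \code{time_s} (window midpoints) and
#'   \code{median}.
#' @examples
#' windowMedians(seq(0, 99))  # medians of a linear ramp
#' @export
windowMedians <- function(values, window_s = 10, t0 = 0) {
  n <- length(values)
  if (n < window_s)
    .stopf("insufficient data: %d reading(s), need at least one %d-s window",
           n, window_s)
  if (n %% window_s != 0)
    .stopf("series length (%d) must be a positive multiple of window_s (%d)",
           n, window_s)
  k <- n %/% window_s
  med <- vapply(seq_len(k), function(i)
    median(values[((i - 1) * window_s + 1):(i * window_s)]), numeric(1))
  data.frame(time_s = t0 + (seq_len(k) - 1) * window_s + window_s / 2,
             median = med)
}

#' Ordinary least-squares slope
#'
#' Closed-form OLS slope of \code{value} on \code{time_s}; the intercept is
#' discarded.
#'
#' @param time_s,value numeric vectors of equal length (>= 2 distinct
#'   times).
#' @return slope in a.u./s.
#' @examples
#' olsSlope(0:9, 2 * (0:9) + 1)  # 2
#' @export
olsSlope <- function(time_s, value) {
  if (length(time_s) != length(value))
    .stopf("'time_s' and 'value' must have equal length")
  if (length(unique(time_s)) < 2L)
    .stopf("degenerate design: need at least 2 distinct time values")
  tc <- time_s - mean(time_s)
  sum(tc * (value - mean(value))) / sum(tc^2)
}

#' Slope features and room-air subtraction
#'
#' \code{slopeFeature} bundles a per-sensor slope with its context;
#' \code{netOdorSlope} subtracts the room-air slope from the sample-air
#' slope of the same sensor, yielding the net odor-emission rate of the
#' sample.
#'
#' @param sensor sensor name.
#' @param slope slope in a.u./s.
#' @param context one of \code{"room_air"}, \code{"sample_air"},
#'   \code{"net"}.
#' @return \code{slopeFeature}: a list of class \code{"slopeFeature"};
#'   \code{netOdorSlope}: a \code{"slopeFeature"} with context
#'   \code{"net"} and \code{slope = sample - room}.
#' @examples
#' netOdorSlope(slopeFeature("MQ7", 0.000120, "sample_air"),
#'              slopeFeature("MQ7", -0.000032, "room_air"))$slope
#' @export
slopeFeature <- function(sensor, slope,
                         context = c("room_air", "sample_air", "net")) {
  context <- match.arg(context)
  structure(list(sensor = as.character(sensor), slope = as.numeric(slope),
                 context = context), class = "slopeFeature")
}

#' @rdname slopeFeature
#' @param sample,room \code{slopeFeature}s for the same sensor.
#' @export
netOdorSlope <- function(sample, room) {
  stopifnot(inherits(sample, "slopeFeature"), inherits(room, "slopeFeature"))
  if (!identical(sample$sensor, room$sensor))
    .stopf("sensor mismatch: sample '%s' vs room '%s'", sample$sensor,
           room$sensor)
  slopeFeature(sample$sensor, sample$slope - room$slope, "net")
}

#' Trim a sampling phase to its stabilized tail
#'
#' Discards the leading readings of a sampling phase, retaining the last
#' \code{keep_last} (default 30 of 100: the warm-up transient after
#' switching from control air to sample air contaminates the first 70
#' points). Order and timestamps are preserved.
#'
#' @param readings numeric vector or data.frame of sampling-phase rows.
#' @param keep_last number of trailing readings to retain.
#' @return the trimmed readings, same type as the input.
#' @export
trimSampling <- function(readings, keep_last = 30) {
  byRow <- !is.null(dim(readings))
  n <- if (byRow) nrow(readings) else length(readings)
  if (n < keep_last)
    .stopf("insufficient data: %d reading(s), need at least %d", n,
           keep_last)
  if (byRow) {
    out <- readings[(n - keep_last + 1L):n, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else readings[(n - keep_last + 1L):n]
}

#' Extract per-sensor slope features from a survey stream
#'
#' Applies the survey measurement logic to every cycle: 10-s windowed
#' medians of each phase, OLS slope of the medians, and room-air
#' subtraction, giving one net odor-emission slope per sensor per cycle.
#'
#' @param stream a \code{\link{SensorStream}} of paired
#'   room-air/sample-air cycles (e.g. from
#'   \code{\link{simulateSurveyExperiment}}, which returns it as
#'   \code{$stream}).
#' @param schedule the survey \code{\link{phaseSchedule}}.
#' @param window_s median window width (s).
#' @return data.frame with columns \code{cycle_id}, \code{fruit_id},
#'   \code{group}, \code{day}, \code{sensor}, \code{slope_room},
#'   \code{slope_sample}, \code{slope_net}.
#' @export
extractSurveySlopes <- function(stream, schedule = phaseSchedule("survey"),
                                window_s = 10) {
  cycles <- segmentCycles(stream, schedule)
  sens <- sensorNames(stream)
  out <- lapply(cycles, function(cyc) {
    d <- cyc$data
    room <- d[d$phase == "room_air", , drop = FALSE]
    samp <- d[d$phase == "sample_air", , drop = FALSE]
    sr <- vapply(sens, function(s) {
      m <- windowMedians(room[[s]], window_s)
      olsSlope(m$time_s, m$median)
    }, numeric(1))
    ss <- vapply(sens, function(s) {
      m <- windowMedians(samp[[s]], window_s)
      olsSlope(m$time_s, m$median)
    }, numeric(1))
    data.frame(cycle_id = cyc$cycle_id, fruit_id = d$fruit_id[1],
               group = d$group[1], day = d$day[1], sensor = sens,
               slope_room = sr, slope_sample = ss, slope_net = ss - sr,
               row.names = NULL)
  })
  do.call(rbind, out)
}
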