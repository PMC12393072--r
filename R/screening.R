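## Per-sensor two-group screening with the Brunner-Munzel test: a rank-based
## two-sample test of the relative effect P(X < Y) + 0.5 P(X = Y), robust to
## unequal variances and distributions (the situation at n = 5 fruits per
## group with wildly different per-group spreads).

#' Brunner-Munzel two-sample test
#'
#' Midrank-based estimate of the relative effect p-hat = P(X < Y) +
#' 0.5 P(X = Y), studentized with the Welch-Satterthwaite-type degrees of
#' freedom of the original test, and a two-sided p-value from the t
#' reference distribution. The statistic is 0 exactly when p-hat = 0.5, is
#' negative when Y tends to be smaller than X, and swapping the samples
#' negates it (p-hat maps to 1 - p-hat, p unchanged).
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param sensor optional sensor name carried into the result.
#' @return A \code{\link{BMResult}}.
#' @examples
#' brunnerMunzel(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
brunnerMunzel <- function(x, y, sensor = NA_character_) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    .stopf("each group needs at least 2 finite values (got %d and %d)",
           n1, n2)
  N <- n1 + n2
  r <- rank(c(x, y))            # midranks
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  s2 <- n1 * v1 + n2 * v2
  if (s2 == 0)
    .stopf(paste0("degenerate variance: the rank configuration admits no ",
                  "variance estimate (all values tied within groups or the ",
                  "samples are completely separated); consider more data or ",
                  "an exact permutation test"))
  statistic <- n1 * n2 * (m2 - m1) / (N * sqrt(s2))
  df <- s2^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(statistic), df)
  new("BMResult", sensor = as.character(sensor), statistic = statistic,
      df = df, p_value = p, p_hat = p_hat,
      summary = data.frame(group = c("x", "y"),
                           mean = c(mean(x), mean(y)),
                           sd = c(stats::sd(x), stats::sd(y)),
                           n = c(n1, n2)))
}

#' Screen sensors for a two-group effect
#'
#' Runs one Brunner-Munzel test per sensor on a table of net
#' odor-emission slopes and flags sensors with p below \code{alpha}. No
#' multiple-testing correction is applied across sensors (raw per-sensor p
#' values are reported; treat flags from many sensors accordingly).
#'
#' @param slopes data.frame with columns \code{sensor}, \code{group} (two
#'   levels) and \code{slope_net}, e.g. from
#'   \code{\link{extractSurveySlopes}}.
#' @param alpha significance threshold (default 0.05).
#' @param reference the group treated as X (first sample); by default
#'   \code{"durian_uninfested"} when present, so negative statistics mean
#'   the infested group's slopes are lower.
#' @return data.frame of class \code{"sensorScreen"} with columns
#'   \code{sensor}, \code{mean_x}, \code{sd_x}, \code{mean_y}, \code{sd_y},
#'   \code{bm}, \code{df}, \code{p}, \code{direction} (sign of the mean
#'   difference y - x) and \code{flag}.
#' @export
screenSensors <- function(slopes, alpha = 0.05, reference = NULL) {
  need <- c("sensor", "group", "slope_net")
  if (!all(need %in% names(slopes)))
    .stopf("'slopes' must have columns: %s", paste(need, collapse = ", "))
  grp <- unique(as.character(slopes$group))
  if (length(grp) != 2L)
    .stopf("screening requires exactly 2 groups (found %d)", length(grp))
  if (is.null(reference))
    reference <- if ("durian_uninfested" %in% grp) "durian_uninfested"
                 else grp[1]
  other <- setdiff(grp, reference)
  out <- do.call(rbind, lapply(unique(slopes$sensor), function(s) {
    xs <- slopes$slope_net[slopes$sensor == s & slopes$group == reference]
    ys <- slopes$slope_net[slopes$sensor == s & slopes$group == other]
    if (length(xs) < 2L || length(ys) < 2L)
      .stopf("sensor %s: need >= 2 slopes per group", s)
    bm <- tryCatch(brunnerMunzel(xs, ys, sensor = s), error = function(e) e)
    if (inherits(bm, "error")) {
      ## degenerate variance: record the limiting behaviour instead of
      ## aborting the whole report (complete separation -> p = 0; groups
      ## indistinguishable in rank -> p = 1)
      p_hat <- (sum(outer(xs, ys, "<")) + 0.5 * sum(outer(xs, ys, "=="))) /
        (length(xs) * length(ys))
      stat <- if (p_hat == 0.5) 0 else sign(p_hat - 0.5) * Inf
      pv <- if (p_hat %in% c(0, 1)) 0 else 1
      return(data.frame(sensor = s, mean_x = mean(xs), sd_x = stats::sd(xs),
                        mean_y = mean(ys), sd_y = stats::sd(ys), bm = stat,
                        df = NA_real_, p = pv,
                        direction = sign(mean(ys) - mean(xs)),
                        flag = pv < alpha))
    }
    data.frame(sensor = s, mean_x = mean(xs), sd_x = stats::sd(xs),
               mean_y = mean(ys), sd_y = stats::sd(ys),
               bm = bm@statistic, df = bm@df, p = bm@p_value,
               direction = sign(mean(ys) - mean(xs)),
               flag = bm@p_value < alpha)
  }))
  attr(out, "reference") <- reference
  attr(out, "alpha") <- alpha
  class(out) <- c("sensorScreen", "data.frame")
  out
}
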