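## Core functional primitives shared by every modality extractor:
## framewise derivatives, the six basic statistics, mean +/- SD threshold run
## detection and run-duration statistics.

#' Construct a framewise signal channel
#'
#' A channel is a regularly sampled low-level signal (one value per frame)
#' with an explicit sampling rate. Missing frames are represented as `NA` and
#' tracked explicitly: they break threshold runs and are excluded from
#' statistics, never zero-filled.
#'
#' @param values Numeric vector, possibly containing `NA` for missing frames.
#' @param rate Sampling rate in Hz (frames per second), positive.
#' @param name Channel name, used in error messages and feature names.
#' @return An object of class `emofun_channel`.
#' @export
#' @examples
#' ch <- channel(c(0, 1, 3, 2), rate = 30, name = "au1")
#' derivative(ch)$values
channel <- function(values, rate, name = "channel") {
  if (!is.numeric(values)) stop("channel values must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("channel rate must be a single positive number")
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 name = as.character(name)[1L]),
            class = "emofun_channel")
}

#' @export
print.emofun_channel <- function(x, ...) {
  cat(sprintf("<channel '%s': %d frames @ %g Hz, %d missing>\n",
              x$name, length(x$values), x$rate, sum(is.na(x$values))))
  invisible(x)
}

ch_values <- function(ch) {
  if (inherits(ch, "emofun_channel")) ch$values else as.numeric(ch)
}

ch_rate <- function(ch, rate = NULL) {
  if (!is.null(rate)) return(rate)
  if (inherits(ch, "emofun_channel")) ch$rate
  else stop("rate must be given when the input is a bare numeric vector")
}

ch_label <- function(ch) {
  if (inherits(ch, "emofun_channel")) ch$name else "channel"
}

#' Framewise derivative (velocity / acceleration) of a channel
#'
#' Velocity is the per-frame first difference and acceleration the first
#' difference of the velocity; both stay in value-per-frame units (durations,
#' not derivatives, are later converted to seconds through the sampling
#' rate). The output is aligned to the frame index, so the first `order`
#' entries are missing; a missing input frame propagates to every difference
#' that involves it.
#'
#' @param ch An [channel()] object or numeric vector.
#' @param order 1 for velocity, 2 for acceleration.
#' @param rate Sampling rate, only needed when `ch` is a bare vector.
#' @return A channel of the same length as the input.
#' @export
derivative <- function(ch, order = 1L, rate = NULL) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 (velocity) or 2 (acceleration)")
  x <- ch_values(ch)
  if (length(x) < order + 1L)
    stop(sprintf("channel '%s' too short (%d frames) for an order-%d derivative",
                 ch_label(ch), length(x), order))
  out <- c(rep(NA_real_, order), diff(x, differences = order))
  channel(out, ch_rate(ch, rate),
          paste0(ch_label(ch), if (order == 1L) "_vel" else "_acc"))
}

#' The six basic statistics of a channel
#'
#' Mean, range, minimum, maximum, standard deviation and variance over the
#' non-missing frames. The sample (n - 1) variance convention is used; a
#' single-frame channel has zero spread by definition, so its sd, var and
#' range are 0. An all-missing channel propagates `NA` for all six values.
#'
#' @param ch A [channel()] or numeric vector.
#' @return Named numeric vector: `mean`, `range`, `min`, `max`, `sd`, `var`.
#' @export
basic_stats <- function(ch) {
  x <- ch_values(ch)
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(c(mean = NA_real_, range = NA_real_, min = NA_real_,
             max = NA_real_, sd = NA_real_, var = NA_real_))
  s <- if (length(x) == 1L) 0 else stats::sd(x)
  mn <- min(x); mx <- max(x)
  c(mean = mean(x), range = mx - mn, min = mn, max = mx, sd = s, var = s * s)
}

## -- run sets -----------------------------------------------------------

new_runs <- function(start, end, total_frames) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 total_frames = as.integer(total_frames)),
            class = "emofun_runs")
}

#' @export
print.emofun_runs <- function(x, ...) {
  cat(sprintf("<runs: %d run(s) over %d frames>\n", length(x$start), x$total_frames))
  if (length(x$start))
    print(data.frame(start = x$start, end = x$end, frames = x$end - x$start))
  invisible(x)
}

#' Number of runs in a run set
#' @param rs An `emofun_runs` object.
#' @return Integer count.
#' @export
n_runs <- function(rs) length(rs$start)

## maximal TRUE runs of a logical vector; NA counts as FALSE (breaks runs)
runs_from_logical <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  keep <- r$values
  new_runs(start = (ends - r$lengths + 1L)[keep], end = ends[keep] + 1L,
           total_frames = length(flag))
}

#' Detect threshold-crossing runs within a segment
#'
#' The threshold is the segment's own mean plus (side `"above"`) or minus
#' (side `"below"`) its standard deviation, computed over the channel's
#' non-missing frames. Runs are maximal stretches of consecutive frames
#' strictly beyond the threshold; ties fall outside runs and missing frames
#' break runs. A zero-variance channel therefore yields an empty run set (no
#' frame is strictly beyond its own mean). For non-negative magnitude
#' channels `floor_at_zero` clips a negative below-threshold at 0.
#'
#' @param ch A [channel()] or numeric vector with at least 2 non-missing
#'   values.
#' @param side `"above"` or `"below"`.
#' @param floor_at_zero Clip a negative `mean - sd` threshold at 0 (used for
#'   magnitude channels such as absolute velocity).
#' @return An `emofun_runs` object with half-open `[start, end)` frame runs.
#' @export
#' @examples
#' threshold_runs(c(0, 0, 0, 10, 10, 0), side = "above")
threshold_runs <- function(ch, side = c("above", "below"), floor_at_zero = FALSE) {
  side <- match.arg(side)
  x <- ch_values(ch)
  ok <- !is.na(x)
  if (sum(ok) < 2L)
    stop(sprintf("channel '%s' needs >= 2 non-missing values for threshold runs",
                 ch_label(ch)))
  mu <- mean(x[ok]); s <- stats::sd(x[ok])
  if (side == "above") {
    runs_from_logical(x > mu + s)
  } else {
    thr <- mu - s
    if (floor_at_zero) thr <- max(thr, 0)
    runs_from_logical(x < thr)
  }
}

## as threshold_runs but degenerate inputs (< 2 non-missing) give an empty
## run set instead of an error; used inside extractors where sparse channels
## (e.g. mostly-absent eyes) are legitimate data.
safe_threshold_runs <- function(x, side, floor_at_zero = FALSE) {
  if (sum(!is.na(ch_values(x))) < 2L)
    return(new_runs(integer(), integer(), length(ch_values(x))))
  threshold_runs(x, side, floor_at_zero)
}

#' The six duration statistics of a run set
#'
#' Maximum, minimum, range and mean of the run durations in seconds, the
#' rate of run frames to total frames, and the run count. An empty run set
#' yields all zeros.
#'
#' @param rs An `emofun_runs` object.
#' @param rate Sampling rate in Hz used to convert frame counts to seconds.
#' @return Named numeric vector: `dur_max`, `dur_min`, `dur_range`,
#'   `dur_mean`, `dur_rate`, `count`.
#' @export
duration_stats <- function(rs, rate) {
  if (rs$total_frames <= 0L) stop("run set has no frames")
  if (length(rs$start) == 0L)
    return(c(dur_max = 0, dur_min = 0, dur_range = 0, dur_mean = 0,
             dur_rate = 0, count = 0))
  frames <- rs$end - rs$start
  d <- frames / rate
  c(dur_max = max(d), dur_min = min(d), dur_range = max(d) - min(d),
    dur_mean = mean(d), dur_rate = sum(frames) / rs$total_frames,
    count = length(d))
}

#' Fast / slow / continuous / steady event runs of a channel
#'
#' Events are detected on derivative magnitudes with the segment-level
#' mean +/- SD threshold device: fast changes are frames where the absolute
#' velocity is above its mean + SD, slow changes where it is below its
#' mean - SD (floored at 0, since magnitudes are non-negative); continuous
#' changes and steady state are the same rules applied to the absolute
#' acceleration.
#'
#' @param ch A [channel()] or numeric vector of length >= 3.
#' @param rate Sampling rate, only needed for bare vectors.
#' @return List of four `emofun_runs`: `fast`, `slow`, `continuous`, `steady`.
#' @export
event_channels <- function(ch, rate = NULL) {
  vel <- derivative(ch, 1L, rate)
  acc <- derivative(ch, 2L, rate)
  av <- abs(vel$values)
  aa <- abs(acc$values)
  list(fast = safe_threshold_runs(av, "above"),
       slow = safe_threshold_runs(av, "below", floor_at_zero = TRUE),
       continuous = safe_threshold_runs(aa, "above"),
       steady = safe_threshold_runs(aa, "below", floor_at_zero = TRUE))
}
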