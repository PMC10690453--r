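#' Construct a calcium indicator trace
#'
#' A unit-tagged time series, used both for slow indicator recordings
#' (minutes) and simulated cytosolic traces (ms).
#'
#' @param time strictly increasing time points.
#' @param signal concentration or indicator signal per time point, finite.
#' @param time_unit `"min"` or `"ms"`.
#' @return An object of class `ca_trace` (a data frame with columns
#'   `time`, `signal`).
#' @export
ca_trace <- function(time, signal, time_unit = c("min", "ms")) {
  time_unit <- match.arg(time_unit)
  if (length(time) != length(signal)) stop("time and signal lengths differ")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("time must be finite and strictly increasing")
  if (any(!is.finite(signal))) stop("signal must be finite")
  structure(data.frame(time = time, signal = signal),
            time_unit = time_unit, class = c("ca_trace", "data.frame"))
}

# uniform (time, signal) access for metric functions
get_time_signal <- function(x) {
  if (inherits(x, "presyn_sim")) {
    list(time = x$time_ms, signal = x$ca_uM)
  } else if (inherits(x, "ca_trace")) {
    list(time = x$time, signal = x$signal)
  } else if (is.data.frame(x) && all(c("time", "signal") %in% names(x))) {
    list(time = x$time, signal = x$signal)
  } else stop("expected a presyn_sim, ca_trace, or data frame with time/signal")
}

#' Peak metrics of a single calcium transient
#'
#' Summarises one stimulus-evoked transient: the baseline (pre-stimulus
#' mean), the peak height (maximum reached), the time from the upward
#' half-maximum crossing to the peak (pre-peak width, dominated by influx)
#' and from the peak to the downward half-maximum crossing (post-peak
#' width, dominated by clearance). Half-maximum is measured above baseline
#' and crossings are located by linear interpolation between samples.
#'
#' @param x a `presyn_sim` from a single-pulse protocol, a [ca_trace()],
#'   or a data frame with `time`/`signal` columns.
#' @param baseline_end end of the pre-stimulus window used for the
#'   baseline mean; defaults to the protocol onset for simulations and to
#'   the first sample otherwise.
#' @param min_rise flag an error unless the peak exceeds the baseline by
#'   this fraction of the baseline (default 1 percent).
#' @return An object of class `peak_metrics`: list with `baseline`,
#'   `peak_height`, `peak_time`, `pre_peak_width`, `post_peak_width`.
#' @export
peak_metrics <- function(x, baseline_end = NULL, min_rise = 0.01) {
  ts <- get_time_signal(x)
  if (is.null(baseline_end) && inherits(x, "presyn_sim"))
    baseline_end <- attr(x, "protocol")$onset
  tt <- ts$time; yy <- ts$signal
  base_idx <- if (!is.null(baseline_end)) which(tt < baseline_end) else 1L
  if (!length(base_idx)) base_idx <- 1L
  baseline <- mean(yy[base_idx])

  ipk <- which.max(yy)
  peak <- yy[ipk]
  if (peak <= baseline * (1 + min_rise) && peak - baseline <= min_rise)
    stop("no transient above baseline detected")
  half <- baseline + (peak - baseline) / 2

  cross_time <- function(i) {  # linear interpolation between samples i, i+1
    tt[i] + (half - yy[i]) / (yy[i + 1] - yy[i]) * (tt[i + 1] - tt[i])
  }
  pre <- which(yy[seq_len(ipk - 1)] < half & yy[2:ipk] >= half)
  t_up <- if (length(pre)) cross_time(max(pre)) else tt[1]
  after <- seq(ipk, length(yy) - 1)
  post <- after[yy[after] >= half & yy[after + 1] < half]
  t_down <- if (length(post)) cross_time(min(post)) else tt[length(tt)]

  structure(list(baseline = baseline, peak_height = peak,
                 peak_time = tt[ipk],
                 pre_peak_width = tt[ipk] - t_up,
                 post_peak_width = t_down - tt[ipk]),
            class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf(paste0("Ca transient: baseline %.4g, peak %.4g at t = %.4g\n",
                     "  pre-peak width %.4g, post-peak width %.4g\n"),
              x$baseline, x$peak_height, x$peak_time,
              x$pre_peak_width, x$post_peak_width))
  invisible(x)
}

#' Maximum of the centered moving average of a calcium trace
#'
#' Averages the signal in a centered window and returns the maximum of
#' that moving average — the summary used for spike-train simulations,
#' where the window (by default one inter-spike interval) removes the
#' within-train oscillation and leaves the accumulating mean.
#'
#' @param x a `presyn_sim`, [ca_trace()], or time/signal data frame on a
#'   uniform time grid.
#' @param window window length in the trace's time unit (ms for
#'   simulations); must not exceed the trace duration.
#' @return maximum of the centered moving average (only windows fully
#'   inside the trace are considered).
#' @export
moving_average_max <- function(x, window = 50) {
  ts <- get_time_signal(x)
  if (window <= 0) stop("window must be positive")
  dur <- max(ts$time) - min(ts$time)
  if (window > dur) stop("window (", window, ") exceeds trace duration (",
                         dur, ")")
  dt <- diff(ts$time)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("moving average requires a uniform time grid")
  k <- max(1L, round(window / mean(dt)))
  if (k %% 2 == 0) k <- k + 1L  # symmetric, centered
  ma <- stats::filter(ts$signal, rep(1 / k, k), sides = 2)
  max(ma, na.rm = TRUE)
}

#' Area under a calcium trace
#'
#' Trapezoidal integral of the signal over `[t_start, t_end]`, with linear
#' interpolation at window edges that fall between samples. The default
#' window, 2-12 min, is the quantification window used for
#' depolarization-evoked neuronal indicator recordings.
#'
#' @param trace a [ca_trace()] or time/signal data frame.
#' @param t_start,t_end integration window, in the trace's time unit.
#' @param baseline_subtract if `TRUE`, subtract the mean signal over
#'   `[0, t_start]` before integrating.
#' @return integral in signal x time units.
#' @export
compute_auc <- function(trace, t_start = 2, t_end = 12,
                        baseline_subtract = FALSE) {
  ts <- get_time_signal(trace)
  if (t_end <= t_start) stop("empty integration window")
  if (t_start < min(ts$time) || t_end > max(ts$time))
    stop("integration window [", t_start, ", ", t_end,
         "] not contained in the trace")
  tt <- ts$time; yy <- ts$signal
  if (baseline_subtract) {
    pre <- tt <= t_start
    yy <- yy - mean(yy[pre])
  }
  inside <- tt > t_start & tt < t_end
  xi <- c(t_start, tt[inside], t_end)
  yi <- c(stats::approx(tt, yy, xout = t_start)$y, yy[inside],
          stats::approx(tt, yy, xout = t_end)$y)
  sum(diff(xi) * (utils::head(yi, -1) + utils::tail(yi, -1)) / 2)
}
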