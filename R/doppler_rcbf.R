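# Laser-Doppler rCBF: baseline normalization to percent change and per-epoch
# averaging against a stimulation schedule. Doppler flow is in arbitrary
# units, so only relative (percent) changes are meaningful; traces are not
# detrended or filtered by default.

#' Normalize a Doppler flow trace to percent change from baseline
#'
#' `100 * (x - xbar_b) / xbar_b`, where `xbar_b` is the mean over the
#' baseline window. The conventional baseline is at least 15 min of
#' pre-stimulation recording; shorter windows (e.g. for synthetic tests) must
#' be opted into.
#'
#' @param trace a [time_series()] with unit `doppler_au`.
#' @param baseline_window_s `c(t0, t1)` in seconds (relative to the series
#'   time base).
#' @param allow_short_baseline permit baseline windows shorter than 15 min.
#' @return a [time_series()] with unit `percent`, with attributes
#'   `baseline_window_s` and `baseline_mean_au`.
#' @export
normalize_rcbf <- function(trace, baseline_window_s,
                           allow_short_baseline = FALSE) {
  stopifnot(inherits(trace, "time_series"))
  if (trace$unit != "doppler_au") stop("expected a doppler_au time series")
  bw <- baseline_window_s
  if (length(bw) != 2L || bw[2] <= bw[1]) stop("baseline_window_s must be c(t0, t1), t1 > t0")
  if ((bw[2] - bw[1]) < 15 * 60 && !allow_short_baseline) {
    stop("baseline window shorter than 15 min; set allow_short_baseline = TRUE to override")
  }
  tms <- sample_times(trace)
  in_b <- tms >= bw[1] & tms < bw[2]
  if (!any(in_b)) stop("baseline window contains no samples")
  xb <- mean(trace$values[in_b])
  if (xb <= 0) stop("non-positive baseline mean (", xb,
                    "); Doppler flow in arbitrary units must be positive")
  out <- time_series(100 * (trace$values - xb) / xb, trace$fs_hz, "percent",
                     t0_s = trace$t0_s)
  attr(out, "baseline_window_s") <- bw
  attr(out, "baseline_mean_au") <- xb
  out
}

#' Per-epoch means of a percent-change trace against a stimulation schedule
#'
#' Means the trace within each stimulation ON interval and within a post-ON
#' window of `window_s` seconds following each interval. Epochs that fall
#' outside the recorded span are marked missing rather than truncated.
#'
#' @param trace a [time_series()] with unit `percent` (see
#'   [normalize_rcbf()]).
#' @param schedule data.frame of ON intervals from [expand_schedule()].
#' @param window_s length of the post-ON averaging window (s).
#' @return data.frame keyed by `train`, `set`, with `on_mean_pct`,
#'   `post_mean_pct` (NA when the epoch lies outside the trace).
#' @export
epoch_average <- function(trace, schedule, window_s = 60) {
  stopifnot(inherits(trace, "time_series"),
            all(c("train", "set", "on_start_s", "on_end_s") %in% names(schedule)))
  tms <- sample_times(trace)
  span <- range(tms)
  win_mean <- function(a, b) {
    if (a < span[1] - 1e-9 || b > span[2] + 1 / trace$fs_hz + 1e-9) return(NA_real_)
    sel <- tms >= a & tms < b
    if (!any(sel)) return(NA_real_)
    mean(trace$values[sel])
  }
  data.frame(
    train = schedule$train, set = schedule$set,
    on_start_s = schedule$on_start_s, on_end_s = schedule$on_end_s,
    on_mean_pct = mapply(win_mean, schedule$on_start_s, schedule$on_end_s),
    post_mean_pct = mapply(win_mean, schedule$on_end_s,
                           schedule$on_end_s + window_s))
}
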