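# Bolus-transit kinetics from 30 fps fluorescent angiography: per-ROI
# intensity curves, arterial-venous peak-to-peak interval, and mean slope of
# rise ("slope to max").

#' Per-frame mean intensity over a region of interest
#'
#' Baseline is the mean of the first `baseline_frames` frames (pre-arrival
#' window); the peak is the global maximum of the curve after centered
#' moving-average smoothing, taking the earliest frame on ties so that
#' transit intervals are conservative and deterministic.
#'
#' @param stack an [image_stack()] (grayscale).
#' @param roi_obj a [roi()] whose mask matches the frame size.
#' @param baseline_frames number of initial frames averaged for the baseline.
#' @param smooth_frames centered moving-average width (frames, odd) used for
#'   peak detection.
#' @return object of class `roi_trace`: `roi` label, `series` (raw curve as a
#'   [time_series()], unit `intensity_iu`), `smoothed` (numeric), `baseline_iu`,
#'   `peak_iu`, `peak_time_s`, `peak_frame`, `no_bolus` flag (peak does not
#'   exceed baseline).
#' @export
roi_intensity_curve <- function(stack, roi_obj, baseline_frames = 10,
                                smooth_frames = 5) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi_obj, "roi"))
  d <- dim(stack$frames)
  if (!all(dim(roi_obj$mask) == d[2:3])) stop("ROI mask does not match frame size")
  idx <- which(roi_obj$mask)
  nf <- d[1]
  curve <- vapply(seq_len(nf), function(i) mean(get_frame(stack, i)[idx]), 0)
  b <- min(baseline_frames, nf)
  baseline <- mean(curve[seq_len(b)])
  sm <- centered_ma(curve, smooth_frames)
  # locate the peak on the smoothed curve (robust to single-frame noise),
  # then refine to the raw maximum within the smoothing half-window: the
  # smoothed maximum of an asymmetric bolus (fast rise, slow washout) is
  # biased toward the shallow side by up to half the window
  h <- floor(smooth_frames / 2)
  pf_sm <- which.max(sm)  # first occurrence on ties
  win <- max(1L, pf_sm - h):min(nf, pf_sm + h)
  peak_frame <- win[which.max(curve[win])]
  peak <- curve[peak_frame]
  tms <- frame_times(stack)
  no_bolus <- peak <= baseline + 1e-9 * max(abs(curve), 1)
  if (no_bolus) warning("no bolus detected: peak does not exceed baseline")
  structure(list(roi = roi_obj$label,
                 series = time_series(curve, 1 / stack$frame_interval_s,
                                      "intensity_iu", t0_s = stack$t0_s),
                 smoothed = sm, baseline_iu = baseline, peak_iu = peak,
                 peak_time_s = tms[peak_frame], peak_frame = peak_frame,
                 no_bolus = no_bolus),
            class = "roi_trace")
}

centered_ma <- function(x, width) {
  if (width <= 1) return(x)
  if (width %% 2 == 0) width <- width + 1
  h <- (width - 1) / 2
  n <- length(x)
  # shrink the window symmetrically at the edges
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(x[(i - k):(i + k)])
  }, 0)
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("<roi_trace> [%s] baseline %.3g iu, peak %.3g iu @ %.3g s%s\n",
              x$roi, x$baseline_iu, x$peak_iu, x$peak_time_s,
              if (x$no_bolus) " (no bolus detected)" else ""))
  invisible(x)
}

#' Arterial-to-venous peak-to-peak interval
#'
#' Time between the venous and arterial bolus peaks, an inverse proxy for
#' transit speed through the imaged vascular bed. A negative interval
#' (venous peak before arterial) is reported as-is with a warning.
#'
#' @param arterial,venous `roi_trace` objects with detected peaks.
#' @return interval in seconds.
#' @export
peak_to_peak <- function(arterial, venous) {
  stopifnot(inherits(arterial, "roi_trace"), inherits(venous, "roi_trace"))
  if (arterial$no_bolus) stop("no peak detected in arterial ROI '", arterial$roi, "'")
  if (venous$no_bolus) stop("no peak detected in venous ROI '", venous$roi, "'")
  p2p <- venous$peak_time_s - arterial$peak_time_s
  if (p2p < 0) warning("venous peak precedes arterial peak (interval ", p2p, " s)")
  p2p
}

#' Mean slope of rise to the bolus peak ("slope to max")
#'
#' Arrival is the first crossing of `baseline + rise_fraction * (peak -
#' baseline)` on the smoothed curve, located at sub-frame resolution by
#' linear interpolation; the slope is the mean rate of rise from arrival to
#' the peak.
#'
#' @param trace a `roi_trace`.
#' @param rise_fraction arrival criterion as a fraction of the peak-minus-
#'   baseline excursion (default 0.1).
#' @return slope in intensity units per second.
#' @export
slope_to_max <- function(trace, rise_fraction = 0.1) {
  stopifnot(inherits(trace, "roi_trace"))
  if (trace$no_bolus) stop("no rise segment: peak does not exceed baseline")
  sm <- trace$smoothed
  tms <- sample_times(trace$series)
  thr <- trace$baseline_iu + rise_fraction * (trace$peak_iu - trace$baseline_iu)
  pk <- trace$peak_frame
  above <- which(sm[seq_len(pk)] >= thr)
  if (length(above) == 0L) stop("no rise segment found before the peak")
  i <- above[1]
  if (i == 1L) {
    if (pk == 1L) stop("no rise segment: peak at first frame")
    t_arr <- tms[1]; v_arr <- sm[1]
  } else {
    frac <- (thr - sm[i - 1]) / (sm[i] - sm[i - 1])
    t_arr <- tms[i - 1] + frac * (tms[i] - tms[i - 1])
    v_arr <- thr
  }
  if (tms[pk] <= t_arr) stop("no rise segment: peak coincides with arrival")
  (trace$peak_iu - v_arr) / (tms[pk] - t_arr)
}

#' Transit metrics for an (artery, vein) ROI pair
#'
#' @param arterial,venous `roi_trace` objects.
#' @return object of class `transit_metrics`: `p2p_interval_s`,
#'   `slope_to_max_iu_per_s` (named, one per ROI), `rois`.
#' @export
transit_metrics <- function(arterial, venous) {
  structure(list(p2p_interval_s = peak_to_peak(arterial, venous),
                 slope_to_max_iu_per_s = c(artery = slope_to_max(arterial),
                                           vein = slope_to_max(venous)),
                 rois = c(arterial$roi, venous$roi)),
            class = "transit_metrics")
}

#' @export
print.transit_metrics <- function(x, ...) {
  cat(sprintf("<transit_metrics> p2p %.4g s; slope artery %.4g, vein %.4g iu/s\n",
              x$p2p_interval_s, x$slope_to_max_iu_per_s[["artery"]],
              x$slope_to_max_iu_per_s[["vein"]]))
  invisible(x)
}
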