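# ECoG analysis: zero-phase band-pass filtering, windowed-periodogram band
# power in the five canonical bands (2-4, 5-10, 11-45, 46-70, 71-90 Hz) with
# two normalization modes, and seizure-like-event detection with the
# fast-activity burden (seconds of event time per recording hour).

#' The five canonical ECoG analysis bands
#' @return named list of `c(lo, hi)` band edges in Hz.
#' @export
default_bands <- function() {
  list(`2-4`  = c(2, 4),  `5-10`  = c(5, 10), `11-45` = c(11, 45),
       `46-70` = c(46, 70), `71-90` = c(71, 90))
}

#' Zero-phase band-pass filter
#'
#' Forward-and-reverse application of a Butterworth band-pass (4th order per
#' pass by default), which cancels the filter's phase response so event
#' timings are not shifted. Edge transients are controlled by odd-reflection
#' padding of three filter lengths at each end before filtering.
#'
#' @param x a [time_series()].
#' @param lo_hz,hi_hz pass-band edges (Hz); `hi_hz` must be below Nyquist.
#' @param order Butterworth order of each pass.
#' @return filtered [time_series()] with the same sampling rate and unit.
#' @export
bandpass_zero_phase <- function(x, lo_hz = 2, hi_hz = 90, order = 4) {
  stopifnot(inherits(x, "time_series"))
  fs <- x$fs_hz
  if (hi_hz >= fs / 2) stop("hi_hz (", hi_hz, ") must be below Nyquist (", fs / 2, ")")
  if (lo_hz <= 0 || lo_hz >= hi_hz) stop("need 0 < lo_hz < hi_hz")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  v <- x$values
  n <- length(v)
  np <- min(n - 1L, 3L * (max(length(bf$b), length(bf$a)) - 1L))
  # odd reflection about the end samples (MATLAB-style filtfilt padding)
  front <- 2 * v[1] - v[(np + 1L):2L]
  back <- 2 * v[n] - v[(n - 1L):(n - np)]
  vp <- c(front, v, back)
  y <- signal::filter(bf, vp)
  y <- rev(signal::filter(bf, rev(y)))
  y <- y[(np + 1L):(np + n)]
  time_series(as.numeric(y), fs, x$unit, t0_s = x$t0_s)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# Windowed-periodogram band powers; Hann taper, non-overlapping windows.
# Bin powers are scaled so their sum over all bins estimates the signal
# variance (Parseval), and bands collect bins with lo <= f < hi.
periodogram_band_power <- function(v, fs, bands, window_s) {
  nw <- round(window_s * fs)
  n_win <- floor(length(v) / nw)
  if (n_win < 1L) stop("signal shorter than one analysis window (", window_s, " s)")
  w <- hann_window(nw)
  wss <- sum(w^2)
  f <- (0:(nw - 1)) * fs / nw
  acc <- numeric(length(bands))
  for (k in seq_len(n_win)) {
    seg <- v[((k - 1L) * nw + 1L):(k * nw)]
    p2 <- Mod(stats::fft(seg * w))^2 / (nw * wss)  # two-sided bin power
    for (b in seq_along(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      sel <- f >= lo & f < hi & f <= fs / 2
      acc[b] <- acc[b] + 2 * sum(p2[sel])
    }
  }
  stats::setNames(acc / n_win, names(bands))
}

#' ECoG band powers with session or day-1 normalization
#'
#' Power spectra are estimated by averaging magnitude-squared Fourier
#' transforms over non-overlapping Hann-tapered windows (default 10 s), and
#' summed per band. `per_session` divides each band by the total power over
#' the analyzed bands, so the reported powers sum to 1; `to_day1` divides
#' each band by the same band's raw power in the animal's day-1 reference
#' summary, so values are fold changes relative to day 1; `none` reports raw
#' power (signal-unit squared).
#'
#' @param x a [time_series()], conventionally already band-passed 2-90 Hz;
#'   at least 2 s long.
#' @param bands named list of band edges, see [default_bands()].
#' @param normalization `"per_session"`, `"to_day1"` or `"none"`.
#' @param day1 a `band_power_summary` of the animal's first recording day
#'   (required for `to_day1`; its `raw_power` is the reference).
#' @param window_s analysis window length (s).
#' @param day_index,animal_id optional labels carried in the result.
#' @return object of class `band_power_summary`: `bands`, `power`
#'   (normalized per mode), `raw_power`, `normalization`, `window_s`,
#'   `day_index`, `animal_id`.
#' @export
band_powers <- function(x, bands = default_bands(),
                        normalization = c("per_session", "to_day1", "none"),
                        day1 = NULL, window_s = 10,
                        day_index = NA_integer_, animal_id = NA_character_) {
  stopifnot(inherits(x, "time_series"))
  normalization <- match.arg(normalization)
  if (length(x$values) < 2 * x$fs_hz) stop("need at least 2 s of signal")
  raw <- periodogram_band_power(x$values, x$fs_hz, bands, window_s)
  power <- switch(normalization,
    per_session = raw / sum(raw),
    to_day1 = {
      if (is.null(day1) || !inherits(day1, "band_power_summary")) {
        stop("to_day1 normalization requires a day-1 band_power_summary reference")
      }
      raw / day1$raw_power
    },
    none = raw)
  structure(list(bands = bands, power = power, raw_power = raw,
                 normalization = normalization, window_s = window_s,
                 day_index = day_index, animal_id = animal_id),
            class = "band_power_summary")
}

#' @export
print.band_power_summary <- function(x, ...) {
  cat(sprintf("<band_power_summary> normalization = %s\n", x$normalization))
  print(round(x$power, 4))
  invisible(x)
}

#' Hilbert envelope of a numeric signal
#'
#' Instantaneous amplitude via the analytic signal (FFT method).
#' @param v numeric vector.
#' @return numeric vector of the same length.
#' @export
hilbert_envelope <- function(v) {
  n <- length(v)
  X <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Detect seizure-like events and their fast-activity burden
#'
#' An event is a high-amplitude episode with concurrent fast (71-90 Hz)
#' activity, both judged against the animal's day-1 baseline: candidate
#' samples are those where the broadband (2-90 Hz) envelope exceeds
#' `k_sd` times the day-1 broadband SD and, simultaneously (`combine =
#' "and"`), the fast-band envelope exceeds `k_sd` times the day-1 SD of the
#' fast-band envelope. Candidate runs shorter than `min_dur_s` are dropped,
#' then surviving runs separated by less than `merge_gap_s` are merged.
#'
#' @param x a [time_series()] to scan.
#' @param day1_baseline a [time_series()] from the same animal's first
#'   recording day (>= 60 s), same sampling rate.
#' @param k_sd detection threshold in baseline SD multiples (the
#'   conventional choice is 3).
#' @param fast_band fast-activity band (Hz).
#' @param broad_band broadband filtering band (Hz).
#' @param min_dur_s minimum event duration (s).
#' @param merge_gap_s events closer than this are merged (s).
#' @param envelope_smooth_s moving-average width applied to the decision
#'   envelopes (s). Seizure-like events are seconds-long episodes, so the
#'   instantaneous Hilbert envelope is smoothed to this time scale before
#'   thresholding; this keeps a sustained event from fragmenting on
#'   within-event envelope dips and makes isolated background excursions too
#'   brief to survive `min_dur_s`.
#' @param combine `"and"` (both criteria concurrently) or `"or"` (either;
#'   provided for sensitivity analysis).
#' @return object of class `event_list`: `events` (data.frame `onset_s`,
#'   `duration_s`, non-overlapping, sorted), `fast_activity_sec_per_h`
#'   (`3600 * sum(duration) / recording length`), `threshold_sd`,
#'   `baseline_sd_uv` (day-1 broadband SD), `recording_length_s`.
#' @export
detect_seizure_like_events <- function(x, day1_baseline, k_sd = 3,
                                       fast_band = c(71, 90),
                                       broad_band = c(2, 90),
                                       min_dur_s = 1, merge_gap_s = 0.5,
                                       envelope_smooth_s = 0.25,
                                       combine = c("and", "or")) {
  stopifnot(inherits(x, "time_series"), inherits(day1_baseline, "time_series"))
  combine <- match.arg(combine)
  if (x$fs_hz != day1_baseline$fs_hz) {
    stop("sampling-rate mismatch: ", x$fs_hz, " vs ", day1_baseline$fs_hz, " Hz")
  }
  if (length(day1_baseline$values) < 60 * day1_baseline$fs_hz) {
    stop("day-1 baseline must be at least 60 s long")
  }
  fs <- x$fs_hz
  bb_x <- bandpass_zero_phase(x, broad_band[1], broad_band[2])
  bb_d <- bandpass_zero_phase(day1_baseline, broad_band[1], broad_band[2])
  fa_x <- bandpass_zero_phase(x, fast_band[1], fast_band[2])
  fa_d <- bandpass_zero_phase(day1_baseline, fast_band[1], fast_band[2])
  sd_broad <- stats::sd(bb_d$values)
  env_fast_d <- hilbert_envelope(fa_d$values)
  nsm <- max(1L, round(envelope_smooth_s * fs))
  amp_ok <- running_mean(hilbert_envelope(bb_x$values), nsm) > k_sd * sd_broad
  fast_ok <- running_mean(hilbert_envelope(fa_x$values), nsm) >
    k_sd * stats::sd(env_fast_d)
  cand <- if (combine == "and") amp_ok & fast_ok else amp_ok | fast_ok
  runs <- logical_runs(cand)
  runs <- runs[(runs$end - runs$start + 1L) / fs >= min_dur_s, , drop = FALSE]
  runs <- merge_runs(runs, gap_samples = merge_gap_s * fs)
  events <- data.frame(onset_s = x$t0_s + (runs$start - 1L) / fs,
                       duration_s = (runs$end - runs$start + 1L) / fs)
  rec_len <- length(x$values) / fs
  structure(list(events = events,
                 fast_activity_sec_per_h = 3600 * sum(events$duration_s) / rec_len,
                 threshold_sd = k_sd, baseline_sd_uv = sd_broad,
                 recording_length_s = rec_len),
            class = "event_list")
}

# centered running mean with windows truncated at the edges; cumsum-based,
# O(n) for the long envelopes the event detector scans
running_mean <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  h <- floor(width / 2)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(0L, i - h - 1L)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

logical_runs <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(runs, gap_samples) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] - 1L < gap_samples) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d event(s) in %.3g h; fast activity %.3g s/h\n",
              nrow(x$events), x$recording_length_s / 3600,
              x$fast_activity_sec_per_h))
  invisible(x)
}
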