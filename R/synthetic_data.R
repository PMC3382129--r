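# Seeded generators for every input modality, each returning programmed
# ground truth alongside the rendered data so downstream estimators have
# parameter-recovery tests that never re-derive truth from the rendered data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic vessel specification
#'
#' Describes one straight or polyline vessel as ground truth for rendering:
#' the centerline, the true local diameter as a function of arclength and
#' time, the vessel-vs-background intensity contrast, and additive noise.
#'
#' @param centerline `n x 2` matrix of (row, col) points in 0-based pixel
#'   coordinates; consecutive points are joined by straight segments.
#' @param diameter_um true diameter in microns: a scalar, or a function
#'   `f(arclength_um, t_s)` returning the local diameter (must be > 0).
#' @param contrast intensity gap between vessel interior and background,
#'   on the rendered unit scale.
#' @param noise_sd additive Gaussian noise SD on the rendered unit scale.
#' @param background background intensity level.
#' @return object of class `vessel_spec`.
#' @export
vessel_spec <- function(centerline, diameter_um, contrast = 0.6,
                        noise_sd = 0, background = 0.2) {
  stopifnot(is.matrix(centerline), ncol(centerline) == 2L,
            nrow(centerline) >= 2L)
  dfun <- if (is.function(diameter_um)) diameter_um else {
    stopifnot(diameter_um > 0)
    function(s_um, t_s) rep(diameter_um, length(s_um))
  }
  structure(list(centerline = centerline, diameter_fun = dfun,
                 contrast = contrast, noise_sd = noise_sd,
                 background = background),
            class = "vessel_spec")
}

# Perpendicular distance of pixel centers to a polyline and arclength of the
# foot point. Returns list(dist, arclen) matrices (px units).
polyline_distance_field <- function(centerline, H, W) {
  py <- rep(0:(H - 1), times = W)
  px <- rep(0:(W - 1), each = H)
  dist <- rep(Inf, H * W)
  arcl <- rep(0, H * W)
  seg_start_len <- 0
  for (i in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[i, ]; b <- centerline[i + 1L, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    if (len == 0) next
    t <- ((py - a[1]) * ab[1] + (px - a[2]) * ab[2]) / len^2
    t <- pmin(pmax(t, 0), 1)
    dy <- py - (a[1] + t * ab[1])
    dx <- px - (a[2] + t * ab[2])
    d <- sqrt(dy^2 + dx^2)
    closer <- d < dist
    dist[closer] <- d[closer]
    arcl[closer] <- seg_start_len + t[closer] * len
    seg_start_len <- seg_start_len + len
  }
  list(dist = matrix(dist, H, W), arclen = matrix(arcl, H, W))
}

#' Render a synthetic vessel image stack with known diameters
#'
#' The vessel cross-section is a top-hat (rectangular) profile with a one-pixel
#' anti-aliased border: a pixel's intensity above background is
#' `contrast * clip(w/2 - d + 1/2, 0, 1)` where `d` is its perpendicular
#' distance to the centerline and `w` the local true width in pixels. The true
#' diameter is therefore unambiguous, unlike a Gaussian ridge.
#'
#' @param spec a [vessel_spec()].
#' @param geometry list with `H`, `W` (pixels), `pixel_size_um`, `n_frames`,
#'   `frame_interval_s`.
#' @param seed integer RNG seed; the generator is deterministic given
#'   `(spec, geometry, seed)`.
#' @param arclengths_um arclength positions (microns along the centerline) at
#'   which the true diameter is tabulated; default five equidistant interior
#'   points.
#' @return list with `stack` (an [image_stack()]), `truth` (data.frame
#'   `frame`, `time_s`, `arclength_um`, `diam_um`) and `footprint` (logical
#'   `H x W` true-vessel mask of frame 1 at half-coverage).
#' @export
make_vessel_stack <- function(spec, geometry, seed, arclengths_um = NULL) {
  stopifnot(inherits(spec, "vessel_spec"))
  H <- geometry$H; W <- geometry$W
  px_um <- geometry$pixel_size_um
  nf <- geometry$n_frames
  dt <- geometry$frame_interval_s
  fld <- polyline_distance_field(spec$centerline, H, W)
  total_len_um <- max(fld$arclen) * px_um
  if (is.null(arclengths_um)) {
    arclengths_um <- seq(0.2, 0.8, length.out = 5) * total_len_um
  }
  times <- (seq_len(nf) - 1) * dt
  wmax <- max(vapply(times, function(t)
    max(spec$diameter_fun(arclengths_um, t)), 0)) / px_um
  if (wmax >= min(H, W)) {
    stop("vessel wider (", round(wmax), " px) than image (", min(H, W), " px)")
  }
  frames <- array(0, c(nf, H, W))
  footprint <- NULL
  truth <- vector("list", nf)
  with_seed(seed, {
    for (i in seq_len(nf)) {
      w_px <- spec$diameter_fun(fld$arclen * px_um, times[i]) / px_um
      if (any(w_px <= 0)) stop("diameter profile must be positive everywhere")
      cov <- pmin(pmax(w_px / 2 - fld$dist + 0.5, 0), 1)
      img <- spec$background + spec$contrast * cov
      if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
      frames[i, , ] <- img
      if (i == 1L) footprint <- cov >= 0.5
      truth[[i]] <- data.frame(
        frame = i, time_s = times[i], arclength_um = arclengths_um,
        diam_um = spec$diameter_fun(arclengths_um, times[i]))
    }
  })
  list(stack = image_stack(frames, px_um, dt),
       truth = do.call(rbind, truth), footprint = footprint)
}

#' Synthetic bolus-transit specification for one ROI
#'
#' @param arrival_s tracer arrival time at the ROI (s, >= 0).
#' @param rise_tau_s time from arrival to peak (s, > 0).
#' @param peak_iu peak intensity (must exceed `baseline_iu`).
#' @param decay_tau_s exponential washout time constant after the peak (s).
#' @param baseline_iu pre-arrival intensity (>= 0).
#' @return object of class `bolus_spec`.
#' @export
bolus_spec <- function(arrival_s, rise_tau_s, peak_iu, decay_tau_s = 4,
                       baseline_iu = 10) {
  stopifnot(arrival_s >= 0, rise_tau_s > 0, peak_iu > baseline_iu,
            baseline_iu >= 0, decay_tau_s > 0)
  structure(list(arrival_s = arrival_s, rise_tau_s = rise_tau_s,
                 peak_iu = peak_iu, decay_tau_s = decay_tau_s,
                 baseline_iu = baseline_iu),
            class = "bolus_spec")
}

bolus_curve <- function(spec, t, shape = c("linear", "gamma")) {
  shape <- match.arg(shape)
  amp <- spec$peak_iu - spec$baseline_iu
  tt <- t - spec$arrival_s
  v <- rep(spec$baseline_iu, length(t))
  if (shape == "linear") {
    rising <- tt >= 0 & tt <= spec$rise_tau_s
    v[rising] <- spec$baseline_iu + amp * tt[rising] / spec$rise_tau_s
    after <- tt > spec$rise_tau_s
    v[after] <- spec$baseline_iu +
      amp * exp(-(tt[after] - spec$rise_tau_s) / spec$decay_tau_s)
  } else {
    a <- 3  # gamma-variate shape; peak at arrival + rise_tau
    pos <- tt > 0
    x <- tt[pos] / spec$rise_tau_s
    v[pos] <- spec$baseline_iu + amp * (x^a * exp(a * (1 - x)))
  }
  v
}

#' Render a synthetic fluorescent-angiography stack
#'
#' Each ROI's pixels follow its programmed bolus curve (baseline, ramp to
#' peak starting at `arrival_s` and peaking at `arrival_s + rise_tau_s`,
#' exponential washout); pixels outside all ROIs stay at a background level.
#' Per-pixel additive Gaussian noise only; pulsatility is not simulated.
#'
#' @param rois named list; each element is `list(roi = , spec = )` pairing a
#'   [roi()] with a [bolus_spec()]. ROI masks must be pairwise disjoint.
#' @param geometry list with `H`, `W`, `pixel_size_um`, `fs` (frames/s,
#'   default 30) and `duration_s`.
#' @param seed integer RNG seed.
#' @param noise_sd per-pixel Gaussian noise SD (iu).
#' @param shape bolus rise shape, `"linear"` or `"gamma"`.
#' @return list with `stack`, and `truth`: per-ROI programmed peak time
#'   (`arrival_s + rise_tau_s`), peak, baseline and mean rise slope
#'   (`(peak - baseline) / rise_tau_s` for the linear shape), plus the
#'   venous-minus-arterial peak-to-peak interval for each (artery, vein) pair.
#' @export
make_angio_stack <- function(rois, geometry, seed, noise_sd = 0,
                             shape = c("linear", "gamma")) {
  shape <- match.arg(shape)
  H <- geometry$H; W <- geometry$W
  fs <- if (is.null(geometry$fs)) 30 else geometry$fs
  nf <- round(geometry$duration_s * fs)
  acc <- matrix(0L, H, W)
  for (r in rois) acc <- acc + r$roi$mask
  if (any(acc > 1L)) stop("ROI masks must be pairwise disjoint")
  t <- (seq_len(nf) - 1) / fs
  frames <- array(0, c(nf, H, W))
  bg <- min(vapply(rois, function(r) r$spec$baseline_iu, 0))
  with_seed(seed, {
    base <- array(bg, c(H, W))
    curves <- lapply(rois, function(r) bolus_curve(r$spec, t, shape))
    for (i in seq_len(nf)) {
      img <- base
      for (k in seq_along(rois)) img[rois[[k]]$roi$mask] <- curves[[k]][i]
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      frames[i, , ] <- img
    }
  })
  per_roi <- data.frame(
    roi = names(rois),
    label = vapply(rois, function(r) r$roi$label, ""),
    arrival_s = vapply(rois, function(r) r$spec$arrival_s, 0),
    peak_time_s = vapply(rois, function(r) r$spec$arrival_s + r$spec$rise_tau_s, 0),
    peak_iu = vapply(rois, function(r) r$spec$peak_iu, 0),
    baseline_iu = vapply(rois, function(r) r$spec$baseline_iu, 0),
    slope_iu_per_s = vapply(rois, function(r)
      (r$spec$peak_iu - r$spec$baseline_iu) / r$spec$rise_tau_s, 0),
    row.names = NULL)
  art <- per_roi[per_roi$label == "artery", ]
  ven <- per_roi[per_roi$label == "vein", ]
  p2p <- if (nrow(art) && nrow(ven)) {
    expand <- expand.grid(a = seq_len(nrow(art)), v = seq_len(nrow(ven)))
    data.frame(artery = art$roi[expand$a], vein = ven$roi[expand$v],
               p2p_interval_s = ven$peak_time_s[expand$v] - art$peak_time_s[expand$a])
  } else NULL
  list(stack = image_stack(frames, geometry$pixel_size_um, 1 / fs),
       truth = list(per_roi = per_roi, p2p = p2p))
}

#' Synthetic ECoG specification
#'
#' Background is a band-limited power-law ("1/f^alpha") noise process;
#' seizure-like events are band-limited oscillatory bursts riding on it.
#' Defaults resemble rodent epidural ECoG: pink background (`alpha = 1`) with
#' 50 uV RMS, band-limited to 2-90 Hz.
#'
#' @param fs_hz sampling rate (Hz, default 1000).
#' @param duration_s recording length (s).
#' @param alpha spectral exponent of the background power law.
#' @param rms_uv target background RMS amplitude (uV).
#' @param band_hz two-element frequency band of the background (Hz).
#' @param events data.frame with columns `onset_s`, `duration_s`,
#'   `amplitude_multiple` (envelope peak as a multiple of background SD) and
#'   `carrier_hz` (burst carrier frequency, within `(0, fs/2)`); may be empty.
#' @return object of class `ecog_spec`.
#' @export
ecog_spec <- function(fs_hz = 1000, duration_s = 60, alpha = 1, rms_uv = 50,
                      band_hz = c(2, 90), events = NULL) {
  if (is.null(events)) {
    events <- data.frame(onset_s = numeric(), duration_s = numeric(),
                         amplitude_multiple = numeric(), carrier_hz = numeric())
  }
  stopifnot(fs_hz > 0, duration_s > 0, rms_uv > 0,
            band_hz[1] > 0, band_hz[2] < fs_hz / 2)
  if (nrow(events)) {
    stopifnot(all(events$onset_s >= 0),
              all(events$onset_s + events$duration_s <= duration_s),
              all(events$amplitude_multiple > 0),
              all(events$carrier_hz > 0), all(events$carrier_hz < fs_hz / 2))
  }
  structure(list(fs_hz = fs_hz, duration_s = duration_s, alpha = alpha,
                 rms_uv = rms_uv, band_hz = band_hz, events = events),
            class = "ecog_spec")
}

#' Synthesize an ECoG recording with programmed seizure-like events
#'
#' Background: white Gaussian noise is shaped in the frequency domain to an
#' `f^-alpha` power spectrum restricted to `band_hz`, then rescaled so its
#' sample SD equals `rms_uv` exactly. Each event adds a raised-cosine-tapered
#' sinusoidal burst at its carrier frequency whose envelope peaks at
#' `amplitude_multiple x` the background SD.
#'
#' @param spec an [ecog_spec()].
#' @param seed integer RNG seed.
#' @param taper_s raised-cosine ramp length at each event edge (s).
#' @return list with `series` (a [time_series()], unit `ecog_uv`) and
#'   `truth` (data.frame `onset_s`, `duration_s` of programmed events,
#'   plus attribute `background_sd_uv`).
#' @export
make_ecog <- function(spec, seed, taper_s = 0.15) {
  stopifnot(inherits(spec, "ecog_spec"))
  n <- round(spec$duration_s * spec$fs_hz)
  x <- with_seed(seed, {
    white <- stats::rnorm(n)
    X <- stats::fft(white)
    f <- (0:(n - 1)) * spec$fs_hz / n
    f <- pmin(f, spec$fs_hz - f)  # two-sided frequency magnitude
    gain <- ifelse(f >= spec$band_hz[1] & f <= spec$band_hz[2],
                   f^(-spec$alpha / 2), 0)
    bg <- Re(stats::fft(X * gain, inverse = TRUE)) / n
    bg <- bg * spec$rms_uv / stats::sd(bg)
    sig <- bg
    if (nrow(spec$events)) {
      phases <- stats::runif(nrow(spec$events), 0, 2 * pi)
      for (k in seq_len(nrow(spec$events))) {
        ev <- spec$events[k, ]
        i0 <- round(ev$onset_s * spec$fs_hz) + 1L
        len <- round(ev$duration_s * spec$fs_hz)
        tt <- (0:(len - 1)) / spec$fs_hz
        env <- cosine_taper_envelope(len, round(taper_s * spec$fs_hz))
        burst <- ev$amplitude_multiple * spec$rms_uv * env *
          sin(2 * pi * ev$carrier_hz * tt + phases[k])
        idx <- i0:(i0 + len - 1L)
        sig[idx] <- sig[idx] + burst
      }
    }
    sig
  })
  truth <- spec$events[, c("onset_s", "duration_s"), drop = FALSE]
  attr(truth, "background_sd_uv") <- spec$rms_uv
  list(series = time_series(x, spec$fs_hz, "ecog_uv"), truth = truth)
}

cosine_taper_envelope <- function(len, ramp) {
  ramp <- min(ramp, floor(len / 2))
  env <- rep(1, len)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * (1:ramp) / (ramp + 1)))
    env[1:ramp] <- up
    env[(len - ramp + 1):len] <- rev(up)
  }
  env
}

#' Synthesize an Evans-blue dorsal-cortex photograph
#'
#' An RGB image split into treated (left) and control (right) hemisphere
#' masks. A contiguous extravasation blob covering exactly
#' `round(fraction * n_treated)` pixels of the treated hemisphere has its blue
#' channel raised to `blob_blue`; everywhere else the blue channel sits at
#' `background_blue`. Intensities are on a 0-255 scale.
#'
#' @param extravasation_fraction fraction of treated-hemisphere pixels inside
#'   the blob, in `[0, 1]`.
#' @param blob_blue programmed mean blue value inside the blob (0-255).
#' @param geometry list with `H`, `W` (default 120 x 160).
#' @param background_blue blue level outside the blob.
#' @param noise_sd additive Gaussian noise SD on each channel (0-255 scale);
#'   clipped to range.
#' @param seed integer RNG seed.
#' @return list with `img` (`H x W x 3` array, 0-255), `treated_mask`,
#'   `control_mask`, and `truth` (`fraction`, `blob_blue`, `background_blue`).
#' @export
make_evansblue_image <- function(extravasation_fraction, blob_blue = 180,
                                 geometry = list(H = 120, W = 160),
                                 background_blue = 60, noise_sd = 0, seed = 1) {
  stopifnot(extravasation_fraction >= 0, extravasation_fraction <= 1,
            blob_blue > background_blue)
  H <- geometry$H; W <- geometry$W
  half <- floor(W / 2)
  treated <- matrix(FALSE, H, W); treated[, 1:half] <- TRUE
  control <- matrix(FALSE, H, W); control[, (half + 1):W] <- TRUE
  n_blob <- round(extravasation_fraction * sum(treated))
  blue <- matrix(background_blue, H, W)
  if (n_blob > 0) {
    cy <- (H - 1) / 2; cx <- (half - 1) / 2
    py <- rep(0:(H - 1), times = half); px <- rep(0:(half - 1), each = H)
    d <- (py - cy)^2 + (px - cx)^2
    ord <- order(d, py, px)[1:n_blob]  # grow blob outward from hemisphere center
    blue[cbind(py[ord] + 1L, px[ord] + 1L)] <- blob_blue
  }
  img <- array(0, c(H, W, 3))
  img[, , 1] <- 120; img[, , 2] <- 100; img[, , 3] <- blue
  if (noise_sd > 0) {
    img <- with_seed(seed, img + array(stats::rnorm(H * W * 3, 0, noise_sd), c(H, W, 3)))
    img <- pmin(pmax(img, 0), 255)
  }
  list(img = img, treated_mask = treated, control_mask = control,
       truth = list(fraction = n_blob / sum(treated), blob_blue = blob_blue,
                    background_blue = background_blue))
}

#' Synthesize serial coronal sections with programmed cortical loss
#'
#' Each section carries an ipsilateral and a contralateral cortex mask; the
#' ipsilateral mask area is exactly `round((1 - loss) * contra_area)` pixels,
#' with tissue removed from the lateral edge inward. Sections are rendered as
#' RGB images (cresyl-violet-like tint on a light background).
#'
#' @param n_sections number of sections (the histology protocol cuts 6-8).
#' @param loss_fraction scalar or length-`n_sections` vector of per-section
#'   cortical loss fractions in `[0, 1)`.
#' @param seed integer RNG seed (reserved for optional jitter; rendering is
#'   deterministic).
#' @param geometry list with `H`, `W` and `cortex_hw = c(h, w)` of the
#'   per-hemisphere cortex rectangle.
#' @return list with `sections` (list of `list(img, ipsi_mask, contra_mask)`)
#'   and `truth` (data.frame `section`, `ipsi_px`, `contra_px`, `pct_loss`;
#'   attribute `aggregate_pct_loss`).
#' @export
make_coronal_sections <- function(n_sections = 6, loss_fraction = 0, seed = 1,
                                  geometry = list(H = 100, W = 140,
                                                  cortex_hw = c(40, 30))) {
  loss <- rep_len(loss_fraction, n_sections)
  stopifnot(all(loss >= 0), all(loss < 1))
  H <- geometry$H; W <- geometry$W
  ch <- geometry$cortex_hw[1]; cw <- geometry$cortex_hw[2]
  mid <- floor(W / 2)
  r0 <- floor((H - ch) / 2) + 1L
  rows <- r0:(r0 + ch - 1L)
  contra_cols <- (mid + 6L):(mid + 5L + cw)
  ipsi_cols_full <- (mid - 5L - cw):(mid - 6L)
  contra_area <- ch * cw
  sections <- vector("list", n_sections)
  truth <- vector("list", n_sections)
  for (s in seq_len(n_sections)) {
    ipsi_area <- round((1 - loss[s]) * contra_area)
    contra <- matrix(FALSE, H, W); contra[rows, contra_cols] <- TRUE
    ipsi <- matrix(FALSE, H, W)
    if (ipsi_area > 0) {
      # remove pixels column-by-column from the lateral (left) edge
      keep <- matrix(FALSE, ch, cw)
      keep[seq_len(ipsi_area) - 1L + 1L] <- TRUE
      keep <- keep[, rev(seq_len(cw))]  # fill from medial edge outward
      ipsi[rows, ipsi_cols_full] <- keep
    }
    img <- array(0, c(H, W, 3))
    img[, , 1] <- 235; img[, , 2] <- 230; img[, , 3] <- 235
    for (ch_i in 1:3) {
      plane <- img[, , ch_i]
      plane[ipsi | contra] <- c(150, 90, 160)[ch_i]
      img[, , ch_i] <- plane
    }
    sections[[s]] <- list(img = img, ipsi_mask = ipsi, contra_mask = contra)
    truth[[s]] <- data.frame(section = s, ipsi_px = sum(ipsi),
                             contra_px = sum(contra),
                             pct_loss = 100 * (1 - sum(ipsi) / sum(contra)))
  }
  truth <- do.call(rbind, truth)
  attr(truth, "aggregate_pct_loss") <-
    100 * (1 - sum(truth$ipsi_px) / sum(truth$contra_px))
  list(sections = sections, truth = truth)
}

#' Synthesize a laser-Doppler flow trace with a programmed percent step
#'
#' Baseline flow at `baseline_au` with multiplicative-free additive Gaussian
#' noise, stepping to `baseline_au * (1 + step_pct/100)` at `step_at_s`.
#'
#' @param duration_s recording length (s).
#' @param fs_hz sampling rate (Hz).
#' @param baseline_au baseline flow level (arbitrary units, > 0).
#' @param step_pct programmed percent change after the step.
#' @param step_at_s step onset time (s).
#' @param noise_sd additive noise SD (a.u.).
#' @param seed integer RNG seed.
#' @return list with `series` (unit `doppler_au`) and `truth`
#'   (`step_pct`, `step_at_s`).
#' @export
make_doppler_trace <- function(duration_s = 120, fs_hz = 10, baseline_au = 100,
                               step_pct = 50, step_at_s = 60, noise_sd = 0,
                               seed = 1) {
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  v <- ifelse(t < step_at_s, baseline_au, baseline_au * (1 + step_pct / 100))
  if (noise_sd > 0) v <- with_seed(seed, v + stats::rnorm(n, 0, noise_sd))
  list(series = time_series(v, fs_hz, "doppler_au"),
       truth = list(step_pct = step_pct, step_at_s = step_at_s))
}
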