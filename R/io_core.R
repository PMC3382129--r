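#' Time-ordered image stack
#'
#' Container for a sequence of 2-D frames acquired at a fixed interval, the
#' common currency of the imaging stages (diameter imaging at ~0.5 frame/s,
#' fluorescent angiography at 30 frames/s, single histology photographs).
#'
#' Pixel coordinates throughout the package are 0-based and row-major:
#' `(row = y, col = x)`, with `(0, 0)` the top-left pixel. Time origin is
#' `t = 0` at the first frame; `t0_s` offsets the whole recording when several
#' recordings must be aligned to a stimulation schedule.
#'
#' @param frames numeric array, `T x H x W` (grayscale) or `T x H x W x 3`
#'   (RGB). A single matrix is promoted to a one-frame stack. Integer
#'   intensities are kept as given; no rescaling is applied.
#' @param pixel_size_um microns per pixel (> 0).
#' @param frame_interval_s seconds between consecutive frames (> 0).
#' @param t0_s acquisition start offset in seconds.
#' @return An object of class `image_stack` with fields `frames`,
#'   `pixel_size_um`, `frame_interval_s`, `t0_s`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s, t0_s = 0) {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  }
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) {
    stop("frames must be T x H x W or T x H x W x 3 (got ", nd, " dims)")
  }
  if (nd == 4L && dim(frames)[4] != 3L) {
    stop("RGB stacks must have 3 channels, got ", dim(frames)[4])
  }
  if (dim(frames)[1] < 1L) stop("image_stack needs T >= 1 frames")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, t0_s = t0_s),
    class = "image_stack")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(name, " must be a positive finite scalar (got ",
         paste(format(x), collapse = ","), ")")
  }
  invisible(TRUE)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s), %d x %d px%s, %.3g um/px, dt = %.4g s\n",
              d[1], d[2], d[3],
              if (length(d) == 4L) " (RGB)" else "",
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' Extract one frame from a stack
#' @param stack an `image_stack`.
#' @param i frame index (1-based).
#' @return an `H x W` matrix or `H x W x 3` array.
#' @export
get_frame <- function(stack, i) {
  d <- dim(stack$frames)
  if (i < 1L || i > d[1]) stop("frame index ", i, " out of range 1..", d[1])
  if (length(d) == 3L) {
    matrix(stack$frames[i, , ], d[2], d[3])
  } else {
    array(stack$frames[i, , , ], d[2:4])
  }
}

#' Frame times of a stack
#' @param stack an `image_stack`.
#' @return numeric vector of frame acquisition times (s), `t0_s` included.
#' @export
frame_times <- function(stack) {
  stack$t0_s + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval_s
}

#' Read a multi-page TIFF into an image stack
#'
#' Pages are taken in file order. Integer sample values are preserved without
#' rescaling (`as.is` read), so 8/16-bit stacks round-trip losslessly through
#' [write_image_stack()].
#'
#' @param path path to a multi-page TIFF file, or a directory of single-page
#'   TIFFs read in lexicographic filename order.
#' @param pixel_size_um,frame_interval_s,t0_s acquisition metadata, see
#'   [image_stack()].
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path, pixel_size_um, frame_interval_s, t0_s = 0) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF files found in directory: ", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent frame shapes across pages: ",
         paste(unique(shapes), collapse = ", "))
  }
  d1 <- dim(pages[[1]])
  frames <- if (length(d1) == 2L) {
    array(NA_real_, c(length(pages), d1[1], d1[2]))
  } else {
    array(NA_real_, c(length(pages), d1[1], d1[2], d1[3]))
  }
  for (i in seq_along(pages)) {
    if (length(d1) == 2L) frames[i, , ] <- pages[[i]] else frames[i, , , ] <- pages[[i]]
  }
  image_stack(frames, pixel_size_um, frame_interval_s, t0_s)
}

#' Write an image stack to a multi-page TIFF
#'
#' Integer-valued stacks are written at the stated bit depth and read back
#' bit-exactly by [read_image_stack()]; float stacks must lie in the unit
#' interval and are written as 32-bit float.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @param bits bits per sample for integer data (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 16L) {
  fr <- stack$frames
  d <- dim(fr)
  is_int <- max(abs(fr - round(fr))) == 0
  pages <- lapply(seq_len(d[1]), function(i) {
    p <- if (length(d) == 3L) matrix(fr[i, , ], d[2], d[3]) else array(fr[i, , , ], d[2:4])
    if (is_int) p / (2^bits - 1) else p
  })
  if (is_int) {
    if (min(fr) < 0 || max(fr) > 2^bits - 1) {
      stop("integer intensities outside 0..", 2^bits - 1, " for ", bits, "-bit TIFF")
    }
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  } else {
    if (min(fr) < 0 || max(fr) > 1) stop("float stacks must lie in [0, 1]")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a single RGB photograph (PNG or TIFF)
#'
#' For histology images (dorsal-cortex Evans-blue photographs, coronal
#' sections). PNG values are returned on the 0-255 scale; TIFF integer
#' samples are preserved as stored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric `H x W x 3` array.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG images requires the 'png' package")
    }
    png::readPNG(path) * 255
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img[, , 1:3, drop = FALSE]
  } else {
    stop("expected an RGB image, got ", paste(dim(img), collapse = "x"))
  }
}

#' Uniformly sampled 1-D signal
#'
#' @param values numeric vector, length >= 2, no missing samples (split gapped
#'   recordings into separate series).
#' @param fs_hz sampling rate in Hz (> 0).
#' @param unit one of `"doppler_au"`, `"ecog_uv"`, `"intensity_iu"`,
#'   `"percent"`.
#' @param t0_s start time offset in seconds.
#' @return An object of class `time_series`.
#' @export
time_series <- function(values, fs_hz, unit = c("doppler_au", "ecog_uv",
                                                "intensity_iu", "percent"),
                        t0_s = 0) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("time_series needs length >= 2")
  if (anyNA(values)) stop("time_series must not contain missing samples")
  check_positive_scalar(fs_hz, "fs_hz")
  structure(list(values = values, fs_hz = fs_hz, unit = unit, t0_s = t0_s),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz [%s], %.4g s\n",
              length(x$values), x$fs_hz, x$unit,
              length(x$values) / x$fs_hz))
  invisible(x)
}

#' Sample times of a time series
#' @param ts a `time_series`.
#' @return numeric vector of sample times in seconds.
#' @export
sample_times <- function(ts) ts$t0_s + (seq_along(ts$values) - 1L) / ts$fs_hz

#' Read a time series from CSV
#'
#' Two dialects are accepted: a two-column `time_s,value` file with header
#' (sampling rate inferred from the median time step, which must be uniform to
#' 1e-6 relative tolerance), or a single `value` column with `fs_hz` supplied
#' either as an argument or in a YAML sidecar `<path>.yaml` with keys `fs_hz`,
#' `unit`, `t0_s`.
#'
#' @param path CSV file path.
#' @param fs_hz sampling rate; required for the single-column dialect when no
#'   sidecar exists.
#' @param unit unit tag, see [time_series()]; sidecar value wins if present.
#' @return a `time_series`.
#' @export
read_time_series_csv <- function(path, fs_hz = NULL, unit = "doppler_au") {
  if (!file.exists(path)) stop("path does not exist: ", path)
  df <- utils::read.csv(path)
  t0 <- 0
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$fs_hz)) fs_hz <- meta$fs_hz
    if (!is.null(meta$unit)) unit <- meta$unit
    if (!is.null(meta$t0_s)) t0 <- meta$t0_s
  }
  if (all(c("time_s", "value") %in% names(df))) {
    dt <- diff(df$time_s)
    if (length(dt) < 1L || any(dt <= 0)) stop("time_s must be strictly increasing")
    if (max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt)) {
      stop("non-uniform sampling in ", path,
           "; split gapped recordings into separate series")
    }
    time_series(df$value, 1 / stats::median(dt), unit, t0_s = df$time_s[1])
  } else if ("value" %in% names(df)) {
    if (is.null(fs_hz)) stop("single-column CSV needs fs_hz (argument or sidecar)")
    time_series(df$value, fs_hz, unit, t0_s = t0)
  } else {
    stop("CSV must have columns (time_s, value) or (value); got: ",
         paste(names(df), collapse = ", "))
  }
}

#' Write a time series to CSV (two-column dialect)
#' @param ts a `time_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_time_series_csv <- function(ts, path) {
  utils::write.csv(data.frame(time_s = sample_times(ts), value = ts$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Region of interest on an image frame
#'
#' @param label vessel-compartment label: `"artery"`, `"vein"`,
#'   `"parenchyma"` or `"other"`.
#' @param mask logical `H x W` matrix; alternatively supply `polygon`.
#' @param polygon optional `n x 2` matrix of (row, col) vertices in 0-based
#'   pixel coordinates; rasterized to a mask against `dim_hw`.
#' @param dim_hw frame dimensions `c(H, W)`, required with `polygon`.
#' @return An object of class `roi` with fields `label` and `mask`.
#' @export
roi <- function(label = c("artery", "vein", "parenchyma", "other"),
                mask = NULL, polygon = NULL, dim_hw = NULL) {
  label <- match.arg(label)
  if (is.null(mask)) {
    if (is.null(polygon) || is.null(dim_hw)) {
      stop("supply either mask or polygon + dim_hw")
    }
    mask <- rasterize_polygon(polygon, dim_hw)
  }
  if (!is.matrix(mask)) stop("mask must be a logical matrix")
  mask <- mask > 0
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(label = label, mask = mask), class = "roi")
}

# Even-odd rule point-in-polygon rasterization; vertices are (row, col),
# 0-based, tested against pixel centers.
rasterize_polygon <- function(polygon, dim_hw) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2L, nrow(polygon) >= 3L)
  if (any(polygon[, 1] < 0) || any(polygon[, 1] > dim_hw[1] - 1) ||
      any(polygon[, 2] < 0) || any(polygon[, 2] > dim_hw[2] - 1)) {
    stop("polygon vertices outside frame bounds")
  }
  H <- dim_hw[1]; W <- dim_hw[2]
  ys <- polygon[, 1]; xs <- polygon[, 2]
  n <- nrow(polygon)
  mask <- matrix(FALSE, H, W)
  px <- rep(0:(W - 1), each = H)
  py <- rep(0:(H - 1), times = W)
  inside <- rep(FALSE, H * W)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(py + 1L, px + 1L)] <- inside
  mask
}

#' Stimulation protocol schedule
#'
#' Parameters of a repeated-train stimulation protocol. The default is the
#' acute protocol used for pial-vessel imaging: 12 trains, each two 60-s
#' 10-Hz sets separated by a 12-s interval, followed by 13.6 min of OFF time.
#' The protocol's nominal total treatment time (180 min as originally stated)
#' can be carried in `total_treatment_min` as metadata; it is never recomputed
#' from the per-train parameters, whose expansion gives 189.6 min.
#'
#' @param n_trains number of stimulation trains (>= 1).
#' @param sets_per_train stimulation sets per train.
#' @param set_duration_s duration of one ON set (s).
#' @param inter_set_gap_s gap between consecutive sets within a train (s).
#' @param off_time_s OFF time after the last set of a train (s).
#' @param pulse_width_us pulse width (microseconds).
#' @param intensity_ma stimulation intensity (mA).
#' @param frequency_hz pulse frequency within a set (Hz).
#' @param total_treatment_min optional nominal total treatment time, stored
#'   as metadata only.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(n_trains = 12, sets_per_train = 2,
                          set_duration_s = 60, inter_set_gap_s = 12,
                          off_time_s = 13.6 * 60, pulse_width_us = 500,
                          intensity_ma = 2, frequency_hz = 10,
                          total_treatment_min = NULL) {
  for (nm in c("set_duration_s", "inter_set_gap_s", "off_time_s",
               "pulse_width_us", "intensity_ma", "frequency_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop(nm, " must be a non-negative scalar")
    }
  }
  if (n_trains < 1 || sets_per_train < 1) stop("n_trains and sets_per_train must be >= 1")
  if (set_duration_s <= 0) stop("set_duration_s must be > 0")
  structure(list(n_trains = as.integer(n_trains),
                 sets_per_train = as.integer(sets_per_train),
                 set_duration_s = set_duration_s,
                 inter_set_gap_s = inter_set_gap_s,
                 off_time_s = off_time_s, pulse_width_us = pulse_width_us,
                 intensity_ma = intensity_ma, frequency_hz = frequency_hz,
                 total_treatment_min = total_treatment_min),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(paste0("<stim_protocol> %d train(s) x %d set(s) of %g s ",
                     "(gap %g s, OFF %g s), %g Hz, %g mA, %g us\n"),
              x$n_trains, x$sets_per_train, x$set_duration_s,
              x$inter_set_gap_s, x$off_time_s, x$frequency_hz,
              x$intensity_ma, x$pulse_width_us))
  invisible(x)
}

#' Expand a stimulation protocol into ON intervals
#'
#' Times are relative to schedule start (the onset of the first set). Within a
#' train, consecutive sets are separated by `inter_set_gap_s`; the next train
#' starts `off_time_s` after the last set of the previous one.
#'
#' @param p a `stim_protocol`.
#' @return data.frame with columns `train`, `set`, `on_start_s`, `on_end_s`;
#'   `n_trains * sets_per_train` rows, sorted, non-overlapping.
#' @export
expand_schedule <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  train_len <- p$sets_per_train * p$set_duration_s +
    (p$sets_per_train - 1) * p$inter_set_gap_s
  train_starts <- (seq_len(p$n_trains) - 1) * (train_len + p$off_time_s)
  out <- do.call(rbind, lapply(seq_len(p$n_trains), function(k) {
    set_starts <- train_starts[k] +
      (seq_len(p$sets_per_train) - 1) * (p$set_duration_s + p$inter_set_gap_s)
    data.frame(train = k, set = seq_len(p$sets_per_train),
               on_start_s = set_starts, on_end_s = set_starts + p$set_duration_s)
  }))
  stopifnot(all(diff(out$on_start_s) > 0),
            all(out$on_end_s[-nrow(out)] <= out$on_start_s[-1]))
  out
}
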