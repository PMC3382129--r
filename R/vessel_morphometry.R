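# Pial-vessel segmentation and diameter morphometry.
#
# Segmentation follows the classical binary-mask recipe for intravital
# images: median denoise -> local-mean adaptive threshold -> morphological
# hole filling -> small-object removal. Diameter is the perpendicular chord
# through the vessel skeleton ("pixels across the vessel"), not twice the
# distance transform.

#' Default vessel segmentation parameters
#'
#' @param denoise_radius median-filter radius (px).
#' @param threshold_window side of the square local-mean window (px, odd).
#' @param threshold_offset threshold offset above (bright) / below (dark) the
#'   local mean, as a fraction of the frame's dynamic range.
#' @param min_object_px connected components smaller than this are removed.
#' @param polarity `"bright"` if vessels are brighter than background,
#'   `"dark"` otherwise.
#' @return named list of parameters.
#' @export
vessel_cfg <- function(denoise_radius = 2, threshold_window = 51,
                       threshold_offset = 0.02, min_object_px = 50,
                       polarity = c("bright", "dark")) {
  list(denoise_radius = denoise_radius,
       threshold_window = as.integer(threshold_window),
       threshold_offset = threshold_offset,
       min_object_px = min_object_px,
       polarity = match.arg(polarity))
}

#' Segment vessels in one grayscale frame
#'
#' Pipeline order is fixed: median denoise, local adaptive threshold (mean of
#' the `threshold_window` neighborhood plus `threshold_offset` of the dynamic
#' range, polarity-aware), morphological hole filling, removal of connected
#' components below `min_object_px`. The frame is first normalized to its own
#' dynamic range, which makes the mask invariant to affine intensity
#' rescaling.
#'
#' @param frame numeric `H x W` matrix.
#' @param cfg parameter list from [vessel_cfg()].
#' @param frame_index optional frame index recorded in provenance.
#' @return object of class `vessel_mask`: `mask` (logical `H x W`),
#'   `frame_index`, `provenance` (the parameters used). A frame with zero
#'   dynamic range yields an empty mask with a warning.
#' @export
segment_vessels <- function(frame, cfg = vessel_cfg(), frame_index = NA_integer_) {
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (diff(rng) == 0) {
    warning("frame has zero dynamic range; returning empty mask")
    return(structure(list(mask = matrix(FALSE, nrow(frame), ncol(frame)),
                          frame_index = frame_index, provenance = cfg),
                     class = "vessel_mask"))
  }
  x <- (frame - rng[1]) / diff(rng)
  if (cfg$polarity == "dark") x <- 1 - x
  if (cfg$denoise_radius > 0) x <- EBImage::medianFilter(x, cfg$denoise_radius)
  w <- cfg$threshold_window
  if (w %% 2L == 0L) w <- w + 1L
  box <- matrix(1 / (w * w), w, w)
  local_mean <- EBImage::filter2(x, box, boundary = "replicate")
  mask <- x > local_mean + cfg$threshold_offset
  mask <- EBImage::fillHull(mask) > 0
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= cfg$min_object_px)
    mask <- matrix(lab %in% keep, nrow(frame), ncol(frame))
  }
  structure(list(mask = mask, frame_index = frame_index, provenance = cfg),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d, %d foreground px (frame %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$frame_index))
  invisible(x)
}

shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subpass thinning to a one-pixel-wide, 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- shift_mat(m,  1,  0); p3 <- shift_mat(m,  1, -1)
      p4 <- shift_mat(m,  0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1,  0); p7 <- shift_mat(m, -1,  1)
      p8 <- shift_mat(m,  0,  1); p9 <- shift_mat(m,  1,  1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & b >= 2 & b <= 6 & a == 1
      if (pass == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Bilinear interpolation of a numeric matrix at continuous 0-based (row, col)
# positions; positions outside the grid evaluate to 0.
bilinear_at <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- numeric(length(rows))
  get_px <- function(r, c) {
    ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok] + 1L, c[ok] + 1L)]
    v
  }
  val <- get_px(r0, c0) * (1 - fr) * (1 - fc) +
    get_px(r0 + 1, c0) * fr * (1 - fc) +
    get_px(r0, c0 + 1) * (1 - fr) * fc +
    get_px(r0 + 1, c0 + 1) * fr * fc
  val
}

snap_to_skeleton <- function(skel, point, snap_radius) {
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no skeleton; no vessel detected")
  ry <- idx[, 1] - 1; cx <- idx[, 2] - 1
  d2 <- (ry - point[1])^2 + (cx - point[2])^2
  if (min(d2) > snap_radius^2) {
    stop(sprintf("point (%g, %g) farther than snap radius %g from any vessel",
                 point[1], point[2], snap_radius))
  }
  # tie-break: smallest distance, then lowest row, then lowest column
  ord <- order(d2, ry, cx)
  c(ry[ord[1]], cx[ord[1]])
}

local_tangent <- function(skel, center, window = 3) {
  idx <- which(skel, arr.ind = TRUE)
  ry <- idx[, 1] - 1; cx <- idx[, 2] - 1
  near <- abs(ry - center[1]) <= window & abs(cx - center[2]) <= window
  pts <- cbind(ry[near], cx[near])
  if (nrow(pts) < 2L) return(c(0, 1))  # isolated pixel: assume horizontal run
  pc <- sweep(pts, 2, colMeans(pts))
  v <- eigen(crossprod(pc), symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Measure local vessel diameter at a point
#'
#' The query point is snapped to the nearest skeleton pixel of the mask;
#' local orientation is taken from the skeleton tangent in a +-3 px window;
#' the diameter is the length of the contiguous foreground chord along the
#' perpendicular through the snapped point. The chord is traced on the
#' bilinearly interpolated mask at 0.1-px steps with the half-coverage (0.5)
#' crossing located by linear interpolation, which corrects for non-axis-
#' aligned perpendiculars at sub-pixel resolution.
#'
#' @param mask a `vessel_mask` or logical matrix.
#' @param point `c(row, col)` in 0-based pixel coordinates.
#' @param pixel_size_um microns per pixel.
#' @param snap_radius maximum snap distance (px).
#' @param skeleton optional precomputed [skeletonize()] result.
#' @return diameter in microns.
#' @export
measure_diameter <- function(mask, point, pixel_size_um, snap_radius = 5,
                             skeleton = NULL) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  if (is.null(skeleton)) skeleton <- skeletonize(m)
  ctr <- snap_to_skeleton(skeleton, point, snap_radius)
  tang <- local_tangent(skeleton, ctr)
  perp <- c(-tang[2], tang[1])
  num <- matrix(as.numeric(m), nrow(m), ncol(m))
  step <- 0.1
  L <- max(nrow(m), ncol(m))
  s <- seq(-L, L, by = step)
  vals <- bilinear_at(num, ctr[1] + s * perp[1], ctr[2] + s * perp[2])
  fg <- vals >= 0.5
  i0 <- which.min(abs(s))
  if (!fg[i0]) stop("snapped point not inside vessel foreground")
  lo <- i0; while (lo > 1L && fg[lo - 1L]) lo <- lo - 1L
  hi <- i0; while (hi < length(s) && fg[hi + 1L]) hi <- hi + 1L
  cross_at <- function(i_in, i_out) {
    # linear interpolation of the 0.5 crossing between grid samples
    if (i_out < 1L || i_out > length(s)) return(s[i_in])
    s[i_in] + (s[i_out] - s[i_in]) * (0.5 - vals[i_in]) /
      (vals[i_out] - vals[i_in])
  }
  s_lo <- cross_at(lo, lo - 1L)
  s_hi <- cross_at(hi, hi + 1L)
  (s_hi - s_lo) * pixel_size_um
}

#' Vessel diameter time course at fixed measurement points
#'
#' Segments every frame, measures the diameter at each of the supplied
#' points (conventionally five, chosen manually along the vessel of
#' interest), normalizes each point to its own baseline mean, and averages
#' the per-point percent changes. Frames where a point cannot be measured are
#' recorded as missing, never interpolated; a point missing in more than 20%
#' of frames is flagged in the provenance.
#'
#' @param stack an [image_stack()] of grayscale frames.
#' @param points `P x 2` matrix of 0-based (row, col) measurement points.
#' @param baseline_window integer frame range `c(first, last)` (1-based) used
#'   as the pre-stimulation baseline; must contain at least one frame. The
#'   conventional choice is every frame in the minute before the first
#'   stimulation ON interval.
#' @param cfg segmentation parameters, see [vessel_cfg()].
#' @param snap_radius maximum point-to-skeleton snap distance (px).
#' @return object of class `diameter_trace`: `points`, `time_s`, `diam_um`
#'   (`T x P`), `baseline_um` (per point), `pct_change` (`T x P`,
#'   `100 * (d - baseline)/baseline`), `avg_pct_change` (length `T`,
#'   point-averaged after per-point normalization), `baseline_window`,
#'   `provenance` (cfg, per-point missing fraction, flagged points).
#' @export
diameter_timeseries <- function(stack, points, baseline_window, cfg = vessel_cfg(),
                                snap_radius = 5) {
  stopifnot(inherits(stack, "image_stack"), is.matrix(points),
            ncol(points) == 2L)
  nf <- n_frames(stack)
  bw <- as.integer(baseline_window)
  if (length(bw) != 2L || bw[1] < 1L || bw[2] > nf || bw[2] < bw[1]) {
    stop("baseline_window must be a frame range within 1..", nf)
  }
  P <- nrow(points)
  diam <- matrix(NA_real_, nf, P)
  for (i in seq_len(nf)) {
    vm <- segment_vessels(get_frame(stack, i), cfg, frame_index = i)
    if (!any(vm$mask)) next
    skel <- skeletonize(vm$mask)
    for (p in seq_len(P)) {
      diam[i, p] <- tryCatch(
        measure_diameter(vm$mask, points[p, ], stack$pixel_size_um,
                         snap_radius, skeleton = skel),
        error = function(e) NA_real_)
    }
  }
  baseline <- colMeans(diam[bw[1]:bw[2], , drop = FALSE], na.rm = TRUE)
  if (all(!is.finite(baseline))) {
    stop("no baseline diameter could be measured at any point")
  }
  if (any(!is.finite(baseline))) {
    warning("no baseline diameter at point(s) ",
            paste(which(!is.finite(baseline)), collapse = ", "),
            "; their traces are all-missing")
    baseline[!is.finite(baseline)] <- NA_real_
  }
  pct <- sweep(sweep(diam, 2, baseline), 2, baseline, "/") * 100
  missing_frac <- colMeans(is.na(diam))
  structure(list(points = points, time_s = frame_times(stack),
                 diam_um = diam, baseline_um = baseline, pct_change = pct,
                 avg_pct_change = rowMeans(pct, na.rm = TRUE),
                 baseline_window = bw,
                 provenance = list(cfg = cfg, snap_radius = snap_radius,
                                   missing_fraction = missing_frac,
                                   flagged_points = which(missing_frac > 0.2))),
            class = "diameter_trace")
}

#' @export
print.diameter_trace <- function(x, ...) {
  cat(sprintf("<diameter_trace> %d frames x %d points; baseline %s um\n",
              nrow(x$diam_um), ncol(x$diam_um),
              paste(round(x$baseline_um, 2), collapse = ", ")))
  if (length(x$provenance$flagged_points)) {
    cat("  flagged (>20% missing): point(s) ",
        paste(x$provenance$flagged_points, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.diameter_trace <- function(x, ...) {
  graphics::matplot(x$time_s, x$pct_change, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "diameter (% of baseline)", ...)
  graphics::lines(x$time_s, x$avg_pct_change, lwd = 2)
  invisible(x)
}

#' Export a diameter trace as a tidy data.frame
#' @param trace a `diameter_trace`.
#' @return data.frame with columns `frame`, `time_s`, `point_id`, `diam_um`,
#'   `pct_change`.
#' @export
diameter_trace_table <- function(trace) {
  P <- ncol(trace$diam_um); T_ <- nrow(trace$diam_um)
  data.frame(frame = rep(seq_len(T_), P),
             time_s = rep(trace$time_s, P),
             point_id = rep(seq_len(P), each = T_),
             diam_um = as.vector(trace$diam_um),
             pct_change = as.vector(trace$pct_change))
}
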