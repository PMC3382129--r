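# Evans-blue BBB quantification from dorsal-cortex RGB photographs and
# cortical-volume loss from serial coronal sections. Hemisphere and cortex
# masks are inputs: the imaging protocol gives no rule to auto-segment them.

#' Quantify Evans-blue extravasation in the treated hemisphere
#'
#' Extracts the blue channel, averages it over the whole treated-hemisphere
#' mask, and reports the percentage of treated-hemisphere pixels whose blue
#' value exceeds a fixed threshold. The threshold has no default: the imaging
#' protocol leaves its value to the operator, so it must be stated explicitly
#' and is recorded in the result.
#'
#' @param img RGB array `H x W x 3` (any consistent intensity scale; 0-255
#'   for the synthetic photographs).
#' @param treated_mask logical `H x W` mask of the treated hemisphere;
#'   non-empty.
#' @param fixed_threshold blue-channel cutoff defining a "blue pixel".
#' @return object of class `evans_blue_result`: `mean_blue`,
#'   `pct_blue_pixels` (0-100), `fixed_threshold`, `n_pixels`.
#' @export
quantify_evans_blue <- function(img, treated_mask, fixed_threshold) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L, is.matrix(treated_mask))
  if (!all(dim(treated_mask) == dim(img)[1:2])) {
    stop("mask does not match image dimensions")
  }
  if (!any(treated_mask)) stop("treated-hemisphere mask is empty")
  if (missing(fixed_threshold)) stop("fixed_threshold must be given explicitly")
  blue <- img[, , 3][treated_mask]
  structure(list(mean_blue = mean(blue),
                 pct_blue_pixels = 100 * mean(blue > fixed_threshold),
                 fixed_threshold = fixed_threshold,
                 n_pixels = length(blue)),
            class = "evans_blue_result")
}

#' @export
print.evans_blue_result <- function(x, ...) {
  cat(sprintf("<evans_blue_result> mean blue %.4g; %.2f%% pixels above threshold %g (n = %d px)\n",
              x$mean_blue, x$pct_blue_pixels, x$fixed_threshold, x$n_pixels))
  invisible(x)
}

#' Cortical-volume loss from serial coronal sections
#'
#' Per section, the remaining ipsilateral cortical area (pixel count) is
#' compared with the contralateral control hemisphere:
#' `pct_loss = 100 * (1 - ipsi_px / contra_px)`. The aggregate pools pixel
#' counts over sections (area-weighted), which stands in for volume because
#' sections are cut at equal thickness (40 um in the histology protocol).
#'
#' @param sections list of `list(ipsi_mask, contra_mask)` (an `img` element,
#'   if present, is ignored by the computation).
#' @return object of class `lesion_volume_result`: `per_section`
#'   (data.frame `section`, `ipsi_px`, `contra_px`, `pct_loss`),
#'   `aggregate_pct_loss` (`100 * (1 - sum(ipsi)/sum(contra))`), `n_sections`.
#' @export
cortical_volume_change <- function(sections) {
  stopifnot(length(sections) >= 1L)
  per <- lapply(seq_along(sections), function(s) {
    sec <- sections[[s]]
    ipsi <- sum(sec$ipsi_mask > 0)
    contra <- sum(sec$contra_mask > 0)
    if (contra == 0) stop("section ", s, ": contralateral mask is empty")
    data.frame(section = s, ipsi_px = ipsi, contra_px = contra,
               pct_loss = 100 * (1 - ipsi / contra))
  })
  per <- do.call(rbind, per)
  agg <- 100 * (1 - sum(per$ipsi_px) / sum(per$contra_px))
  # consistency check: aggregate must be reproducible from the table
  stopifnot(abs(agg - 100 * (1 - sum(per$ipsi_px) / sum(per$contra_px))) < 1e-12)
  structure(list(per_section = per, aggregate_pct_loss = agg,
                 n_sections = nrow(per)),
            class = "lesion_volume_result")
}

#' @export
print.lesion_volume_result <- function(x, ...) {
  cat(sprintf("<lesion_volume_result> %d section(s); aggregate cortical loss %.2f%%\n",
              x$n_sections, x$aggregate_pct_loss))
  invisible(x)
}
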