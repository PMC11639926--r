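# Optimal acquisition-parameter selection: line profiles through the bruise,
# peak-to-valley contrast, and ranking over (spatial frequency, wavelength).

#' Extract a pixel intensity profile along a line segment
#'
#' Samples the image at the nearest pixel along the rasterized segment
#' between two endpoints (rounded linear interpolation with one sample per
#' pixel step along the major axis), mirroring how a pixel-intensity curve
#' is read off an AC image through the bruise.
#'
#' @param image numeric matrix.
#' @param from,to integer c(row, col) endpoints, inside the image.
#' @return object of class `siri_profile`: list with `rows`, `cols` (pixel
#'   coordinates along the segment), `intensities`, and `endpoints`.
#' @export
extract_line_profile <- function(image, from, to) {
  stopifnot(is.matrix(image), length(from) == 2, length(to) == 2)
  pts <- rbind(from, to)
  if (any(pts[, 1] < 1 | pts[, 1] > nrow(image) |
          pts[, 2] < 1 | pts[, 2] > ncol(image)))
    stop("endpoints outside image", call. = FALSE)
  seg <- raster_segment(from[1], from[2], to[1], to[2])
  structure(list(rows = seg$r, cols = seg$c,
                 intensities = image[cbind(seg$r, seg$c)],
                 endpoints = list(from = from, to = to)),
            class = "siri_profile")
}

# nearest-pixel raster line between (r0,c0) and (r1,c1), both endpoints
# included: one sample per pixel step along the major axis
raster_segment <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  list(r = as.integer(round(seq(r0, r1, length.out = n))),
       c = as.integer(round(seq(c0, c1, length.out = n))))
}

#' Peak-to-valley contrast of a line profile
#'
#' Contrast between the normal and bruised regions along a profile, measured
#' as the peak intensity over the normal window minus the valley intensity
#' over the bruise window, floored at 0.
#'
#' @param profile a `siri_profile`.
#' @param bruise_window,normal_window integer index ranges into the profile;
#'   must be non-empty and non-overlapping.
#' @return single non-negative contrast value (same intensity units as the
#'   profile).
#' @export
peak_to_valley_contrast <- function(profile, bruise_window, normal_window) {
  stopifnot(inherits(profile, "siri_profile"))
  n <- length(profile$intensities)
  if (!length(bruise_window) || !length(normal_window))
    stop("windows must be non-empty", call. = FALSE)
  if (any(c(bruise_window, normal_window) < 1) ||
      any(c(bruise_window, normal_window) > n))
    stop("window indices outside profile", call. = FALSE)
  if (length(intersect(bruise_window, normal_window)))
    stop("windows must not overlap", call. = FALSE)
  v <- profile$intensities
  max(max(v[normal_window]) - min(v[bruise_window]), 0)
}

#' Build a contrast table over (spatial frequency, wavelength)
#'
#' @param frequencies,wavelengths,contrasts equal-length vectors, one row per
#'   acquisition condition.
#' @return data.frame of class `siri_contrast_table` with columns
#'   `frequency_cyc_per_mm`, `wavelength_nm`, `contrast`.
#' @export
contrast_table <- function(frequencies, wavelengths, contrasts) {
  stopifnot(length(frequencies) == length(wavelengths),
            length(frequencies) == length(contrasts))
  if (any(contrasts < 0)) stop("contrasts must be >= 0", call. = FALSE)
  if (anyDuplicated(paste(frequencies, wavelengths)))
    stop("duplicate (frequency, wavelength) rows", call. = FALSE)
  structure(data.frame(frequency_cyc_per_mm = frequencies,
                       wavelength_nm = wavelengths,
                       contrast = contrasts),
            class = c("siri_contrast_table", "data.frame"))
}

#' Select the optimal (spatial frequency, wavelength)
#'
#' Returns the acquisition condition with the largest bruise/normal contrast.
#' Ties are broken toward the lower spatial frequency, then the lower
#' wavelength, so the result does not depend on row order.
#'
#' @param table a [contrast_table()] (or data.frame with the same columns).
#' @return list with `frequency`, `wavelength`, `contrast`.
#' @export
rank_parameters <- function(table) {
  if (!nrow(table)) stop("empty contrast table", call. = FALSE)
  ord <- order(-table$contrast, table$frequency_cyc_per_mm, table$wavelength_nm)
  best <- table[ord[1], ]
  list(frequency = best$frequency_cyc_per_mm,
       wavelength = best$wavelength_nm,
       contrast = best$contrast)
}
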