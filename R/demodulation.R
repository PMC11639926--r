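# Three-phase demodulation of structured-illumination pattern images.
#
# Pattern images are held as plain numeric matrices on the unit intensity
# scale; a triplet bundles the three phase-shifted acquisitions together with
# the acquisition metadata (spatial frequency, wavelength, pixel pitch).

PHASE_OFFSETS <- c(-2 * pi / 3, 0, 2 * pi / 3)

#' Bundle three phase-shifted pattern images into a triplet
#'
#' Structured-illumination acquisition projects a sinusoidal pattern at three
#' phase offsets (-2pi/3, 0, 2pi/3) and records one image per offset; the
#' triplet is the unit of demodulation.
#'
#' @param i1,i2,i3 numeric matrices in \[0,1\]: the pattern images at phase
#'   offsets -2pi/3, 0 and 2pi/3 respectively.
#' @param spatial_frequency spatial frequency of the projected sinusoid, in
#'   cycles per mm on the sample.
#' @param wavelength illumination wavelength in nm.
#' @param pixel_pitch size of one pixel on the sample, mm per pixel.
#' @return an object of class `siri_triplet`.
#' @export
siri_triplet <- function(i1, i2, i3, spatial_frequency = NA_real_,
                         wavelength = NA_real_, pixel_pitch = NA_real_) {
  check_gray(i1); check_gray(i2); check_gray(i3)
  check_same_shape(i1, i2, "pattern images")
  check_same_shape(i1, i3, "pattern images")
  if (!is.na(spatial_frequency) && spatial_frequency < 0)
    stop("spatial_frequency must be >= 0", call. = FALSE)
  if (!is.na(wavelength) && wavelength <= 0)
    stop("wavelength must be > 0", call. = FALSE)
  structure(list(images = list(i1, i2, i3),
                 phase_offsets = PHASE_OFFSETS,
                 spatial_frequency = spatial_frequency,
                 wavelength = wavelength,
                 pixel_pitch = pixel_pitch),
            class = "siri_triplet")
}

#' @export
print.siri_triplet <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<siri_triplet> %d x %d px, f = %s cycle/mm, lambda = %s nm\n",
              d[1], d[2], format(x$spatial_frequency), format(x$wavelength)))
  invisible(x)
}

#' Flat-field / dark-frame calibration of a pattern image
#'
#' Corrects a raw acquisition for spatial non-uniformity of the light source
#' and for the sensor dark current, using a white reference (image of a
#' quasi-white plate) and a black reference (lens covered):
#' `R = (R0 - B) / (W - B)`, clipped to \[0,1\].  Pixels where the white
#' reference does not exceed the black reference carry no usable signal; they
#' are set to 0 and counted in the `invalid_pixels` attribute.
#'
#' @param raw numeric matrix: the raw pattern image.
#' @param white,black numeric matrices: the reference images, same shape as
#'   `raw`.
#' @return corrected image in \[0,1\] with attribute `invalid_pixels` (count
#'   of pixels flagged invalid).
#' @export
correct_reference <- function(raw, white, black) {
  check_gray(raw); check_gray(white); check_gray(black)
  check_same_shape(raw, white, "raw/white")
  check_same_shape(raw, black, "raw/black")
  denom <- white - black
  bad <- denom <= 0
  if (all(bad)) stop("all reference pixels invalid (white <= black)", call. = FALSE)
  out <- (raw - black) / ifelse(bad, 1, denom)
  out[bad] <- 0
  out <- pmin(pmax(out, 0), 1)
  attr(out, "invalid_pixels") <- sum(bad)
  out
}

#' Apply reference calibration to every image of a triplet
#'
#' @param triplet a [siri_triplet()].
#' @param white,black reference images (see [correct_reference()]).
#' @return a calibrated `siri_triplet`.
#' @export
correct_triplet <- function(triplet, white, black) {
  stopifnot(inherits(triplet, "siri_triplet"))
  imgs <- lapply(triplet$images, correct_reference, white = white, black = black)
  triplet$images <- lapply(imgs, function(m) { attributes(m)$invalid_pixels <- NULL; m })
  triplet$invalid_pixels <- attr(imgs[[1]], "invalid_pixels")
  triplet
}

#' Demodulate a three-phase triplet into AC and DC images
#'
#' With pattern images I1, I2, I3 acquired at phase offsets -2pi/3, 0, 2pi/3,
#' the amplitude (AC) and offset (DC) of the modulated reflectance are
#' recovered per pixel as
#' \deqn{I_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_1-I_3)^2 + (I_2-I_3)^2}}
#' \deqn{I_{DC} = (I_1+I_2+I_3)/3.}
#' The DC image is equivalent to a uniform-illumination reflectance image;
#' the AC image carries the depth-resolved contrast tied to the spatial
#' frequency of the illumination.
#'
#' @param triplet a [siri_triplet()].
#' @return an object of class `siri_demod` with elements `ac`, `dc`
#'   (matrices, `ac >= 0`), and the acquisition metadata.
#' @export
demodulate_three_phase <- function(triplet) {
  stopifnot(inherits(triplet, "siri_triplet"))
  i1 <- triplet$images[[1]]; i2 <- triplet$images[[2]]; i3 <- triplet$images[[3]]
  ac <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i1 - i3)^2 + (i2 - i3)^2)
  dc <- (i1 + i2 + i3) / 3
  structure(list(ac = ac, dc = dc,
                 spatial_frequency = triplet$spatial_frequency,
                 wavelength = triplet$wavelength,
                 pixel_pitch = triplet$pixel_pitch),
            class = "siri_demod")
}

#' @export
print.siri_demod <- function(x, ...) {
  d <- dim(x$ac)
  cat(sprintf("<siri_demod> %d x %d px, f = %s cycle/mm, lambda = %s nm\n",
              d[1], d[2], format(x$spatial_frequency), format(x$wavelength)))
  cat(sprintf("  AC range [%.4f, %.4f], DC range [%.4f, %.4f]\n",
              min(x$ac), max(x$ac), min(x$dc), max(x$dc)))
  invisible(x)
}

#' Build the fruit foreground mask from the DC image
#'
#' The background of the scene is much darker than the fruit, so a fixed
#' global threshold on the DC image separates them: pixels whose DC level on
#' the 8-bit scale is strictly greater than `threshold` (default 15) form the
#' foreground.  The comparison is strict; the DC image (unit scale) is
#' quantized with round-half-up before comparing.
#'
#' @param demod a `siri_demod` (or a plain DC matrix in \[0,1\]).
#' @param threshold 8-bit intensity in \[0,255\].
#' @return an object of class `siri_mask`: list with `mask` (logical matrix)
#'   and `threshold_used`.
#' @export
create_background_mask <- function(demod, threshold = 15) {
  dc <- if (inherits(demod, "siri_demod")) demod$dc else demod
  check_gray(dc, "dc")
  if (threshold < 0 || threshold > 255)
    stop("threshold must be in [0, 255]", call. = FALSE)
  mask <- quantize8(dc) > threshold
  structure(list(mask = mask, threshold_used = threshold), class = "siri_mask")
}

#' @export
print.siri_mask <- function(x, ...) {
  cat(sprintf("<siri_mask> %d x %d px, %d foreground pixels (threshold %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), format(x$threshold_used)))
  invisible(x)
}

#' Zero out background pixels of an image
#'
#' @param image numeric matrix.
#' @param mask a `siri_mask` or logical matrix of the same shape.
#' @return the image with background pixels set to exactly 0.
#' @export
apply_mask <- function(image, mask) {
  m <- as_mask_matrix(mask)
  check_same_shape(image, m, "image/mask")
  image[!m] <- 0
  image
}
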