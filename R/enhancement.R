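# Enhancement of demodulated images: histogram equalization, AC/DC ratio
# image, and median filtering.

#' Histogram equalization over the foreground
#'
#' Global histogram equalization with 256 levels, computed from the masked
#' pixels only; background pixels stay 0.  The mapping is the (monotone)
#' empirical CDF of the quantized foreground intensities, so the weak
#' ordering of foreground pixels is preserved.
#'
#' @param image numeric matrix in \[0,1\].
#' @param mask a `siri_mask` or logical matrix; must select at least one pixel.
#' @return equalized image in \[0,1\], background 0.
#' @export
histogram_equalize <- function(image, mask) {
  m <- as_mask_matrix(mask)
  check_gray(image)
  check_same_shape(image, m, "image/mask")
  if (!any(m)) stop("empty mask", call. = FALSE)
  lv <- quantize8(image[m])
  counts <- tabulate(lv + 1L, nbins = 256L)
  cdf <- cumsum(counts) / sum(counts)
  # anchor the lowest occupied level at 0 (standard equalization convention)
  cdf_min <- cdf[which(counts > 0)[1]]
  map <- if (cdf_min < 1) (cdf - cdf_min) / (1 - cdf_min) else rep(1, 256)
  out <- image
  out[m] <- map[lv + 1L]
  out[!m] <- 0
  pmin(pmax(out, 0), 1)
}

#' Ratio image: AC divided by DC
#'
#' The AC image is divided pixelwise by the DC image inside the foreground.
#' Because multiplicative illumination non-uniformity (vignetting) affects AC
#' and DC identically, the ratio cancels it while retaining defect contrast.
#' Pixels where DC falls below `eps` (default one 8-bit quantum, 1/255) carry
#' no reliable signal; the ratio is set to 0 there and the guard counter in
#' the result records how many pixels were affected.
#'
#' @param demod a `siri_demod`.
#' @param mask a `siri_mask` or logical matrix.
#' @param eps division guard on the DC (unit) scale.
#' @param equalized use the histogram-equalized AC image as the numerator
#'   instead of the raw demodulated AC (default `FALSE`).
#' @return object of class `siri_ratio`: list with `rt` (matrix, 0 outside
#'   the mask, finite everywhere), `mask`, `n_guarded` (pixels hit by the
#'   division guard) and `eps`.
#' @export
ratio_image <- function(demod, mask, eps = 1 / 255, equalized = FALSE) {
  stopifnot(inherits(demod, "siri_demod"))
  m <- as_mask_matrix(mask)
  check_same_shape(demod$ac, m, "ac/mask")
  ac <- if (equalized) histogram_equalize(demod$ac, m) else demod$ac
  dc <- demod$dc
  ok <- m & dc > eps
  rt <- matrix(0, nrow(ac), ncol(ac))
  rt[ok] <- ac[ok] / dc[ok]
  structure(list(rt = rt, mask = mask, n_guarded = sum(m & !ok), eps = eps),
            class = "siri_ratio")
}

#' @export
print.siri_ratio <- function(x, ...) {
  cat(sprintf("<siri_ratio> %d x %d px, %d guarded pixels (eps = %.5f)\n",
              nrow(x$rt), ncol(x$rt), x$n_guarded, x$eps))
  invisible(x)
}

#' Sliding-window median filter
#'
#' Median filtering suppresses small dark-spot noise (surface pits, stem and
#' suture marks) while preserving the extended bruise region.  Edges are
#' handled by reflect padding.  For an even window dimension the output pixel
#' sits at position (ceil(h/2), ceil(w/2)) inside the window, and the median
#' of the even-sized sample is taken as the upper-middle order statistic so
#' that output values always come from the input value set.
#'
#' @param image numeric matrix.
#' @param window window size in pixels; a single number or c(height, width).
#'   Default 10 x 10.
#' @param mask optional `siri_mask` or logical matrix.  When supplied, the
#'   window sample at each foreground pixel is restricted to foreground
#'   pixels, so the zeroed background can never contaminate medians near the
#'   fruit boundary; background pixels are returned as 0.
#' @return filtered matrix, same shape.
#' @export
median_filter <- function(image, window = c(10, 10), mask = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  window <- rep(as.integer(window), length.out = 2)
  if (any(window < 1)) stop("window dimensions must be >= 1", call. = FALSE)
  if (window[1] > nrow(image) || window[2] > ncol(image))
    stop("window larger than image", call. = FALSE)
  if (is.null(mask)) return(median_filter_cpp(image, window[1], window[2]))
  m <- as_mask_matrix(mask)
  check_same_shape(image, m, "image/mask")
  if (!any(m)) stop("empty mask", call. = FALSE)
  median_filter_masked_cpp(image, m, window[1], window[2])
}
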