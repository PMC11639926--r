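# Threshold segmentation of enhanced images into bruised vs normal tissue:
# global thresholding, Otsu's between-class-variance criterion, and an
# improved Otsu objective robust to dark-spot noise, followed by
# connected-component cleanup and sample-level classification.

#' Grey-level histogram over the foreground
#'
#' Quantizes the masked pixels to 256 grey levels (round-half-up) and counts
#' them.  Histograms are built over foreground pixels only: the zeroed
#' background would otherwise dominate bin 0 and every threshold would merely
#' re-separate background from fruit.
#'
#' @param image numeric matrix in \[0,1\].
#' @param mask a `siri_mask` or logical matrix; must select at least one pixel.
#' @return object of class `siri_hist`: list with `counts` (integer vector of
#'   length 256 for levels 0..255) and `n_pixels`.
#' @export
masked_histogram <- function(image, mask) {
  m <- as_mask_matrix(mask)
  check_same_shape(image, m, "image/mask")
  if (!any(m)) stop("empty mask", call. = FALSE)
  lv <- quantize8(image[m])
  counts <- tabulate(lv + 1L, nbins = 256L)
  structure(list(counts = counts, n_pixels = sum(counts)), class = "siri_hist")
}

#' @export
print.siri_hist <- function(x, ...) {
  occ <- which(x$counts > 0) - 1L
  cat(sprintf("<siri_hist> %d pixels over levels %d..%d (%d occupied)\n",
              x$n_pixels, min(occ), max(occ), length(occ)))
  invisible(x)
}

as_siri_hist <- function(hist) {
  if (inherits(hist, "siri_hist")) return(hist)
  if (is.numeric(hist) && length(hist) == 256)
    return(structure(list(counts = as.integer(hist), n_pixels = sum(hist)),
                     class = "siri_hist"))
  stop("expected a 'siri_hist' or a length-256 count vector", call. = FALSE)
}

#' Two-class statistics of a histogram split at a threshold
#'
#' Splits the grey levels at `T` into class C0 (levels <= T) and C1
#' (levels > T) and returns the class probabilities, means and variances plus
#' the global mean.  By construction the global mean always decomposes as
#' `mu = p0*mu0 + p1*mu1` when both classes are non-empty.  An empty class
#' has probability 0 and `NA` mean/variance.
#'
#' @param hist a `siri_hist` (or length-256 count vector).
#' @param T threshold level in 0..255.
#' @return list with `T`, `p0`, `p1`, `mu0`, `mu1`, `var0`, `var1`, `mu`.
#' @export
class_split <- function(hist, T) {
  h <- as_siri_hist(hist)
  if (T < 0 || T > 255) stop("T must be in [0, 255]", call. = FALSE)
  lev <- 0:255
  in0 <- lev <= T
  n0 <- sum(h$counts[in0]); n1 <- h$n_pixels - n0
  p0 <- n0 / h$n_pixels; p1 <- n1 / h$n_pixels
  mu <- sum(h$counts * lev) / h$n_pixels
  stat <- function(sel, nsel) {
    if (nsel == 0) return(c(NA_real_, NA_real_))
    m <- sum(h$counts[sel] * lev[sel]) / nsel
    v <- sum(h$counts[sel] * (lev[sel] - m)^2) / nsel
    c(m, v)
  }
  s0 <- stat(in0, n0); s1 <- stat(!in0, n1)
  list(T = as.integer(T), p0 = p0, p1 = p1,
       mu0 = s0[1], mu1 = s1[1], var0 = s0[2], var1 = s1[2], mu = mu)
}

# Vectorized class statistics for all 256 candidate thresholds.
# Returns a list of vectors indexed by T = 0..255; entries where a class is
# empty are NA.
all_splits <- function(h) {
  lev <- 0:255
  n <- h$n_pixels
  N0 <- cumsum(h$counts)          # integer cumulative counts: exact
  S0 <- cumsum(h$counts * lev)
  mu <- S0[256] / n
  nonempty0 <- N0 > 0
  nonempty1 <- N0 < n
  p0 <- N0 / n
  p1 <- (n - N0) / n
  mu0 <- ifelse(nonempty0, S0 / N0, NA_real_)
  mu1 <- ifelse(nonempty1, (S0[256] - S0) / (n - N0), NA_real_)
  list(p0 = p0, p1 = p1, mu0 = mu0, mu1 = mu1, mu = mu,
       valid = nonempty0 & nonempty1)
}

# shared scaffolding for the two automatic threshold selectors
select_threshold <- function(hist, objective_fn) {
  h <- as_siri_hist(hist)
  if (sum(h$counts > 0) < 2)
    stop("degenerate histogram: fewer than 2 occupied levels", call. = FALSE)
  s <- all_splits(h)
  obj <- objective_fn(s)
  # candidates with an empty class are excluded from the argmax
  obj[!s$valid] <- NA_real_
  T <- which.max(ifelse(s$valid, obj, -Inf)) - 1L  # smallest maximizer on ties
  list(threshold = T, objective = obj)
}

#' Otsu's automatic threshold
#'
#' Selects the threshold maximizing the between-class variance
#' `p0*p1*(mu0 - mu1)^2`, equivalently minimizing the within-class variance
#' `p0*var0 + p1*var1`.  Candidates that leave one class empty are excluded;
#' the smallest maximizing level is returned on ties.
#'
#' @param hist a `siri_hist` (or length-256 count vector) with at least two
#'   occupied levels.
#' @return list with `threshold` (level in 0..255) and `objective` (the
#'   between-class variance at each candidate level, `NA` where invalid).
#' @export
otsu_threshold <- function(hist) {
  select_threshold(hist, function(s) s$p0 * s$p1 * (s$mu0 - s$mu1)^2)
}

#' Improved Otsu threshold (robust to dark-spot noise)
#'
#' Augments Otsu's between-class variance with the squared distances of each
#' class mean from the global mean:
#' `p0*p1*(mu0-mu1)^2 + (mu0-mu)^2 + (mu1-mu)^2`.
#' The extra terms penalize splits whose class means sit close to the global
#' mean, balancing the weight of each class and reducing the
#' over-segmentation that plain Otsu produces when small dark spots (surface
#' pits, stems, sutures) perturb an otherwise unimodal foreground.
#' Substituting the mean decomposition `mu = p0*mu0 + p1*mu1` shows the
#' objective equals `(mu0-mu1)^2 * (1 - p0*p1)`.
#'
#' @inheritParams otsu_threshold
#' @return list with `threshold` and `objective` as in [otsu_threshold()].
#' @export
improved_otsu_threshold <- function(hist) {
  select_threshold(hist, function(s)
    s$p0 * s$p1 * (s$mu0 - s$mu1)^2 + (s$mu0 - s$mu)^2 + (s$mu1 - s$mu)^2)
}

#' Threshold an image into a candidate bruise mask
#'
#' Bruised tissue appears dark in AC and ratio images, so with the default
#' polarity `"below"` the candidate bruise pixels are the foreground pixels
#' whose quantized level is `<= T`.
#'
#' @param image numeric matrix in \[0,1\].
#' @param mask a `siri_mask` or logical matrix (foreground).
#' @param T threshold level in 0..255.
#' @param polarity `"below"` (bruise = dark, default) or `"above"`.
#' @param method label stored in the result (for provenance).
#' @param objective optional objective curve to carry along.
#' @return object of class `siri_seg`: list with `method`, `threshold`,
#'   `bruise_mask` (logical matrix, subset of the foreground), `polarity`,
#'   `objective`.
#' @export
apply_threshold <- function(image, mask, T, polarity = c("below", "above"),
                            method = "global", objective = NULL) {
  polarity <- match.arg(polarity)
  m <- as_mask_matrix(mask)
  check_same_shape(image, m, "image/mask")
  if (T < 0 || T > 255) stop("T must be in [0, 255]", call. = FALSE)
  lv <- quantize8(image)
  sel <- if (polarity == "below") lv <= T else lv > T
  structure(list(method = method, threshold = as.integer(T),
                 bruise_mask = m & sel, polarity = polarity,
                 objective = objective),
            class = "siri_seg")
}

#' @export
print.siri_seg <- function(x, ...) {
  cat(sprintf("<siri_seg> method %s, threshold %d (%s), %d bruise-candidate px\n",
              x$method, x$threshold, x$polarity, sum(x$bruise_mask)))
  invisible(x)
}

#' Segment with a fixed global threshold
#'
#' @inheritParams apply_threshold
#' @param T_fixed user-chosen threshold level in 0..255.
#' @return a `siri_seg` (see [apply_threshold()]).
#' @export
global_threshold_segment <- function(image, mask, T_fixed,
                                     polarity = c("below", "above")) {
  apply_threshold(image, mask, T_fixed, polarity = match.arg(polarity),
                  method = "global")
}

#' Segment with an automatic threshold (Otsu or improved Otsu)
#'
#' Builds the foreground histogram, selects the threshold with the requested
#' criterion and applies it.
#'
#' @inheritParams apply_threshold
#' @param method `"otsu"` or `"iotsu"`.
#' @param min_contrast degenerate-histogram guard: if the class means at the
#'   selected threshold are separated by fewer than `min_contrast` grey
#'   levels, the foreground is a single population whose "split" is mere
#'   quantization ripple, and an empty defect mask is returned (the selected
#'   threshold is still reported).  Default 2 levels.
#' @return a `siri_seg` carrying the selected threshold and objective curve.
#' @export
auto_threshold_segment <- function(image, mask, method = c("iotsu", "otsu"),
                                   polarity = c("below", "above"),
                                   min_contrast = 2) {
  method <- match.arg(method)
  h <- masked_histogram(image, mask)
  sel <- if (method == "otsu") otsu_threshold(h) else improved_otsu_threshold(h)
  seg <- apply_threshold(image, mask, sel$threshold,
                         polarity = match.arg(polarity),
                         method = method, objective = sel$objective)
  cs <- class_split(h, sel$threshold)
  if (is.finite(cs$mu0) && is.finite(cs$mu1) &&
      abs(cs$mu1 - cs$mu0) < min_contrast) {
    seg$bruise_mask <- seg$bruise_mask & FALSE
    seg$degenerate <- TRUE
  }
  seg
}

#' Remove small connected components from a segmentation
#'
#' Bruise candidates produced by thresholding include small scattered
#' false-positive blobs (sensor noise, residual dark spots).  Connected
#' regions whose pixel count (area) is below `min_area` are removed;
#' components with area exactly `min_area` are retained.
#'
#' @param seg a `siri_seg`.
#' @param min_area minimum surviving component area in pixels (default 50).
#' @param connectivity 4 or 8 (default 8).
#' @return the `siri_seg` with small components removed and a `components`
#'   element: data.frame of surviving components (area, centroid_row,
#'   centroid_col).
#' @export
remove_small_components <- function(seg, min_area = 50, connectivity = 8) {
  stopifnot(inherits(seg, "siri_seg"))
  if (min_area < 0) stop("min_area must be >= 0", call. = FALSE)
  lab <- label_components_cpp(seg$bruise_mask, as.integer(connectivity))
  comps <- data.frame(area = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_area)
    keep_mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    seg$bruise_mask <- keep_mask
    if (length(keep)) {
      idx <- which(keep_mask, arr.ind = TRUE)
      l <- lab[keep_mask]
      comps <- data.frame(
        area = areas[keep],
        centroid_row = vapply(keep, function(k) mean(idx[l == k, 1]), 0),
        centroid_col = vapply(keep, function(k) mean(idx[l == k, 2]), 0))
    }
  } else {
    seg$bruise_mask <- seg$bruise_mask & FALSE
  }
  seg$components <- comps
  seg$min_area <- min_area
  seg$connectivity <- connectivity
  seg
}

#' Classify a sample as bruised or normal
#'
#' After small-component removal, any surviving non-zero pixel marks the
#' sample as bruised; an empty cleaned mask means normal.
#'
#' @param seg a `siri_seg`, normally after [remove_small_components()].
#' @return object of class `siri_class`: list with `label` ("normal" or
#'   "bruised"), `surviving_pixels`, and `components` (data.frame).
#' @export
classify_sample <- function(seg) {
  stopifnot(inherits(seg, "siri_seg"))
  n <- sum(seg$bruise_mask)
  comps <- seg$components
  if (is.null(comps)) {
    comps <- data.frame(area = integer(0), centroid_row = numeric(0),
                        centroid_col = numeric(0))
  }
  structure(list(label = if (n > 0) "bruised" else "normal",
                 surviving_pixels = n, components = comps),
            class = "siri_class")
}

#' @export
print.siri_class <- function(x, ...) {
  cat(sprintf("<siri_class> %s (%d surviving px in %d components)\n",
              x$label, x$surviving_pixels, nrow(x$components)))
  invisible(x)
}
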