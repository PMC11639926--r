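# End-to-end pipeline (calibrate -> demodulate -> mask -> enhance ->
# segment -> clean -> classify) and accuracy evaluation against known labels.

#' Pipeline configuration
#'
#' One object holds every stage parameter of the bruise-detection chain so a
#' run is fully reproducible from its config.
#'
#' @param image_style `"RT"` (ratio image, default) or `"AC"`.
#' @param mask_threshold 8-bit DC threshold for the fruit foreground mask.
#' @param equalize histogram-equalize the AC image before segmenting (only
#'   used for `image_style = "AC"`; the ratio image consumes the raw
#'   demodulated AC).
#' @param median_window median filter window, c(height, width); `NULL`
#'   disables filtering.
#' @param method `"iotsu"`, `"otsu"` or `"global"`.
#' @param fixed_t threshold level for `method = "global"`.
#' @param polarity `"below"` (bruise = dark, default) or `"above"`.
#' @param min_area minimum connected-component area kept, px.
#' @param connectivity 4 or 8.
#' @param eps division guard for the ratio image.
#' @param min_contrast degenerate-histogram guard for the automatic
#'   thresholds, in grey levels (see [auto_threshold_segment()]).
#' @return list of class `siri_config`.
#' @export
siri_config <- function(image_style = c("RT", "AC"),
                        mask_threshold = 15,
                        equalize = TRUE,
                        median_window = c(10, 10),
                        method = c("iotsu", "otsu", "global"),
                        fixed_t = 40,
                        polarity = c("below", "above"),
                        min_area = 50,
                        connectivity = 8,
                        eps = 1 / 255,
                        min_contrast = 2) {
  structure(list(image_style = match.arg(image_style),
                 mask_threshold = mask_threshold,
                 equalize = equalize,
                 median_window = median_window,
                 method = match.arg(method),
                 fixed_t = fixed_t,
                 polarity = match.arg(polarity),
                 min_area = min_area,
                 connectivity = connectivity,
                 eps = eps,
                 min_contrast = min_contrast),
            class = "siri_config")
}

#' Run the full bruise-detection pipeline on one sample
#'
#' Stages: reference calibration (if references are given), three-phase
#' demodulation, DC-based foreground masking, enhancement (equalized AC or
#' rescaled ratio image per config), median filtering, threshold
#' segmentation, small-component removal, and sample classification.
#'
#' @param sample a `phantom_sample`, or a `siri_triplet`.
#' @param config a [siri_config()].
#' @param white,black optional reference images when `sample` is a triplet
#'   (a `phantom_sample` carries its own).
#' @param keep_intermediates return the intermediate images as well.
#' @return object of class `siri_run`: list with `classification`
#'   (a `siri_class`), `segmentation` (a `siri_seg`), `config`, and -- if
#'   requested -- `intermediates` (demod, mask, enhanced image).
#' @export
run_pipeline <- function(sample, config = siri_config(), white = NULL,
                         black = NULL, keep_intermediates = FALSE) {
  if (inherits(sample, "phantom_sample")) {
    triplet <- sample$triplet
    if (is.null(white)) white <- sample$white
    if (is.null(black)) black <- sample$black
  } else if (inherits(sample, "siri_triplet")) {
    triplet <- sample
  } else stop("sample must be a 'phantom_sample' or 'siri_triplet'", call. = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(white) && !is.null(black))
    triplet <- stage("calibration", correct_triplet(triplet, white, black))
  demod <- stage("demodulation", demodulate_three_phase(triplet))
  mask <- stage("masking", create_background_mask(demod, config$mask_threshold))

  enhanced <- stage("enhancement", {
    if (config$image_style == "RT") {
      rt <- ratio_image(demod, mask, eps = config$eps)
      # AC/DC is a modulation ratio, physically in [0, 1] up to noise; clip
      # to that fixed range rather than min-max stretching per sample, so
      # grey levels are comparable across samples and noise is not amplified
      # by a sample-dependent factor
      pmin(rt$rt, 1)
    } else {
      ac <- if (config$equalize) histogram_equalize(demod$ac, mask)
            else rescale_unit(apply_mask(demod$ac, mask), mask)$image
      apply_mask(ac, mask)
    }
  })
  if (!is.null(config$median_window))
    enhanced <- stage("median_filter",
                      median_filter(enhanced, config$median_window, mask = mask))

  seg <- stage("segmentation", {
    if (config$method == "global")
      global_threshold_segment(enhanced, mask, config$fixed_t,
                               polarity = config$polarity)
    else
      auto_threshold_segment(enhanced, mask, method = config$method,
                             polarity = config$polarity,
                             min_contrast = config$min_contrast)
  })
  seg <- stage("component_cleanup",
               remove_small_components(seg, config$min_area,
                                       config$connectivity))
  cls <- stage("classification", classify_sample(seg))

  out <- list(classification = cls, segmentation = seg, config = config)
  if (keep_intermediates)
    out$intermediates <- list(demod = demod, mask = mask, enhanced = enhanced)
  structure(out, class = "siri_run")
}

#' @export
print.siri_run <- function(x, ...) {
  cat(sprintf("<siri_run> %s/%s -> %s (threshold %d, %d surviving px)\n",
              x$config$method, x$config$image_style, x$classification$label,
              x$segmentation$threshold, x$classification$surviving_pixels))
  invisible(x)
}

#' Evaluate predicted labels against ground truth
#'
#' Builds the per-set, per-class accuracy table used to compare segmentation
#' variants: for each set (training/testing) and each sample class
#' (normal/bruised) the number of correctly and wrongly classified samples
#' and the accuracy in percent, plus per-class totals pooled over both sets
#' and the grand total accuracy over all samples.
#'
#' @param predictions,truth character vectors of `"normal"` / `"bruised"`
#'   labels, same length.
#' @param split character vector assigning each sample to `"training"` or
#'   `"testing"`; default puts everything in one `"testing"` set.
#' @return object of class `siri_report`: list with `by_set_class`
#'   (data.frame: set, class, n, correct, wrong, accuracy), `by_class`
#'   (data.frame: class, n, correct, accuracy), `total_accuracy`, `n`.
#'   Accuracies are exact percentages; the print method rounds half-up to
#'   one decimal.
#' @export
evaluate <- function(predictions, truth, split = NULL) {
  if (length(predictions) != length(truth))
    stop("predictions and truth have different lengths", call. = FALSE)
  bad <- setdiff(unique(c(predictions, truth)), c("normal", "bruised"))
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(split)) split <- rep("testing", length(truth))
  if (length(split) != length(truth))
    stop("split has wrong length", call. = FALSE)

  cell <- function(sel) {
    n <- sum(sel)
    correct <- sum(predictions[sel] == truth[sel])
    c(n = n, correct = correct, wrong = n - correct,
      accuracy = if (n > 0) 100 * correct / n else NA_real_)
  }
  sets <- intersect(c("training", "testing"), unique(split))
  classes <- intersect(c("normal", "bruised"), unique(truth))
  by_set_class <- do.call(rbind, lapply(sets, function(s) {
    do.call(rbind, lapply(classes, function(cl) {
      stats <- cell(split == s & truth == cl)
      data.frame(set = s, class = cl, n = stats["n"], correct = stats["correct"],
                 wrong = stats["wrong"], accuracy = stats["accuracy"],
                 row.names = NULL)
    }))
  }))
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    stats <- cell(truth == cl)
    data.frame(class = cl, n = stats["n"], correct = stats["correct"],
               accuracy = stats["accuracy"], row.names = NULL)
  }))
  structure(list(by_set_class = by_set_class, by_class = by_class,
                 total_accuracy = 100 * sum(predictions == truth) / length(truth),
                 n = length(truth)),
            class = "siri_report")
}

# round half up to `digits` decimals (R's round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.siri_report <- function(x, ...) {
  cat(sprintf("<siri_report> %d samples, total accuracy %.1f%%\n\n",
              x$n, round_half_up(x$total_accuracy)))
  df <- x$by_set_class
  df$accuracy <- sprintf("%.1f", round_half_up(df$accuracy))
  print(df, row.names = FALSE)
  cat("\nper-class totals:\n")
  dc <- x$by_class
  dc$accuracy <- sprintf("%.1f", round_half_up(dc$accuracy))
  print(dc, row.names = FALSE)
  invisible(x)
}

#' Classify a dataset and evaluate against its ground truth
#'
#' Convenience wrapper: runs the pipeline on every sample of a phantom
#' dataset and evaluates the predicted labels against the simulator's
#' ground-truth labels.
#'
#' @param samples list of `phantom_sample` (see [generate_dataset()]).
#' @param config a [siri_config()].
#' @param split optional set assignment (see [evaluate()]).
#' @return list with `report` (a `siri_report`) and `predictions`.
#' @export
evaluate_pipeline <- function(samples, config = siri_config(), split = NULL) {
  predictions <- vapply(samples, function(s)
    run_pipeline(s, config)$classification$label, "")
  truth <- vapply(samples, function(s) s$label, "")
  list(report = evaluate(predictions, truth, split), predictions = predictions)
}
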