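test_that("masked histogram counts quantized foreground pixels", {
  m <- matrix(TRUE, 10, 10)
  h <- masked_histogram(matrix(0.5, 10, 10), m)
  expect_equal(which(h$counts > 0) - 1L, 128L)
  expect_equal(h$n_pixels, 100L)

  img <- matrix(rep(c(0, 1), each = 50), 10, 10)
  h2 <- masked_histogram(img, m)
  expect_equal(h2$counts[c(1, 256)], c(50L, 50L))

  set.seed(2)
  m3 <- matrix(runif(100) > 0.4, 10, 10)
  h3 <- masked_histogram(matrix(runif(100), 10, 10), m3)
  expect_equal(h3$n_pixels, sum(m3))
  expect_error(masked_histogram(img, m & FALSE), "empty mask")
})

test_that("class split statistics satisfy the mean decomposition", {
  counts <- integer(256); counts[c(51, 201)] <- 40L  # levels 50 and 200
  s <- class_split(counts, 100)
  expect_equal(s$p0, 0.5); expect_equal(s$p1, 0.5)
  expect_equal(s$mu0, 50); expect_equal(s$mu1, 200)

  # boundary: everything in class 0
  sb <- class_split(counts, 255)
  expect_equal(sb$p1, 0)
  expect_equal(sb$mu0, sb$mu)
  expect_true(is.na(sb$mu1))

  # mu = p0*mu0 + p1*mu1 on arbitrary histograms and thresholds
  set.seed(13)
  for (i in 1:25) {
    cts <- random_histogram()
    T <- sample(0:255, 1)
    s <- class_split(cts, T)
    o <- oracle_split(cts, T)
    expect_equal(s$mu0, o$mu0); expect_equal(s$var1, o$var1)
    if (s$p0 > 0 && s$p1 > 0)
      expect_equal(s$p0 * s$mu0 + s$p1 * s$mu1, s$mu, tolerance = 1e-12)
  }
})

test_that("Otsu threshold equals the exhaustive scan and its dual form", {
  # two-level histogram: all T between the levels tie; smallest returned
  counts <- integer(256); counts[c(51, 201)] <- 10L
  expect_equal(otsu_threshold(counts)$threshold, 50L)

  set.seed(17)
  for (i in 1:100) {
    cts <- random_histogram()
    T <- otsu_threshold(cts)$threshold
    expect_equal(T, oracle_otsu_max(cts))
    # minimizing within-class variance selects the same threshold
    expect_equal(T, oracle_otsu_min(cts))
  }
})

test_that("improved Otsu equals its closed form and the exhaustive scan", {
  set.seed(19)
  for (i in 1:100) {
    cts <- random_histogram()
    sel <- improved_otsu_threshold(cts)
    expect_equal(sel$threshold, oracle_iotsu(cts))
    # printed objective == (mu0 - mu1)^2 * (1 - p0 p1) at sampled valid T
    valid_T <- which(!is.na(sel$objective)) - 1L
    for (T in sample(valid_T, min(8, length(valid_T)))) {
      s <- oracle_split(cts, T)
      expect_equal(sel$objective[T + 1],
                   (s$mu0 - s$mu1)^2 * (1 - s$p0 * s$p1), tolerance = 1e-9)
    }
  }

  # two-level histogram admits a single nontrivial partition: same as Otsu
  counts <- integer(256); counts[c(51, 201)] <- 10L
  expect_equal(improved_otsu_threshold(counts)$threshold,
               otsu_threshold(counts)$threshold)

  single <- integer(256); single[100] <- 5L
  expect_error(otsu_threshold(single), "degenerate")
  expect_error(improved_otsu_threshold(single), "degenerate")
})

test_that("threshold selection is shift-invariant where no clipping occurs", {
  set.seed(23)
  for (i in 1:20) {
    cts <- random_histogram(max_levels = 200)
    shift <- sample(1:50, 1)
    shifted <- integer(256)
    shifted[(which(cts > 0) - 1L + shift) + 1L] <- cts[cts > 0]
    expect_equal(otsu_threshold(shifted)$threshold,
                 otsu_threshold(cts)$threshold + shift)
    expect_equal(improved_otsu_threshold(shifted)$threshold,
                 improved_otsu_threshold(cts)$threshold + shift)
  }
})

test_that("thresholding polarity and global segmentation behave at bounds", {
  set.seed(29)
  img <- matrix(runif(100, 0.2, 0.9), 10, 10)
  m <- matrix(TRUE, 10, 10); m[1, ] <- FALSE

  expect_equal(apply_threshold(img, m, 255)$bruise_mask, m)
  expect_equal(sum(apply_threshold(img, m, 0)$bruise_mask), 0)

  # above polarity is the complement within the mask
  lo <- apply_threshold(img, m, 128, "below")$bruise_mask
  hi <- apply_threshold(img, m, 128, "above")$bruise_mask
  expect_equal(lo | hi, m)
  expect_false(any(lo & hi))

  # fixed threshold equal to Otsu's reproduces the Otsu mask
  h <- masked_histogram(img, m)
  T <- otsu_threshold(h)$threshold
  expect_equal(global_threshold_segment(img, m, T)$bruise_mask,
               auto_threshold_segment(img, m, "otsu")$bruise_mask)

  # area is monotone nondecreasing in the fixed threshold
  areas <- vapply(seq(0, 255, by = 15), function(t)
    sum(global_threshold_segment(img, m, t)$bruise_mask), 0L)
  expect_true(all(diff(areas) >= 0))
})

test_that("small-component removal agrees with a flood-fill oracle", {
  set.seed(37)
  for (conn in c(4, 8)) {
    mask <- matrix(runif(40 * 40) < 0.35, 40, 40)
    seg <- structure(list(method = "global", threshold = 0L,
                          bruise_mask = mask, polarity = "below",
                          objective = NULL), class = "siri_seg")
    out <- remove_small_components(seg, min_area = 50, connectivity = conn)
    lab <- oracle_label(mask, conn)
    areas <- tabulate(lab[lab > 0])
    expected <- matrix(FALSE, 40, 40)
    for (k in which(areas >= 50)) expected <- expected | (lab == k)
    expect_equal(out$bruise_mask, expected, info = paste("conn", conn))
    expect_true(all(out$components$area >= 50))
  }
})

test_that("component removal boundary convention and antitone behaviour", {
  mask <- matrix(FALSE, 12, 12)
  mask[3:5, 3:6] <- TRUE  # one component of exactly 12 pixels
  seg <- structure(list(method = "global", threshold = 0L, bruise_mask = mask,
                        polarity = "below", objective = NULL),
                   class = "siri_seg")
  expect_equal(sum(remove_small_components(seg, 12)$bruise_mask), 12)
  expect_equal(sum(remove_small_components(seg, 13)$bruise_mask), 0)

  empty <- seg; empty$bruise_mask <- mask & FALSE
  expect_equal(sum(remove_small_components(empty, 1)$bruise_mask), 0)

  set.seed(41)
  rnd <- matrix(runif(900) < 0.4, 30, 30)
  segr <- seg; segr$bruise_mask <- rnd
  sizes <- vapply(c(0, 5, 20, 60, 200), function(a)
    sum(remove_small_components(segr, a)$bruise_mask), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("sample classification follows surviving pixels", {
  mask <- matrix(FALSE, 10, 10)
  seg <- structure(list(method = "iotsu", threshold = 10L, bruise_mask = mask,
                        polarity = "below", objective = NULL),
                   class = "siri_seg")
  expect_equal(classify_sample(remove_small_components(seg, 5))$label, "normal")

  mask[4:8, 4:8] <- TRUE
  seg$bruise_mask <- mask
  cls <- classify_sample(remove_small_components(seg, 5))
  expect_equal(cls$label, "bruised")
  expect_equal(cls$surviving_pixels, 25L)
  expect_equal(nrow(cls$components), 1L)
})
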