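test_that("reference calibration implements (R0 - B) / (W - B)", {
  w <- matrix(210 / 255, 8, 8)
  b <- matrix(10 / 255, 8, 8)

  # flat-field identity: raw equal to white, black zero
  expect_equal(correct_reference(w, w, matrix(0, 8, 8)),
               matrix(1, 8, 8), ignore_attr = TRUE)
  # dark-frame cancellation
  expect_equal(correct_reference(b, w, b), matrix(0, 8, 8),
               ignore_attr = TRUE)
  # direct arithmetic on the 8-bit example values
  out <- correct_reference(matrix(120 / 255, 8, 8), w, b)
  expect_equal(out[1, 1], (120 - 10) / (210 - 10))

  # idempotence against trivial references
  r <- matrix(runif(64), 8, 8)
  expect_equal(correct_reference(r, matrix(1, 8, 8), matrix(0, 8, 8)), r,
               ignore_attr = TRUE)
})

test_that("invalid reference pixels are zeroed and counted, errors propagate", {
  w <- matrix(0.8, 4, 4); b <- matrix(0.1, 4, 4)
  w[2, 3] <- 0.05  # white below black at one pixel
  out <- correct_reference(matrix(0.5, 4, 4), w, b)
  expect_equal(out[2, 3], 0)
  expect_equal(attr(out, "invalid_pixels"), 1L)

  expect_error(correct_reference(matrix(0.5, 4, 5), w, b), "shape")
  expect_error(correct_reference(matrix(0.5, 4, 4), matrix(0.1, 4, 4),
                                 matrix(0.8, 4, 4)), "invalid")
})

test_that("three-phase demodulation recovers amplitude and offset exactly", {
  # constant input: zero amplitude
  c04 <- matrix(0.4, 6, 6)
  d <- demodulate_three_phase(siri_triplet(c04, c04, c04))
  expect_equal(d$ac, matrix(0, 6, 6))
  expect_equal(d$dc, c04)

  # ideal sinusoid at 120-degree offsets: ac = amplitude, dc = offset,
  # whatever the global phase
  th <- c(-2 * pi / 3, 0, 2 * pi / 3)
  for (phi in seq(0, 2 * pi, length.out = 13)) {
    imgs <- lapply(th, function(t) matrix(0.5 + 0.25 * cos(phi + t), 5, 5))
    d <- demodulate_three_phase(siri_triplet(imgs[[1]], imgs[[2]], imgs[[3]]))
    expect_equal(d$ac, matrix(0.25, 5, 5), tolerance = 1e-12)
    expect_equal(d$dc, matrix(0.5, 5, 5), tolerance = 1e-12)
  }
})

test_that("demodulation matches a scalar evaluation of the formulas", {
  set.seed(101)
  i1 <- matrix(runif(256), 16, 16)
  i2 <- matrix(runif(256), 16, 16)
  i3 <- matrix(runif(256), 16, 16)
  d <- demodulate_three_phase(siri_triplet(i1, i2, i3))
  for (k in sample(256, 40)) {
    a <- sqrt(2) / 3 *
      sqrt((i1[k] - i2[k])^2 + (i1[k] - i3[k])^2 + (i2[k] - i3[k])^2)
    expect_equal(d$ac[k], a, tolerance = 1e-12)
    expect_equal(d$dc[k], (i1[k] + i2[k] + i3[k]) / 3, tolerance = 1e-12)
  }
  expect_true(all(d$ac >= 0))
})

test_that("demodulated AC and DC are invariant to phase-image permutation", {
  set.seed(7)
  imgs <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
  ref <- demodulate_three_phase(siri_triplet(imgs[[1]], imgs[[2]], imgs[[3]]))
  perms <- list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  for (p in perms) {
    d <- demodulate_three_phase(siri_triplet(imgs[[p[1]]], imgs[[p[2]]], imgs[[p[3]]]))
    expect_equal(d$ac, ref$ac, tolerance = 1e-12)
    expect_equal(d$dc, ref$dc, tolerance = 1e-12)
  }
})

test_that("background mask thresholds the DC image on the 8-bit scale", {
  z <- matrix(0, 10, 10)
  expect_false(any(create_background_mask(z)$mask))
  expect_true(all(create_background_mask(matrix(1, 10, 10))$mask))

  # strict comparison: level exactly 15 is background
  at15 <- matrix(15 / 255, 4, 4)
  expect_false(any(create_background_mask(at15)$mask))
  expect_true(all(create_background_mask(matrix(16 / 255, 4, 4))$mask))
})

test_that("phantom DC mask recovers the disc to within a 2-px boundary band", {
  s <- render_phantom(phantom_spec(seed = 5), 0.10, 700)
  d <- demodulate_three_phase(correct_triplet(s$triplet, s$white, s$black))
  m <- create_background_mask(d)$mask
  # band: pixels within 2 px of the disc boundary are excused
  spec <- s$spec
  h <- spec$image_size[1]; w <- spec$image_size[2]
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt((rows - spec$disc_center[1])^2 + (cols - spec$disc_center[2])^2)
  core <- abs(r - spec$disc_radius) > 2
  expect_gte(mean(m[core] == s$truth_disc[core]), 0.99)
})

test_that("apply_mask zeroes exactly the background", {
  img <- matrix(runif(36), 6, 6)
  all_true <- matrix(TRUE, 6, 6)
  expect_equal(apply_mask(img, all_true), img)
  expect_equal(apply_mask(img, !all_true), matrix(0, 6, 6))
  chk <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  out <- apply_mask(matrix(1, 6, 6), chk)
  expect_equal(sum(out == 0), 18)
  expect_error(apply_mask(img, matrix(TRUE, 5, 6)), "shape")
})
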