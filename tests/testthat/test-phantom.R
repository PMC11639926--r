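test_that("impact energy follows E = m g h", {
  # the bruising protocol: 100 g ball dropped from 400 mm
  e <- impact_energy(0.1, 0.4)
  expect_equal(round(e, 1), 0.4)
  expect_equal(e, 0.1 * 9.8 * 0.4)

  expect_equal(impact_energy(0.1, 0), 0)
  expect_equal(impact_energy(0.1, 0.8), 2 * e)  # linear in height
  expect_error(impact_energy(-0.1, 0.4), ">= 0")
})

test_that("modulation depth decays exponentially in frequency", {
  spec <- phantom_spec()
  for (wl in c(700, 750, 800)) {
    expect_equal(modulation_depth(spec, 0, wl),
                 spec$modulation_depth0 * unname(spec$wavelength_gain[as.character(wl)]))
    fs <- c(0.05, 0.10, 0.15, 0.20)
    d <- vapply(fs, function(f) modulation_depth(spec, f, wl), 0)
    expect_true(all(diff(d) < 0))
    # direct formula evaluation
    expect_equal(d, spec$modulation_depth0 *
                   unname(spec$wavelength_gain[as.character(wl)]) *
                   exp(-fs * unname(spec$freq_decay[as.character(wl)])))
  }
  expect_error(modulation_depth(spec, 0.1, 650), "unknown wavelength")
})

test_that("noiseless defect-free phantom demodulates to its closed form", {
  spec <- phantom_spec(vignette_strength = 0, noise_sigma = 0,
                       n_dark_spots = 0, texture_amp = 0, seed = 1)
  s <- render_phantom(spec, 0.10, 700)
  d <- demodulate_three_phase(correct_triplet(s$triplet, s$white, s$black))
  core <- s$truth_disc
  # stay clear of the disc boundary (partial pixels)
  core[c(1:2, 127:128), ] <- FALSE

  white_lvl <- round(0.98 * 255) / 255
  dc_expect <- spec$dc_reflectance / white_lvl
  expect_lt(max(abs(d$dc[core] - dc_expect)), 2 / 255)

  depth <- modulation_depth(spec, 0.10, 700)
  rt <- d$ac[core] / d$dc[core]
  expect_lt(max(abs(rt - depth)), 0.02)
})

test_that("rendering is deterministic in the seed", {
  spec <- tiny_spec(seed = 9)
  a <- render_phantom(spec, 0.10, 700)
  b <- render_phantom(spec, 0.10, 700)
  expect_identical(a$triplet$images, b$triplet$images)
  expect_identical(a$white, b$white)

  c <- render_phantom(tiny_spec(seed = 10), 0.10, 700)
  expect_false(identical(a$triplet$images, c$triplet$images))
})

test_that("ratio image of a noiseless phantom is vignetting-independent", {
  base <- list(noise_sigma = 0, n_dark_spots = 0, texture_amp = 0, seed = 2)
  s0 <- render_phantom(do.call(phantom_spec, c(base, vignette_strength = 0)), 0.10, 700)
  s1 <- render_phantom(do.call(phantom_spec, c(base, vignette_strength = 0.4)), 0.10, 700)
  rt <- function(s) {
    d <- demodulate_three_phase(correct_triplet(s$triplet, s$white, s$black))
    m <- create_background_mask(d)
    ratio_image(d, m)$rt
  }
  core <- s0$truth_disc
  core[abs(row(core) - 64.5) > 50 | abs(col(core) - 64.5) > 50] <- FALSE
  expect_lt(max(abs(rt(s0)[core] - rt(s1)[core])), 0.03)
})

test_that("bruise lowers the phantom ratio image where the truth says so", {
  lower <- vapply(1:20, function(seed) {
    spec <- phantom_spec(bruise = list(center = c(60, 70), semi_axes = c(20, 16)),
                         seed = seed)
    s <- render_phantom(spec, 0.10, 700)
    d <- demodulate_three_phase(correct_triplet(s$triplet, s$white, s$black))
    m <- create_background_mask(d)
    rt <- ratio_image(d, m)$rt
    normal <- s$truth_disc & !s$truth_bruise & m$mask
    mean(rt[s$truth_bruise]) < mean(rt[normal])
  }, logical(1))
  expect_true(all(lower))
})

test_that("dataset generation is seeded, counted and reproducible", {
  expect_equal(generate_dataset(0, 0), list())

  ds1 <- generate_dataset(3, 4, tiny_spec(), seed = 6)
  ds2 <- generate_dataset(3, 4, tiny_spec(), seed = 6)
  expect_equal(vapply(ds1, `[[`, "", "label"),
               rep(c("normal", "bruised"), c(3, 4)))
  expect_identical(ds1[[2]]$triplet$images, ds2[[2]]$triplet$images)
  expect_identical(ds1[[5]]$truth_bruise, ds2[[5]]$truth_bruise)
  # bruise locations vary across samples
  expect_false(identical(ds1[[4]]$truth_bruise, ds1[[5]]$truth_bruise))

  ds3 <- generate_dataset(3, 4, tiny_spec(), seed = 7)
  expect_false(identical(ds1[[1]]$triplet$images, ds3[[1]]$triplet$images))
})

test_that("phantom spec validates geometry", {
  expect_error(phantom_spec(disc_radius = 100), "disc")
  expect_error(phantom_spec(bruise = list(center = c(10, 10),
                                          semi_axes = c(20, 16))), "bruise")
})
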