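# Synthetic optical phantom generator: seeded three-phase pattern triplets of
# a disc-shaped fruit sample with optional subsurface bruise, dark-spot pits,
# stem/suture streak, vignetting, frequency/wavelength-dependent modulation
# decay, sensor noise, and matching white/black references, with full ground
# truth.

#' Impact energy of the bruising ball drop
#'
#' Bruise severity in impact tests is set by the gravitational potential
#' energy of the dropped ball, `E = m * g * h`.
#'
#' @param mass ball mass in kg.
#' @param height drop height in m.
#' @param g gravitational acceleration, m/s^2 (default 9.8).
#' @return energy in joules.
#' @export
impact_energy <- function(mass, height, g = 9.8) {
  if (mass < 0 || height < 0 || g < 0)
    stop("mass, height and g must be >= 0", call. = FALSE)
  mass * g * height
}

#' Specification of a synthetic SIRI phantom
#'
#' Collects every parameter of the synthetic sample: geometry, optics,
#' defects, noise and seed.  Defaults describe a bright fruit disc
#' (reflectance 0.55) of 28 mm radius at 0.5 mm/px in a 128 x 128 frame,
#' with moderate vignetting, three surface-pit dark spots, and -- when a
#' bruise is requested -- an elliptical subsurface bruise whose contrast is
#' mostly in the AC channel.
#'
#' @param image_size c(height, width) in pixels.
#' @param pixel_pitch mm per pixel.
#' @param disc_center c(row, col); `NULL` = image centre.
#' @param disc_radius fruit disc radius, px.
#' @param dc_reflectance diffuse reflectance of normal tissue, \[0,1\].
#' @param background_reflectance reflectance of the dark box behind the
#'   sample.
#' @param vignette_strength relative intensity drop at the disc edge, \[0,1).
#' @param modulation_depth0 modulation depth at zero spatial frequency.
#' @param freq_decay named vector, mm/cycle per wavelength: exponential decay
#'   constant of the modulation depth with spatial frequency.
#' @param wavelength_gain named vector in \[0,1\]: relative AC efficiency per
#'   wavelength (camera/projector photon efficiency and tissue reflectivity).
#' @param bruise `NULL` for a normal sample, or a list with `center`
#'   (c(row, col)), `semi_axes` (c(a, b) px), `ac_contrast` and `dc_contrast`
#'   in \[0,1\].
#' @param bruise_peak_frequency spatial frequency (cycle/mm) at which the
#'   subsurface bruise is most visible; visibility falls to zero at f = 0
#'   (uniform illumination barely sees it) and decays beyond the peak (high
#'   frequencies no longer reach the bruise depth).
#' @param n_dark_spots number of surface-pit dark spots.
#' @param spot_radius_px dark spot radius, px.
#' @param spot_depth relative reflectance drop inside a spot, \[0,1\].
#' @param spot_ac_extra additional relative AC-only attenuation inside a
#'   spot (pits scatter the pattern), so a faint residue survives in the
#'   ratio image.
#' @param texture_amp amplitude of the subsurface heterogeneity texture:
#'   the modulation depth is multiplied by `1 - texture_amp * g^2` with `g`
#'   a smooth unit-variance Gaussian random field, producing sparse shallow
#'   dark dips (flesh heterogeneity, micro-pits) with the left-skewed
#'   intensity distribution seen in real AC/ratio images.
#' @param texture_scale correlation length of the texture field, px
#'   (Gaussian smoothing sigma).
#' @param stem `NULL`, or a list with `angle` (radians), `width_px`,
#'   `length_px`, `depth` describing a dark streak from the disc centre.
#' @param noise_sigma additive Gaussian sensor noise, unit-intensity scale.
#' @param bit_depth quantization of rendered images (8 or 16).
#' @param ball_mass,drop_height,g impact-test parameters (kg, m, m/s^2)
#'   recording the bruising severity of the emulated protocol.
#' @param seed integer seed driving all randomness of this sample.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(128, 128),
                         pixel_pitch = 0.5,
                         disc_center = NULL,
                         disc_radius = 56,
                         dc_reflectance = 0.55,
                         background_reflectance = 0.02,
                         vignette_strength = 0.3,
                         modulation_depth0 = 0.6,
                         freq_decay = c("700" = 3.0, "750" = 3.5, "800" = 4.0),
                         wavelength_gain = c("700" = 1.0, "750" = 0.85, "800" = 0.70),
                         bruise = NULL,
                         bruise_peak_frequency = 0.12,
                         n_dark_spots = 3,
                         spot_radius_px = 2.5,
                         spot_depth = 0.25,
                         spot_ac_extra = 0.15,
                         texture_amp = 0.03,
                         texture_scale = 4,
                         stem = NULL,
                         noise_sigma = 0.004,
                         bit_depth = 8,
                         ball_mass = 0.1,
                         drop_height = 0.4,
                         g = 9.8,
                         seed = 1L) {
  if (is.null(disc_center)) disc_center <- (image_size + 1) / 2
  if (disc_center[1] - disc_radius < 0 || disc_center[2] - disc_radius < 0 ||
      disc_center[1] + disc_radius > image_size[1] + 1 ||
      disc_center[2] + disc_radius > image_size[2] + 1)
    stop("disc not inside image", call. = FALSE)
  stopifnot(dc_reflectance >= 0, dc_reflectance <= 1,
            vignette_strength >= 0, vignette_strength < 1,
            modulation_depth0 >= 0, modulation_depth0 <= 1,
            noise_sigma >= 0, bit_depth %in% c(8, 16))
  if (!is.null(bruise)) {
    stopifnot(all(c("center", "semi_axes") %in% names(bruise)))
    if (is.null(bruise$ac_contrast)) bruise$ac_contrast <- 0.4
    if (is.null(bruise$dc_contrast)) bruise$dc_contrast <- 0.05
    d <- sqrt(sum((bruise$center - disc_center)^2))
    if (d + max(bruise$semi_axes) > disc_radius)
      stop("bruise not inside disc", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), pixel_pitch = pixel_pitch,
                 disc_center = disc_center, disc_radius = disc_radius,
                 dc_reflectance = dc_reflectance,
                 background_reflectance = background_reflectance,
                 vignette_strength = vignette_strength,
                 modulation_depth0 = modulation_depth0,
                 freq_decay = freq_decay, wavelength_gain = wavelength_gain,
                 bruise = bruise, bruise_peak_frequency = bruise_peak_frequency,
                 n_dark_spots = n_dark_spots, spot_radius_px = spot_radius_px,
                 spot_depth = spot_depth, spot_ac_extra = spot_ac_extra,
                 texture_amp = texture_amp, texture_scale = texture_scale,
                 stem = stem, noise_sigma = noise_sigma, bit_depth = bit_depth,
                 ball_mass = ball_mass, drop_height = drop_height, g = g,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px (%.2f mm/px), disc r = %.0f px, %s\n",
              x$image_size[1], x$image_size[2], x$pixel_pitch, x$disc_radius,
              if (is.null(x$bruise)) "normal" else "bruised"))
  cat(sprintf("  impact energy %.3f J, %d dark spots, noise sigma %.3f, seed %d\n",
              impact_energy(x$ball_mass, x$drop_height, x$g),
              x$n_dark_spots, x$noise_sigma, x$seed))
  invisible(x)
}

#' Modulation depth of the rendered sinusoid
#'
#' Phenomenological stand-in for light diffusion in turbid tissue: the
#' modulation transfer of the medium decays exponentially with spatial
#' frequency, faster at longer wavelengths, so
#' `depth(f, lambda) = modulation_depth0 * wavelength_gain(lambda) *
#' exp(-f * freq_decay(lambda))`.
#'
#' @param spec a [phantom_spec()].
#' @param f spatial frequency, cycle/mm, >= 0.
#' @param wavelength wavelength in nm; must be tabulated in the spec.
#' @return modulation depth in \[0,1\].
#' @export
modulation_depth <- function(spec, f, wavelength) {
  stopifnot(inherits(spec, "phantom_spec"), f >= 0)
  key <- as.character(wavelength)
  if (!key %in% names(spec$wavelength_gain) || !key %in% names(spec$freq_decay))
    stop("unknown wavelength: ", wavelength, call. = FALSE)
  spec$modulation_depth0 * unname(spec$wavelength_gain[key]) *
    exp(-f * unname(spec$freq_decay[key]))
}

# relative visibility of the subsurface bruise as a function of spatial
# frequency: zero under uniform illumination, peaking at f = fp, decaying
# beyond it (high-frequency light no longer reaches the bruise depth)
bruise_visibility <- function(f, fp) {
  if (fp <= 0) return(rep(1, length(f)))
  (f / fp) * exp(1 - f / fp)
}

# evaluate an expression with a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Render a synthetic three-phase SIRI sample
#'
#' Forms, for each phase offset theta in (-2pi/3, 0, 2pi/3), the pattern
#' image
#' `I = gain(x, y) * (Rdc(x, y) + Rac(x, y) * cos(2 pi f x_mm + theta))`
#' plus Gaussian sensor noise, quantized to the spec's bit depth.  The
#' sinusoid runs along image columns.  `gain` encodes radial vignetting;
#' `Rdc` is lowered inside the bruise (weakly, `dc_contrast`), inside dark
#' spots (`spot_depth`) and under the stem streak; `Rac = Rdc * depth` with
#' the frequency/wavelength-dependent modulation depth, additionally lowered
#' inside the bruise by `ac_contrast` scaled by the frequency-dependent
#' bruise visibility.  References are rendered as a uniform quasi-white
#' plate (reflectivity 0.98) and a dark frame.
#'
#' @param spec a [phantom_spec()].
#' @param f spatial frequency, cycle/mm.
#' @param wavelength wavelength, nm (tabulated in the spec).
#' @return object of class `phantom_sample`: list with `triplet`
#'   (a `siri_triplet`), `white`, `black` (reference matrices), `truth_disc`,
#'   `truth_bruise` (logical matrices), `label`, `spec`, `f`, `wavelength`.
#' @export
render_phantom <- function(spec, f = 0.10, wavelength = 700) {
  stopifnot(inherits(spec, "phantom_spec"))
  depth <- modulation_depth(spec, f, wavelength)  # validates wavelength
  h <- spec$image_size[1]; w <- spec$image_size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  r2 <- (rows - spec$disc_center[1])^2 + (cols - spec$disc_center[2])^2
  disc <- r2 <= spec$disc_radius^2

  with_seed(spec$seed, {
    gain <- 1 - spec$vignette_strength * pmin(r2 / spec$disc_radius^2, 1)
    rdc <- ifelse(disc, spec$dc_reflectance, spec$background_reflectance)
    dmap <- matrix(depth, h, w)

    truth_bruise <- matrix(FALSE, h, w)
    if (!is.null(spec[["bruise"]])) {
      b <- spec[["bruise"]]
      e <- ((rows - b$center[1]) / b$semi_axes[1])^2 +
           ((cols - b$center[2]) / b$semi_axes[2])^2
      truth_bruise <- disc & e <= 1
      rdc[truth_bruise] <- rdc[truth_bruise] * (1 - b$dc_contrast)
      vis <- bruise_visibility(f, spec$bruise_peak_frequency)
      dmap[truth_bruise] <- dmap[truth_bruise] * (1 - b$ac_contrast * min(vis, 1))
    }

    # subsurface heterogeneity: smooth, dark-only (left-skewed) modulation
    # dips that survive median filtering, as in real fruit tissue; bruised
    # tissue is water-soaked and structurally homogenized, so its intrinsic
    # heterogeneity is largely destroyed
    if (spec$texture_amp > 0) {
      g <- smooth_field(h, w, spec$texture_scale)
      tex <- spec$texture_amp * g^2
      tex[truth_bruise] <- 0.1 * tex[truth_bruise]
      dmap <- dmap * pmax(1 - tex, 0)
    }

    # surface-pit dark spots: random positions inside the disc, kept clear of
    # the bruise so the ground truth stays unambiguous
    if (spec$n_dark_spots > 0) {
      placed <- 0; tries <- 0
      while (placed < spec$n_dark_spots && tries < 200) {
        tries <- tries + 1
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * (spec$disc_radius - 2 * spot_margin(spec))
        cr <- spec$disc_center[1] + rad * sin(ang)
        cc <- spec$disc_center[2] + rad * cos(ang)
        sp <- (rows - cr)^2 + (cols - cc)^2 <= spec$spot_radius_px^2
        if (any(sp & truth_bruise)) next
        rdc[sp] <- rdc[sp] * (1 - spec$spot_depth)
        dmap[sp] <- dmap[sp] * (1 - spec$spot_ac_extra)
        placed <- placed + 1
      }
    }

    if (!is.null(spec$stem)) {
      s <- spec$stem
      u <- c(sin(s$angle), cos(s$angle))                 # along-streak direction
      drc <- cbind(rows - spec$disc_center[1], cols - spec$disc_center[2])
      along <- drc[, 1] * u[1] + drc[, 2] * u[2]
      across <- abs(drc[, 1] * u[2] - drc[, 2] * u[1])
      streak <- matrix(along >= 0 & along <= s$length_px &
                         across <= s$width_px / 2, h, w) & disc
      rdc[streak] <- rdc[streak] * (1 - s$depth)
      dmap[streak] <- dmap[streak] * (1 - s$depth)
    }

    rac <- rdc * dmap
    x_mm <- (cols - 1) * spec$pixel_pitch
    render_one <- function(theta) {
      img <- gain * (rdc + rac * cos(2 * pi * f * x_mm + theta))
      if (spec$noise_sigma > 0) img <- img + rnorm(h * w, 0, spec$noise_sigma)
      quantize_to_depth(img, spec$bit_depth)
    }
    imgs <- lapply(PHASE_OFFSETS, render_one)
    white <- matrix(0.98, h, w)
    black <- matrix(0, h, w)
    if (spec$noise_sigma > 0) {
      white <- white + rnorm(h * w, 0, spec$noise_sigma)
      black <- black + abs(rnorm(h * w, 0, spec$noise_sigma / 4))
    }
    white <- quantize_to_depth(white, spec$bit_depth)
    black <- quantize_to_depth(black, spec$bit_depth)

    structure(list(
      triplet = siri_triplet(imgs[[1]], imgs[[2]], imgs[[3]],
                             spatial_frequency = f, wavelength = wavelength,
                             pixel_pitch = spec$pixel_pitch),
      white = white, black = black,
      truth_disc = disc, truth_bruise = truth_bruise,
      label = if (any(truth_bruise)) "bruised" else "normal",
      spec = spec, f = f, wavelength = wavelength),
      class = "phantom_sample")
  })
}

spot_margin <- function(spec) spec$spot_radius_px + 1

# smooth unit-variance Gaussian random field: white noise convolved with a
# separable Gaussian kernel (sigma px), standardized after smoothing.
# Uses the current RNG state.
smooth_field <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-half):half / sigma)^2)
    k <- k / sum(k)
    pad_conv <- function(m) {
      n <- nrow(m)
      idx <- pmin(pmax(seq(1 - half, n + half), 1), n)  # replicate padding
      mp <- m[idx, , drop = FALSE]
      out <- matrix(0, n, ncol(m))
      for (d in seq_along(k))
        out <- out + k[d] * mp[seq_len(n) + d - 1L, , drop = FALSE]
      out
    }
    z <- pad_conv(z)            # rows
    z <- t(pad_conv(t(z)))      # columns
  }
  (z - mean(z)) / sd(z)
}

quantize_to_depth <- function(x, bit_depth) {
  maxval <- 2^bit_depth - 1
  floor(pmin(pmax(x, 0), 1) * maxval + 0.5) / maxval
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s, f = %.2f cycle/mm, lambda = %d nm, seed %d\n",
              x$label, x$f, x$wavelength, x$spec$seed))
  invisible(x)
}

#' Generate a seeded dataset of phantom samples
#'
#' Renders `n_normal` normal and `n_bruised` bruised samples from a common
#' base spec.  Bruise location (and mild size jitter) and dark-spot placement
#' are randomized per sample; all randomness derives deterministically from
#' `seed` through per-sample sub-seeds, so the same call reproduces the same
#' dataset bit for bit.
#'
#' @param n_normal,n_bruised sample counts (>= 0).
#' @param base_spec a [phantom_spec()]; its `bruise` field is overridden per
#'   sample.
#' @param f,wavelength acquisition parameters for every sample.
#' @param seed master seed.
#' @return list of `phantom_sample`, normals first.
#' @export
generate_dataset <- function(n_normal, n_bruised, base_spec = phantom_spec(),
                             f = 0.10, wavelength = 700, seed = 1L) {
  stopifnot(n_normal >= 0, n_bruised >= 0)
  n <- n_normal + n_bruised
  if (n == 0) return(list())
  labels <- rep(c("normal", "bruised"), c(n_normal, n_bruised))
  lapply(seq_len(n), function(i) {
    sub_seed <- (as.integer(seed) %% 100000L) * 20011L + i
    spec_i <- base_spec
    spec_i$seed <- sub_seed
    if (labels[i] == "bruised") {
      spec_i$bruise <- with_seed(sub_seed + 7L, random_bruise(base_spec))
    } else {
      spec_i$bruise <- NULL
    }
    render_phantom(spec_i, f = f, wavelength = wavelength)
  })
}

# draw a random bruise wholly inside the disc (uses the current RNG state)
random_bruise <- function(spec) {
  base <- if (!is.null(spec[["bruise"]])) spec[["bruise"]] else list()
  ax0 <- if (!is.null(base$semi_axes)) base$semi_axes else c(20, 16)
  ax <- ax0 * runif(2, 0.9, 1.1)
  margin <- max(ax) + 2
  repeat {
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * (spec$disc_radius - margin)
    ctr <- spec$disc_center + rad * c(sin(ang), cos(ang))
    if (rad + max(ax) <= spec$disc_radius - 1) break
  }
  ac0 <- if (!is.null(base$ac_contrast)) base$ac_contrast else 0.4
  dc0 <- if (!is.null(base$dc_contrast)) base$dc_contrast else 0.05
  # impact severity varies between drops; jitter the contrasts around the
  # nominal values so samples do not share an identical bruise intensity
  list(center = ctr, semi_axes = ax,
       ac_contrast = ac0 * runif(1, 0.9, 1.1),
       dc_contrast = dc0 * runif(1, 0.9, 1.1))
}
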