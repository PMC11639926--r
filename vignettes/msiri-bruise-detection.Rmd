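---
title: "Detecting subsurface fruit bruises with structured-illumination reflectance imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting subsurface fruit bruises with structured-illumination reflectance imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siribruise)
```

## The measurement model

Structured-illumination reflectance imaging (SIRI) projects a sinusoidal
intensity pattern of spatial frequency $f$ (cycle/mm) onto the sample and
records the reflected image. In a turbid medium such as fruit flesh the
modulated component of the light field attenuates with depth, and it
attenuates faster at higher spatial frequency — the tissue acts as a low-pass
filter. A camera image of the patterned scene therefore mixes two signals: a
phase-independent component equivalent to uniform illumination, and a
modulated component whose effective sampling depth is set by $f$.

Acquiring three images $I_1, I_2, I_3$ with the pattern phase shifted by
$-2\pi/3, 0, 2\pi/3$ lets both components be recovered per pixel:

$$I_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_1-I_3)^2 + (I_2-I_3)^2},
\qquad I_{DC} = \frac{I_1+I_2+I_3}{3}.$$

For an ideal sinusoid $I_k = A + B\cos(\phi + \theta_k)$ these return exactly
$I_{AC}=B$ and $I_{DC}=A$ at any global phase $\phi$; the test suite checks
this identity to machine precision, along with its symmetry under permutation
of the three images.

Before demodulation each raw image is corrected with a white reference $W$
(quasi-white plate, reflectivity 0.98) and a black reference $B$ (capped
lens): $R = (R_0 - B)/(W - B)$. Pixels where $W \le B$ carry no signal; they
are zeroed and counted rather than propagating infinities.

A subsurface bruise barely alters the overall diffuse reflectance (the DC
image) but damps the modulation transfer at the depths the AC image samples,
so it appears as a dark region in AC. The ratio image

$$RT = I_{AC} / I_{DC}$$

cancels any multiplicative illumination non-uniformity — vignetting,
irradiance fall-off — because such gains multiply numerator and denominator
alike, while the bruise contrast (carried by AC only) is retained. This gain
invariance is tested as an exact property.

## Pipeline and parameters

`run_pipeline()` chains the stages with one configuration object,
`siri_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `mask_threshold` | 15 | 8-bit level | DC level (strictly) above which a pixel is fruit foreground |
| `image_style` | `"RT"` | — | segment the ratio image or the (equalized) AC image |
| `equalize` | `TRUE` | — | AC path only: 256-level histogram equalization over the foreground |
| `median_window` | 10×10 | px | median filter; an odd 9×9 can be configured if the even anchor is undesirable |
| `method` | `"iotsu"` | — | `"global"`, `"otsu"` or `"iotsu"` |
| `polarity` | `"below"` | — | bruises are dark in AC/RT, so candidates are levels ≤ T |
| `min_area` | 50 | px | smallest connected component kept after thresholding |
| `connectivity` | 8 | — | neighbourhood for component labelling |
| `eps` | 1/255 | intensity | DC division guard: below one 8-bit quantum DC carries no signal |
| `min_contrast` | 2 | 8-bit levels | degenerate-histogram guard (see below) |

Pixels are represented as real values in $[0,1]$ throughout; conversion to
the 8-bit scale (multiply by 255, round half up) happens only at file I/O and
where the protocol fixes 8-bit constants (the mask threshold, the
segmentation histograms). The `min_area` default of 50 px corresponds to
about 12 mm² at the phantom's default 0.5 mm/px — comfortably below the
smallest bruise of interest and above isolated noise blobs.

## Threshold selection

With a 256-level foreground histogram split at level $T$ into classes $C_0$
(levels $\le T$) and $C_1$, with probabilities $p_0, p_1$, means
$\mu_0, \mu_1$ and global mean $\mu = p_0\mu_0 + p_1\mu_1$:

* **Otsu** maximizes the between-class variance $p_0 p_1 (\mu_0-\mu_1)^2$,
  equivalently minimizes the within-class variance — the suite verifies both
  forms select the same threshold by exhaustive scan.
* **Improved Otsu** maximizes
  $p_0 p_1 (\mu_0-\mu_1)^2 + (\mu_0-\mu)^2 + (\mu_1-\mu)^2$. Substituting
  the mean decomposition collapses this to
  $(\mu_0-\mu_1)^2\,(1 - p_0 p_1)$ — an identity the tests verify to
  $10^{-9}$, and a useful lens on its behaviour: where Otsu *rewards*
  balanced splits (the $p_0 p_1$ factor), the improved objective *penalizes*
  them.

The practical consequence is that the improved objective selects
conservative thresholds deep in the dark tail of the histogram: it flags
only pixels well separated from the bulk, instead of splitting a unimodal,
noisy foreground down the middle the way Otsu does. This is precisely the
robustness to dark-spot noise that motivates it — small pits produce few
extreme pixels, which the area cleanup then removes — at the price of
under-segmenting diffuse defects. A genuine bruise forms a large,
homogeneous dark mode, which the conservative threshold still captures en
masse.

Numerical conventions, all tested: candidate thresholds that leave a class
empty are excluded (detected on integer counts, not on floating-point
probabilities); ties return the smallest maximizing level; both selectors
equal an independent brute-force scan on random histograms; a uniform level
shift moves the threshold by the same shift.

**Degenerate histograms.** On a foreground that is essentially constant —
e.g. a noiseless synthetic sample — every split separates nothing but
quantization ripple, yet an argmax must still pick some level, and with dark
polarity the whole fruit can end up flagged. `auto_threshold_segment()`
therefore reports an empty defect mask whenever the class means at the
selected threshold differ by fewer than `min_contrast = 2` grey levels:
below two quantization steps there is no evidence of two populations. The
threshold itself is still reported.

**Ratio-image scaling.** The ratio image is clipped to the fixed physical
range $[0,1]$ (AC cannot exceed DC for modulation depth ≤ 1, up to noise)
and quantized directly, rather than min–max stretched per sample. Per-sample
stretching would amplify noise by a factor that depends on each sample's own
extremes, and would make thresholds and the fixed `min_area` incomparable
across samples; the fixed scale keeps one grey level equal to one physical
modulation-ratio quantum everywhere. (A min–max helper, `rescale_unit()`,
remains available.)

**Median filtering at the fruit boundary.** A plain sliding window near the
mask boundary would mix zeroed background pixels into the sample and
manufacture an artificial dark ring — which a dark-polarity threshold then
"detects". The pipeline therefore uses the mask-aware variant
(`median_filter(..., mask = )`) whose window sample is restricted to
foreground pixels. The unmasked filter keeps the documented contract:
reflect padding, and for even windows the output pixel anchored at
$(\lceil h/2\rceil, \lceil w/2\rceil)$ with the upper-middle order statistic,
so that output values always belong to the input value set.

## The synthetic phantom

`phantom_spec()` + `render_phantom()` generate fully ground-truthed
three-phase samples. The image formation is

$$I_k(x,y) = g(x,y)\,\bigl[R_{dc}(x,y) + R_{ac}(x,y)\cos(2\pi f x_{mm} + \theta_k)\bigr] + \varepsilon,$$

quantized to 8 bits, with the sinusoid along image columns and
$\varepsilon \sim N(0, \sigma^2)$ sensor noise. The components:

* **Geometry** — a 56-px-radius disc ("fruit") at 0.5 mm/px in a 128×128
  frame: a ~56 mm fruit in a 64 mm field. Background reflectance 0.02
  (dark enclosure).
* **Vignetting** — radial gain $g = 1 - v\,(r/R)^2$ with $v = 0.3$: the
  uneven brightness that motivates the ratio image.
* **Modulation transfer** — $R_{ac} = R_{dc}\cdot d(f,\lambda)$ with
  $d(f,\lambda) = d_0\, w(\lambda)\, e^{-f\,k(\lambda)}$, a single-exponential
  stand-in for diffusion theory. Defaults $d_0 = 0.6$;
  $w = (1.0, 0.85, 0.70)$ and $k = (3.0, 3.5, 4.0)$ mm/cycle at
  $\lambda = 700, 750, 800$ nm, encoding lower photon efficiency and faster
  attenuation at longer wavelengths.
* **Bruise** — an ellipse (default semi-axes 20×16 px = a 20×16 mm bruise,
  appropriate for a 0.4 J impact of a 30 mm ball; `impact_energy()` records
  the protocol) that damps $R_{ac}$ by `ac_contrast` (default 0.4) and
  $R_{dc}$ by only `dc_contrast` (default 0.05): a defect visible in AC and
  nearly invisible in DC. Because the bruise lies at a finite depth, its AC
  visibility depends on $f$: zero under uniform illumination (photons
  average over all depths), maximal when the sensing depth matches the
  bruise depth, fading at high $f$ (light no longer reaches it). This is
  modelled as $(f/f_p)\,e^{1-f/f_p}$ with $f_p = 0.12$ cycle/mm, chosen so
  that — combined with the modulation decay — the bruise contrast over the
  acquisition grid peaks at $f = 0.10$, $\lambda = 700$, the optimum the
  selection module is expected to find. Without some depth dependence a
  fixed contrast would make bruise visibility monotone in $f$ and no
  interior optimum could exist.
* **Dark-spot pits** — small discs (default 3 per sample, radius 2.5 px)
  that lower $R_{dc}$ by 25%: strong spots in AC and DC that largely cancel
  in RT, plus a 15% AC-only extra attenuation leaving a faint RT residue.
  These are the false-positive drivers the improved objective is meant to
  resist.
* **Tissue heterogeneity** — the modulation depth is multiplied by
  $1 - a\,g^2$ with $g$ a smooth unit-variance Gaussian field
  (correlation ~4 px) and $a = 0.03$: sparse, shallow, *dark-only* dips, the
  left-skewed intensity structure of real AC/RT images. It survives median
  filtering (unlike pixel noise), which matters: without it a synthetic
  normal sample collapses to a two-grey-level histogram on which any
  automatic threshold behaves degenerately. Inside the bruise the texture is
  suppressed (×0.1): water-soaked, structurally damaged tissue is optically
  much more homogeneous than intact flesh, which also makes the bruise the
  coherent dark mode the conservative threshold needs.
* **Noise and references** — $\sigma = 0.004$ (~1 grey level at 8 bits,
  realistic for a machine-vision camera at a 500 ms exposure); a uniform
  0.98 white plate and near-zero dark frame, rendered with the same noise.
* **Seeding** — one integer seed drives everything; `generate_dataset()`
  derives per-sample sub-seeds deterministically and randomizes bruise
  location (size and severity jittered ±10%: a fixed-energy impact protocol
  yields consistent but not identical bruises) and spot placement. Identical
  calls are bit-identical.

**What the phantom does not emulate** — and hence what a green end-to-end
test does *not* establish: 3-D fruit geometry and specular reflection
(phantoms are flat discs); physically accurate photon transport (the decay
model is phenomenological); stem/suture streaks in the default datasets
(supported via `stem =`, off by default); bruises at the extreme fruit edge
(random bruises are kept inside the disc); and the rich surface texture of
real peaches. Real-fruit accuracy is substantially harder than phantom
accuracy: the end-to-end phantom study passing its ≥95% bound says the chain
is implemented coherently, not that any given cultivar will reach that
figure.

## Resolved ambiguities

Choices the protocol leaves open, fixed here and documented:

* The background mask threshold (15) applies to the DC image on its native
  8-bit scale, with a strict `>` comparison.
* The ratio image consumes the *raw* demodulated AC, not the equalized AC
  (equalization and RT are parallel enhancements; an `equalized` flag
  exists).
* "Removing connected regions with pixel values less than the threshold" is
  read as regions with pixel *counts* (areas) below an area threshold,
  consistent with its purpose of removing small scattered pixels.
* Bruise polarity: candidates are levels ≤ T (bruises are dark); configurable.
* Line profiles use nearest-pixel rasterization (rounded linear
  interpolation, one sample per major-axis step); peak-to-valley contrast is
  max over the normal window minus min over the bruise window, floored at 0,
  with the windows supplied explicitly (from ground truth, in tests).

## Known limitations

* The improved-Otsu objective's preference for extreme splits means its
  threshold often sits at the very bottom of the histogram; detection then
  hinges on the defect contributing a sizeable mass near the minimum level.
  Diffuse, low-contrast defects can be under-segmented in favour of a tiny
  extreme tail. The `min_contrast` guard handles only the fully degenerate
  case.
* Otsu on near-uniform synthetic normals mid-splits smooth texture and can
  flag large false regions; on real fruit its failure mode is milder. The
  phantom therefore *overstates* the gap between the two methods on normal
  samples, while ranking them in the same order.
* PNG and PGM are supported; TIFF is not (no TIFF reader in the supported
  dependency set).
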