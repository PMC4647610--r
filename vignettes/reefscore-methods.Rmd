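---
title: "Scoring coral-reef aesthetics: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring coral-reef aesthetics: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reef monitoring programmes quantify biogeochemistry, benthic cover and
fish communities, but not the property that draws people (and tourism
revenue) to reefs in the first place: how the reefscape *looks*.
`reefscore` implements a standardized computational pipeline that turns
ordinary benthic photographs into a continuous **coral reef aesthetic
value**. The pipeline has three stages:

1. **Feature extraction** — 109 hand-crafted aesthetic image features,
   adapted from the photographic- and painting-aesthetics literature,
   spanning three groups: *color* (intensity and diversity of colour
   across the whole image), *objects* (relative size, colour and spatial
   distribution of discernable objects), and *texture* (wavelet detail
   energies, local range, smoothness).
2. **Calibration** — a single-hidden-layer feed-forward neural network
   regresses the 109 features of each image on a site-level
   anthropogenic-impact score (an NCEAS-style cumulative human-impact
   index), producing one continuous value per image.
3. **Analysis** — aggregation of several images from the same locale,
   random-forest feature importances with group roll-ups, site
   comparison by ANOVA with Tukey HSD letters, and ordinary regression
   of aesthetic values on impact scores.

Because representative field imagery cannot ship with a package, a
seeded **synthetic reefscape generator** is a first-class module: every
stage of the pipeline can be exercised, tested and benchmarked on
generated data.

## The feature set

The canonical input is a `raster_image`: an RGB array in `[0, 1]`, at
least 16 x 16 px (the minimum for a three-level wavelet decomposition
and a thirds grid). Features are computed at native resolution; an
optional global pre-resize exists in `feature_config()` but is off by
default, and image size and aspect ratio are deliberately *not*
features — survey photographs are samples of a seascape, not
compositions.

Highlights of the registry (`feature_registry()` is the single source of
truth; `extract_features()` emits values in exactly its order):

* **Brightness.** Arithmetic mean of the HSV value channel, and the
  logarithmic average `exp(mean(log(V + 1/255))) - 1/255`. The 1/255
  guard (one 8-bit quantisation step) keeps black pixels finite and is
  configurable.
* **Brightness contrast.** The width, in 0-255 gray levels, of the
  smallest contiguous window of the 256-bin value histogram holding 98%
  of the pixels. The mass is configurable; the 8-bit scale makes the
  statistic an integer with the conventional magnitudes (a crisp
  reefscape scores near 100, a washed-out one near 50).
* **Colour diversity.** Shannon entropies of all channels (256 bins,
  bits, `0 log 0 = 0`), opponent-space colourfulness
  (`sqrt(sd(rg)^2 + sd(yb)^2) + 0.3 sqrt(mean(rg)^2 + mean(yb)^2)` with
  population standard deviations), and the hue count over a 20-bin hue
  histogram restricted to sufficiently saturated, bright pixels.
  Hue is averaged arithmetically on `[0, 1)`, not circularly — the
  convention of the aesthetics feature sets this package follows; the
  wrap-around bias is documented rather than "fixed" so values remain
  comparable with that literature.
* **Colour models.** Images are matched against a registry of reference
  colour histograms (L1 distance on a 4x4x4 RGB quantisation). The
  original reference models are not distributable, so the package ships
  clearly-synthetic palettes built in code (`default_color_models()`);
  the registry is a JSON-exchangeable override point, and any per-model
  reference score is user metadata.
* **Composition.** The rule-of-thirds focus region — the central ninth,
  widened by a margin `mu = 0.1` — yields brightness and colour
  statistics of the natural subject area. Bounds follow the exact
  rational arithmetic `floor(h(1/3 - mu))` .. `floor(h(2/3 + mu))`
  (an epsilon guard prevents double-precision floor artifacts from
  shifting the central ninth).
* **Objects.** K-means segmentation in RGB (`K = 2`, one seeded
  k-means++ initialisation, Lloyd iterations), connected-component
  counting over the label map (8-adjacency by default), and per-region
  statistics of the five largest connected regions (area, centroid,
  mean HSV, log-brightness), zero-padded to fixed width. Cluster labels
  are ordered by size then darkness so the feature block is stable
  under label permutation.
* **Edge energy.** The absolute response of the 3x3 four-neighbour
  Laplacian on the value channel (edge-replicating borders). Its
  concentration is summarised by bounding boxes containing 81% and
  96.04% of the total energy, found by the marginal-trim construction:
  trim rows/columns from each margin while their cumulative marginal
  energy stays within `(1 - f)/2` per side. Because the row band and
  column band each lose up to `1 - f`, their intersection can fall
  short of `f`; the implementation then grows the box back one
  row/column at a time on the side recovering the most energy, so the
  containment guarantee always holds while remaining `O(H + W)` and
  deterministic. The spatial *distribution* of edges is compared
  against reference profiles on a fixed 100x100 grid by total-variation
  similarity `1 - L1/2`; profiles are an explicit input
  (`default_edge_profiles()` ships constructed ones) because the
  original comparison profiles are unrecoverable.
* **Texture.** Three-level 2-D Haar detail energies per HSV channel
  (mean absolute detail coefficient per level, plus per-channel sums),
  the local range filter (max - min over 3/5/7-px windows), and
  smoothness `1 - mean(|Laplacian|)`. The wavelet family is Haar
  (`db1`) — the default in the source aesthetics literature — and is the
  only family implemented; odd dimensions are symmetrically padded.
  Whether "range of texture" denotes a local range filter or the spread
  of a texture statistic is ambiguous in the source descriptions; the
  local range filter is implemented and the ambiguity noted here.

Degenerate inputs are defined, not exceptional: a featureless constant
image has zero contrast, entropies, wavelet energies and texture range,
one connected component, bounding-box area 1 (the whole image) and edge
similarity 0, so every vector is finite.

## The calibration model

`aesthetic_train()` fits features-to-score regression with a
single-hidden-layer feed-forward network (default width 10, logistic
hidden units, linear output) via `nnet`:

* The training pool (everything outside the site-stratified holdout) is
  subdivided 70/15/15 into training, validation and internal-test
  subsets.
* Standardisation constants (per-feature mean and sd) come from the
  70% training subset only; holdout images can never influence them.
* Optimisation runs in chunks of 100 BFGS iterations; after each chunk
  the validation rms is evaluated, and training stops after 20 chunks
  without improvement (early stopping, best weights kept). The weight
  decay is selected from a small grid (0.01, 0.1, 1) by validation rms
  — the validation subset, not the analyst, chooses the regularisation.
* Everything is deterministic given the seed; `predict()` is an
  explicit standardise-affine-logistic-affine pass over the stored flat
  weight vector, so a JSON round trip (`save_aesthetic_model()` /
  `load_aesthetic_model()`) reproduces predictions exactly.

Targets are used raw; predictions are continuous and not clipped to the
observed score range. With constant targets the model degrades to a
constant predictor with a warning.

Aggregation over `N` images from one locale is a plain arithmetic mean
(`aggregate_score()`); `holdout_rms()` resamples `N`-image subsets per
holdout site to estimate the site-level error. Feature importances come
from a seeded random forest (impurity-based, normalised to sum to one)
with roll-ups over the three groups; the forest ranks features but never
replaces the network as the predictor. Site comparison uses one-way
ANOVA plus Tukey HSD with an insert-and-absorb connecting-letters
report.

## The synthetic generator

`generator_params()` maps a latent degradation score on `[0, 50]` to
image-composition parameters, encoding the documented visual correlates
of degradation monotonically: colour diversity 6 palettes at score 0
down to 1 at 50; object count 25 down to 7 blobs; mean object radius 12
down to 4 px (at a 128-px reference side); Gaussian blur 0.5 up to 4 px
(the amorphous-slime proxy); brightness 0.8 down to 0.35 and saturation
0.85 down to 0.3. Additive noise is constant (sd 0.03). A scene is a
flat bluish water background, elliptical blobs with palette hues,
Gaussian smoothing and clipped noise — deliberately an abstraction, not
a rendering: no fish shapes, no lighting model, no water-column optics.

The default desk-scale survey (`simulate_reef_survey()`) is 11 sites
with latent scores evenly spread over 2-45, 30 images per site at
128 x 128 px — small enough to generate and featurise in about two
minutes on one CPU, large enough that the calibration is a meaningful
recovery problem. The default holdout is 5 images per site (~17%,
site-stratified), mirroring at desk scale the roughly-10% site-stratified
holdout proportion a full field survey would use; `split_dataset()`
takes any `holdout_per_site`, so the 20-per-site design of a full-size
survey is equally expressible when sites are large enough.

Because the generator drives brightness, saturation and colour
diversity directly, the features that read those parameters out
globally and unambiguously — `brightness_arith`, `brightness_log`,
`mean_v`, `colorfulness` (`generator_driver_features()`) — are planted
signals that an importance analysis should place near the top of the
ranking. (Planted saturation is read out redundantly by global *and*
per-segment means, so no single saturation feature is canonical.)
What passing on synthetic data does *not* show: robustness to camera
optics, lighting and water colour casts, semantic content (a gray reef
shark is drab but delightful), or the actual effect sizes of real
degradation gradients. The synthetic results demonstrate that the
pipeline is correct and identifiable, not that it is field-calibrated.

## Numerical choices and edge cases

* Intensities live on `[0, 1]`; 8-bit-scale features (contrast) use a
  256-bin quantisation of `round(v * 255)`.
* Bilinear resizing uses the half-pixel-centre convention, so aligned
  2x downscaling averages 2x2 blocks exactly.
* Colour-model and edge-profile ties break toward the lowest index;
  k-means label ties break toward the darker centre; the box-growth
  step prefers top, bottom, left, right on exact ties.
* EXIF orientation is not honoured at load: none of the installed
  raster readers exposes it. Images that need rotation should be
  rotated upstream.
* `simulate()` is provided at the dataset level (the reefscape
  generator) rather than as a model method: the calibration network has
  no stochastic error model of its own to draw from.

## Problem sizes used by the test-suite and acceptance script

The behavioural checks run on the default desk-scale survey (330 images,
128 px), with 10 seeded re-splits for the aggregation property, 20
seeded forests for importance recovery, and 50 random small images per
brute-force oracle comparison. These sizes were chosen as the smallest
at which the properties of interest are statistically unambiguous.

## Known limitations

* Arithmetic hue means wrap badly for hue distributions straddling 0/1;
  kept for comparability (see above).
* Only the Haar wavelet is available.
* The per-index correspondence of the 109 registry slots to any
  external feature numbering is approximate by necessity; the registry
  (`feature_registry()`, `write_registry_json()`) is the authoritative
  mapping for this package.
* Site labels containing `-` would collide with Tukey pair-name parsing
  in `site_comparison()`; use alphanumeric site ids.
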