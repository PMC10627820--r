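---
title: "Probabilistic canopy-height retrieval with sparse LiDAR supervision"
author: "canopyfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic canopy-height retrieval with sparse LiDAR supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyfuse)
```

# The retrieval problem

Spaceborne large-footprint LiDAR missions sample the world's forests with
~25-m footprints, each yielding one canopy-top height (RH98: the relative
height at which 98 % of the waveform energy has returned). Optical
multispectral imagery, by contrast, is wall-to-wall at 10-m ground sampling
distance but only indirectly sensitive to vegetation height. canopyfuse
implements the retrieval strategy that combines the two: a fully
convolutional network regresses dense canopy-top height from multi-band
imagery, is *supervised only at the sparse footprint pixels*, models its own
predictive uncertainty, and fuses repeated acquisitions of the same site by
inverse-variance weighting.

# Model

## Network

The regressor is a fully convolutional residual network with separable
convolutions and **no downsampling**, so output grids always match the input
grid and arbitrarily sized tiles can be processed. Input channels are the
reflectance bands plus three cyclically encoded coordinate channels
(`sin(pi*lat/180)`, `sin(pi*lon/180)`, `cos(pi*lon/180)`): latitude is
injective under a single sine on [-90, 90], while longitude needs the
sin/cos pair to be continuous across the antimeridian. These channels let
the model learn geographical priors.

The precise block, which the exported contract documents (the literature
leaves the separable-convolution variant open, so we fix one):

```
entry:  x0  = ReLU(pointwise(input))
block:  out = ReLU(x + P2(DW2(ReLU(P1(DW1(x)) + c1))) + c2)
heads:  mu = 1x1 conv(trunk);  log sigma^2 = 1x1 conv(trunk)
```

`DWk` are depthwise 3x3 convolutions with zero padding, `Pk` pointwise 1x1
convolutions. The variance head predicts **log-variance** and is
exponentiated on output, guaranteeing a strictly positive variance for any
finite weights without constrained optimization. Each depthwise layer grows
the receptive field by one pixel per side, so the receptive-field margin is
`2 * blocks`; windowed inference overlaps windows by exactly this margin and
centre-crops, which reproduces whole-tile inference on interiors (the test
suite checks equality to 1e-5 m and translation covariance to 1e-10).

Two profiles are built in: `"paper"` (8 blocks x 256 filters, the
deployment-scale configuration) and `"small"` (2 blocks x 32 filters), the
desk-scale default used throughout the tests. The reduction is an
engineering choice, not an algorithmic one; every contract holds for both.

## Sparse heteroscedastic loss

Training minimizes the Gaussian negative log likelihood

$$\mathcal{L} = \frac{1}{N}\sum_{i=1}^{N}
  \frac{(\hat\mu(x_i) - y_i)^2}{2\hat\sigma^2(x_i)}
  + \frac{1}{2}\log \hat\sigma^2(x_i),$$

evaluated **only at labelled pixels**; everything else contributes nothing
(adding unlabelled pixels provably leaves the loss unchanged — a unit
test). This makes the per-pixel output a conditional Gaussian whose variance
absorbs the aleatoric noise of inputs and labels. Channels and targets are
standardized with statistics fitted on the training split only; the loss is
optimized in normalized space and predictions are reported in metres
(variance rescaled by the squared target sd).

## Ensembles, acquisition fusion and total variance

Epistemic uncertainty comes from a deep ensemble (deployment size five,
desk-scale three) of independently initialized networks. At inference, each
of the `T` acquisition dates of a site is processed by one member picked
uniformly at random — a cheap test-time-augmentation variant — and per-pixel
estimates are merged by inverse-variance weighting with the weighted law of
total variance:

$$\hat p_t = \frac{1/\hat\sigma_t^2}{\sum_j 1/\hat\sigma_j^2},\qquad
  \hat y = \sum_t \hat p_t \hat\mu_t,\qquad
  \mathrm{Var}(\hat y) = \sum_t \hat p_t \hat\mu_t^2
    - \Big(\sum_t \hat p_t \hat\mu_t\Big)^2 + \sum_t \hat p_t \hat\sigma_t^2.$$

Weights are renormalized per pixel over the *valid* (cloud-free) dates —
the natural extension to partially cloudy stacks; pixels with no valid date
become nodata. Variances are floored at 1e-6 m² before inversion (logged),
a numerical guard that avoids overflow without materially moving any
weight. When `T` exceeds the ensemble size, the fusion stays symmetric over
the `T` per-date outputs, the literal reading of the formulas above.

## Imbalance correction

Tall canopies are rare, which biases a plain fit toward underestimating
them. The correction reweights samples by the normalized square root of the
inverse frequency of their 1-m height bin,
$q_k = \sqrt{1/N_k} \,/\, \sum_j \sqrt{1/N_j}$ (empty bins are excluded
from the normalization — the source is silent; excluding them keeps
$\sum q_k = 1$), applied as a per-sample multiplicative weight — the most
literal reading of the formulation; a per-batch renormalized variant would
change only the effective learning rate. Crucially, fine-tuning updates
**only the final mean-regression layer**: the trunk and the variance head
are bit-identical before and after (asserted down to `identical()` in the
tests), which preserves the uncertainty calibration.

# Evaluation toolkit

Point metrics are RMSE, MAE, ME and the normalized mean error
`NME = 100 * ME / mean(y)`. Balanced variants (aRMSE, aMAE, aME) compute the
metric per 5-m reference-height interval and average unweighted over
nonempty intervals (empty intervals are skipped, not imputed). Calibration
sorts samples by predicted variance into `K` equal-count bins (stable ties
by sample index; remainder to the last bin) and compares each bin's
empirical RMSE with its root mean variance; `UCE` weights bins by
occupancy, `AUCE` averages them. Uncertainty filtering drops a fixed
fraction either by raw variance or by relative standard deviation
`sqrt(u)/max(pred, 0.1 m)` — the adaptive criterion preserves the full
height range because tall (large-sd but large-mean) predictions are not
preferentially discarded.

For comparison against airborne-laser canopy height models, a 1-m CHM is
converted to a "GEDI-like" canopy top: circular max-pooling (pixel-centre
distance ≤ 12 m, inclusive; neighbourhoods clipped at the grid edge) at
stride 1, then aggregation to the 10-m grid. The resampling operator after
max-pooling is not pinned down by the protocol we follow; block mean is the
default, with `nearest` and `max` as flags. The implementation is verified
pixel-exact against a naive O(N·r²) disc-scan oracle.

# The synthetic-scene generator

Real archives are replaced by a generator that reproduces the statistical
structure the method relies on, with every default chosen once as the
study condition:

* **Height field** — zero-inflated two-mode Gaussian mixture (defaults:
  30 % bare, low mode 8 ± 5 m, 5 % tall mode 35 ± 8 m, clipped to
  [0, 60] m), matching a long-tailed distribution dominated by low
  vegetation. Spatial structure comes from a Gaussian copula: a
  Gaussian-smoothed white-noise field (circular convolution, kernel
  normalized to unit L2 norm so the marginal stays exactly N(0,1)) pushed
  through the mixture quantile function. The marginal is therefore *exactly*
  the configured mixture — testable against a direct Monte-Carlo sampling
  oracle — while correlation length 3 px (30 m) produces stands.
* **Reflectance** — per band a monotone saturating link
  `a + s (1 - exp(-h/hscale))` with band-dependent sign and scale (visible
  darkens, NIR brightens, SWIR darkens, on the 0-1 surface-reflectance
  scale), a shared spatially correlated texture (sd 0.01), and per-date
  noise (sd 0.015, a realistic surface-reflectance noise level).
* **Clouds** — per date, a smooth field thresholded at the cloud fraction
  (default 0.2) gives coherent occlusion; obstructed pixels are overwritten
  with a bright deck and flagged invalid.
* **Footprints** — labels are the disc maximum (radius 12.5 m, the 25-m
  footprint; deliberately distinct from the 12-m CHM-comparison radius)
  at the TRUE centre plus label noise, clipped at 0; the REPORTED centre is
  jittered isotropically (default sd 8 m, the order of the documented
  geolocation uncertainty of the first-release footprint geolocations).
  The label noise magnitude is not documented for the real data, so it is
  an explicit free parameter (default 2 m, the order of RH98 retrieval
  error). Rasterization writes the pixel containing the reported centre;
  collisions resolve last-written-wins with a logged counter, off-grid
  footprints are dropped and counted.
* **Scene-class zeroing** — labels on pixels classed bare or water are
  forced to 0 m, mirroring the geolocation-noise correction applied to the
  real reference data.

What the generator does *not* emulate: radiative-transfer effects,
phenology/seasonality, orbit geometry, terrain slope and sensor-specific
artefacts. Passing end-to-end tests therefore demonstrates that the
estimator, losses, fusion and calibration machinery are correct and that
the method recovers height when its assumptions hold — not that any
particular accuracy transfers to real archives.

# Numerical and schedule choices

* Desk-scale schedule: the deployment schedule (5 M iterations, base
  learning rate 1e-4, decay 0.1 at 2 M and 3.5 M) is scaled by keeping the
  milestone *fractions* (0.4, 0.7) and batch size 64 while shortening the
  run; for runs of a few thousand iterations the base rate is raised to
  1e-3, which converges reliably on the synthetic sets.
* End-to-end recovery is scored against the **GEDI-like canopy top of the
  true field** (circular max-pool at the footprint radius), not the raw
  per-pixel height: the labels are footprint disc maxima, so the footprint
  maximum is what the estimator is trained to produce — each map pixel
  effectively carries the largest canopy top within a footprint centred on
  it. Against the raw field the estimator would look biased high by
  construction.
* End-to-end experiments use 500 training scenes of 15 x 15 px with T = 10
  dates (~5,000 usable scene-date patches), a 3-member small-profile
  ensemble at 2,000 iterations plus 500 mean-head fine-tuning iterations,
  and 60 held-out scenes — sizes chosen so the full study runs comfortably
  on a single workstation core while leaving the tall stratum populated
  enough (hundreds of >30-m pixels) for the bias checks.
* Determinism: every stochastic step (field, rendering, footprints,
  initialization, batch sampling, member assignment) is seeded and restores
  the caller's RNG state; two runs with one seed are bit-identical.
* Degenerate inputs: a batch with zero labelled pixels raises an error (a
  silent 0 would corrupt the running loss); a non-finite loss aborts with
  iteration diagnostics; an all-cloudy stack returns an all-nodata map with
  a warning rather than failing.
* Export: the product height band is unsigned 8-bit whole metres
  (round-half-even) clipped to [0, 254] with 255 = nodata; the predictive
  standard deviation is stored in whole centimetres (uint16). Both round
  trip bit-identically; a lossless float TSV export exists for analysis.
  Rasters travel as plain TIFF plus a JSON georeference sidecar, with
  reflectance stored as the conventional 1e4-scaled digital numbers.

# Known limitations

* The simulator's band links are monotone in height by construction; real
  spectra saturate harder and confound height with composition, moisture
  and illumination. Absolute synthetic accuracies are therefore optimistic
  and are never compared against real-archive numbers.
* Calibration is assessed globally; per-region re-calibration (advisable in
  deployment) is a diagnostic here, not an automatic correction.
* The equirectangular pixel georeference is adequate for patch/tile scales
  but not for continental mosaics.
* Orbit/tile scheduling and archive access are out of scope; the
  acquisition catalog abstraction (`selectImages()`) replaces them.
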