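---
title: "Quantifying perinuclear chromatin-mark accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perinuclear chromatin-mark accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(perinuc)
library(dplyr)
```

## The measurement

In fluorescence images of cultured-cell nuclei, repressive chromatin marks
such as H3K27me3 sometimes concentrate in a shell just inside the nuclear
envelope instead of distributing through the nucleoplasm. `perinuc`
quantifies this *perinuclear accumulation* per nucleus:

1. An ellipse is fitted to the nucleus mask — the moments-equivalent
   ellipse, i.e. the ellipse with the same centroid and normalized second
   central moments as the mask foreground.
2. The ellipse interior is divided into three concentric elliptic regions,
   equally spaced in *normalized elliptic radius*
   $r = \sqrt{(u/a)^2 + (v/b)^2}$ (0 at the center, 1 on the boundary), so
   the ring boundaries sit at $r = 1/3, 2/3, 1$.
3. The mean pixel intensity of the mark channel is taken over the outermost
   (perinuclear) and innermost (central) regions, and their ratio

   $$\rho = \frac{\bar I_{\text{outer}}}{\bar I_{\text{inner}}}$$

   classifies the nucleus as *accumulating* when $\rho > 2$ — a strict
   inequality, so $\rho = 2$ is not accumulating. The middle ring never
   enters the statistic; it is reported for diagnostics only.
4. Nuclei with aberrant morphology — masks an ellipse does not fit — are
   excluded before classification.

Conditions are then summarized as the fraction of (included) nuclei
classified accumulating, overall and per biological replicate.

Alongside the classifier the package implements the companion
quantifications used in the same experimental programme: counting
PLA (proximity ligation assay) puncta that overlap the perinuclear lamin
rim, measuring the colocalization area of two channels within a nucleus,
internal-standard lipid quantification with the PA/PE ratio, relative
expression by $2^{-\Delta\Delta C_t}$, and the group statistics (two-tailed
unpaired t test; one-way ANOVA followed by Dunnett's test, significance at
p < 0.05).

## Design choices where the procedure was open

The verbal description of the assay leaves several details open; the
package fixes them as follows.

**Equal spacing.** "Equally spaced" concentric regions is read as equal
spacing in normalized radius — every ring has the same thickness along each
radial direction, matching a construction that starts from the nuclear
boundary and steps inward. The alternative, rings of equal area
(boundaries $\sqrt{k/n}$), is available via `spacing = "area"` in
`partition_rings()` but is not the default.

**Ellipse, not free-hand outline.** Scoring is performed over the fitted
ellipse's interior rather than the raw mask, so the three regions are
exactly elliptic. The mask enters twice: it determines the fitted ellipse,
and its Jaccard overlap with the ellipse interior defines fit quality.

**Aberrant morphology.** Exclusion is operationalized as
$J(\text{mask}, \text{ellipse}) < 0.85$ (configurable), a single
scale-free criterion: lobed, blebbed or crescent nuclei score low, clean
ellipses score near 1. On clean rasterized ellipses $J$ exceeds 0.98, so
the default threshold only removes genuinely non-elliptic shapes.

**Pixel membership.** Pixels belong to a region when their *center* falls
in the half-open radial interval $((k-1)/n,\, k/n]$, with $r = 0$ assigned
to the innermost region; coordinates are 0-based with pixel centers at
integer positions. This removes boundary double-counting: the three rings
are pairwise disjoint and their union is exactly the pixel set with
$r \le 1$, a property the tests assert pixel-exactly against an
independent per-pixel binning oracle.

**Degenerate inputs.** Empty masks and masks without two-dimensional
extent (a single pixel, a collinear run) are rejected with distinct
errors. Masks with several 8-connected components are reduced to the
largest component with a warning. A mean central intensity of zero
excludes the nucleus ("zero central intensity") rather than producing an
infinite ratio, and regions smaller than 10 px (configurable) exclude it
as "region too small". No background subtraction is applied by default —
an optional constant-offset subtraction exists — and because a positive
offset pulls every ratio toward 1, offsets make the classifier
conservative, never liberal.

**Perinuclear spot overlap.** "Overlap with the perinuclear lamin rim" is
operationalized as membership of the spot *center's pixel* in a
perinuclear region mask: the outer ring, dilated outward by a configurable
radius (default 2 px in the pipeline) to admit signal at or just outside
the fitted boundary, and optionally intersected with the Otsu-thresholded
lamin foreground inside a band around the boundary. Center membership,
rather than any-pixel overlap of a spot disc, keeps the count deterministic
and coherent with sub-pixel localization.

**Spot detection.** Spots are detected by multiscale scale-normalized
Laplacian-of-Gaussian filtering (scales 1–3 px by default, matching
diffraction-limited puncta at 0.05–0.1 µm sampling), local-maximum
selection above a threshold, and sub-pixel refinement by a three-point
parabola in each axis. The threshold has two parts: a fraction (0.1) of
the channel's dynamic range, and a robust noise floor of 5 median absolute
deviations of the per-scale response — the latter is inactive on noiseless
images and suppresses isolated noise maxima on noisy ones. Detections
closer than the minimum separation are merged keeping the stronger
response.

**Colocalization.** Within the nucleus mask each channel is thresholded
(per-channel Otsu by default; fixed thresholds for full reproducibility)
and the overlap area of the two foregrounds is reported in µm² (and px²).
The measure is symmetric in its channels and can never exceed either
single-channel area.

## What the simulator emulates

`synthetic_config()` / `generate_image()` generate the statistical
structure the pipeline assumes, with complete ground truth:

* **Nuclei** as non-overlapping ellipses, semi-axes a ∈ [80, 110] px and
  b ∈ [55, 80] px at 0.05 µm/px (major axes of 8–11 µm), up to 8 per
  1024×1024 field by default.
* **Histone channel** piecewise-constant in normalized radius: the inner
  value (default 100) for $r \le 2/3$ and $E \times$ inner for
  $2/3 < r \le 1$. The middle ring deliberately takes the inner value —
  the statistic ignores it — and the noiseless perinuclear/central ratio
  therefore equals the enrichment parameter $E$ *exactly*, which makes
  parameter-recovery tests sharp. A `rim_gaussian` profile adds the
  enrichment as a boundary ridge instead; its true ratio is integrated
  numerically into the ground truth.
* **Lamin channel** as a Gaussian ridge of constant physical thickness
  (sd 2 px) centered on the ellipse boundary, using the first-order
  Euclidean distance $(r-1)/|\nabla r|$.
* **Spot channel** with Gaussian puncta (σ 1.5 px, amplitude 150), placed
  perinuclear (outer band) with a configurable probability, else central;
  placements keep 2 px clear of the ring boundaries so each spot's band
  remains unambiguous under pixel-center rounding, and respect a minimum
  separation (default 6 px).
* **Replication channel** with larger foci for colocalization tests.
* **Camera noise**: Poisson shot noise with gain $g$
  (pixel $\sim g\,\mathrm{Pois}(\mu/g)$) plus Gaussian read noise
  (sd 3 DN); a flat region's variance is $g\mu + \sigma^2$, which the
  tests verify. Intensities written to disk are 16-bit digital numbers,
  clamped at 0 — as a real camera clips.

Every draw comes from a single seeded generator, so identical
configurations are bit-identical, and `generate_dataset()` writes images,
masks, truth tables and the resolved configuration together.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: optical blur of the histone/DNA channels
(region edges are sharp in $r$), intra-nuclear texture such as chromocenters
or nucleoli, autofluorescence gradients, segmentation errors in the input
masks (masks come from the true ellipses), spectral bleed-through, and
spot-intensity heterogeneity. Results on real images depend on mask
quality and background structure in ways the synthetic benchmark cannot
certify.

## A worked run

```{r worked, fig.width = 5, fig.height = 4}
cfg_lo <- synthetic_config(image_shape = c(512, 512), n_nuclei = 2,
                           enrichment = 1, seed = 1)
cfg_hi <- synthetic_config(image_shape = c(512, 512), n_nuclei = 2,
                           enrichment = 3, seed = 2)
g_lo <- generate_image(cfg_lo, channels = "histone")
g_hi <- generate_image(cfg_hi, channels = "histone")

scores <- bind_rows(
  score_image(g_lo$channels$histone, g_lo$mask) |> mutate(condition = "E = 1"),
  score_image(g_hi$channels$histone, g_hi$mask) |> mutate(condition = "E = 3"))
scores |> select(condition, nucleus_id, mean_inner, mean_outer,
                 ratio, accumulating)

summarize_condition(scores |> filter(condition == "E = 3"), "E = 3")
```

```{r plots, fig.width = 5, fig.height = 3.5, eval = FALSE}
autoplot(score_image(g_hi$channels$histone, g_hi$mask))
```

## Problem sizes used in the validation suite

The shipped tests and the acceptance script validate on: a decision-boundary
sweep of 301 noiseless ratio levels; 100 random ellipses for the
partition-oracle equivalence; circles of radius 50–100 px for the analytic
annulus-area limit; 100 simulated nuclei per enrichment level
$E \in \{1, 1.5, 2, 3\}$ (200 for the two classification extremes) under
default noise, in 2048×2048 fields of 25 nuclei; three 512×512 fields of
50 puncta at peak SNR 10 for detector recall/precision/localization; and
1,000 null simulations of three groups of 10 for the Dunnett family-wise
error rate. These sizes keep each stage's Monte-Carlo error well below the
tolerances being asserted (e.g. binomial sd ≈ 0.7 % at n = 1,000).

## Known limitations

* The ellipse is fitted from moments, so for strongly non-elliptic masks
  the "ellipse" is only a second-moment summary — which is precisely why
  such nuclei are excluded by the Jaccard criterion rather than scored.
* Ring membership at pixel resolution makes ring areas exact only in the
  large-nucleus limit; for circles the inner-ring pixel count is within
  0.3 % of the analytic value by radius 50 px, but very small nuclei
  (inner ring < 10 px) are excluded rather than scored.
* The LoG detector assumes roughly isotropic puncta within the configured
  scale range; elongated or clustered signals closer than the minimum
  separation are merged.
* Otsu thresholds adapt to each nucleus's intensity distribution; for
  cross-condition comparability of colocalization areas, fixed thresholds
  should be preferred.
* The ΔΔCt computation assumes equal amplification efficiency of target
  and reference; efficiency-corrected models are out of scope.
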