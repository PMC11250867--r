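---
title: "Quantifying chromogenic immunohistochemistry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromogenic immunohistochemistry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
library(dplyr)
```

## The measurement problem

Chromogenic immunohistochemistry (IHC) reports where an antibody binds
through a brown DAB precipitate, usually over a blue hematoxylin nuclear
counterstain. Turning such slides into numbers requires four things this
package provides: (i) separating the two chromogens from an RGB scan,
(ii) deciding whether the brown is specific at all — which only a
knockout-control comparison can establish, (iii) summarizing spatial
patterns (gradients along anatomical axes, per-cell and per-vessel
levels, percent positive area), and (iv) detecting subcellular puncta
such as necrosomes, the cytoplasmic RIPK1/RIPK3/Caspase-8 clusters that
form during necroptotic signalling.

Because real slide scans are large, proprietary and biologically
variable, the package ships a synthetic scene generator that renders
two-stain brightfield images through the same physical model the
unmixing assumes, with exact ground truth for every planted object.
Every quantification stage is validated against these scenes.

## Beer–Lambert mixing and H-DAB unmixing

Stains absorb, so they mix additively in optical density (OD), not in
RGB. A pixel with per-stain concentrations $A_s$ renders as

$$I_c = \mathrm{round}\!\left(255 \cdot 10^{-\sum_s M_{c,s} A_s}\right),
\qquad c \in \{R,G,B\},$$

where $M$ holds unit-norm OD stain vectors. We use the standard
published H-DAB preset — hematoxylin $\approx (0.650, 0.704, 0.286)$,
DAB $\approx (0.269, 0.568, 0.778)$, residual = their normalized cross
product — and make it user-overridable. Unmixing inverts the model:
$OD_c = -\log_{10}(\max(I_c, 1)/255)$, concentrations $M^{-1} \cdot OD$,
negatives clamped to zero. Renders quantize exactly once to 8-bit and
clamp OD at 3 (a transmittance below one gray level), mirroring the
dynamic range of brightfield scanners.

**Quantization limits.** One gray level at intensity $I$ spans about
$0.434/I$ OD, so recovery accuracy degrades at the dark end: across
random stain ODs up to 0.8 the render–unmix round trip is accurate to
about 0.01 OD, up to 1.0 about 0.025, and near (1.5, 1.5) — where the
green channel falls to intensity ~3 and one gray level spans ~0.125
OD — the worst-case error reaches ~0.08 OD regardless of decoder. The
test suite asserts the honest bounds; no decoder operating on the
8-bit image can do fundamentally better.

The inverted-gray convention used by every downstream stage maps a
stain's OD through its isolated transmittance,
`gray = 255 - round(255 * 10^(-OD))`, so 0 means no stain, 229 means
OD 1, and 255 the OD-3 clamp; 8-bit thresholds such as the 50–255
percent-area window are defined on this fixed scale.

## Knockout-controlled specificity (S/N index)

Brown color alone does not demonstrate specificity; matched wild-type
(WT) and knockout (KO) tissue on one slide does. The pipeline:
auto-threshold the WT hematoxylin channel (Otsu's between-class
variance criterion), dilate it with a Euclidean disc (default 5 px,
~1.4 µm at 0.27 µm/px) into a perinuclear area of interest, histogram
the DAB inverted-gray intensities of both images inside that mask,
normalize to frequencies (so section-area differences cancel), and
ratio bin by bin:

$$r_i = \frac{f^{WT}_i + \varepsilon}{f^{KO}_i + \varepsilon},
\qquad \text{index} = \sum_{i=0}^{255} \frac{i}{\sum_j j}\, r_i .$$

Design choices, made where the procedure is otherwise underdetermined:

- **Weights.** Intensity-proportional weights $w_i = i/\sum_j j$ make
  the high-intensity bins — where genuine chromogen accumulates —
  dominate, and give zero weight to the empty bin. Any fixed weighting
  yields a valid *relative* ranking of staining protocols, which is how
  the index is used; absolute values are not comparable across weight
  conventions.
- **Pseudocount.** $\varepsilon = 1/\min(n_{WT}, n_{KO})$ (one
  pixel's worth of frequency) keeps the curve finite in empty KO bins
  and makes the identity case exact: WT = KO gives $r \equiv 1$ and
  index exactly 1.
- Pairs in a batch must share one parameter record (stain matrix,
  dilation, pseudocount): the comparison is only meaningful between
  closely matched acquisitions.

## Zonation profiles

Expression gradients along anatomical axes (crypt→villus,
pericentral→periportal, white→red pulp) are measured with a wide-line
profile: a hand-drawn polyline sampled every 1 px of arc length, each
sample averaging the DAB inverted gray over a perpendicular segment
(27.4 µm by default, ≈ two cell widths; samples every 0.5 px, bilinear
interpolation). In this workflow — and only here, matching the order
of operations of the underlying protocol — each RGB channel is first
linearly rescaled from display range 0–235 to 0–255 before unmixing;
`rescale = FALSE` disables it.

Axis positions are normalized to [0, 1] before averaging because axes
differ in physical length; profiles are resampled to a common grid
(default 100 points) and averaged pointwise. The smoother is LOWESS
with tricube weights and two robustness iterations, span 0.3 — smooth
at ~100 samples without flattening crypt-tip structure; local linear
fitting reproduces exactly linear profiles to machine precision, a
property the tests assert. Both fitting modes are exposed: on the mean
profile (default) or on the pooled per-axis datapoints, since either
averaging convention is defensible. Group comparisons use per-position
unpaired pooled-variance t tests, reported without multiplicity
correction; positions with zero variance in both groups are flagged
rather than silently dropped.

## Object-level scoring

**Nuclei.** Otsu threshold on the hematoxylin channel, hole filling,
8-connected labelling, physical-area filter, then morphometrics.
Circularity is $4\pi A/P^2$ with the perimeter of the
moment-equivalent ellipse (second central moments plus the 1/12
per-pixel term, Ramanujan's approximation): raw pixel-edge perimeters
undershoot so badly that a perfect disk scores ~0.78, while this
estimator is rotation-invariant, exact for elliptical nuclei, and puts
a rasterized disk at ~0.999.

**Classification.** Hepatocyte-like ⇔ area ≥ 40 µm² *and* circularity
≥ 0.8 (inclusive); Kupffer-like ⇔ both strictly below; otherwise
`other`. The cuts are configurable; the defaults sit between typical
hepatocyte nuclei (~8–10 µm, round) and Kupffer nuclei (small,
elongated) and leave a wide margin on synthetic populations.

**Cytosolic signal.** A ring of 1.5 µm (default) around each nucleus,
excluding all nuclei; fully-overlapped rings are flagged and excluded.
Signal "per unit area" is reported both as mean intensity and as
summed intensity per µm² — identical up to the fixed pixel area; mean
intensity is the headline number.

**Vessels.** Within each user-chosen seed box: Otsu on the
smooth-muscle (SMA) channel, largest component, check that it encloses
a lumen, then measure DAB in a band 2 µm interior to the ring's inner
boundary. The band-interior reading was chosen because endothelium
lies luminal to the smooth muscle; measuring the ring itself would mix
in the muscle wall.

**Percent area.** The fraction of region pixels inside the inclusive
8-bit window 50–255 — a pure counting operation, tested for exact
agreement with a per-pixel loop.

## Puncta detection and the 2×-mean filter

Necrosome-like puncta are 2–6 px spots near scanner resolution. The
detector band-passes with a difference of Gaussians
($\sigma_s = 1.2$ px, $\sigma_l = 2\sigma_s$), takes local DoG maxima
above a 2-gray-unit technical floor inside labelled cells, and
suppresses the weaker of any two maxima closer than $\sigma_l$ (so a
merged pair yields one detection). Each punctum's amplitude is the
mean image intensity over a disk of radius $2\sigma_s$ at its maximum.
The biological filter keeps a punctum only if its amplitude strictly
exceeds **twice the mean signal of its parent cell**; the cell mean
includes punctum pixels by default (the literal reading), with an
option to exclude them. Cell segmentation is pluggable — any label
image is accepted; ground-truth labels serve in the synthetic tests.

Summaries report percent of cells with ≥1 punctum, the per-cell count
vector, and per-region rates per 100 cells (a region with no cells is
excluded with a flag).

## The synthetic scene generator

Scenes are parametric: elliptical nuclei (geometric-mean radius and
eccentricity; hepatocyte-like = 4.5 µm round, Kupffer-like = 2 × 6 µm
ellipse), cytoplasm disks around nuclei carrying constant, per-cell or
axis-graded DAB, isotropic Gaussian puncta in OD space (σ = 1.5 px
planted against the 1.2 px detector), vessel rings with an interior
endothelial band, small constant background OD (0.02 hematoxylin,
0.01 DAB), and an optional additive Gaussian intensity noise term
(default off, so tests are exact). A knockout render zeroes exactly
the target-specific DAB terms and nothing else. Puncta benchmarks
calibrate planted peak ODs numerically (two fixed-point passes of a
root solve) so each punctum's *measured* footprint amplitude is a
stated multiple of its cell's mean — 3× for true puncta, 1.5× for
decoys — straddling the 2× rule with wide margins.

What the generator does *not* emulate: texture, chromatic aberration,
uneven illumination, stain variation between labs, scanner compression
artifacts, crowded/overlapping nuclei, and tissue autofluorescence
equivalents. Passing tests therefore demonstrate algorithmic
correctness under the stated optical model, not robustness to every
real-slide artifact; stain-vector mismatch in particular must be
handled by supplying a calibrated matrix.

## Numerical choices and degenerate inputs

- Rendering quantizes once; no intermediate rounding.
- Otsu requires a nonconstant image and errors otherwise; a blank
  segmentation input yields an empty record set, not an error.
- Dilation uses exact Euclidean disc offsets ($dx^2+dy^2 \le r^2$);
  radius 0 is the identity.
- Ties in the zone-score cluster selection break by ascending cluster
  id; the eligibility rule reads "top five scores within the Xth
  percentile of the maximum" as score ≥ X% of the maximum, since a
  distribution percentile is incoherent for a handful of clusters.
- All simulation randomness flows through explicit integer seeds; the
  generator restores the caller's RNG state.
- Problem sizes used in the shipped validation: 1000 random OD pairs
  for the round trip, 100 puncta scenes of 3 cells (plus one 60-cell
  scene for rates), 20 axes of 240 × 80 px gradient scenes, 200 random
  zone-score matrices, 500 cells per ontology group, 50 random
  percent-area images.

## Known limitations

- At most three stains, and no stain-vector estimation from the image
  (Macenko-style methods are out of scope).
- The S/N index's absolute scale depends on the declared weights and
  pseudocount; use it for relative comparisons only.
- The puncta detector is 2-D and single-scale-band; it does not claim
  to distinguish necrosomes from other protein clusters biologically.
- Axes and region outlines are user input; there is no automatic
  crypt/villus discovery or deep-learning segmentation.
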