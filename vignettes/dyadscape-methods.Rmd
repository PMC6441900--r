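---
title: "Measuring t-tubule architecture, dyads and local calcium release with dyadscape"
author: "dyadscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring t-tubule architecture, dyads and local calcium release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadscape)
```

`dyadscape` packages the image computations needed to quantify how the
cardiomyocyte t-tubule network, its dyadic junctions, and local Ca²⁺
release change between developing, adult and failing cells. This vignette
explains each measurement model, the parameters that matter, the numerical
decisions behind them, and what the synthetic-data module does and does not
establish about real data.

## 1. Tubule morphometry

A membrane-dye confocal image is processed in a fixed order:
rolling-ball background subtraction (radius 15 px), rotation of the cell
long axis to horizontal, linear contrast stretch with 0.8 % saturated
pixels, Mexican-hat ridge filtering (radius 3 px), median filtering over a
Euclidean disk (radius 1 px), and Otsu thresholding. Density is the
percentage of an interior ROI — the cell footprint eroded inward by 1 µm,
i.e. a region "just inside" the surface sarcolemma — covered by the tubule
mask. The mask restricted to the same interior ROI is thinned to a
one-pixel skeleton, split into branches at junction pixels, and each
branch is labelled *transverse* when its absolute angle to the image
vertical is at most 45° (after rotation the cell long axis is horizontal,
so transverse tubules run vertically), else *longitudinal*.

Implementation decisions worth knowing:

* **Rolling ball as greyscale opening.** The background estimate is a
  morphological opening with a disc of the stated radius — deterministic,
  flat-background-exact (a constant image maps to zero) and never
  increasing any pixel.
* **Mexican hat kernel.** The kernel is an inverted Laplacian of Gaussian
  on a square support of half-width `radiusPx` with σ = `radiusPx`/3, so
  the support truncates at ±3σ and the default radius 3 matches the 2–3 px
  apparent width of confocal t-tubules. Defining σ equal to the radius
  instead broadens every ridge: on noise-free phantoms the segmented mask
  then overlaps the rendered tubule object poorly (IoU ≈ 0.46) and density
  overshoots by ~6 points, whereas with σ = radius/3 the overlap exceeds
  0.7 and density agrees to ~0.5 points. The kernel is normalized to zero
  sum and negative responses are clipped.
* **Otsu on 256 equal-width bins** spanning the observed range, with class
  means computed from exact per-bin intensity sums. For quantized (8-bit)
  data the maximizing split provably coincides with an exhaustive search
  over all candidate grey-level thresholds; ties resolve to the lowest
  threshold. Constant images are an error, not a guess.
* **Orientation from second moments.** The long-axis angle comes from the
  second central moments of the filled, largest connected Otsu component;
  perfectly circular footprints give 0° by the `atan2` convention.
  Rotation is bilinear with zero padding, and the output canvas encloses
  the rotated frame.
* **Skeleton accounting.** Branch path length uses the 8-connected step
  metric (1 or √2 pixels per step, summed over a minimum spanning tree so
  the spurious diagonal chord at a turn is not double counted). Junction
  pixels (≥ 3 skeleton neighbours) belong to no branch and are reported
  separately. Branches shorter than 3 px inherit the label of their
  longest junction-neighbour; ties and isolated short branches default to
  transverse.
* **Organization is measured inside the interior ROI**, as density is.
  The bright surface sarcolemma segments like any membrane and would
  otherwise contribute long "longitudinal" branches that are not
  t-tubules.

## 2. Dyadic colocalization

Two aligned channels (RyR and LTCC, or RyR and a tubule marker) are
background-subtracted (rolling ball, 20 px) and cleared outside the cell
ROI. The Manders coefficient M1 — the fraction of above-threshold LTCC
intensity found at pixels also above the RyR threshold — together with its
mirror M2 quantifies fractional overlap. Thresholds are generated by the
Costes regression procedure: a reduced-major-axis regression of LTCC on
RyR defines a line through the joint histogram, and the threshold is
lowered from the maximum until the correlation of below-threshold pixels
is statistically indistinguishable from zero (ρ ≤ 2.5/√n). The
significance form matters: on clean, densely labelled images the
below-threshold correlation has a long flat tail hovering a few
thousandths above zero, and a strict ρ ≤ 0 rule walks into the noise floor
at a seed-dependent point, flipping thresholds (and densities) by an order
of magnitude. When the correlation never reaches the band, the threshold
of minimal ρ is used; per-channel Otsu is the fallback only when the
regression is inapplicable (non-positive covariance). Reduced-major-axis
regression is used because it is equivariant under rescaling either
channel, which makes M1/M2 exactly invariant to acquisition gain.

Orientation-specific analysis builds a single *transverse territory*: the
RyR channel is processed, binarized, closed (0.5 µm default — bridging a
single missing cluster at the typical 0.6 µm pitch without merging
neighbouring Z-lines at 1.8 µm), skeletonized and labelled as in module 1;
the transverse skeleton is then dilated with a 17×1 vertical and a 1×13
horizontal line kernel and binarized. Fluorescence inside the territory is
transverse; the longitudinal compartment is its complement within the ROI.
The complement matters for measurement: a non-dyadic LTCC displaced along
its tubule must stay in the longitudinal denominator to be counted as
non-colocalized — a narrow per-skeleton longitudinal band loses those
pixels and the longitudinal M1 saturates towards 1 regardless of the true
fraction. A per-skeleton longitudinal band remains available
(`longitudinal = "skeleton"`). Kernel sizes are in pixels at Airyscan-like
sampling (34–71 nm) and should be rescaled for other pixel sizes. Both
orientation M1 values reuse the cell-wide automatic thresholds, so
"signal" means the same thing in both compartments.

Protein densities are the percentage of the nucleus-excluded ROI above
threshold (the Manders thresholds for a matched analysis, Otsu by
default); the dyadic density is exactly LTCC density × M1. Nearest-LTCC
distances evaluate the Euclidean distance transform of the LTCC mask at
every RyR pixel; here the default thresholds are per-channel Otsu, because
positional analysis needs object-level masks — under the permissive
overlap thresholds a fifth of the ROI can be "LTCC" and stray background
pixels sit within the 0.5 µm orphan cutoff of every RyR. Distances are
per-pixel, not per cluster centroid, so no clustering step is required.

Known bias: the per-orientation M1 of a strongly coupled cell reads
slightly low (≈ 0.82 for a truth of 0.9 under the default synthetic
conditions) because the territory denominator honestly includes displaced
LTCC and residual background intensity. Parameter-recovery checks
therefore assert the across-seed mean within ±0.1 and the
transverse-greater-than-longitudinal ordering per seed.

## 3. Ca²⁺ release kinetics

The global transient is the ROI-mean trace; baseline F₀ is the mean of the
pre-stimulus frames, F₅₀ lies halfway between baseline and the
post-stimulus peak, and crossing times are linearly interpolated between
frames. The dyssynchrony map computes, per pixel after 3×3 spatial
smoothing, the time from the stimulus to the pixel's own half-maximal
crossing; the dyssynchrony index (DI) is the population standard deviation
of those times over pixels with a valid crossing (population form so that
the two-half-cell case with 10 and 30 ms gives exactly 10 ms; IQR is
available as an alternative). Pixels without a crossing are excluded and
counted, and a map with more than half its ROI excluded is flagged
unreliable. DI is invariant to intensity offset and gain by construction.

Local sites are 1×1 µm boxes (rounded to odd pixel counts) centred on
transverse or longitudinal skeleton pixels of a co-acquired membrane-dye
frame (segmented without rotation, to stay in register with the video), or
— for *orphaned* sites — on local maxima of the distance-to-skeleton field
exceeding 1.2 µm. The cutoff must exceed half the sarcomere pitch
(0.9 µm), otherwise the centre of every intact sarcomere would qualify;
1.2 µm admits genuine gaps (a single missing Z-line leaves a ≥ 1.8 µm
hole) while rejecting the intact lattice. Site selection is deterministic
(evenly spaced along the candidates), so results do not depend on an RNG.

TTF₅₀ is the time from the start of the Ca²⁺ rise to the site trace's
crossing of the *global* F₅₀ level. The reference "start of rise" is the
global transient's onset (sustained excursion above baseline + 2 SD for
≥ 2 frames). Using each site's own onset instead would subtract any
release delay from its own timing — a site delayed by d ms would report
the same TTF₅₀ as an undelayed one — so the local-onset variant (provided
as `reference = "local"`) cannot resolve delayed orphaned release; the
global reference reports the full delay. Non-responding sites (never
reaching the global F₅₀) are flagged rather than imputed.

## 4. Voltage-dye tubule activation

The three frames before contraction are restricted to the skeleton
pixels, each pixel is normalized by the first frame of the recording
(F/F₀), the pooled values are Otsu-thresholded, and a skeleton pixel is
depolarized when above threshold in at least one of the three frames
("all three" is available). Pixels with non-positive F₀ are excluded and
counted; more than 20 % excluded flags the result. Because F/F₀ of a
resting pixel is exactly 1, the Otsu split is calibrated against that
anchor: when even the lower class lies clearly above 1 (mean > 1 + 3 SD)
the distribution is a unimodal step and the whole skeleton is called
depolarized — a histogram split would otherwise halve a fully activated
network — and when even the upper class sits at baseline the result is 0
with a `no-signal` flag. The contraction frame can be auto-detected as the
first frame whose mean absolute frame difference (normalized by the
previous frame's mean) exceeds the baseline mean + 3 SD; note that a
large, sharp electrical fluorescence step can also trigger this metric,
so supply the frame explicitly when the optical onset precedes motion.

## 5. Surface topography

Z-spine annotation tables give two cell-level indices: the Z-groove index,
total crest length divided by total Z-spine length (ratio of sums, not a
mean of per-spine ratios, so long spines carry their proper weight), and
the fraction of Z-spines with a visible t-tubule lumen. Records violating
the geometry (crest longer than its spine, non-positive lengths) fail
validation naming the offending spine.

## 6. The synthetic-data module

The generators are the package's test bench. They emulate, with a fixed
seed and bit-reproducible output:

* **Tubule images** (default 0.16 µm/px): a superelliptical cell with a
  bright sarcolemma outline, transverse tubules at jittered Z-line
  positions (1.8 µm pitch, ≤ 5 % jitter, occupancy 0–1), longitudinal
  connectors at a set areal density, dilation to a 0.4 µm tubule width,
  Gaussian PSF (σ 0.18 µm), and Poisson-like noise
  (variance = intensity / `photonScale`, plus read noise).
* **Dyad pairs** (default 0.05 µm/px, so the 17/13 px kernels apply
  unscaled): beaded RyR cluster rows along Z-lines (0.6 µm pitch) and
  along longitudinal segments placed strictly between Z-lines; a
  per-orientation fraction of LTCC partners is placed coincident (15 nm
  offset — dyad partners face each other across a cleft far below optical
  resolution — with correlated brightness, as packed dyads carry more of
  both proteins), and the remainder is displaced along its own tubule
  membrane into RyR-free stretches (≥ 0.45 µm from any cluster). The
  exclusion is what keeps the ground-truth label honest: a "displaced"
  punctum rendered on top of a neighbouring RyR cluster *is* colocalized
  as imaged, and no measurement could then recover the programmed
  fraction. Channel-independent nonspecific background texture
  (amplitude 8) plays the role nonspecific antibody binding plays in real
  immunostains: it decorrelates the channels at low intensity and anchors
  the automatic thresholds; without it the coincident PSF halos correlate
  at every level and regression thresholding is ill-posed. Orphan gaps are
  Z-line stretches that keep RyR but lose their LTCC partners.
* **Ca²⁺ videos** (1.5 ms/frame): each pixel follows
  baseline + A·(1 − e^(−(t−t₀)/τᵣ))·e^(−(t−t₀)/τ_d) with
  t₀ = stimulus + site delay of the nearest ~1 µm skeleton segment +
  distance-to-tubule / propagation speed. Adding the propagation term on
  top of the nearest site's delay (rather than replacing it) keeps the
  delay field's dispersion equal to the programmed site-delay SD in the
  fast-propagation limit and makes orphaned regions late relative to the
  tubules that actually feed them. A registered membrane frame of the same
  network accompanies every video. With ~100 release sites per cell the
  realized delay-field SD varies by about ±1 ms around the programmed
  value; recovery checks compare each cell against its own realized field.
* **Voltage videos** (10 ms/frame): a random subset of skeleton branches
  (topped up pixel-wise to hit the requested fraction exactly) steps up by
  12 % at the onset frame; rigid translation models contraction; the truth
  set stores the depolarized skeleton pixels.

Phenotype presets (`developing`, `adult`, `hf`) fix illustrative parameter
sets — sparse, longitudinal-leaning, slow and propagation-limited for
developing; dense, transverse-dominant, tightly coupled and fast for
adult; reduced transverse occupancy, orphan gaps, large site delays and
slow propagation for failing — chosen so the pipelines face the
qualitative contrasts they are meant to resolve, not fitted to any
data set.

**What passing tests do and do not show.** The generators prove that the
implementations recover known truth under controlled imaging physics:
blur, photon noise, background, nonspecific labelling, jitter. They do not
capture optical sectioning of a 3-D network, depth-dependent aberrations,
motion within the exposure, cell-to-cell variation in labelling
efficiency, or RyR cluster substructure below the PSF. Absolute numbers
from real micrographs therefore inherit the biases of the measurement
chain (see below), and group comparisons should rely on consistent
acquisition settings.

## 7. Problem sizes, degeneracies, limitations

The test-bench conditions use cells of roughly 16–28 µm × 8–13 µm at
0.05–0.16 µm/px and videos of 24–160 frames; these sizes resolve every
programmed contrast while keeping a full verification run in minutes on a
single core.

Degenerate inputs have defined behaviour: constant images fail Otsu with
an explicit message and pass through contrast enhancement unchanged; an
empty skeleton makes orientation fractions an error and orientation masks
empty-but-flagged; flat transients, non-responding sites, motionless
videos and zero-F₀ pixels are flagged, not imputed.

Known limitations: segmented tubule masks ride the ridge core and
underestimate object density by ~1.5–3 points, more on mesh-like networks
whose spacing approaches the ridge-filter support; noise-free mask IoU
against the rendered object saturates near 0.7–0.75 for the same reason.
Per-orientation M1 carries the small negative bias discussed in § 2. The
Costes procedure on densely labelled images is intrinsically
threshold-soft; the significance-based stop makes it reproducible, not
sharp. The motion metric cannot distinguish a large global fluorescence
step from contraction. None of these affect the *orderings* between
phenotypes, which is how the measurements are meant to be used.
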