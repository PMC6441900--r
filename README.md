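# dyadscape

Quantitative image analysis of cardiomyocyte t-tubule architecture, dyadic
protein organization, and local Ca²⁺ release.

## What it is for

Cardiomyocyte contraction depends on dyads: junctions where L-type Ca²⁺
channels (LTCC) in t-tubule membranes face ryanodine receptors (RyR) of the
sarcoplasmic reticulum across a ~15 nm cleft. During postnatal development
the t-tubule network grows and dyads are packed; in heart failure the
network disorganizes, RyR clusters become "orphaned" at gaps between
transverse tubules, and Ca²⁺ release turns slow and dyssynchronous.
`dyadscape` provides the measurement pipelines a lab needs to quantify
those changes from fluorescence microscopy:

* **Tubule morphometry** — membrane-dye confocal images are
  background-subtracted (rolling ball, 15 px), rotated so the cell long
  axis is horizontal, contrast-stretched to 0.8 % saturated pixels,
  ridge-filtered (Mexican hat, radius 3), median-filtered (radius 1) and
  Otsu-thresholded. Density is the mask fraction inside an ROI traced just
  inside the surface sarcolemma; the skeletonized network is decomposed
  into transverse vs longitudinal branch length (45° rule).
* **Dyadic colocalization** — two-channel immunostains (RyR / LTCC) yield
  Manders fractional-overlap coefficients under automatic Costes
  regression thresholds,

  M1 = Σᵢ Lᵢ [Lᵢ > t_L, Rᵢ > t_R] / Σᵢ Lᵢ [Lᵢ > t_L],

  orientation-resolved M1 via territory masks built from the skeletonized
  RyR channel (17×17 vertical / 13×13 horizontal line kernels), protein
  %-area densities with nuclei excluded, nearest-LTCC distance maps for
  every RyR pixel, and the dyadic density

  dyadic density (% area) = LTCC density (% area) × M1.
* **Ca²⁺ release kinetics** — rapid 2D time-lapse stacks (1.5 ms/frame)
  give whole-cell transients (F₅₀, time to peak), per-pixel
  time-to-half-max maps whose dispersion is the dyssynchrony index (DI),
  and local transient timing (TTF₅₀) in 1×1 µm boxes centred on
  transverse, longitudinal or orphaned sites.
* **Voltage-dye activation** — FluoVolt stacks (10 ms/frame) give the
  fraction of the skeletonized tubule network whose F/F₀ rises above an
  Otsu threshold in the three frames before contraction.
* **Surface topography** — Z-groove index (crest length / Z-spine length)
  and t-tubule opening fraction from SEM annotation tables.

A seeded synthetic-data module simulates developing, adult and failing
phenotypes — striated networks at sarcomere spacing, paired punctate
channels with programmable colocalized fractions, Ca²⁺ videos with
site-wise release delays and propagation-limited orphans, voltage videos
with a programmable depolarized fraction — each with a ground-truth
sidecar, so every measurement stage is verifiable without external data.

## Worked example

```r
library(dyadscape)

## simulate an adult cell and measure its t-tubule network
g   <- generateTubuleImage(phenotypePreset("adult", "tubules", seed = 3))
res <- tubuleMetrics(g$image)
res$metrics
#> TubuleMetrics: density 28.1%, transverse 0.89 / longitudinal 0.11, skeleton 143.1 um
res$skeleton
#> TubuleSkeleton: 1001 px, 43 branches (33 transverse / 10 longitudinal), 73 junction px
c(g$truth$transverseFraction, g$truth$densityPercent)  # generator truth
#> [1]  0.842 28.590

## dyadic organization of a simulated RyR/LTCC pair
d  <- generateDyadPair(phenotypePreset("adult", "dyads", seed = 3))
dyadMetrics(d$pair)
#> DyadMetrics: LTCC 32.20%, RyR 33.33%, M1 0.732 -> dyadic 23.55%
#>   (M1 transverse 0.891 / longitudinal 0.322)

## dyssynchrony of a failing-phenotype Ca2+ video
cs <- phenotypePreset("hf", "calcium", seed = 3)
v  <- generateCalciumVideo(cs)
dyssynchronyMap(v$video, v$truth$footprint, cs$stimulusFrame)
#> DIMap: DI = 11.27 ms (sd over 5909 px, 0 excluded)
```

The measured transverse fraction (0.89) and density (28.1 %) recover the
generator's ground truth (0.84, 28.6 %); the adult pair's transverse M1
(0.89) sits near the programmed 0.9 while longitudinal dyads are sparse
(0.32 vs programmed 0.3); the failing cell's DI (11.3 ms) reflects its
programmed site-delay dispersion.

A command-line wrapper is installed with the package
(`system.file("scripts", "dyadscape", package = "dyadscape")`), with
subcommands `tubules`, `dyads`, `calcium`, `voltage`, `topography`,
`simulate` and `batch` operating on TIFF/CSV files.

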