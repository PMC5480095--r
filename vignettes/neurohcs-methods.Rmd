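---
title: "Morphofunctional profiling of neuronal cultures: models and methods"
author: "neurohcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphofunctional profiling of neuronal cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`neurohcs` re-implements, as a tested and reusable pipeline, the analysis
layer of a high-content screen of primary neuronal cultures: morphology
readouts from fixed multi-channel fields (cytotoxicity, neurite density,
synapse density, tubulin intensity ratios and colocalization, fibrillar-Tau
load), functional readouts from calcium time-lapse recordings (percentage of
active neurons, synchronous burst frequency, burst correlation), microtubule
growth velocity from EB3 comet kymographs, and the per-well nonparametric
statistics used to compare treatment groups. Because such screens rarely
deposit raw images, the package ships a synthetic-data generator that renders
every input with known ground truth; all quantitative claims about the
pipeline are made, and tested, against that ground truth.

## Data model

A well is a 5D dataset: 16 fields on a 4 x 4 grid, each field a multi-channel
z-stack (up to 4 channels, at least 6 axial planes at 1 um spacing).
Downstream analysis always operates on maximum-intensity projections; no
other projection is offered. Fields remain independent analysis units - the
grid is never stitched. All analysis parameters are stated in micrometres
and converted with the image's own calibration; when an image carries no
calibration the default 0.325 um/px (a typical 40x high-content
configuration) is used and the provenance is flagged. Coordinates are
pixel-centred, areas are pixel counts times the pixel area. Images are
written as 16-bit grayscale TIFF; the generator quantizes intensities to the
16-bit grid in memory, which makes load -> write -> load round trips
bit-exact.

## Morphology pipelines

All fixed-image workflows start from a rolling-ball-style background
subtraction, implemented as grayscale opening with a flat disc of radius 25
px (configurable; the radius must exceed foreground object scale).

**Cytotoxicity.** The nuclear counterstain is smoothed with a Gaussian of
radius 1.75 um, thresholded at a fixed, documented intensity (never
auto-chosen; 10% of the dynamic range by default), touching nuclei are
separated by a watershed on the distance transform, and objects below 90 um^2
are discarded as debris. A nucleus is dead when its mean propidium-iodide
intensity exceeds a second fixed threshold. A field without nuclei reports an
*undefined* percentage, never zero. The watershed stage conserves the
thresholded foreground exactly: the label areas before size filtering sum to
the mask area.

**Neurite mask.** Two masks are combined. Mask 1 is an Isodata threshold of
the background-subtracted marker image and captures the bright network core.
Mask 2 recovers the faint, fine processes: contrast-limited adaptive
histogram equalization with tiles of 1.8 um and clip limit 3, followed by
Laplacian edge enhancement (`image + |LoG response|`), again
Isodata-thresholded. With tiles this small, CLAHE amplifies read noise into
speckle; a light Gaussian pre-smoothing (0.8 px, configurable) is applied
before the equalization only. On synthetic fields this raised mask precision
from 0.40 to about 0.88 at unchanged recall (about 0.97). The network ROI is
the union of both masks; intensity ratios (acetylated over total tubulin,
phospho- over total Tau) and the Pearson colocalization coefficient are
computed inside it.

**Fibrillar-Tau load.** Curvilinear structures in the amyloid-dye channel
are enhanced with a Hessian ridge ("tubeness") filter at scale 3 px (the
plugin convention; a micrometre interpretation is available by flag),
thresholded with the Triangle criterion, and measured as particles. Kept
particles must be at least 15 um^2 with circularity in [0, 0.30], where
circularity is `4 pi area / perimeter^2` with a weighted-contour perimeter
estimator, clipped to [0, 1]. The load is the summed area of kept-particle
pixels *inside* the microtubule-network mask (pixel intersection; a
centroid-based alternative is provided). The intersection is load-bearing:
the thresholded support of a ridge response is systematically wider than the
underlying structure (the Triangle threshold sits just above the background
of a sparse-signal histogram), so an unmasked load overestimates areas by up
to a factor of ~3, while clipping to the network mask recovers the true
fibril area almost exactly. Ridge filters also respond to the rims of large
compact blobs; such rims again fall outside the network mask.

**Synapse density.** Puncta are detected by a Laplacian-of-Gaussian filter
at 0.35 um (response signed so bright puncta are maxima), Triangle
thresholding, and a 0.75 um^2 minimum-size filter; density is puncta per
um^2 of neurite area. A consequence of the optics worth stating: the
thresholded footprint of *any* detected punctum is bounded below by roughly
the LoG positive-lobe area, `2 pi sigma^2` which is 0.77 um^2 at the 0.35 um
scale. The minimum-size filter therefore rejects sub-lobe *noise* crossings
(it removes dozens per synthetic field) but cannot distinguish a true
punctum of 0.5 um^2 from one of 1 um^2 by measured area - sub-resolution
debris is excluded by response amplitude (it stays below threshold), not by
size. The synthetic small-spot rejection test documents this limit.

## Calcium analysis

Traces are per-ROI mean intensities. Normalization to dF/F0 uses a rolling
10th-percentile baseline over 30 s windows (evaluated on a coarse grid and
interpolated - the baseline is slowly varying by construction). Neurons are
gated by their response to glutamate applied in the last 20 s of the 260 s
recording (frames 481-520 at 2 fps): a cell is neuronal when its mean
stimulus-window dF/F0 exceeds 5 robust (MAD-based) SDs of its pre-stimulus
dF/F0. Recordings without a stimulus window (genetically encoded indicators
expressed only in neurons) skip gating, retain all cells, and are flagged.

Peaks are local maxima of the lightly smoothed dF/F0 (3-frame boxcar, about
one transient at 2 fps) exceeding the spontaneous-epoch median by `k_mad`
robust SDs with at least 0.05 dF/F0 prominence. The published analysis this
reconstructs does not state its threshold; we ship `k_mad = 5` because at
480 spontaneous frames a 3.5-SD threshold carries a per-trace family-wise
false-positive rate of about 0.18 (measured on pure-noise traces), which
structurally inflates the percentage of active neurons by ~7 points, whereas
5 SDs yields essentially zero false positives while planted transients (0.5
dF/F0 against 0.03 noise) remain far above threshold. All detection
parameters are configurable.

Network bursts are bins (1 s) in which at least 50% of the *active* neurons
fire, adjacent qualifying bins merged; the frequency denominator is the
spontaneous (non-stimulus) duration. Both the bin width and the
participation fraction are reconstructions and configurable. Burst
correlation is the mean off-diagonal entry of the pairwise Pearson matrix of
the neurons' continuous dF/F0 traces on the spontaneous epoch - all gated
neurons by default, active-only by flag. Fewer than 5 active neurons in a
field marks the network metrics "not determined" (ND); ND fields are
excluded from well means with their count reported. Subpopulation analysis
(e.g. aggregate-bearing vs. spared neurons in the same field) computes every
metric per subgroup plus each subgroup's correlation with the whole-network
mean trace. Two transients closer than about 1.5 s can merge at 2 fps
sampling, so burst counts carry a small negative bias that stays within the
Poisson error of the planted rate.

## EB3 velocimetry

A kymograph resamples the user polyline at 1 px arclength steps; each entry
is the mean of 3 bilinear samples perpendicular to the path (averaging, not
maximum, across the line width). The faithful readout is manual: two streak
endpoints give `|dx| * pixel_size / (dframe * interval)`. An automatic mode
- an extension for batch validation, clearly labelled as such - thresholds
the kymograph (Triangle), labels streaks, fits a line through per-frame
intensity-weighted centroids, and reports per-track velocities; parallel
streaks that merge into one component share a slope, so the fit remains
consistent. Velocity is orientation-free (absolute value); paths shorter
than the 20 um segment criterion warn.

## Statistics

Fields are averaged per well before any testing; the well mean is the
statistical unit throughout, and no normalization across biological
replicates or mixed modelling is applied. Per metric: Shapiro-Wilk per group
(normality record), then a tie-corrected Kruskal-Wallis omnibus test.
Post-hoc tests run only when the omnibus test rejects at alpha = 0.05 (the
gatekeeping alpha is not stated by the convention we mirror; 0.05 follows
from its significance marks). With a designated control the post-hoc is
Steel's many-to-one rank test; otherwise Dunn's all-pairs joint-rank test
with Bonferroni adjustment. Ties take midranks with tie-corrected variances
everywhere. Significance tiers are `*` p < 0.05 and `**` p < 0.005.

Steel's test standardizes each treatment-vs-control pairwise rank sum and
refers the *maximum* absolute statistic to its joint null. The default
reference is a seeded Monte-Carlo permutation of group labels (10^4
permutations by default; the inner loop is compiled) because closed-form
critical values for small unequal samples with ties are not standardized; a
fast alternative uses the equicorrelated multivariate-normal approximation
(`lambda_i = sqrt(n_i / (n_i + n_0))`, evaluated by one-dimensional
quadrature). The permutation route matters at screen-typical sizes: with 6
wells per group, a completely separated treatment has permutation tail
probability about `2 k / C(12, 6)` for `k` comparisons - below the 0.005
tier for two treatments, but not for three, and the normal approximation is
2-3x conservative there. Dunn's Bonferroni-adjusted test cannot reach 0.005
at n = 6 at all (its minimum adjusted p is about 0.01); strong-tier claims
at these sample sizes are a property of the Steel procedure.

## Synthetic data: what it emulates, and what it does not

Each generator renders a ground-truth object set and then the image or trace
with Gaussian read noise plus Poisson-like shot noise (no noise model is
published for the original data; both are exposed). Defaults were chosen
once, as a realistic regime, and the tests run against them:

* nuclei: 140 um^2 mean area ellipses (comfortably above the 90 um^2 debris
  cut), 60 per 1024 px field, matching typical plating density; a crowding
  parameter plants touching pairs for the watershed;
* neurites: random-walk tubes in two tiers - bright 4 px trunks and faint
  2 px branches - to exercise the dual-mask design; 2000 um of path per 512
  px field;
* acetylation channel: constructed inside the truth mask as
  `rho * z(tubulin) + sqrt(1 - rho^2) * noise`, so the within-mask sample
  correlation approaches the requested value by construction;
* puncta: 1.5 um^2 discs placed on the mask at the requested density with a
  minimum separation where space permits;
* fibrils: curved rods (width 2 um, length 25-45 um; circularity < 0.30 by
  construction, re-drawn otherwise) and compact discs (circularity > 0.6) as
  negative controls, kept at least ~15 px apart so ridge-response halos of
  distinct rods do not bridge;
* calcium: population burst times as a Poisson process (3/min default), each
  active neuron joining each burst with probability `sync_prob`; transients
  rise instantaneously and decay with tau = 1.5 s (about 3 frames at 2 fps);
  the glutamate response is a step of 3x the transient amplitude held to the
  end of the recording; 260 s at 2 fps with the last 20 s stimulated;
* comets: Gaussian spots advancing at constant velocity (0.2 um/s regime)
  along a gently curved 25 um path, one frame per 2 s for one minute.

Identical parameters and seed give bit-identical output. What the generator
does *not* emulate: realistic point-spread functions (blur is Gaussian),
photobleaching, stage drift, out-of-focus haze, autofluorescence texture, or
biologically structured background. Passing tests therefore demonstrate that
the algorithms recover known truth under controlled conditions - they do not
certify performance on real micrographs, where threshold behaviour (Triangle
in particular is shaped by mid-intensity background structure) can differ.

## Problem sizes and numerical choices

Tests and the acceptance script use 512 px fields for neurite, synapse and
fibril work and 1024 px fields where counting statistics or correlation
precision need the area (nuclei at realistic density, colocalization);
calcium studies use 20 recordings of 50 cells; null calibrations of the
testing scheme use 5,000-10,000 simulated datasets of 3 groups x 6 wells.
These sizes were chosen so the full suite characterizes every stage at
useful precision on a single CPU.

Degenerate inputs are contracts, not accidents: constant images refuse to
threshold; blank fields segment to empty maps; empty masks, zero
denominators, zero neurite area and all-ND wells yield flagged `NA`s;
classification without a stimulus window retains cells and flags the mode.
Histogram thresholds use 256 bins over the observed range; response images
whose dynamic range is numerically zero (< 1e-9 relative) are treated as
blank. Watershed splitting uses tolerance 1 on the distance map. The
connectivity convention is 8-connected throughout.

## Known limitations

* The measured area of thresholded ridge and spot responses exceeds the
  underlying structure's footprint; area-accurate load readouts require the
  network-mask intersection (provided), and the minimum-size spot filter
  cannot reject sub-resolution *fluorescent* objects (see above).
* Peak/burst criteria reconstruct an unpublished analysis script; absolute
  frequencies depend on them, and the defaults are documented rather than
  canonical.
* The automatic comet tracker is a convenience extension; the manual
  endpoint mode is the faithful readout.
* Steel p-values are Monte-Carlo estimates; at tier boundaries use a large
  permutation count (the functions accept any).
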