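---
title: "Quantifying LIM-domain reporter recruitment to stressed actin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LIM-domain reporter recruitment to stressed actin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainsight)
```

## The measurement problem

Tandem LIM domains recognize a tension-induced conformational state of
F-actin. When a LIM-domain containing region (LCR) is excised from its
parent protein and expressed as a fluorescent fusion, it decorates
strained filament segments; fusing back regulatory domains (e.g. the
Prickle PET domain) or mutating the LIM interface abolishes that
recruitment. Two quantities operationalize these phenotypes in live
tissue imaging:

* an **enrichment score** for a construct (GFP channel) relative to
  stressed-actin sites marked by a Zyxin-LCR reference reporter (RFP
  channel), and
* a **per-frame object count** tracking the disappearance of
  reporter-positive structures after myosin II inhibition relaxes
  cytoskeletal tension.

`strainsight` implements both, together with every image operator they
depend on, and a synthetic scene generator that provides exact ground
truth for validation.

## The enrichment score

For one image pair, a binary reference mask `M` is computed from the RFP
channel only, and three intensity means are taken **on the original,
unprocessed channels**:

* `RFP_i`: mean RFP inside `M`,
* `GFP_i`: mean GFP inside `M`,
* `GFP_o`: mean GFP outside `M`,

giving `score = (GFP_i − GFP_o) / RFP_i`. The numerator is the construct's
excess signal at reference-marked sites; the denominator scales by how
strongly the reference itself labels them. Three algebraic identities make
the statistic robust and are enforced by tests: a uniform additive GFP
offset cancels exactly; multiplying GFP by a gain rescales the score by
exactly that gain; spatially uniform GFP scores exactly 0.

The mask recipe is, in order: background subtraction (sliding paraboloid,
radius 3 px), Gaussian blur (sigma 1 px), Triangle auto-threshold, one
pass of binary erosion, and removal of particles smaller than 30 px
(8-connectivity). The blur's "radius = 1 pixel" is interpreted as
sigma = 1 px — the blur parameter of the platform this recipe originates
from is a sigma. The erosion iteration count is not specified by the
recipe; the default here is 1 (the reference-platform default), and
`mask_params(erode_iterations = 0)` lets users measure its effect — the
mask tightens with erosion but group rank order is preserved (tested).

Scores are normalized per trial by dividing by the mean raw score of the
reference (wild-type) group of that trial, making the reference group's
mean exactly 1. The originating description says scores were scaled "to a
maximum of 1"; division by the reference mean is the operative reading
(the reference group's *mean*, not its maximum, becomes 1), since
normalizing to a per-trial maximum would make the statistic depend on a
single extreme image. Group differences are then assessed by classical
one-way fixed-effects ANOVA (`stats::aov`); no post-hoc tests are added.

Two regions are candidates for `GFP_o`: the whole-image complement of the
mask (default — the recipe says only "outside of this mask") and an
optional user-supplied region (`outside_region`) for restricting to a
cytosol ROI. Both are exposed; the default is the literal reading.
Intensity statistics are means by default (`stat = "integrated"` is
available); a mean is what the reference platform's measurement reports
by default and is what makes the offset-invariance identity exact.

## The object counter

Each time-lapse frame passes through: background subtraction (sliding
paraboloid, radius 3 px), Rényi-entropy auto-threshold, and removal of
particles smaller than 10 px; the count is the number of surviving
8-connected components.

**Where the threshold is estimated matters.** The entropy criterion
assumes a histogram with separable foreground; on a frame whose
structures have fully decayed the histogram is unimodal noise, the
criterion lands in the noise bulk rather than the far tail, and random
8-connected noise clusters of ≥ 10 px are then
counted as objects — the count *rises* as the last structures vanish.
This was verified against an independent re-implementation of the
three-alpha entropy rule: the thresholds are bin-exact, so the behavior
is a property of the method, not a defect of this implementation. Since
the counter exists to report the loss of structures, `count_stack()`
estimates the threshold on frame 0 and holds its native-intensity cutoff
fixed for the series by default; per-frame re-estimation remains
available (`fixed_threshold = FALSE`) for sensitivity analysis.
`count_frame()` on a single constant frame returns 0 with a warning so
fully dark series terminate cleanly.

Replicate series are summarized per condition and timepoint as mean ± SD
(the error-bar convention for inhibition response curves); optional
frame-0 self-normalization is off by default, as absolute counts are the
reported quantity.

## The operators

All operators are implemented in the package and checked against
brute-force oracles (direct double-loop opening, exhaustive threshold
search, flood-fill labeling, neighbor-count erosion sweeps):

* **Background subtraction** is grayscale opening (erosion then dilation)
  with a non-flat structuring element on a disc footprint of the stated
  radius: a spherical cap ("rolling ball") or a paraboloid of apex
  curvature radius equal to the stated radius ("sliding paraboloid").
  The output is the input minus its opening, clamped at 0 for integer
  images, and is pointwise ≤ the input. The reference platform's
  shrink/interpolate speedups are deliberately omitted: exactness over
  speed at these image sizes. Note the morphological fact exercised in
  the tests: a flat plateau wider than the element is background by
  definition and is removed, while peaked (diffraction-limited-like)
  structures survive essentially intact — which is why the pipelines are
  appropriate for punctate/filamentous signal and not for wide uniform
  objects.
* **Gaussian blur** is separable convolution with a normalized kernel
  truncated at `ceiling(3.5 sigma)` taps, mirror-reflected boundary.
* **Auto-thresholds** operate on a 256-bin histogram: native bins for
  8-bit images, min–max linear rescale for 16-bit/float (the convention
  of histogram-based auto-thresholders). Foreground is *strictly above*
  the returned bin; ties break toward background. The Triangle method
  maximizes the perpendicular distance between histogram and the chord
  from the peak to the far end of the longer tail (histogram mirrored
  first if the tail lies below the peak); the distance argmax is
  computed in exact integer arithmetic so bin ties resolve
  deterministically to the lower bin rather than by floating-point
  rounding. The Rényi-entropy method maximizes the summed
  background/foreground Rényi entropies at orders α → 1, 0.5 and 2 and
  combines the three candidates by the published weighted rule on the
  sorted triple.
* **Erosion** removes any foreground pixel with ≥ 1 background neighbor
  in its 8-neighborhood; out-of-image pixels count as background, so
  masks erode at the frame edge.
* **Connected components** use two-pass union-find labeling (4- or
  8-connectivity; 8 is the default used by both pipelines), with
  "particles smaller than N px" meaning area < N is removed.

Coordinates are (row, col); images are plain numeric matrices with a
`bits` attribute recording native depth.

## The synthetic scenes

`make_scene()` emulates the statistical structure of a dorsal-mesoderm
field: `n_filaments` random-orientation line segments with Gaussian
cross-section (sigma 1.5 px), each carrying one contiguous bright
strain-site sub-segment covering `strain_fraction` (default 0.25) of its
length; optional round puncta; diffuse cytosol filling the frame; then
per-pixel Poisson-law photon noise plus Gaussian read noise
(sigma 5), quantized to the requested bit depth (default 16-bit,
512 × 512). Default ideal photon levels — RFP background 100, dim
filament 150, strain sites 1200; GFP diffuse 300, strain-site signal
1200, puncta 600 — were chosen once as plausible mid-range confocal
counts giving strain-site SNR comfortably above, and dim-filament
contrast comfortably below, the thresholds' operating point.

Ground-truth masks use a half-width of one cross-section sigma around
each segment axis, and the GFP recruitment component is rendered
strictly inside the strain mask, so inside/outside compartment
statistics are exact rather than blurred by Gaussian tails. The design
parameter `enrichment_rho` scales the strain-site GFP component: 0 means
fully diffuse construct, 1 full recruitment; with `conserve_total = TRUE`
the recruited photons are debited from the diffuse pool so total GFP
photons stay constant across `rho` (redistribution, not addition), which
lets offset-type invariances be tested independently of brightness.

`make_timelapse()` reuses one scene geometry and scales the
filament-associated construct component of frame *t* by
`exp(−t · interval / tau)`; `tau = Inf` is the vehicle control. Frames
0–15 at one frame per minute emulate a 15-minute inhibition series; the
per-frame noise streams are derived deterministically from the base
seed, and (spec, seed) determines every output bit-for-bit. Time-lapse
bases default to zero puncta: the modeled experiment images the LCR
construct whose structures all decay.

What the generator does **not** emulate: optics (no PSF, no
TIRF-vs-confocal distinction), cell boundaries (cytosol fills the
frame), filament curvature, structure motion, photobleaching, or
spatially varying background. Passing tests therefore demonstrate
correctness of the measurement chain on images with the right gross
statistics — compartmentalized signal over diffuse background with
realistic shot noise — not robustness to every real-microscopy artifact.

## Problem sizes and numerical choices

The validation suite runs scenes of 96–160 px and cohorts of 3–10 images
per group; the acceptance script uses 256 × 256 scenes with 10 images
per group and 10 time-lapse replicates per condition — sizes chosen so a
full run completes in well under a minute while every structure remains
several times larger than the particle-filter cutoffs. Degenerate inputs
are contracts, not accidents: constant images raise a typed
degenerate-histogram condition from the thresholders, which the counter
maps to a zero count and the mask builder to an empty mask; empty masks
and zero reference signal reject the measurement with a named error;
per-trial normalization refuses trials lacking reference rows. ANOVA
with zero within-group variance is flagged degenerate and reported as
F = ∞ rather than silently returning `NaN`.

## Known limitations

* The enrichment score is the recipe's statistic, not a general
  colocalization coefficient; no Pearson/Manders measures are provided.
* No object tracking: the counter counts per frame and cannot
  distinguish fragmentation from appearance (transient count spikes as
  fading structures break apart are visible in decaying series).
* The rolling-ball variant implements the opening definition directly;
  it is exact but makes no claim of matching any specific platform's
  speed-optimized approximation pixel-for-pixel.
* Reading multi-page TIFFs requires an explicit axis hint (`"T"` or
  `"C"`); the package does not guess from metadata.
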