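---
title: "qdmi3d: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qdmi3d: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the analytical model behind `qdmi3d`, the
parameters that matter, the synthetic phantom model used for validation,
and the numerical and design choices made where the method left room.

## The measurement model

The assay characterises fixed interphase nuclei from two-channel 3D
confocal stacks: DAPI (counterstain; intensity tracks local genomic DNA
density, i.e. chromatin condensation) and MeC (anti-5-methylcytosine
immunofluorescence; intensity tracks local DNA methylation load). The
acquisition geometry is anisotropic — 120 nm laterally, 250 nm axially,
12 bits per pixel — and all physical reasoning in the package (distance
transforms, analysis cubes, seed separations, blur) is done in
nanometres, never in pixel units, so the anisotropy is handled uniformly.

Assumptions worth stating explicitly:

* nuclei are convex-ish, roughly ellipsoidal, and separable in the DAPI
  channel; heavily overlapping or fragmented (apoptotic, M-phase) nuclei
  are not segmented correctly, but the codistribution filter is designed
  to remove exactly those;
* the two channels are acquired sequentially on the same geometry, so a
  pixel's (DAPI, MeC) pair is spatially matched;
* intensity scales are arbitrary per image. Every feature is therefore
  normalised against image-inherent quantities (Otsu-style thresholds,
  robust percentile scales) rather than fixed intensity values.

## Pipeline stages and their parameters

### Segmentation

The DAPI volume is binarised with a global, image-inherent threshold.
Two methods are provided:

* `otsu` — maximises between-class variance of the intensity histogram;
* `envelope` (pipeline default) — Otsu first splits foreground from
  background, then the threshold is re-placed at the midpoint between
  the background mean and the lower quartile of the foreground. The
  midpoint is where the blur-smeared intensity ramp of the nuclear
  envelope crosses half-height, which is the unbiased boundary position
  for a step edge under symmetric blur. Plain Otsu puts the cut well
  above that midpoint whenever background dominates the histogram (most
  fields: nuclei occupy a few percent of the volume), which erodes every
  nucleus by a shell one to two pixels thick; on the package's default
  phantoms the test suite measures this as a 12–17% per-nucleus volume
  deficit for plain Otsu versus under 8% for the envelope refinement,
  with identical nucleus counts. Both are deterministic; the method is a
  config slot.

Seeds are local maxima of the anisotropic Euclidean distance transform
(EDT) of the mask, computed in physical units by a separable
lower-envelope transform in C++. The discrete EDT carries ridge
plateaus, so it is smoothed with a 1-pixel isotropic Gaussian before
maxima detection; maxima below 0.3 of the global peak are discarded
(they sit on necks between touching nuclei, not at centres), and the
survivors are thinned greedily with a minimum separation of
0.7 × expected nuclear radius (`expectedRadiusNm`, default 5000 nm — a
typical cultured-fibroblast nucleus). Holes (nucleoli) are filled per
z-slice first so the EDT peaks at the nuclear centre and the reported
volume counts whole nuclei.

The watershed floods the negated EDT from the seeds, 6-connected, using
a priority queue with FIFO tie-breaking in insertion order — identical
inputs give bit-identical labelings. ROI filters: `min_volume_px`
(default 50) drops debris; border-touching nuclei are dropped by default
because their volumes are truncated.

### Codistribution filtering

Each nucleus's joint (DAPI, MeC) histogram is accumulated on shared
population bin edges (64 × 64 bins by default over the pooled within-ROI
range; 64 balances resolution against empty-bin noise for ROIs of
10^3–10^5 pixels) and scored with the Kullback-Leibler divergence, base
2, cell-against-reference. Nuclei above 4.5 bits are excluded as
dissimilar. Numerical choices:

* **Reference** — the mean histogram over the other nuclei
  (leave-one-out). A self-inclusive mean bounds the divergence at
  log2(n) — at n = 21 the 4.5-bit cut could never fire — while the
  leave-one-out mean differs from the full mean by O(1/n) and is
  indistinguishable from it at the >1000-cell populations the assay
  targets. The plain mean remains available as
  `populationReference()`.
* **Smoothing** — zero reference bins make the divergence infinite, so
  both tables receive a per-bin pseudocount ε before re-normalisation.
  ε defaults to 1e-6: far below one pixel's probability mass for any
  realistic ROI, so the divergence scale is untouched. A large
  pseudocount (order 1/bins) effectively mixes half the mass with a
  uniform table and compresses all divergences to ~1 bit, detaching the
  score from the 4.5-bit threshold scale; both ε and the threshold are
  config values because the threshold's meaning depends on the binning.
* The test suite verifies the intended operating regime on phantoms:
  planted anti-correlated or mitotic-compact nuclei score far above 4.5
  bits while homogeneous nuclei stay around 1 bit, and fewer than 1% of
  nuclei in homogeneous populations are flagged.

### Topological voxel analysis

Each ROI is partitioned by a cube lattice of physical edge 500 nm
(`cube_size_nm`), anchored at the ROI bounding-box corner so that
identical nuclei at different positions produce identical features. At
the default pitch a cube is 5 × 5 × 2 pixels. Partial cubes at the
boundary are kept with their occupancy; occupancies sum exactly to the
ROI volume, and all aggregation is occupancy-weighted, so boundary cubes
contribute in proportion to their actual volume rather than being
discarded (discarding would bias against the nuclear periphery, which is
precisely where chromatin reorganisation is most visible).

Per cube, with pooled-ROI Otsu thresholds t and robust scales s (99.5th
percentile of pooled ROI intensities per channel — the maximum is
fragile to hot pixels at 12 bits):

* `cond` = clip(mean DAPI / s_DAPI, 0, 1)
* `meth` = clip(mean MeC / s_MeC, 0, 1)
* `assoc` = fraction of pixels with (DAPI < t_DAPI) == (MeC < t_MeC);
  a cube whose pixels all fall in one agreement class scores 1
  (degenerate agreement is still agreement — this keeps `assoc`
  continuous as a population drifts towards all-low intensities).

Thresholds and scales are computed once per image over the pooled kept
ROIs (per-image rather than per-experiment: stain efficiency varies
between slides; the choice is a config slot). Because both thresholds
and scales are image-inherent, a global intensity rescaling leaves
`assoc` unchanged and moves `cond`/`meth` by less than the histogram
bin width — the suite asserts <1% under exact doubling.

Each cube's normalised radial position is r = |c − centroid| / b(c),
where b(c) is the centroid-to-surface distance along the same ray,
found by marching on the ROI pixel set in half-pixel steps. The
direction-dependent denominator makes r comparable across ellipsoidal
(and flattened adherent) nuclei; a plain distance-to-centroid norm would
conflate nuclear shape with radial topology. Radial profiles bin cubes
into `n_shells` equal-width r-shells (default 5) with occupancy-weighted
means; empty shells are NA, and `profileDispersion` summarises
per-shell spread across a population.

### Population statistics

Growth rate is g = 1/doubling time, with g = 0 for senescent samples
(infinite doubling time) — growth arrest is the natural zero of an
inverse-time axis. Correlations are computed on sample-level means (one
point per stained sample), because doubling time is a sample-level
quantity; a cell-count-weighted variant is exposed but not the default.
The logistic growth-response model y = b + L/(1 + exp(−k(x − x₀))) is
fitted by Levenberg-Marquardt from a multi-start grid (both signs and
four magnitudes of k, three quantiles of x₀) with the best residual sum
of squares winning; the parameterisation has an exact (L, k, x₀, b) ↔
(−L, −k, x₀, b + L) degeneracy, so fits are canonicalised to L > 0.
A near-constant response is reported as degenerate (k unidentifiable)
rather than fitted. Model selection fits linear, logarithmic (skipped
when any x ≤ 0), quadratic, exponential and logistic candidates, ranks
them by small-sample-corrected AICc, and guards parsimony with the
extra-sum-of-squares F-test: a simpler model displaces the AICc winner
whenever the F-test cannot reject it at α = 0.05. Between-class
comparisons use the Welch t-test (the population tables are plainly
heteroscedastic).

## The phantom generator

`generatePopulation` emulates what the pipeline consumes, not the
underlying optics: ellipsoidal nuclei (axial flattening 0.7, as for
adherent cells) placed by rejection sampling, a two-level chromatin
texture driven by a shared random focus field — the top `condLevel`
fraction of the field is "condensed" (high DAPI) and the top `mecLevel`
fraction is "methylated" (high MeC), so the two channels are spatially
coupled through their shared foci, which is what gives `assoc` its
meaning — then anisotropic Gaussian blur standing in for the confocal
point-spread function, Poisson photon noise plus Gaussian read noise,
and 12-bit quantisation. The three presets encode the growth-behaviour
scheme the analysis must recover: methylation and condensation ordered
senescent < cancer < proliferating, senescent nuclei enlarged (~1.6×
volume), with levels chosen to land the measured `meth` near 0.5 / 0.3
/ 0.15 for the three classes, in the range the per-population feature
tables of real cultures occupy. Intensity levels put the mean DAPI
signal near 1600 counts on the 12-bit scale with moderate nuclear
contrast, so that image-inherent thresholds face realistic class
imbalance.

What the phantoms deliberately do **not** model: senescence-associated
heterochromatin foci morphology, photobleaching, tile overlap,
cross-channel bleed-through, depth-dependent attenuation, and any
quantitative texture calibration. Passing tests therefore demonstrate
that the pipeline recovers planted orderings, volumes, outliers and
correlation structure under confocal-like degradation — not that
absolute feature values match any particular real dataset; on real data
the absolute values depend on staining and acquisition settings and
should only be compared within an experiment.

Planted outliers (`plantOutlier`) give the K-L filter true positives:
`mitotic-compact` shrinks a nucleus to 0.55× linear size with uniformly
bright DAPI (an M-phase mimic), `inverted-texture` keeps the shape but
puts high MeC where DAPI is low, displacing the joint histogram off the
population's support.

## Problem sizes used by the test suite

The suite and the acceptance script run phantom nuclei of 1.1–1.9 µm
radius in fields of roughly 300 × 300 × 25 pixels, with 8–50 nuclei per
field and 20–100 seeded replicates per property — chosen so that each
nucleus still spans dozens of 500 nm analysis cubes and each property is
tested at meaningful population sizes. The same code paths run unchanged
on full-scale 2048 × 2048 × z stacks with 5 µm nuclei; only memory and
time scale.

## Known limitations

* The watershed has no shape regularisation; heavily fused nuclei with a
  weak distance ridge can merge (mitigated by seed prominence/separation
  tuning, and flagged downstream by the K-L filter when the merged
  object's codistribution is aberrant).
* Radial profiles assume a star-convex nucleus with respect to its
  centroid; strongly lobed nuclei give r values clipped at 1.
* The Ki-67 channel, when present, is carried through as an annotation
  only; no intensity quantification is attempted.
* Tiled acquisitions are analysed per field and pooled; stitching is out
  of scope.
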