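# qdmi3d

Cell-by-cell 3D DNA methylation imaging cytometry with topological voxel
analysis, in R.

## The problem

Global DNA hypomethylation and chromatin decondensation accompany both
cellular aging and malignant transformation. Both can be read out *in situ*
from two-channel 3D confocal stacks of fixed nuclei: an
anti-5-methylcytosine (MeC) immunofluorescence channel reports the spatial
distribution of methylated DNA, and the DAPI counterstain reports local
genomic DNA density (chromatin condensation). `qdmi3d` turns such stacks
into per-nucleus chromatin-texture features, pools them into population
statistics, and relates them to the growth behaviour of the cultured cells
— distinguishing normally proliferating, rapidly growing/immortal, and
senescent populations. It is written for imaging cytometry and chromatin
biology groups who have (or want to simulate) 3D MeC/DAPI stacks.

## The method

For each field of view (voxel pitch 120 × 120 × 250 nm, 12-bit):

1. **Segmentation** — the DAPI channel is binarised by an image-inherent
   global threshold, seeds are taken as local maxima of the anisotropic
   Euclidean distance transform, and nuclei are separated by a 3D seeded
   watershed on the inverted distance map.
2. **Outlier rejection** — each nucleus's MeC/DAPI joint intensity
   histogram p is scored against the population reference q by
   Kullback-Leibler divergence

   D(p‖q) = Σ_b p_b · log2(p_b / q_b)   (bits),

   and nuclei with D > 4.5 are excluded as "dissimilar" (this
   automatically catches M-phase-like compact nuclei). In homogeneous
   populations fewer than 1% of nuclei are flagged.
3. **Topological voxel analysis (TVA)** — each nuclear ROI is partitioned
   into 500 nm cubes. Per cube: *cond* (DAPI mean over the robust image
   scale; chromatin condensation), *meth* (MeC analogue; relative
   methylation) and *assoc* (fraction of pixels whose two channels agree
   in thresholded low/high state), all in [0, 1]. Whole-nucleus values
   are occupancy-weighted (volume-weighted) means over cubes; LID% and
   LIM% count the pixels below image-inherent low-intensity thresholds.
   Each cube also gets a normalised radial position r ∈ [0, 1]
   (centre-to-periphery), giving per-nucleus radial profiles.
4. **Population statistics** — per-sample mean ± σ tables, Pearson
   correlation of sample-mean features against growth rate g = 1/doubling
   time (g = 0 at senescence), logistic growth-response fits
   y = b + L/(1 + e^{−k(x−x₀)}) with F-test/AICc model selection, and
   Welch two-sample t-tests between cell classes.

A ground-truthed phantom generator (`generatePopulation`,
`plantOutlier`) emulates fields of interphase nuclei with programmable
phenotype (size, methylation/condensation levels, heterochromatin foci,
confocal-like anisotropic blur and Poisson-Gaussian noise), so the entire
pipeline is testable without microscopy data.

## Worked example

```r
library(qdmi3d)

spec <- phenotypeSpec("proliferating", radiusNm = 1500, radiusSdNm = 100)
pop  <- generatePopulation(8, spec, fieldShape = c(24, 220, 220), seed = 42)
seg  <- segmentNuclei(pop$stack, expectedRadiusNm = 1500, minVolumePx = 200)
length(seg$rois)
#> [1] 8

res <- analyzeStack(pop$stack,
                    defaultConfig(expected_radius_nm = 1500,
                                  min_volume_px = 200))
res$counts
#>  found   kept border  small     kl
#>      8      8      0      0      0
res$cells[1:5, c("label", "volume_px", "lid_pct", "lim_pct",
                 "cond", "meth", "assoc", "kld", "outlier_flag")]
#>   label volume_px lid_pct lim_pct  cond  meth assoc   kld outlier_flag
#> 1     1      4135    49.7    54.6 0.621 0.460 0.927 0.857        FALSE
#> 2     2      3167    56.6    55.9 0.579 0.452 0.937 0.742        FALSE
#> 3     3      3770    53.9    54.1 0.582 0.465 0.949 0.509        FALSE
#> 4     4      3358    54.5    56.9 0.582 0.429 0.946 0.574        FALSE
#> 5     5      2765    59.5    51.2 0.537 0.497 0.915 2.882        FALSE

summarizeSample(res$cells[!res$cells$outlier_flag, ])
#>     feature     mean       sd
#> 1 volume_px 3168.875 551.0536
#> 2 mean_dapi 1542.705  62.9752
#> 3  mean_mec 1469.605  80.0330
#> 4   lid_pct   55.228   2.9927
#> 5   lim_pct   55.638   2.2769
#> 6      cond    0.579   0.0236
#> 7      meth    0.450   0.0245
#> 8     assoc    0.935   0.0105
```

All 8 planted nuclei are found, none are K-L-flagged, and the
population shows the proliferating phenotype: *meth* ≈ 0.45,
*cond* ≈ 0.58, with cell-to-cell scatter of a few percent. Every nucleus's
K-L divergence is far below the 4.5-bit dissimilarity cut.

A thin command-line wrapper lives at `inst/cli/qdmi.R`
(`simulate` / `segment` / `features` / `stats` subcommands over a YAML
config).

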