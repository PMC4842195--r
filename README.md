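# hmrseg

Hybrid morphological reconstruction (HMR) enhancement with
marker-controlled watershed segmentation for layered and blob-like
anomalies in 8-bit medical-style images — artery cross-sections whose
lumen is narrowed by plaque, and retinal fundus images carrying bright
exudates and dark hemorrhages. The package is for image-analysis work
where the structures of interest are near-homogeneous regions separated
by intensity edges and the question is *where those regions are and how
big they are* (e.g. how much open lumen remains as an occlusion grows).

## The method

The pipeline composes two classical morphological ideas:

1. **HMR enhancement.** With ℜ(m, g) the grayscale geodesic
   reconstruction by dilation of marker *m* under mask *g*, and ⊖ erosion
   by a structuring element *S*:

   R̄ = 255 − R,  R̄_obr = ℜ(R̄ ⊖ S, R̄),  R̄_obrcbr = closing-by-reconstruction(R̄_obr),  R̄′ = 255 − R̄_obrcbr

   Opening- and closing-by-reconstruction remove bright and dark
   structures smaller than *S* while restoring every survivor's contour
   exactly, so the enhanced image is piecewise near-constant inside
   structures with edges intact.

2. **Marker-controlled watershed.** The Sobel gradient magnitude
   |∇R̄′| = √(gx² + gy²) is treated as topography. The regional maxima of
   the enhanced image (constant plateaus with strictly lower
   surroundings) mark structure interiors; minima imposition rewrites the
   surface so exactly those components are its regional minima; priority
   flooding in increasing surface order then grows one catchment basin
   per marker, with divide pixels (label 0) where floods meet.

Per-basin ROI statistics — area, perimeter, and per-channel standard
deviation, skewness and median, measured on the original intensities —
and a before/after severity-trend report round out the analysis: a
shrinking open-region area/perimeter reads as increasing severity.

Because the clinical images behind this kind of study are not publicly
deposited, the package includes a synthetic phantom generator (concentric
artery cross-sections with a controllable, eccentrically grown occlusion
fraction; fundus-like discs with seeded exudate/hemorrhage blobs) whose
outputs carry exact ground-truth label maps, making every stage testable.

## Worked example

```r
library(hmrseg)

spec <- phantom_spec("artery", occlusion_fraction = 0.5, noise_sd = 5, seed = 42)
res  <- run_pipeline(spec, pipeline_config(seed = 42))
res
#> hmrseg result: 2 basins, 0 watershed-line pixels (256x256)

gt_open <- sum(res$ground_truth == ARTERY_LABELS["lumen"])
ks <- sort(unique(res$labels[res$labels > 0]))
ov <- sapply(ks, function(k) sum(res$labels == k & res$ground_truth == ARTERY_LABELS["lumen"]))
lumen <- ks[which.max(ov)]
c(ground_truth = gt_open, recovered = sum(res$labels == lumen))
#> ground_truth    recovered
#>         2314         2316

res$stats[res$stats$channel == 1, ][1:2, ]
#>   basin  area perimeter channel        sd   skewness median
#> 1     1 63220      1250       1 74.220767  0.6004433     27
#> 4     2  2316       226       1  5.434994 -7.9605429    250
```

The phantom fills 50% of the lumen disc with plaque; the pipeline seeds
one basin in the remaining open lumen and one in the vessel wall, and the
recovered open-lumen basin (2316 px) matches the ground truth (2314 px)
to within two pixels. In the statistics table the lumen basin (basin 2)
shows the high median (250, the lumen intensity) and low spread of a
homogeneous bright region, while the wall-and-background basin mixes
several structures and so carries a large standard deviation.

A shell front end with `segment`, `phantom` and `stats` subcommands is
installed under `inst/cli/hmrseg`:

```sh
Rscript inst/cli/hmrseg phantom artery --occlusion 0.5 --seed 42 --out out/
Rscript inst/cli/hmrseg segment out/phantom.png --out out/seg
```

See `vignettes/hmr-watershed-methods.Rmd` for the model, every tunable
parameter, the phantom design, and known limitations.

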