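# ihcseg

Immunohistochemistry-guided epithelium segmentation for breast
tissue-microarray (TMA) images.

## The problem

Pixel-accurate epithelium annotations are the bottleneck for training
segmentation models on HE-stained breast tissue. `ihcseg` implements a
restaining-based pipeline that removes the human from the pixel level: an
HE-stained slide is scanned, destained, restained with the pan-cytokeratin
antibody cocktail CK AE1/AE3 (visualized with the brown DAB chromogen) and
rescanned. Since cytokeratin marks all epithelial cytoplasm, thresholding
the DAB channel yields a dense binary epithelium mask, and coarse
pathologist region annotations (benign structures, in-situ lesions,
exclusion tags, case groups) refine it into a four-class pixel ground
truth — background / invasive / benign / in-situ — that trains an
attention-gated U-Net (AGU-Net) to segment plain HE images. The package is
aimed at computational-pathology groups building such ground truths and at
anyone who needs its parts: H-DAB colour deconvolution, TMA core
extraction, registration of restained sections, or per-core segmentation
metrics.

## What is implemented

* **Stain separation** — Beer–Lambert optical densities
  `OD_c = -log10(I_c / I0_c)` unmixed with the standard H-DAB stain matrix
  (hematoxylin `(0.65, 0.70, 0.29)`, DAB `(0.27, 0.57, 0.78)`, residual =
  normalized cross product), plus the exact forward synthesis used as a
  test oracle.
* **Epithelium mask** — Gaussian prefilter (sigma 3.0 px at 0.3448 µm/px,
  rescalable to other resolutions at fixed physical scale), DAB threshold
  0.25; nuclear holes < 150 µm² filled, fragments < 25 µm² removed.
* **TMA core extraction** — colour-threshold tissue segmentation on a
  low-resolution overview, flood-fill labelling, removal of regions under
  100 px, exclusion of regions deviating more than 50% from the median area
  or equivalent diameter (merged/partial cores), extraction at any
  magnification, and greedy HE/CK core pairing by centroid.
* **Registration** — integer-pixel phase cross-correlation at 4×
  downsampling with CK histogram equalization, shifts upscaled to full
  resolution; a second pass at patch scale.
* **Ground truth** — in-situ = mask ∧ in-situ annotation; benign = mask ∧
  benign ∧ ¬in-situ; invasive = the rest of the mask; one-hot partition,
  exclusion tagging and case grouping from QuPath-dialect GeoJSON.
* **Patching and sampling** — 1024 px tiles at 25% overlap (stride 768),
  < 25% tissue excluded; each patch assigned to the in-situ / benign /
  invasive set by priority; balanced sampling; augmentation (flip, rot90,
  brightness, hue, saturation, shift at p = 0.5 each, blur at p = 0.1).
* **AGU-Net** — seven levels, filters 16–128, multiscale input, additive
  attention gates, deep supervision; soft Dice loss; Adam 5e-4 with
  plateau halving (patience 10), early stop 200, epochs of exactly 160/40
  train/validation updates; tiled inference at 30% overlap with
  probability averaging. The network and its backpropagation are
  implemented natively in R (finite-difference-verified); a miniature
  configuration trains in minutes on one CPU.
* **Evaluation** — per-core Dice / precision / recall over the three
  epithelium classes (background disregarded), zero denominators scored as
  1, aggregation rows I (all cores), II (class in ground truth or
  prediction), III (class in ground truth), subgroup summaries by
  histological subtype and grade, and a validated 0–5 qualitative scoring
  schema.
* **Synthetic data** — paired HE/CK slide pyramids with known ground truth,
  annotation GeoJSON/CSV fixtures, and artifact flags (debris, merged or
  missing cores, background DAB, false-negative staining), so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(ihcseg)

# A small synthetic restained slide pair: 2x2 cores of 150 um radius at
# 2 um/px, each with invasive nests, one benign gland and one in-situ duct,
# and the CK image rigidly shifted by (8, -12) px against the HE image.
cfg <- synth_config(grid = c(2, 2), core_radius_um = 150,
                    invasive_nests = 4, benign_glands = 1, insitu_ducts = 1,
                    nest_radius_um = c(20, 32), gland_radius_um = c(30, 45),
                    duct_radius_um = c(38, 55), seed = 42)
pair <- generate_slide_pair(cfg)
pair$he
#> <pyramidal_image 'synthetic_he' stain=HE  3 levels  580x580 @ 2.0000 um/px>

# TMA core detection on the slide overview
cores <- detect_cores(pair$he)
dplyr::select(cores, region, area_px, diameter_px, cx, cy, kept)
#> # A tibble: 4 × 6
#>   region area_px diameter_px    cx    cy kept
#>    <int>   <dbl>       <dbl> <dbl> <dbl> <lgl>
#> 1      2    1107        37.5  211.  212. TRUE
#> 2      1    1139        38.1  383.  207. TRUE
#> 3      3    1162        38.5  208.  370. TRUE
#> 4      4    1172        38.6  381.  376. TRUE

# Full data-creation path: pairing, registration, DAB mask, ground truth
recs <- process_slide_pair(pair$he, pair$ck, pair$annotations,
                           magnification = "x40")
recs[[1]]$shift      # correction applied to the CK core (true shift negated)
#> <shift dx=-8 dy=12>
recs[[1]]$gt
#> <label_map 152x152  bg=20530 inv=1534 ben=1040 ins=0>
```

The detected cores all have ~38 px equivalent diameter on the overview, so
none is excluded by the 50% size-deviation rule; the registration recovers
the built-in (8, −12) px translation exactly. Scoring the pipeline's
recovered ground truth against the generator's exact truth with the
package's metric conventions:

```r
ev <- evaluate_cores(lapply(recs, function(r) {
  d <- sapply(pair$truth, function(tr) sum(abs(tr$labels$origin - r$bbox[1:2])))
  tr <- pair$truth[[which.min(d)]]     # nearest generator truth ...
  x0 <- max(tr$labels$origin[1], r$bbox[1])
  y0 <- max(tr$labels$origin[2], r$bbox[2])
  x1 <- min(tr$labels$origin[1] + ncol(tr$labels$raster),
            r$bbox[1] + ncol(r$gt$labels$raster))
  y1 <- min(tr$labels$origin[2] + nrow(tr$labels$raster),
            r$bbox[2] + nrow(r$gt$labels$raster))
  crop <- function(m, o) m[(y0 - o[2] + 1):(y1 - o[2]),
                           (x0 - o[1] + 1):(x1 - o[1])]
  list(pred = crop(r$gt$labels$raster, r$bbox[1:2]),   # ... cropped to the
       gt = crop(tr$labels$raster, tr$labels$origin),  # bbox intersection
       core_ref = r$core_ref)
}))
ev$rows[, c("class", "row", "n", "dice_mean", "dice_sd")]
#> # A tibble: 9 × 5
#>   class    row       n dice_mean dice_sd
#>   <chr>    <chr> <int>     <dbl>   <dbl>
#> 1 benign   I         4     0.977 0.00800
#> 2 benign   II        4     0.977 0.00800
#> 3 benign   III       4     0.977 0.00800
#> 4 in_situ  I         4     0.991 0.00618
#> 5 in_situ  II        3     0.988 0.00415
#> 6 in_situ  III       3     0.988 0.00415
#> 7 invasive I         4     0.981 0.00550
#> 8 invasive II        4     0.981 0.00550
#> 9 invasive III       4     0.981 0.00550
```

Per-class Dice of 0.98–0.99 is the discretization-and-registration limit of
the restaining construction on this material; the in-situ row II/III count
is 3 because one core contains no in-situ duct (its row-I Dice of 1 is the
zero-denominator convention at work). `run_synthetic_experiment()` runs the
same chain end to end — including training the miniature AGU-Net and
evaluating held-out cores; `tidy()`, `glance()` and `autoplot()` work on
the fitted model and on evaluation results.

A thin CLI over the same functions ships in `inst/scripts/ihcseg`
(`mask`, `extract-cores`, `register`, `synth`, `evaluate`).

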