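# mitoseg

Segmentation and morphometry of mitochondria in 2D fluorescence microscopy
images.

Mitochondrial networks shift between fragmented, tubular, elongated and
mixed morphologies as the fission/fusion balance changes, and quantifying
those shifts requires segmenting individual organelles accurately — not
just per pixel, but per shape, because the biology is read from per-object
descriptors. `mitoseg` provides the full workflow in one R package, for
cell biologists and image analysts who want a scriptable, fully seeded
pipeline:

* **Synthetic data** — a seeded generator of mitochondria-like fluorescence
  images (four phenotype classes, Poisson + Gaussian camera noise) with
  exact ground-truth masks, plus controlled mask perturbations for metric
  testing.
* **Training pipeline** — 2×2 overlapping tiling, U-Net border weight maps
  `w(x) = w_c(x) + w0·exp(−(d1+d2)²/2σ²)`, 80-fold geometric augmentation,
  80/20 split, leave-one-out cross-validation folds
  (12 images × 4 tiles × 80 copies = 3,840 training tiles at defaults).
* **Segmentation network** — a modified U-Net (batch normalization after
  every contracting-path convolution, no dropout) with weighted
  cross-entropy training, per-epoch validation dice, overlapping-tile
  prediction with probability averaging, fine-tuning from a saved state.
  The convolutional engine is implemented in the package in pure R (im2col
  + BLAS) and its gradients are tested against numerical differentiation.
* **Classical comparators** — Gaussian, Hessian-eigenvalue and
  Laplacian-of-Gaussian enhancement followed by Otsu/mean/triangle/fixed
  thresholding.
* **Accuracy framework** — dice coefficient; object matching with
  exclusion of one-to-many correspondences; average fold deviation
  `max(a,b)/min(a,b)` of five shape descriptors (area, eccentricity,
  aspect ratio, perimeter, solidity); energy distance
  `sqrt(2E|X−Y| − E|X−X′| − E|Y−Y′|)` between descriptor distributions,
  normalized per descriptor across methods.
* **Morphometry** — per-object tables with ten morphological and three
  intensity features, skeleton branch counts and lengths (Zhang–Suen
  thinning, ImageJ-style junction merging), per-image summaries.
* **Statistics** — D'Agostino K² normality gate selecting t-test vs
  Mann–Whitney U, Kruskal–Wallis with Dunn's Bonferroni-adjusted post-hoc
  comparisons, correlation analysis.

All tabular results are tibbles; fitted models and result objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(mitoseg)

pair <- generate_image(synth_spec(96, 96, "fragmented", n_objects = 10, seed = 42))
lab  <- label_objects(pair$mask)
feats <- measure_objects(lab$labels, pair$raw)
head(feats[c("object", "area", "perimeter", "eccentricity", "solidity",
             "mean_intensity")], 4)
#>   object  area perimeter eccentricity solidity mean_intensity
#> 1      1    36      19.1        0.537    0.935          0.677
#> 2      2    14      11.1        0.611    0.848          0.495
#> 3      3    17      16.2        0.937    0.829          0.384
#> 4      4    15      11.7        0.537    0.882          0.441

branch_statistics(pair$mask)$per_image
#>   n_objects n_branches average_branch_length n_cycles
#> 1        10         10                 0.883        0
```

Ten fragments were rendered and ten are found; small round fragments
skeletonize to near-point medial axes, hence the short average branch
length. Degrading the mask by a 1-pixel dilation and scoring it against the
original shows how the metrics react:

```r
pred <- perturb_mask(pair$mask, "dilate", 1)
ev   <- evaluate_method(list(pair$mask), list(pred))
ev$dice
#>   image  dice
#> 1 img1  0.667
head(ev$morphology, 5)
#>   image descriptor   avg_fold_deviation energy_distance
#> 1 img1  area                       2.14           5.05
#> 2 img1  eccentricity               1.16           0.198
#> 3 img1  aspect_ratio               1.10           0.227
#> 4 img1  perimeter                  1.51           2.76
#> 5 img1  solidity                   1.07           0.222
```

A one-pixel halo on tiny objects roughly doubles their area (fold deviation
2.14) while barely changing eccentricity or solidity — exactly why
object-level metrics complement the dice coefficient. Feature tables feed
straight into the statistics layer:

```r
compare_two(feats$area, feats$area * 1.5)
#> independent two-sample t-test: statistic = -1.875, p = 0.07954 (n = 10, 10; parametric)
```

Training and applying a network (small test-scale configuration):

```r
tiles <- lapply(simulate_dataset(16, synth_spec(64, 64, "fragmented",
                                                n_objects = 8, seed = 1),
                                 seed = 11)$pair,
                function(p) list(raw = p$raw, mask = p$mask,
                                 weights = compute_weight_map(p$mask)$weights))
tiles <- augment_tiles(tiles, augmentation_spec(copies_per_tile = 4, seed = 2))
sp    <- train_val_split(tiles, 0.8, seed = 3)
cfg   <- unet_config(depth = 2, base_filters = 8, input_side = 64,
                     learning_rate = 1e-3, epochs = 14, batch_size = 8, seed = 7)
fit   <- unet_train(build_unet(cfg), sp$train, sp$validation, cfg)
mask  <- unet_predict(fit$model, pair$raw)
autoplot(fit$history)
```

A command-line front end over the same functions (subcommands `simulate`,
`prepare`, `train`, `finetune`, `predict`, `evaluate`, `analyze`,
`compare`) ships as `inst/cli/mitoseg.R`.

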