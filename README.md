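# tmaseg

Superpixel-based segmentation of tissue-microarray (TMA) histopathology
core images into **tumor**, **non-tumor tissue** and **background**.

A digitized TMA core is a square RGB image (~6000 × 6000 px) showing a
circular disc of stained tissue on a light gray background. `tmaseg`
implements a computer-assisted-diagnosis workflow for such images:

1. rescale (default 25%) and enhance each image (contrast normalization,
   histogram equalization, or histogram matching);
2. partition it into **SLIC superpixels** — localized k-means over color
   and position with grid size *S* = 30 and regularization *r* = 0.20,
   distance *D* = *d*<sub>color</sub> + (*m*/*S*) · *d*<sub>xy</sub>,
   *m* = 40·*r*;
3. describe every superpixel with **69 texture features**: 17 first-order
   histogram statistics and 6 Tamura features (coarseness, contrast,
   directionality, line-likeness, regularity, roughness) on each RGB
   channel;
4. build ground truth from expert ImageJ polygon ROIs and assign each
   superpixel the **majority class** of its pixels (codes 0 = background,
   2 = tumor, 3 = non-tumor);
5. compare five classifier families (random forest, SVM, LogitBoost,
   C4.5-style tree, naive Bayes) under **leave-one-image-out
   cross-validation** with per-class PPV = TP/(TP+FP), TPR = TP/(TP+FN),
   F1 = 2TP/(2TP+FP+FN) and multiclass accuracy;
6. retrain the best (enhancement, classifier) pair and **reassemble**
   the classified superpixels into a segmented label image
   (white/red/green preview).

A built-in synthetic TMA generator (circular tissue disc, irregular tumor
blobs, exact paired labels) makes the entire pipeline testable without
any external data.

## Worked example

```r
library(tmaseg)

# one synthetic TMA core with its exact label image
d <- generate_tma(synthetic_params(size = 256, seed = 42))
d$tumor_fraction
#> [1] 0.35

map <- slic(d$image, slic_params())       # grid 30, regularization 0.20
map$K
#> [1] 81

tab <- extract_feature_table(d$image, map, "core_1", labels = d$labels)
dim(tab)                                  # 81 superpixels x (4 keys + 69 + class)
#> [1] 81 74
table(tab$class)
#>  0  2  3
#> 32 22 27
```

`map$K` is the superpixel count (the 256 × 256 image holds a 9 × 9 grid of
30-px sites); each of the 81 rows of `tab` carries the 69 features plus
the majority-vote class — here 32 background, 22 tumor and 27 non-tumor
superpixels, consistent with a 0.35 tumor fraction inside the disc.

The full experiment — grid comparison, best-pair selection, segmentation:

```r
rep <- run_experiment(list(n_images = 5, size = 256, seed = 42,
                           enhancements = c("equalize", "normalize"),
                           classifiers = c("random_forest", "bayes_net")))
rep$grid
#>   enhancement        family mean_accuracy mean_macro_f1
#> 1    equalize random_forest         0.996         0.995
#> 2   normalize random_forest         0.995         0.995
#> 3   normalize     bayes_net         0.976         0.977
#> 4    equalize     bayes_net         0.968         0.971
rep$best[c("enhancement", "family")]
#> $enhancement
#> [1] "equalize"
#> $family
#> [1] "random_forest"
rep$segmentation[, 1:3]
#>      image accuracy macro_f1
#> 1 image_01    0.914    0.915
#> 2 image_02    0.898    0.896
#> 3 image_03    0.867    0.865
#> 4 image_04    0.878    0.881
#> 5 image_05    0.871    0.865
```

The grid rows are leave-one-image-out means per (enhancement, classifier)
pair, best first — here histogram equalization + random forest, which is
then retrained on all five images. The `segmentation` table scores the
reconstructed label images against the *pixel-level* ground truth; these
values are bounded by how well 30-px superpixels can trace tumor
boundaries (cross-validated accuracy *at superpixel level* is ~0.99,
while pixel-level agreement pays the boundary quantization cost).

A command-line wrapper for simulation and full runs ships in
`inst/cli/tmaseg.R`:

```sh
Rscript inst/cli/tmaseg.R simulate --n 10 --seed 42 --out data/
Rscript inst/cli/tmaseg.R run --config run.cfg
```

## Documentation

The methods vignette (`vignettes/tmaseg-methods.Rmd`) documents the
models, every tunable parameter with its default and rationale, the
synthetic generator's scope, numerical conventions and known limitations.
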