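# cometrics

Quantitative comet assay (single-cell gel electrophoresis) image analysis
in R. In a comet assay, electrophoresed single-cell DNA images as a
"comet": a bright near-spherical **head** of intact DNA and a **tail** of
migrated fragments that grows with DNA damage. `cometrics` segments comets
and their heads in fluorescent *and* silver-stained micrographs, extracts
the 21 standard intensity/morphological features per comet, classifies
damage with classical machine-learning algorithms, and scores instance
segmentations with a per-object Jaccard procedure. A synthetic comet
generator with exact ground truth makes the whole pipeline testable
without any external data.

It is aimed at radiation-biology, genotoxicity and oncology labs that want
scriptable, reproducible comet quantification rather than an interactive
GUI.

## The methods at the core

**Segmentation.** Each comet is segmented inside a region of interest by
grey-level histogram thresholding with one of three modalities — Otsu
(maximal between-class variance), the Zack *triangle* method (maximal
perpendicular distance from the histogram to the peak-to-tail line), or
their arithmetic **average** — with multiplicative threshold scaling and
optional mask dilation as user adjustments. The head is the
super-threshold connected component containing the comet's intensity
maximum (no left-to-right orientation assumption); the tail is the comet
minus the head.

**Features** (per comet, head, tail): Area, Max Length, Mean/Std/Sum
Intensity; Sphericity = sqrt(4·π·Area) / Perimeter (comet, head);
PercentDNA = 100 · region_sum / comet_sum (head, tail); and for the tail

    Extent Moment = Tail Max Length · (Tail Sum / Comet Sum)
    Olive Moment  = |Head centroid − Tail centroid| · (Tail Sum / Comet Sum)

**Classification.** Decision tree, k-nearest neighbours, naive Bayes and
SVM on z-scored features, with unlimited integer damage classes
(conventionally 1 = undamaged … 5 = nearly all tail).

**Evaluation.** For label masks (0 = background, k = object k), each
ground-truth object is paired with the prediction of maximum overlap; less
than 50% overlap scores 0, otherwise the pairwise Jaccard index
|A∩B| / |A∪B|; the mean over ground-truth objects is reported.

## Worked example

Simulate a noiseless scene with known ground truth, segment it
semi-automatically, measure, classify and evaluate:

```r
library(cometrics)

ds    <- generate_dataset(1, comets_per_image = c(6, 6),
                          image_shape = c(500, 650),
                          noise = list(gaussian_sd = 0, background_level = 10),
                          seed = 42)
truth <- ds[[1]]
img   <- ingest_image(truth$image)          # bright-comet convention
rois  <- truth_rois(truth)                  # one circle per comet
segs  <- lapply(seq_along(rois), function(i)
  segment_roi(img, rois[[i]], threshold_settings("triangle"), comet_id = i))
feats <- do.call(rbind, lapply(segs, function(s) comet_features(img, s)))
feats[, c("comet_id", "comet_area", "tail_percent_dna",
          "tail_extent_moment", "tail_olive_moment")]
#>   comet_id comet_area tail_percent_dna tail_extent_moment tail_olive_moment
#> 1        1        481             0.00               0.00              0.00
#> 2        2       2011            46.68              39.14             12.89
#> 3        3        293             0.00               0.00              0.00
#> 4        4       2758            51.35              68.33             13.81
#> 5        5       1130            29.54              19.54              3.47
#> 6        6       3588            52.30              71.20             11.30
```

Comets 1 and 3 are undamaged (no tail, 0% tail DNA); the others carry
29–52% of their DNA in the tail, with correspondingly larger Extent and
Olive moments. Scoring the predicted comet masks against the generator's
ground truth:

```r
pred <- matrix(0L, img$height, img$width)
for (s in segs) pred[s$comet_mask] <- s$comet_id
multi_object_ji(truth$comet_mask, pred)
#> multi-object Jaccard: 6 GT objects, 5 matched, mean JI 0.7650
```

Training a damage classifier on 300 rendered comets with ground-truth-mask
features and applying it to the measured comets:

```r
tab   <- synthetic_feature_table(300, seed = 7)
model <- train_classifier(tab, "decision_tree", seed = 1)
predict(model, feats)
#> [1] 1 4 1 5 3 5      # true classes: 1 3 1 5 4 5
```

The undamaged and heavily damaged comets are recovered exactly; the two
mid-range comets land in adjacent classes because thresholding splits
their head/tail boundary slightly differently than the geometric truth.

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "cometr", package = "cometrics")`):

```sh
cometr simulate --n-images 2 --comets 20:100 --stain fluorescent --seed 7 --out sim/
cometr segment  --image img.tif --modality triangle --out masks/
cometr measure  --image img.tif --comet-mask c.png --head-mask h.png --out feats.csv
cometr classify-train --features feats.csv --algo tree --out model.rds
cometr classify-predict --model model.rds --features new.csv --out labels.csv
cometr evaluate --gt gt.png --pred pred.png --out report.csv
cometr run --images a.tif,b.tif --modality triangle --seed 1 --out results/
```

## Package layout

- `R/` — image/mask/project I/O, synthetic generator, thresholds and
  segmentation, features, classifiers, Jaccard evaluation, pipeline.
- `src/` — a minimal zlib-based 16-bit grayscale PNG encoder for label
  masks (no installed R package writes 16-bit PNG).
- `vignettes/cometrics-methods.Rmd` — the models, parameter choices,
  numerical conventions and limitations, in detail.
- `tests/testthat/` — unit, property and acceptance suites, all on
  generated data.
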