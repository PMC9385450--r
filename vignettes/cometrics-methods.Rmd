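---
title: "Methods: comet segmentation, features and evaluation in cometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comet segmentation, features and evaluation in cometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometrics)
```

## The measurement problem

In single-cell gel electrophoresis (the comet assay), cells embedded in
agarose are lysed and electrophoresed; fragmented DNA migrates farther than
intact DNA, so a damaged cell images as a "comet": a bright, near-spherical
head of intact nuclear DNA and a one-sided tail of migrated fragments whose
extent and intensity grow with damage. Quantification requires three
segmentations per cell — comet vs background, head vs tail — followed by
intensity/morphological feature extraction, and often a damage-class call
per comet. `cometrics` implements this pipeline for both fluorescent images
(bright comets on a dark background) and silver-stained brightfield images
(dark comets on a bright background).

## Stain handling

All analysis assumes bright comets. Silver-stained images are
intensity-inverted at ingestion (`v -> max_grey - v`, where `max_grey` is
`2^bit_depth - 1`), so a single code path serves both stains; writing an
ingested silver image back to disk undoes the inversion. RGB inputs are
collapsed with Rec. 601 luminance weights. 16-bit data keep their raw
values for feature extraction; only threshold statistics are computed on a
256-level binned histogram, which keeps the threshold estimates stable.

## Threshold modalities

Semi-automatic segmentation is histogram thresholding inside a
user-supplied region of interest (ROI) around one comet. Three modalities
are provided, all operating on the 256-bin grey-level histogram:

* **Otsu** — the threshold maximising the between-class variance of the
  two classes `{level <= t}` and `{level > t}`; ties broken toward the
  lowest level. Foreground is strictly above the threshold.
* **Triangle (Zack)** — a line is drawn from the histogram peak to the
  farthest nonempty level on the longer-tail side (the brighter side when
  both reach equally far); the threshold is the level between them with
  maximum perpendicular distance to that line, taking the first maximum
  scanning from the peak toward the tail. Peak ties break toward the lower
  (background) level. Because the perpendicular-distance argmax is
  invariant to rescaling of counts, no histogram normalisation is needed.
* **Average** — the arithmetic mean of the two.

Both primitive modalities are verified in the test suite against exhaustive
brute-force scans over all candidate levels on randomized histograms.

In practice the triangle modality is the recommended default for the
comet/background stage: a local ROI histogram is dominated by a large
background spike with a long, thin bright tail, precisely the regime the
triangle construction was designed for. Otsu, a balanced two-class
criterion, tends to place the comet/background cut far into the comet and
amputate dim tails.

## Comet and head segmentation

Inside an ROI (circle, box, or freehand polygon rasterized with an even-odd
boundary-inclusive rule), segmentation proceeds as:

1. threshold the ROI histogram with the selected modality, multiply by
   `comet_scale` (a monotone user adjustment), and keep pixels strictly
   above the result;
2. among 4-connected foreground components, keep the one with the highest
   peak intensity (ties: larger area, then smaller label) — the comet;
3. optionally dilate the comet mask by a disc of radius `dilation_radius`
   (dilation precedes the head/tail split so `head ⊆ comet` holds by
   construction);
4. threshold the histogram of the comet's own pixels, scaled by
   `head_scale`; the head is the super-threshold component containing the
   comet's intensity maximum; the tail is the set difference.

Two deliberate choices in step 4:

* **The head/tail statistic is always the Otsu/triangle average**,
  regardless of the modality chosen for the comet/background stage. On
  comet-only histograms Otsu systematically shrinks the head (cutting
  mid-intensity head pixels into the tail) while triangle absorbs the
  bright tail root into the head; their mean balances the two biases. On
  rendered comets with a known 50% tail-intensity fraction, the averaged
  statistic recovers tail PercentDNA within a few points, where either
  single statistic errs by 15–25.
* **A displacement rule suppresses phantom tails.** For an undamaged comet
  the sub-threshold pixels form a dim rim *around* the head; calling that
  rim a tail would assign spurious damage. If the centroid of the
  candidate tail lies within 0.3 equivalent-head-radii of the head
  centroid, the whole comet is taken as head and the tail is empty. Real
  tails displace the candidate centroid by far more than this.

The head definition is orientation-free: no left-to-right comet layout is
assumed anywhere, since the brightest pixels of a comet sit in the head
regardless of the electrophoresis direction.

Automatic detection (`detect_comets()`) is a classical front-end standing
behind a pluggable interface: a global average-modality threshold,
connected components filtered by area and border contact, one padded
circular ROI per surviving component. A learned detector can replace it by
returning the same list of ROIs.

## The 21 features

For each comet, `comet_features()` reports, per region (whole comet, head,
tail): area in pixels; max length (the longest mask chord through the
intensity-weighted centroid, sampled at 1° steps, with a Feret-diameter
fallback when the centroid lies off the mask); mean, population standard
deviation and sum of raw intensities. Sphericity
(`sqrt(4 * pi * area) / perimeter`, 1 for a circle, clamped to `[0, 1]`
against rasterization overshoot) is reported for comet and head; the
perimeter estimator is the traced boundary polygon length with diagonal
steps counted as `sqrt(2)`, so sphericity is reproducible bit for bit.
PercentDNA (`100 * region_sum / comet_sum`) is reported for head and tail
and sums to exactly 100 whenever head and tail partition the comet. The
tail adds the two damage moments:

* **Extent Moment** = tail max length × (tail sum / comet sum);
* **Olive Moment** = Euclidean distance between head and tail centroids ×
  (tail sum / comet sum).

Centroids are intensity-weighted by default (the DNA-mass reading of the
Olive moment); geometric centroids are available via
`weighted_centroids = FALSE`. A comet with an empty tail reports zeros for
all tail features — never missing values — keeping measurement tables
rectangular and undamaged comets representable. User-defined features
(`register_feature()`) receive the image and all three masks and appear as
extra CSV columns; non-finite returns are recorded as missing with a
warning.

## Classification

Damage classes are opaque positive integers, so any number of classes or
sub-classes is supported. Four classical families are provided with
conventional defaults: a CART decision tree (Gini impurity), k-nearest
neighbours (Euclidean, `k = 5`), Gaussian naive Bayes, and an RBF-kernel
SVM (one-vs-one, `cost = 1`, `gamma = 1/p`). Features are z-scored with
training statistics stored in the model; constant columns pass through
unscaled. Naive Bayes receives a small per-class standard-deviation floor
(`1e-3` on the z-scored scale) because tail features are identically zero
within the undamaged class and would otherwise produce degenerate Gaussian
densities. Feature selection is an explicit include-list — no automatic
selection. Training and prediction are deterministic given the model seed
(kNN vote ties are resolved under the stored seed).

## Multi-object Jaccard evaluation

Instance segmentations are scored per ground-truth (GT) object: each GT
object is paired with the predicted object covering the largest share of
its pixels; if that share is below 50% the object scores 0 and stays
unmatched, otherwise it scores the pairwise Jaccard index
`|A ∩ B| / |A ∪ B|` with its match; the summary is the mean over GT
objects. The overlap fraction's denominator is the GT object's area by
default (configurable to the union), ties between predictions break toward
the lower ID, and a predicted object may serve several GT objects. An
optional one-to-one mode assigns predictions greedily by descending
overlap so each is used at most once; it is off by default because the
per-GT procedure is the reference behaviour. Two empty masks have pairwise
JI 0 by convention; an empty GT mask is an error (the mean is undefined).

## The synthetic generator

`generate_dataset()` renders scenes with exact ground truth so every stage
is testable without external data. The photometric model per comet: an
isotropic Gaussian-profile head disc (`sigma = head_radius / 2`) and a
one-sided tail lobe along the shared electrophoresis direction with
exponential axial decay (`lambda = tail_length / 3`) and Gaussian
cross-section, scaled analytically so the tail's integrated intensity over
the comet total equals the requested `tail_fraction` (±1% before noise; a
truncation warning reports the achieved value otherwise). Masks keep only
pixels carrying at least 1.5 grey levels of signal — one quantization step
above background is not a recoverable object pixel at 8 bits — so the
ground truth equals the detectable signal support and is exactly
recoverable in the noiseless limit.

Defaults emulate the two dataset regimes the tool targets: fluorescent
1200 × 1600 px scenes with 20–100 comets, and silver 1280 × 1024 px scenes
with 2–20 comets (rendered dark-on-bright as acquired). Head radii are
drawn from 8–14 px and head peaks from 60–90% of the grey range — 10×
magnification scales, chosen as documented defaults since the generator's
intensity statistics are a modelling choice, not a measured property.
Damage classes follow the conventional five-category scheme; the
tail-fraction bins are `[0, 0.05)`, `[0.05, 0.25)`, `[0.25, 0.5)`,
`[0.5, 0.8)`, `[0.8, 1]`, with class 1 rendered tail-free ("no or barely
detectable tails") and class 5 capped at a 0.95 fraction so the head keeps
nonzero mass. Tail length grows with the tail fraction
(`30 + 90 * fraction` px). Comets are placed by rejection sampling with
non-overlapping comet masks (2 px clearance); a scene too dense to place
raises an explicit error. Noise is additive Gaussian (default SD 5) on a
constant background (default 10), clipped to the bit depth; Poisson noise
and uneven illumination are deliberately not modelled.

What passing on synthetic data does and does not show: the generator
exercises stain conventions, threshold behaviour on skewed histograms,
head/tail geometry, feature formulas and the evaluation protocol, but its
comets are isolated, its background flat, and its noise white — real
micrographs add overlap, illumination gradients, debris and halo
artefacts, so quality numbers on synthetic scenes are an upper bound, not
a forecast, for real images.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)`; masks are boundary-inclusive;
  connected components are 4-connected.
* Histograms use 256 bins; a threshold at level `t` means foreground is
  strictly above `(t + 0.5) * bin_width` after scaling, clipped to the
  representable range.
* Constant images warn as degenerate; single-level histograms error.
* Empty segmentation (no pixel above the comet threshold) is a per-ROI
  error, skipped and logged by the pipeline rather than aborting the run.
* A polygon contour containing no pixel above the image-wide comet
  threshold is rejected as lying over background.
* Label masks are written as 16-bit grayscale PNG (up to 65535 objects,
  exact round trip); the bit depth of a mask file is read from its PNG
  header, never guessed from pixel values.
* Projects serialize to a canonical JSON document plus sidecar mask PNGs;
  saving, loading and saving again is byte-identical, and a format-version
  mismatch is an explicit error, never a silent reinterpretation.

## Problem sizes used in the checks

The bundled verification suites run entirely on generated data: threshold
oracles on 50+ randomized histograms; classifier recovery on 1000 rendered
comets with ground-truth-mask features (5-fold cross-validated decision
tree, accuracy ≥ 0.8 expected since PercentDNA nearly separates the
tail-fraction bins); segmentation quality on noiseless seeded scenes of
15–25 comets at 800 × 1000 px, scored with the multi-object Jaccard
procedure against generator truth (mean JI ≥ 0.8 with the triangle
modality and ground-truth-derived circular ROIs). These sizes are the
package's own validation choices and scale linearly if larger studies are
wanted.

## Known limitations

* Head detection keys on the intensity maximum; for heavily damaged comets
  ("just tails without visible nuclei") the brightest pixels can sit in
  the tail root, and an intensity criterion cannot recover a head that is
  not visibly there. Class-5 morphology is therefore measured but its
  head/tail split is unreliable — as it is for any intensity-based tool.
* Measured PercentDNA includes the background pedestal under the masks; no
  background subtraction is applied. On noisy images the dim tail fringe
  present in the ground truth is genuinely unrecoverable, so Jaccard
  scores against synthetic truth degrade with noise even when the visible
  comet is segmented well.
* Touching or overlapping comets are not separated; the generator never
  produces them and the detector will merge them.
* The deep-learning segmentation route of the original tool is out of
  scope; `detect_comets()` is a classical stand-in behind the same
  interface.
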