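Package: cometrics
Title: Quantitative Comet Assay Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation, feature extraction, classification and evaluation
    for single-cell gel electrophoresis ("comet assay") micrographs, in both
    fluorescent- and silver-stained modalities. Comets and their heads are
    segmented with histogram-threshold modalities (Otsu, Zack triangle, and
    their average) inside user-supplied or automatically proposed regions of
    interest; 21 intensity/morphological features (including PercentDNA and
    the Extent and Olive tail moments) are extracted per comet; comets are
    classified with decision trees, k-nearest neighbours, naive Bayes or
    support vector machines; instance segmentations are scored with a
    per-object Jaccard index using maximum-overlap pairing and a 50% overlap
    gate. A synthetic comet image generator with exact ground truth supports
    end-to-end validation without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jpeg,
    jsonlite,
    e1071,
    rpart,
    class,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: zlib
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
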