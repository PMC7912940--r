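---
title: "Multiscale three-pathway segmentation and tumor typing: methods"
author: "triseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale three-pathway segmentation and tumor typing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`triseg` segments and types brain tumors in single 2D contrast-enhanced
(T1-CE) MRI slices. Three tumor classes are handled — meningioma (label 1),
glioma (label 2) and pituitary tumor (label 3) — plus a healthy label 0.
Skull and other non-brain structures are deliberately *not* stripped from
the input: the classifier itself must learn to reject them, which is one of
the harder aspects of the task (bright skull rings and sinus structures are
frequent false-positive sources).

Segmentation is cast as sliding-window pixel classification. Each pixel is
represented by its N x N neighborhood (N = 65 in the reference
configuration) and classified independently. The network processes every
window along three parallel convolutional pathways operating at three
feature scales, with kernels of 11x11, 7x7 and 3x3 and 128, 96 and 64
feature maps respectively — more maps at coarser scales. Each pathway is two
stages of [same-padding convolution -> ReLU -> 3x3 max-pool, stride 2].
Pathway outputs are concatenated along the feature axis (288 maps),
processed by one more 3x3 convolution (128 maps) with ReLU and a 2x2
stride-2 pool, flattened, passed through dropout (p = 0.5), and mapped by a
single fully connected layer to 4 softmax outputs.

Two printed facts pin down the conventions that the reference never states
explicitly. With same-padding convolutions and ceiling-mode pool sizing
(`out = ceil((n - k)/stride) + 1`), the spatial trace is 65 -> 32 -> 16 -> 8,
giving 128 x 8^2 = 8192 flattened features, and the parameter count is

    pathways   1,998,208 + 456,480 + 37,568 = 2,492,256
    concat     128 x (9 x 288 + 1)          =   331,904
    fully conn (8192 + 1) x 4               =    32,772
    total                                   = 2,856,932

which matches the published figure exactly. Floor-mode pooling, valid
convolutions, a hidden fully-connected layer, or unbiased convolutions all
break one of the two identities, so the configuration recorded in
`network_config()` is the unique natural reading. `count_parameters()`
implements the closed form; the test suite checks it against enumeration of
instantiated layer shapes on randomized configurations.

The network itself is implemented in this package (im2col/col2im
convolution and ceiling-mode max-pooling as C++ kernels via Rcpp and
RcppArmadillo, with the layer graph, softmax/cross-entropy and SGD in R),
since the contribution of the method *is* this architecture. The backward
pass is verified against central finite differences in the tests. When the
three pathway kernels are equal (as in scaled-down test configurations),
the three stage-1 convolutions share one im2col expansion and run as a
single matrix product; gradient tests cover the merged and unmerged paths
separately.

## From label map to slice diagnosis

Inference labels every pixel, producing a label map P. Slice-level typing
is a direct aggregation of the segmentation: for each class l, the ratio
`f_l = |P == l| / |P > 0|` measures the fraction of tumor-labeled pixels
carrying class l. Ratios not strictly above a confidence threshold
`tau_c` are zeroed; the surviving maximum determines the slice label, and
if none survives the slice is *non-classified* (label -1). The reference
operating point is `tau_c = 0.75`; `threshold_precision_curve()` exposes
the full threshold/precision trade-off.

Per-slice segmentation quality is scored against the expert mask T with
`P1 = {P == l_gt}` (the region of the slice's true class): Dice
`2TP/(2TP+FP+FN)`, Sensitivity `TP/(TP+FN)`, and `pttas = |P1|/|P > 0|`,
the fraction of all tumor-labeled pixels with the correct class. Note the
published prose displays segmentations as `{P > 0}` while the metric
formulas score `P1`; the package follows the formulas for metrics and uses
`{P > 0}` for the red/green/yellow overlays, matching both conventions in
their own context.

Slice-level results aggregate into a 3x3 confusion matrix with an extra
non-classified column. Accuracy is `sum(diag)/total` with non-classified
slices *in the denominator*: the published counts (2984 correct of 3064,
61 non-classified) yield 0.97389, printed as 0.973 — which shows the
summary values are truncated, not rounded, to three decimals. Published
per-class averages behave the same way (e.g. mean Dice 0.82866 printed as
0.828), so `macro_average()` and `build_confusion()` expose a truncation
mode used when matching printed values.

## Training protocol

Each cross-validation fold trains for 80 epochs of mini-batch SGD
(momentum 0.9, starting learning rate 0.005, stepwise exponential decay
every 20 epochs, dropout 0.5). The loss is categorical cross-entropy (the
natural partner of a softmax output; the reference names none). The decay
factor (default 0.1) and batch size (default 128) are likewise unstated
upstream and are exposed as configuration with those defaults.

Training windows are sampled per training slice: 150 centered on tumor
pixels and 325 on healthy pixels ("per tumor" is read as "per training
slice", since every slice carries exactly one tumor). Negative centers are
drawn from *all* non-tumor pixels, including skull and background — the
method must learn to reject non-brain structures, and the published
failure cases show exactly such confusions. Windows overrunning the slice
edge are zero-padded, at training and at test time, so corner pixels stay
classifiable. The pooled pixel mean and standard deviation of all training
windows standardize both training and testing windows; the statistics are
computed once per fold from training data only and reused unchanged at
test time.

Each fold is augmented by exactly one elastic-deformation copy per
training slice (2452 slices become 4904 in the reference protocol). The
deformation smooths a per-pixel uniform(-1,1) displacement field with a
Gaussian of bandwidth `sigma` and scales it by `alpha`; image and mask are
warped by the *same* field, the image bilinearly (clamp-to-edge, so warped
intensities are convex combinations of the originals) and the mask by
nearest neighbor (so it stays binary); the border polyline is re-derived
from the warped mask. The transform's parameters are not published;
defaults scale with resolution (`alpha = 0.1 * image_size`,
`sigma = 0.02 * image_size`) and are configurable.

## The phantom generator

Real T1-CE records (512x512 slices with patient id, class label, border
polyline and binary mask) require a large download and days of GPU
training, so every stage of the pipeline is exercised on synthetic
phantoms with the same record structure and the same statistical
challenges: a dark background, a bright unstripped skull ring (an ellipse
annulus), a smooth brain interior with low-frequency intensity variation,
a bright sinus-like blob near the inferior midline, and exactly one lesion
per slice. Lesion placement mimics the classes' anatomy-driven confusion
sources: meningiomas abut the inner skull boundary, gliomas sit in deep
parenchyma, pituitary lesions lie near the sinus blob. Class textures are
parameterized by base intensity, contrast and spatial frequency; defaults
make meningiomas bright and homogeneous, gliomas darker and strongly
heterogeneous, pituitary lesions intermediate, so within-lesion local
variance separates the classes — a property the tests assert. Intensities
are floats in [0, 1]; the arbitrary intensity scale of real data is
irrelevant after standardization.

Phantoms are *not* anatomically realistic MRI (no bias fields, no k-space
artifacts, no partial-volume effects, single lesion, no 3D consistency).
Passing tests on phantoms demonstrates that the pipeline's machinery —
sampling, augmentation, training dynamics, inference, aggregation,
scoring — is correct and reproducible, not that the reported real-data
accuracy transfers; reproducing the published headline numbers requires
the real dataset and full-scale training.

Records serialize one per file with the field names of the source datasets
(`pid`, `label`, `image`, `tumorBorder`, `tumorMask`) plus a CSV manifest
and a JSON fold-index file. Border coordinates are stored 0-based
((row, col); a stored (x, y) ordering is auto-detected by validating
border points against the mask and flipping if most points miss).
Internally the package uses R-native 1-based (row, col) indexing
throughout, converting only at the serialization boundary — fighting R's
indexing convention internally would be a standing source of off-by-one
errors. The real datasets ship MATLAB v7.3 (HDF5) containers; no HDF5
reader is part of this package's dependency set, so `read_record()`
recognizes the HDF5 signature and asks for a one-time conversion to the
fixture container instead of guessing.

## Cross-validation and folds

Five-fold cross-validation follows the published protocol (80%/20% splits,
each slice tested exactly once). When a dataset ships its own fold
indices, `load_fold_indices()` validates and uses them. Synthetic datasets
use `make_stratified_folds()`: slices are dealt per class with remainders
assigned to the smallest folds (for the published class mix of
708/1426/930 this produces test sets of 612-613 slices), and with
`patient_aware = TRUE` all slices of a patient share one test set,
patients being assigned greedily (largest groups first) to the fold with
the fewest slices of that class. Note 5 x 612 is less than 3064, so the
published "612 per fold" cannot be exact for all folds; the partition rule
above is the package's resolution, with no claim of matching the shipped
indices.

## Numerical choices and degenerate inputs

* Pooling ties take the first element in column-major scan order;
  probability ties take the smallest label; nearest-center fill ties (for
  strided inference) take the top-left center. All are deterministic.
* `classify_slice` survives only ratios *strictly* above `tau_c`; an
  all-healthy label map is non-classified.
* Dice is defined 1 when prediction and truth are both empty (unreachable
  for valid records, which require nonempty masks); `pttas` is 0 when no
  pixel is labeled tumor.
* A slice whose elastic copy loses its whole lesion is retried with a
  fresh derived seed a bounded number of times, then errors.
* Every stochastic step (phantoms, folds, sampling, initialization,
  shuffling, dropout, deformation) derives its stream from an explicit
  seed and restores the caller's RNG state; identical seeds reproduce
  identical evaluation reports byte-for-byte.

## Scaled-down study sizes

Desk-scale verification uses reduced problem sizes chosen once: phantoms
of 96-128 pixels per side, toy networks with pathway maps [16, 12, 8] or
smaller, 13-17 pixel windows, tens of windows per slice, strided (4-12 px)
inference, and 10 or fewer epochs. The end-to-end learning check trains
the [16, 12, 8] toy (32 concatenation maps) on 60 phantoms (20 per class,
128 px, 5 patient-aware folds) with 15-px windows, 40 positive / 80
negative windows per slice, batch 64, 10 epochs, and a compressed
schedule — learning rate 0.02 halved every 4 epochs — then requires
slice-classification accuracy of at
least 0.80 at `tau_c = 0` in at least 4 of 5 seeds. The schedule is
steeper than the full-scale default because the toy problem must converge
within 10 epochs; elastic copies are omitted in this run (augmentation
correctness is asserted by its own tests, and the toy task does not
overfit in 10 epochs). Determinism of the full report JSON is asserted on
a smaller two-fold run with identical machinery. Full-scale training
(65-px windows, 80 epochs, 512-px slices) uses exactly the same code
paths and is supported but not exercised by the tests.

## Known limitations

* Phantom textures are a stand-in; no claim is made that they match real
  tumor appearance statistically.
* Dense stride-1 inference on 512x512 slices is computationally heavy by
  design (sliding-window, not fully convolutional); strided inference with
  nearest-center fill is an artifact extension, exact only for inputs
  constant within each fill cell.
* No DICOM/NIfTI ingestion, no 3D volume assembly, no HDF5 reading.
* Single-lesion-per-slice assumption matches the source datasets but not
  multifocal disease.
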