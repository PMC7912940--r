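#' Confidence-thresholded slice classification
#'
#' From a per-pixel label map, computes the per-class ratios
#' `f_l = |P == l| / |P > 0|` for `l` in 1..3, zeroes every ratio not
#' strictly above the confidence threshold `tau_c`, and predicts the label
#' with the largest surviving ratio (ties toward the smallest label). If no
#' ratio survives, or no pixel is labeled as tumor, the slice is
#' non-classified (`lp = -1`).
#'
#' @param label_map a `triseg_label_map` or an integer matrix of labels.
#' @param tau_c confidence threshold in \[0, 1\].
#' @return list with `ratios` (length 3), `tau_c`, `lp` in `{-1, 1, 2, 3}`.
#' @export
classify_slice <- function(label_map, tau_c = 0.75) {
  stopifnot(tau_c >= 0, tau_c <= 1)
  L <- if (inherits(label_map, "triseg_label_map")) label_map$labels else label_map
  counts <- vapply(1:3, function(l) sum(L == l), 0L)
  total <- sum(counts)
  ratios <- if (total > 0) counts / total else c(0, 0, 0)
  classify_from_ratios(ratios, tau_c)
}

classify_from_ratios <- function(ratios, tau_c) {
  f <- ifelse(ratios > tau_c, ratios, 0)
  lp <- if (all(f == 0)) -1L else as.integer(which.max(f))
  list(ratios = ratios, tau_c = tau_c, lp = lp)
}

#' Per-slice segmentation metrics
#'
#' Scores the predicted region of the slice's true class,
#' `P1 = {P == l_gt}`, against the ground-truth mask `T1`:
#' `Dice = 2TP / (2TP + FP + FN)`, `Sensitivity = TP / (TP + FN)`, and the
#' predicted-tumor-type ratio score `pttas = |P1| / |P > 0|` (0 when no
#' pixel is labeled tumor).
#'
#' @param label_map a `triseg_label_map` or integer label matrix.
#' @param record the slice record holding `label` and `mask`.
#' @return list with `dice`, `sensitivity`, `pttas`, `tp`, `fp`, `fn`.
#' @export
slice_metrics <- function(label_map, record) {
  L <- if (inherits(label_map, "triseg_label_map")) label_map$labels else label_map
  if (!identical(dim(L), dim(record$mask)))
    stopf("triseg_shape_error", "label map shape %s does not match mask %s",
          paste(dim(L), collapse = "x"),
          paste(dim(record$mask), collapse = "x"))
  P1 <- L == record$label
  T1 <- record$mask == 1L
  tp <- sum(P1 & T1)
  fp <- sum(P1) - tp
  fn <- sum(T1) - tp
  n_tumor_pred <- sum(L > 0L)
  list(dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 1,
       pttas = if (n_tumor_pred > 0) sum(P1) / n_tumor_pred else 0,
       tp = tp, fp = fp, fn = fn)
}

#' Arithmetic mean with optional 3-decimal truncation
#'
#' The printed per-class summary tables this package reproduces truncate
#' (not round) their averages to three decimals; `truncate = TRUE` applies
#' the same convention.
#'
#' @param values nonempty numeric vector.
#' @param truncate truncate the mean to `digits` decimals.
#' @param digits decimals kept when truncating.
#' @return the (possibly truncated) mean.
#' @export
macro_average <- function(values, truncate = FALSE, digits = 3) {
  if (length(values) == 0)
    stopf("triseg_validation_error", "macro_average of empty input")
  m <- mean(values)
  if (truncate) truncate_decimals(m, digits) else m
}

#' Confusion matrix with a non-classified category
#'
#' Tallies slice-level predictions into a 3x3 confusion matrix (true class
#' x predicted class) plus a per-class non-classified column (`lp = -1`).
#' Accuracy is `sum(diag) / total slices` with non-classified slices in the
#' denominator, truncated to three decimals; per-class sensitivity is
#' `diag / full true-class count`, rounded to two decimals.
#'
#' @param truths per-slice true labels in `{1, 2, 3}`.
#' @param predictions per-slice predicted labels in `{-1, 1, 2, 3}` (or a
#'   list of [classify_slice()] results).
#' @return list with `confusion` (3x4 matrix, last column `NC`),
#'   `accuracy`, `accuracy_exact`, `per_class_sensitivity`,
#'   `non_classified`, `n`.
#' @export
build_confusion <- function(truths, predictions) {
  if (is.list(predictions))
    predictions <- vapply(predictions, `[[`, 0L, "lp")
  if (!all(truths %in% 1:3))
    stopf("triseg_validation_error", "true labels must be in {1,2,3}")
  if (!all(predictions %in% c(-1L, 1L, 2L, 3L)))
    stopf("triseg_validation_error",
          "predicted labels must be in {-1,1,2,3}")
  cm <- matrix(0L, 3, 4, dimnames = list(
    true = c("meningioma", "glioma", "pituitary"),
    pred = c("meningioma", "glioma", "pituitary", "NC")))
  for (i in seq_along(truths)) {
    col <- if (predictions[i] == -1L) 4L else predictions[i]
    cm[truths[i], col] <- cm[truths[i], col] + 1L
  }
  n <- length(truths)
  acc <- sum(diag(cm[, 1:3])) / n
  row_tot <- rowSums(cm)
  list(confusion = cm,
       accuracy = truncate_decimals(acc, 3),
       accuracy_exact = acc,
       per_class_sensitivity = round(diag(cm[, 1:3]) / row_tot, 2),
       non_classified = cm[, 4],
       n = n)
}

#' Confidence-threshold versus precision curve
#'
#' Re-thresholds stored per-slice ratio vectors over a grid of confidence
#' thresholds and reports, for each, the classification accuracy
#' (`sum(diag) / total`, non-classified in the denominator) and the number
#' of classified slices (non-increasing in the threshold).
#'
#' @param truths per-slice true labels.
#' @param ratios n x 3 matrix of per-slice class ratios (pre-threshold).
#' @param taus threshold grid in \[0, 1\].
#' @return data frame with `tau`, `precision`, `n_classified`.
#' @export
threshold_precision_curve <- function(truths, ratios,
                                      taus = seq(0, 0.95, by = 0.05)) {
  stopifnot(all(taus >= 0 & taus <= 1))
  ratios <- as.matrix(ratios)
  out <- lapply(taus, function(tau) {
    lp <- apply(ratios, 1, function(r) classify_from_ratios(r, tau)$lp)
    data.frame(tau = tau,
               precision = sum(lp == truths) / length(truths),
               n_classified = sum(lp != -1L))
  })
  do.call(rbind, out)
}

#' Histogram bin counts of a per-slice metric
#'
#' @param values metric values in \[0, 1\].
#' @param breaks histogram break points.
#' @return data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
metric_histogram <- function(values, breaks = seq(0, 1, by = 0.05)) {
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  data.frame(bin_lo = head(h$breaks, -1), bin_hi = h$breaks[-1],
             count = h$counts)
}

#' Render a segmentation or class-tag overlay
#'
#' Segmentation mode colors the predicted tumor region `{P > 0}` red, the
#' ground-truth mask green, and their intersection yellow, over the
#' grayscale slice. Class-tags mode colors pixels by predicted class
#' (1 red, 2 green, 3 blue).
#'
#' @param label_map a `triseg_label_map` or integer label matrix.
#' @param record the slice record (image + mask).
#' @param mode `"segmentation"` or `"class-tags"`.
#' @return an H x W x 3 RGB array in \[0, 1\].
#' @export
render_overlay <- function(label_map, record,
                           mode = c("segmentation", "class-tags")) {
  mode <- match.arg(mode)
  L <- if (inherits(label_map, "triseg_label_map")) label_map$labels else label_map
  if (!identical(dim(L), dim(record$image)))
    stopf("triseg_shape_error", "label map / image shape mismatch")
  g <- record$image
  rng <- range(g)
  if (diff(rng) > 0) g <- (g - rng[1]) / diff(rng)
  arr <- array(rep(g, 3), c(dim(g), 3))
  if (mode == "segmentation") {
    pred <- L > 0L
    gt <- record$mask == 1L
    red <- pred & !gt; green <- gt & !pred; yellow <- pred & gt
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[red] <- if (ch == 1) 1 else 0
      plane[green] <- if (ch == 2) 1 else 0
      plane[yellow] <- if (ch <= 2) 1 else 0
      arr[, , ch] <- plane
    }
  } else {
    for (cls in 1:3) {
      sel <- L == cls
      for (ch in 1:3) {
        plane <- arr[, , ch]
        plane[sel] <- if (ch == cls) 1 else 0
        arr[, , ch] <- plane
      }
    }
  }
  arr
}

#' Write an overlay PNG
#'
#' @param overlay RGB array from [render_overlay()].
#' @param path destination file.
#' @export
write_overlay_png <- function(overlay, path) {
  png::writePNG(overlay, path)
  invisible(path)
}
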