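#' Argmax class of a probability vector
#'
#' Index of the maximal probability minus one (labels are 0-based:
#' 0 healthy, 1-3 tumor classes); ties break toward the smallest label.
#'
#' @param probs numeric probability vector.
#' @return integer class label.
#' @export
argmax_label <- function(probs) {
  as.integer(which.max(probs) - 1L)
}

## Nearest-sampled-center fill map for one axis: for pixel p the index of
## its closest center in `centers`, ties toward the smaller coordinate.
nearest_center_map <- function(n, centers) {
  vapply(seq_len(n), function(p) which.min(abs(centers - p)), 0L)
}

#' Sliding-window segmentation of a slice
#'
#' Classifies every `stride`-th pixel by evaluating the model on its
#' zero-padded, standardized `window_size` window and assigning the argmax
#' class to the center. For `stride > 1`, unsampled pixels take the label
#' of their nearest sampled center (ties toward the top-left), so the
#' returned label map covers every pixel. `stride = 1` reproduces dense
#' per-pixel classification.
#'
#' @param model a `triseg_net` or [stub_model()].
#' @param stats training-fold [fit_standardization()] statistics.
#' @param image 2D grayscale matrix.
#' @param window_size window side in pixels (must match the model).
#' @param stride sampling stride in pixels.
#' @param batch_size windows per forward pass.
#' @return an object of class `triseg_label_map`: list with `labels`
#'   (integer matrix in `{0,1,2,3}`, same shape as `image`) and `stride`.
#' @export
segment_slice <- function(model, stats, image, window_size = model$config$window_size,
                          stride = 1L, batch_size = 256L) {
  stopifnot(stride >= 1L)
  if (window_size != model$config$window_size)
    stopf("triseg_shape_error",
          "window_size %d does not match model window_size %d",
          window_size, model$config$window_size)
  H <- nrow(image); W <- ncol(image)
  rc <- seq(1L, H, by = stride)
  cc <- seq(1L, W, by = stride)
  centers <- cbind(row = rep(rc, times = length(cc)),
                   col = rep(cc, each = length(rc)))
  n <- nrow(centers)
  lab <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    patches <- extract_windows(image, centers[start:end, , drop = FALSE],
                               window_size)
    probs <- forward_windows(model, standardize(patches, stats),
                             batch_size = batch_size)
    lab[start:end] <- max.col(probs, ties.method = "first") - 1L
  }
  grid <- matrix(lab, length(rc), length(cc))
  labels <- grid[nearest_center_map(H, rc), nearest_center_map(W, cc),
                 drop = FALSE]
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, stride = as.integer(stride)),
            class = "triseg_label_map")
}

#' Save a label map as a paletted PNG
#'
#' Class colors: 0 black, 1 red (meningioma), 2 green (glioma),
#' 3 blue (pituitary).
#'
#' @param label_map a `triseg_label_map`.
#' @param path destination PNG file.
#' @export
write_label_map_png <- function(label_map, path) {
  pal <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  L <- label_map$labels
  arr <- array(0, c(nrow(L), ncol(L), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(pal[L + 1L, ch], nrow(L), ncol(L))
  png::writePNG(arr, path)
  invisible(path)
}
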