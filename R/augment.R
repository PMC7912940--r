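#' Elastic-deformation parameters
#'
#' A per-pixel uniform(-1, 1) displacement field is smoothed with a
#' Gaussian of bandwidth `sigma` (pixels) and scaled by `alpha` (pixels).
#' Defaults scale with the slice resolution: `alpha = 0.1 * image_size`,
#' `sigma = 0.02 * image_size`.
#'
#' @param image_size slice side in pixels (sets the defaults).
#' @param alpha displacement magnitude in pixels.
#' @param sigma Gaussian smoothing bandwidth in pixels.
#' @param seed RNG seed.
#' @return an object of class `triseg_elastic_params`.
#' @export
elastic_params <- function(image_size = 256L, alpha = 0.1 * image_size,
                           sigma = 0.02 * image_size, seed = 1L) {
  if (alpha < 0) stopf("triseg_config_error", "alpha must be >= 0")
  if (sigma <= 0) stopf("triseg_config_error", "sigma must be > 0")
  structure(list(alpha = alpha, sigma = sigma, seed = as.integer(seed)),
            class = "triseg_elastic_params")
}

#' Elastically deform a slice record
#'
#' Image and mask are warped by the same smoothed random displacement
#' field: the image with bilinear interpolation (clamp-to-edge, so outputs
#' stay within the input intensity range), the mask with nearest-neighbour
#' interpolation (so it stays binary). The border polyline is re-derived
#' from the warped mask. `alpha = 0` is the identity. Deterministic under
#' `params$seed`.
#'
#' @param record a valid slice record.
#' @param params an [elastic_params()].
#' @return a new slice record with pid suffixed `"-aug"`.
#' @export
elastic_transform <- function(record, params) {
  validate_slice_record(record)
  stopifnot(inherits(params, "triseg_elastic_params"))
  H <- nrow(record$image); W <- ncol(record$image)
  out <- with_seed(params$seed, {
    drow <- gaussian_smooth(matrix(runif(H * W, -1, 1), H, W), params$sigma)
    dcol <- gaussian_smooth(matrix(runif(H * W, -1, 1), H, W), params$sigma)
    ri <- matrix(seq_len(H), H, W) + params$alpha * drow
    ci <- matrix(seq_len(W), H, W, byrow = TRUE) + params$alpha * dcol
    img <- matrix(bilinear_sample(record$image, as.vector(ri), as.vector(ci)),
                  H, W)
    msk <- matrix(nearest_sample(record$mask, as.vector(ri), as.vector(ci)),
                  H, W)
    list(img = img, msk = msk)
  })
  if (sum(out$msk) < 1L)
    stopf("triseg_augmentation_error",
          "elastic transform displaced the whole lesion out of frame (seed %d)",
          params$seed)
  storage.mode(out$msk) <- "integer"
  new_slice_record(pid = paste0(record$pid, "-aug"), label = record$label,
                   image = out$img, mask = out$msk,
                   border = mask_boundary(out$msk))
}

#' Augment a training fold by elastic deformation
#'
#' Returns the original records followed by exactly one elastic copy of
#' each, doubling the fold (2452 training slices become 4904). Per-record
#' seeds are derived from `params$seed`; a record whose deformation empties
#' the mask is retried with a fresh derived seed up to `max_retries` times.
#'
#' @param records nonempty list of slice records.
#' @param params an [elastic_params()].
#' @param max_retries reseeding attempts per record.
#' @return list of `2 * length(records)` records, originals first.
#' @export
augment_fold <- function(records, params, max_retries = 10L) {
  if (length(records) == 0)
    stopf("triseg_validation_error", "augment_fold needs a nonempty fold")
  copies <- vector("list", length(records))
  for (i in seq_along(records)) {
    res <- NULL
    for (try in 0:max_retries) {
      p_i <- params
      p_i$seed <- mix_seed(params$seed, i * 131L + try)
      res <- tryCatch(elastic_transform(records[[i]], p_i),
                      triseg_augmentation_error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res))
      stopf("triseg_augmentation_error",
            "record %d: elastic transform emptied the mask after %d retries",
            i, max_retries)
    copies[[i]] <- res
  }
  c(records, copies)
}

#' Sample training windows from one slice
#'
#' Draws `n_pos` window centers uniformly without replacement from mask
#' foreground (window label = the record's tumor class) and `n_neg` from
#' mask background including skull and image background (window label = 0).
#' Patches are zero-padded where the window overruns the slice edge.
#'
#' @param record a valid slice record.
#' @param n_pos,n_neg positive / negative windows (reference protocol:
#'   150 / 325 per training slice).
#' @param window_size patch side in pixels.
#' @param seed RNG seed.
#' @return list with `patches` (`window_size^2 x (n_pos + n_neg)` matrix),
#'   `labels` (center-pixel class in `{0, 1, 2, 3}`), `centers`
#'   (row/col matrix).
#' @export
sample_windows <- function(record, n_pos = 150L, n_neg = 325L,
                           window_size = 65L, seed = 1L) {
  validate_slice_record(record)
  fg <- which(record$mask == 1L)
  bg <- which(record$mask == 0L)
  if (length(fg) < n_pos)
    stopf("triseg_sampling_error",
          "slice has %d tumor pixels, fewer than n_pos = %d", length(fg), n_pos)
  if (length(bg) < n_neg)
    stopf("triseg_sampling_error",
          "slice has %d healthy pixels, fewer than n_neg = %d",
          length(bg), n_neg)
  H <- nrow(record$mask)
  sel <- with_seed(seed, {
    list(pos = sample(fg, n_pos), neg = sample(bg, n_neg))
  })
  lin <- c(sel$pos, sel$neg)
  centers <- cbind(row = (lin - 1L) %% H + 1L, col = (lin - 1L) %/% H + 1L)
  list(patches = extract_windows(record$image, centers, window_size),
       labels = c(rep(record$label, n_pos), rep(0L, n_neg)),
       centers = centers)
}

#' Pooled standardization statistics
#'
#' Mean and standard deviation over all pixels of all training windows
#' pooled, used to scale both training and testing windows (computed once
#' on the training fold and reused at test time).
#'
#' @param patches `win^2 x n` matrix of training windows (or a list of
#'   such matrices).
#' @return list with `mean` and `sd` (class `triseg_norm_stats`).
#' @export
fit_standardization <- function(patches) {
  if (is.list(patches)) patches <- do.call(cbind, patches)
  if (length(patches) == 0)
    stopf("triseg_validation_error", "no pixels to standardize")
  mu <- mean(patches)
  sdev <- stats::sd(as.vector(patches))
  if (!is.finite(sdev) || sdev < .Machine$double.eps)
    stopf("triseg_statistics_error",
          "pooled pixel variance is zero; cannot standardize")
  structure(list(mean = mu, sd = sdev), class = "triseg_norm_stats")
}

#' Apply standardization statistics
#'
#' @param x numeric array of pixels/windows.
#' @param stats a `triseg_norm_stats` from [fit_standardization()].
#' @return `(x - mean) / sd`, same shape as `x`.
#' @export
standardize <- function(x, stats) {
  stopifnot(inherits(stats, "triseg_norm_stats"))
  (x - stats$mean) / stats$sd
}
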