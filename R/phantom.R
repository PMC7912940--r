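#' Phantom generator configuration
#'
#' Parameters of the synthetic brain-slice generator. Phantoms emulate the
#' record structure and the statistical challenges of T1-CE slice datasets:
#' a dark background, a bright unstripped skull ring, a smooth brain
#' interior, a bright sinus-like structure near the inferior midline, and
#' exactly one lesion per slice with class-distinct texture and placement
#' (meningiomas abut the skull, gliomas sit in deep parenchyma, pituitary
#' lesions lie near the sinus). Intensities are floats in \[0, 1\]; all
#' geometry scales with `image_size`.
#'
#' @param image_size pixels per side (the reference datasets use 512; the
#'   default 256 keeps desk-scale runs fast).
#' @param n_per_class slices generated per tumor class.
#' @param seed RNG seed for the whole dataset.
#' @param lesion_radius_range lesion radius bounds as fractions of
#'   `image_size`.
#' @param noise_sd grayscale standard deviation of additive pixel noise.
#' @param slices_per_patient consecutive slices sharing one patient id,
#'   enabling patient-aware folds.
#' @param class_texture_params per-class list of `base` (mean lesion
#'   intensity), `contrast` (texture amplitude) and `freq` (spatial
#'   frequency of the texture field, cycles per image side). Defaults make
#'   meningiomas bright and homogeneous, gliomas darker and strongly
#'   heterogeneous, pituitary lesions intermediate, so within-lesion local
#'   variance separates the classes.
#' @return an object of class `triseg_phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           n_per_class = 10L,
                           seed = 1L,
                           lesion_radius_range = c(0.055, 0.09),
                           noise_sd = 0.02,
                           slices_per_patient = 4L,
                           class_texture_params = list(
                             list(base = 0.78, contrast = 0.05, freq = 6),
                             list(base = 0.52, contrast = 0.30, freq = 28),
                             list(base = 0.66, contrast = 0.12, freq = 14))) {
  if (n_per_class < 1L)
    stopf("triseg_config_error", "n_per_class must be >= 1")
  if (length(lesion_radius_range) != 2L ||
      any(lesion_radius_range <= 0) || diff(lesion_radius_range) < 0)
    stopf("triseg_config_error", "invalid lesion_radius_range")
  if (noise_sd < 0)
    stopf("triseg_config_error", "noise_sd must be >= 0")
  if (length(class_texture_params) != 3L)
    stopf("triseg_config_error", "class_texture_params must list 3 classes")
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed),
                 lesion_radius_range = lesion_radius_range,
                 noise_sd = noise_sd,
                 slices_per_patient = as.integer(slices_per_patient),
                 class_texture_params = class_texture_params),
            class = "triseg_phantom_config")
}

## Normalized squared elliptical radius of each pixel w.r.t. the head
## ellipse (1 on the outer skull boundary).
head_ellipse_r2 <- function(S) {
  cr <- (S + 1) / 2; cc <- (S + 1) / 2
  ar <- 0.40 * S; ac <- 0.34 * S
  rr <- matrix(seq_len(S), S, S)
  cc_m <- matrix(seq_len(S), S, S, byrow = TRUE)
  ((rr - cr) / ar)^2 + ((cc_m - cc) / ac)^2
}

## Smooth unit-variance random field used for textures.
smooth_field <- function(S, freq) {
  sigma <- max(0.75, S / (2 * freq))
  f <- gaussian_smooth(matrix(runif(S * S, -1, 1), S, S), sigma)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(matrix(0, S, S))
  f / s
}

## Irregular (wobbly-boundary) lesion mask centred at (cr, cc).
lesion_mask <- function(S, cr, cc, radius) {
  n_harm <- 2:4
  amp <- runif(3, 0, 0.12)
  pha <- runif(3, 0, 2 * pi)
  rr <- matrix(seq_len(S), S, S)
  ccm <- matrix(seq_len(S), S, S, byrow = TRUE)
  dr <- rr - cr; dc <- ccm - cc
  th <- atan2(dr, dc)
  rho <- radius * (1 + Reduce(`+`, lapply(1:3, function(i)
    amp[i] * sin(n_harm[i] * th + pha[i]))))
  sqrt(dr^2 + dc^2) <= rho
}

#' Generate one synthetic brain-slice phantom
#'
#' Deterministic under `(config, class_label, slice_seed)`. Lesion
#' placement follows the class conventions: class 1 adjacent to the inner
#' skull boundary, class 2 in deep parenchyma, class 3 near the inferior
#' midline next to the bright sinus-like structure.
#'
#' @param config a [phantom_config()].
#' @param class_label tumor class in `{1, 2, 3}`.
#' @param slice_seed per-slice seed.
#' @param pid patient identifier stored in the record.
#' @return a slice record: list with `pid`, `label`, `image` (matrix in
#'   \[0,1\]), `mask` (0/1 integer matrix with at least one foreground
#'   pixel), `border` (n x 2 matrix of 1-based row/col boundary points).
#' @export
generate_phantom <- function(config, class_label, slice_seed,
                             pid = sprintf("SYN%d-%03d", class_label,
                                           slice_seed %% 1000L)) {
  stopifnot(inherits(config, "triseg_phantom_config"))
  if (!class_label %in% 1:3)
    stopf("triseg_validation_error", "class_label must be in {1,2,3}, got %s",
          class_label)
  S <- config$image_size
  with_seed(mix_seed(config$seed, mix_seed(class_label, slice_seed)), {
    r2 <- head_ellipse_r2(S)
    skull <- r2 <= 1 & r2 > 0.85
    brain <- r2 <= 0.78
    img <- matrix(0.02, S, S)
    img[skull] <- 0.88
    img[r2 <= 0.85 & r2 > 0.78] <- 0.12      # CSF-like gap under the skull
    img[brain] <- 0.35 + 0.08 * smooth_field(S, 4)[brain]

    ## sinus-like bright soft blob, inferior midline
    sr <- 0.70 * S; sc <- 0.50 * S + 0.5
    rr <- matrix(seq_len(S), S, S); ccm <- matrix(seq_len(S), S, S, byrow = TRUE)
    sin_blob <- 0.42 * exp(-((rr - sr)^2 + (ccm - sc)^2) / (2 * (0.028 * S)^2))
    img <- img + sin_blob * brain

    ## soften structural edges so gradients concentrate at skull/lesion
    img <- gaussian_smooth(img, 1.0)

    radius <- runif(1, config$lesion_radius_range[1] * S,
                    config$lesion_radius_range[2] * S)
    ## admissible lesion interior: strictly inside the brain ellipse
    inner_ok <- function(mask) {
      all(r2[mask] <= 0.78)
    }
    place <- function() {
      phi <- runif(1, 0, 2 * pi)
      cr0 <- (S + 1) / 2; cc0 <- (S + 1) / 2
      ar <- 0.40 * S; ac <- 0.34 * S
      if (class_label == 1L) {
        ## edge of lesion close to the inner skull boundary
        t <- sqrt(0.74)
        c(cr0 + (t * ar - 1.25 * radius) * sin(phi),
          cc0 + (t * ac - 1.25 * radius) * cos(phi))
      } else if (class_label == 2L) {
        t <- sqrt(runif(1, 0, 0.18))
        c(cr0 + t * ar * sin(phi), cc0 + t * ac * cos(phi))
      } else {
        c(sr - 0.06 * S + runif(1, -0.02, 0.02) * S,
          sc + runif(1, -0.06, 0.06) * S)
      }
    }
    mask <- NULL
    for (try in 1:50) {
      ctr <- place()
      cand <- lesion_mask(S, ctr[1], ctr[2], radius)
      if (sum(cand) >= 5 && inner_ok(cand)) { mask <- cand; break }
    }
    if (is.null(mask))
      stopf("triseg_generation_error",
            "lesion of radius %.1f px cannot be placed inside the brain ellipse (image_size %d)",
            radius, S)

    tex <- config$class_texture_params[[class_label]]
    lesion_tex <- tex$base + tex$contrast * smooth_field(S, tex$freq)
    img[mask] <- lesion_tex[mask]
    if (config$noise_sd > 0)
      img <- img + rnorm(S * S, sd = config$noise_sd)
    img <- clamp(img, 0, 1)

    storage.mode(mask) <- "integer"
    new_slice_record(pid = pid, label = as.integer(class_label), image = img,
                     mask = mask, border = mask_boundary(mask))
  })
}

## Record constructor + invariant checks shared by the generator and I/O.
new_slice_record <- function(pid, label, image, mask, border) {
  rec <- structure(list(pid = pid, label = label, image = image, mask = mask,
                        border = border), class = "triseg_slice_record")
  validate_slice_record(rec)
  rec
}

validate_slice_record <- function(rec) {
  if (!all(c("pid", "label", "image", "mask", "border") %in% names(rec)))
    stopf("triseg_format_error", "record missing field(s): %s",
          paste(setdiff(c("pid", "label", "image", "mask", "border"),
                        names(rec)), collapse = ", "))
  if (!rec$label %in% 1:3)
    stopf("triseg_validation_error", "label must be in {1,2,3}, got %s",
          rec$label)
  if (!identical(dim(rec$image), dim(rec$mask)))
    stopf("triseg_validation_error", "mask/image shape mismatch: %s vs %s",
          paste(dim(rec$mask), collapse = "x"),
          paste(dim(rec$image), collapse = "x"))
  if (!all(rec$mask %in% c(0L, 1L)))
    stopf("triseg_validation_error", "mask values must be 0/1")
  if (sum(rec$mask) < 1L)
    stopf("triseg_validation_error", "mask has no foreground pixel")
  b <- rec$border
  if (nrow(b) > 0) {
    if (any(b[, 1] < 1 | b[, 1] > nrow(rec$mask) |
            b[, 2] < 1 | b[, 2] > ncol(rec$mask)))
      stopf("triseg_validation_error", "border coordinates out of image bounds")
    if (any(rec$mask[b] != 1L))
      stopf("triseg_validation_error", "border coordinates off mask foreground")
  }
  invisible(rec)
}

#' Generate a balanced phantom dataset
#'
#' Produces `3 * n_per_class` slice records (classes interleaved
#' class-blockwise), assigning `slices_per_patient` consecutive slices of a
#' class to each synthetic patient so patient-aware folds are meaningful.
#' Deterministic under `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list of slice records.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "triseg_phantom_config"))
  recs <- vector("list", 3L * config$n_per_class)
  i <- 0L
  for (cls in 1:3) {
    for (s in seq_len(config$n_per_class)) {
      i <- i + 1L
      patient <- (s - 1L) %/% config$slices_per_patient + 1L
      recs[[i]] <- generate_phantom(
        config, cls, slice_seed = s,
        pid = sprintf("SYNP%d-%02d", cls, patient))
    }
  }
  recs
}
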