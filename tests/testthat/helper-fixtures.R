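## Shared fixtures, generated in code and cached per test session.

.fixture_env <- new.env(parent = emptyenv())

## Small phantom dataset (image 96, 5 slices/class) reused across tests.
tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- phantom_config(image_size = 96L, n_per_class = 5L, seed = 404L,
                          slices_per_patient = 2L)
    .fixture_env$tiny <- list(config = cfg, records = generate_dataset(cfg))
  }
  .fixture_env$tiny
}

## Toy network configuration: equal 3x3 kernels (merged stage-1 path).
toy_net_config <- function(window_size = 13L) {
  network_config(window_size = window_size,
                 pathway_kernels = c(3L, 3L, 3L),
                 pathway_maps = c(6L, 4L, 4L),
                 concat_maps = 6L)
}

## Stub whose prediction depends only on the window's center pixel:
## label = findInterval(center value, cuts).
center_pixel_stub <- function(window_size, cuts = c(0.25, 0.5, 0.75)) {
  center <- (window_size^2 + 1L) %/% 2L
  stub_model(function(pm) {
    cls <- findInterval(pm[center, ], cuts)
    probs <- matrix(0, ncol(pm), 4L)
    probs[cbind(seq_len(ncol(pm)), cls + 1L)] <- 1
    probs
  }, window_size = window_size)
}

identity_stats <- function() {
  structure(list(mean = 0, sd = 1), class = "triseg_norm_stats")
}

## Independent brute-force boundary tracer (double loop, used as oracle
## against mask_boundary's vectorized shifts).
trace_boundary_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1L) next
    nb <- c(if (i > 1) mask[i - 1, j] else 0L,
            if (i < H) mask[i + 1, j] else 0L,
            if (j > 1) mask[i, j - 1] else 0L,
            if (j < W) mask[i, j + 1] else 0L)
    if (any(nb == 0L)) out <- rbind(out, c(i, j))
  }
  out
}

## Canonical ordering for comparing point sets.
sort_points <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
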