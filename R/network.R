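#' Network architecture configuration
#'
#' Describes the three-pathway multiscale CNN. Each `window_size` x
#' `window_size` grayscale window is processed in parallel by one pathway
#' per spatial scale; pathway `p` applies `convs_per_pathway` stages of
#' \[same-padding convolution (kernel `pathway_kernels[p]`,
#' `pathway_maps[p]` maps) -> ReLU -> max-pool\]. Pathway outputs are
#' concatenated along the feature axis and passed through one more
#' convolution + ReLU + pooling stage, flattened, a dropout layer, and a
#' single fully connected softmax layer over `n_classes` labels
#' (0 = healthy, 1 = meningioma, 2 = glioma, 3 = pituitary).
#'
#' Convolutions use same-padding and pooling uses ceiling-mode output
#' sizing (`out = ceil((n - k)/stride) + 1`, edge windows truncated). Under
#' the reference configuration the spatial trace is 65 -> 32 -> 16 -> 8,
#' the flattened feature count is `128 * 8^2 = 8192`, and the trainable
#' parameter count is 2,856,932.
#'
#' @param window_size input window side N in pixels (odd).
#' @param pathway_kernels square kernel sides, one per pathway (odd).
#' @param pathway_maps feature-map counts, one per pathway.
#' @param convs_per_pathway convolution stages per pathway.
#' @param pathway_pool,concat_pool lists with `kernel`, `stride`, `ceil`.
#' @param concat_kernel,concat_maps kernel side and map count of the
#'   concatenation-stage convolution.
#' @param n_classes output labels (healthy + tumor classes).
#' @param dropout_rate dropout probability before the fully connected layer.
#' @return an object of class `triseg_net_config`.
#' @export
network_config <- function(window_size = 65L,
                           pathway_kernels = c(11L, 7L, 3L),
                           pathway_maps = c(128L, 96L, 64L),
                           convs_per_pathway = 2L,
                           pathway_pool = list(kernel = 3L, stride = 2L, ceil = TRUE),
                           concat_kernel = 3L,
                           concat_maps = 128L,
                           concat_pool = list(kernel = 2L, stride = 2L, ceil = TRUE),
                           n_classes = 4L,
                           dropout_rate = 0.5) {
  if (length(pathway_kernels) != length(pathway_maps))
    stopf("triseg_config_error",
          "pathway_kernels and pathway_maps must have equal length (%d vs %d)",
          length(pathway_kernels), length(pathway_maps))
  if (n_classes < 2L)
    stopf("triseg_config_error", "n_classes must be >= 2, got %d", n_classes)
  if (window_size %% 2L != 1L)
    stopf("triseg_config_error", "window_size must be odd, got %d", window_size)
  if (any(pathway_kernels %% 2L != 1L) || concat_kernel %% 2L != 1L)
    stopf("triseg_config_error", "kernel sides must be odd")
  if (convs_per_pathway < 1L)
    stopf("triseg_config_error", "convs_per_pathway must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("triseg_config_error", "dropout_rate must be in [0, 1)")

  cfg <- structure(list(
    window_size = as.integer(window_size),
    pathway_kernels = as.integer(pathway_kernels),
    pathway_maps = as.integer(pathway_maps),
    convs_per_pathway = as.integer(convs_per_pathway),
    pathway_pool = pathway_pool,
    concat_kernel = as.integer(concat_kernel),
    concat_maps = as.integer(concat_maps),
    concat_pool = concat_pool,
    n_classes = as.integer(n_classes),
    dropout_rate = dropout_rate
  ), class = "triseg_net_config")

  tr <- spatial_trace(cfg)
  if (any(tr$pathway_sides <= 0L) || tr$concat_side <= 0L)
    stopf("triseg_config_error",
          "window_size %d collapses to a non-positive spatial size under pooling",
          window_size)
  cfg$flat_features <- cfg$concat_maps * tr$concat_side^2
  cfg
}

pool_out_size <- function(n, pool) {
  q <- (n - pool$kernel) / pool$stride
  as.integer((if (isTRUE(pool$ceil)) ceiling(q) else floor(q)) + 1L)
}

## Spatial side after each pooling stage. All pathways share the same trace
## because same-padding convolutions preserve size and pooling parameters
## are shared; a per-pathway override that broke this would fail
## concatenation, so it is checked here.
spatial_trace <- function(config) {
  s <- config$window_size
  sides <- integer(config$convs_per_pathway)
  for (i in seq_len(config$convs_per_pathway)) {
    s <- pool_out_size(s, config$pathway_pool)
    sides[i] <- s
  }
  list(pathway_sides = sides, concat_side = pool_out_size(s, config$concat_pool))
}

#' Closed-form trainable parameter count
#'
#' Sums weight and bias elements of every layer: for pathway `p` with
#' kernel `k` and `m` maps, the first convolution holds `m (k^2 + 1)`
#' parameters and each subsequent one `m (k^2 m + 1)`; the concatenation
#' convolution holds `concat_maps (concat_kernel^2 sum(maps) + 1)`; the
#' fully connected layer holds `(flat_features + 1) n_classes`. The
#' reference configuration yields 2,856,932.
#'
#' @param config a [network_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "triseg_net_config"))
  path_total <- 0
  for (p in seq_along(config$pathway_kernels)) {
    k2 <- config$pathway_kernels[p]^2
    m <- config$pathway_maps[p]
    cin <- 1
    for (i in seq_len(config$convs_per_pathway)) {
      path_total <- path_total + m * (k2 * cin + 1)
      cin <- m
    }
  }
  concat_in <- sum(config$pathway_maps)
  concat_total <- config$concat_maps * (config$concat_kernel^2 * concat_in + 1)
  fc_total <- (config$flat_features + 1) * config$n_classes
  as.integer(path_total + concat_total + fc_total)
}

init_conv <- function(k, cin, m) {
  fan_in <- k * k * cin
  list(W = matrix(rnorm(fan_in * m, sd = sqrt(2 / fan_in)), fan_in, m),
       b = numeric(m))
}

#' Instantiate the multiscale network
#'
#' Allocates He-initialized weights for every layer of `config`.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return an object of class `triseg_net` usable with [forward_windows()],
#'   [segment_slice()] and [train_fold()].
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "triseg_net_config"))
  params <- with_seed(seed, {
    pathways <- lapply(seq_along(config$pathway_kernels), function(p) {
      k <- config$pathway_kernels[p]; m <- config$pathway_maps[p]
      cin <- 1L
      convs <- vector("list", config$convs_per_pathway)
      for (i in seq_len(config$convs_per_pathway)) {
        convs[[i]] <- init_conv(k, cin, m)
        cin <- m
      }
      convs
    })
    concat <- init_conv(config$concat_kernel, sum(config$pathway_maps),
                        config$concat_maps)
    fc <- list(W = matrix(rnorm(config$flat_features * config$n_classes,
                                sd = sqrt(1 / config$flat_features)),
                          config$flat_features, config$n_classes),
               b = numeric(config$n_classes))
    list(pathways = pathways, concat = concat, fc = fc)
  })
  structure(list(config = config, params = params),
            class = c("triseg_net", "triseg_model"))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Full forward pass. `A` is a (window^2 * B) x 1 activation matrix (rows:
## pixel index fastest, then batch). Returns class probabilities and, when
## `keep_cache`, the intermediates needed by nn_backward().
##
## When all pathway kernels are equal, the three stage-1 convolutions share
## one im2col and run as a single gemm over the concatenated map counts
## (the single-channel input is common to the pathways); stage 2 onward is
## per-pathway because each pathway convolves only its own maps.
nn_forward <- function(model, A, B, train = FALSE, keep_cache = train) {
  cfg <- model$config
  prm <- model$params
  pool <- cfg$pathway_pool
  n_path <- length(prm$pathways)
  path_out <- vector("list", n_path)
  path_cache <- vector("list", n_path)
  merged <- length(unique(cfg$pathway_kernels)) == 1L
  merged_cache <- NULL
  side_out <- NA_integer_
  start_in <- rep(list(A), n_path)
  H1 <- cfg$window_size; W1 <- cfg$window_size
  first_stage <- 1L
  if (merged) {
    W1m <- do.call(cbind, lapply(prm$pathways, function(pw) pw[[1L]]$W))
    b1m <- unlist(lapply(prm$pathways, function(pw) pw[[1L]]$b))
    pl <- nn_conv_pool_fwd(A, W1m, b1m, H1, W1, B, cfg$pathway_kernels[1],
                           pool$kernel, pool$stride, isTRUE(pool$ceil))
    if (keep_cache)
      merged_cache <- list(A_in = A, pool_y = pl$Y, idx = pl$idx,
                           H = H1, W = W1)
    col0 <- 0L
    for (p in seq_len(n_path)) {
      m <- cfg$pathway_maps[p]
      start_in[[p]] <- pl$Y[, (col0 + 1L):(col0 + m), drop = FALSE]
      col0 <- col0 + m
    }
    H1 <- pl$Ho; W1 <- pl$Wo
    first_stage <- 2L
  }
  for (p in seq_len(n_path)) {
    k <- cfg$pathway_kernels[p]
    Ap <- start_in[[p]]; H <- H1; W <- W1
    stages <- vector("list", cfg$convs_per_pathway)
    for (i in seq(from = first_stage, length.out = cfg$convs_per_pathway -
                    first_stage + 1L)) {
      cv <- prm$pathways[[p]][[i]]
      pl <- nn_conv_pool_fwd(Ap, cv$W, cv$b, H, W, B, k,
                             pool$kernel, pool$stride, isTRUE(pool$ceil))
      ## ReLU mask is recovered from the pooled maxima (0 iff clipped),
      ## so no full-resolution mask needs caching.
      if (keep_cache)
        stages[[i]] <- list(A_in = Ap, pool_y = pl$Y, idx = pl$idx,
                            H = H, W = W)
      Ap <- pl$Y; H <- pl$Ho; W <- pl$Wo
    }
    path_out[[p]] <- Ap
    path_cache[[p]] <- stages
    side_out <- H
  }
  Acat <- do.call(cbind, path_out)
  Hc <- side_out; Wc <- side_out
  plc <- nn_conv_pool_fwd(Acat, prm$concat$W, prm$concat$b, Hc, Wc, B,
                          cfg$concat_kernel, cfg$concat_pool$kernel,
                          cfg$concat_pool$stride,
                          isTRUE(cfg$concat_pool$ceil))
  HWo <- plc$Ho * plc$Wo
  ## flatten to B x (HWo * concat_maps), feature order: pixel fastest per map
  Farr <- array(plc$Y, c(HWo, B, cfg$concat_maps))
  F <- t(matrix(aperm(Farr, c(1, 3, 2)), HWo * cfg$concat_maps, B))
  drop_mask <- NULL
  Fd <- F
  if (train && cfg$dropout_rate > 0) {
    drop_mask <- matrix(
      (runif(length(F)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
      nrow(F), ncol(F))
    Fd <- F * drop_mask
  }
  logits <- sweep(Fd %*% prm$fc$W, 2, prm$fc$b, "+")
  probs <- softmax_rows(logits)
  cache <- NULL
  if (keep_cache)
    cache <- list(pathways = path_cache, merged = merged_cache,
                  Acat = Acat, concat = list(
      pool_y = plc$Y, idx = plc$idx, H = Hc, W = Wc, HWo = HWo),
      Fd = Fd, drop_mask = drop_mask, B = B)
  list(probs = probs, cache = cache)
}

## Backward pass from dlogits (B x n_classes); returns gradients shaped
## like model$params.
nn_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  prm <- model$params
  B <- cache$B
  g_fc <- list(W = crossprod(cache$Fd, dlogits), b = colSums(dlogits))
  dFd <- dlogits %*% t(prm$fc$W)
  if (!is.null(cache$drop_mask)) dFd <- dFd * cache$drop_mask
  HWo <- cache$concat$HWo
  dFarr <- aperm(array(t(dFd), c(HWo, cfg$concat_maps, B)), c(1, 3, 2))
  dYc <- matrix(dFarr, HWo * B, cfg$concat_maps)
  bc <- nn_conv_pool_bwd(cache$Acat, dYc, cache$concat$pool_y,
                         cache$concat$idx, prm$concat$W, cache$concat$H,
                         cache$concat$W, B, cfg$concat_kernel)
  g_concat <- list(W = bc$dW, b = as.numeric(bc$db))
  dAcat <- bc$dA
  n_path <- length(prm$pathways)
  merged <- !is.null(cache$merged)
  last_stage <- if (merged) 2L else 1L
  g_paths <- vector("list", n_path)
  d_stage1_in <- vector("list", n_path)  # gradients w.r.t. stage-2 inputs
  col0 <- 0L
  for (p in seq_len(n_path)) {
    m <- cfg$pathway_maps[p]
    dAp <- dAcat[, (col0 + 1L):(col0 + m), drop = FALSE]
    col0 <- col0 + m
    g_stage <- vector("list", cfg$convs_per_pathway)
    for (i in rev(seq(from = last_stage,
                      length.out = cfg$convs_per_pathway - last_stage + 1L))) {
      st <- cache$pathways[[p]][[i]]
      bb <- nn_conv_pool_bwd(st$A_in, dAp, st$pool_y, st$idx,
                             prm$pathways[[p]][[i]]$W, st$H, st$W, B,
                             cfg$pathway_kernels[p],
                             need_da = (i > last_stage) || merged)
      g_stage[[i]] <- list(W = bb$dW, b = as.numeric(bb$db))
      if ((i > last_stage) || merged) dAp <- bb$dA
    }
    g_paths[[p]] <- g_stage
    d_stage1_in[[p]] <- dAp
  }
  if (merged) {
    st <- cache$merged
    dY1 <- do.call(cbind, d_stage1_in)
    W1m <- do.call(cbind, lapply(prm$pathways, function(pw) pw[[1L]]$W))
    b1 <- nn_conv_pool_bwd(st$A_in, dY1, st$pool_y, st$idx, W1m, st$H, st$W,
                           B, cfg$pathway_kernels[1], need_da = FALSE)
    col0 <- 0L
    for (p in seq_len(n_path)) {
      m <- cfg$pathway_maps[p]
      g_paths[[p]][[1L]] <- list(
        W = b1$dW[, (col0 + 1L):(col0 + m), drop = FALSE],
        b = as.numeric(b1$db[(col0 + 1L):(col0 + m)]))
      col0 <- col0 + m
    }
  }
  list(pathways = g_paths, concat = g_concat, fc = g_fc)
}

#' Evaluate the network on a batch of windows
#'
#' Evaluation-mode forward pass (dropout inactive): one probability vector
#' per window, batch order preserved, deterministic.
#'
#' @param model a `triseg_net` from [build_network()] or a [stub_model()].
#' @param patches windows as a `win x win x n` array or a `win^2 x n`
#'   matrix (columns in column-major pixel order), already standardized
#'   with the training [fit_standardization()] statistics.
#' @param batch_size windows per internal forward pass.
#' @return an `n x n_classes` matrix of class probabilities (rows sum to 1).
#' @export
forward_windows <- function(model, patches, batch_size = 256L) {
  UseMethod("forward_windows")
}

as_patch_matrix <- function(patches, window_size) {
  if (is.array(patches) && length(dim(patches)) == 3L) {
    d <- dim(patches)
    if (d[1] != window_size || d[2] != window_size)
      stopf("triseg_shape_error",
            "patch side %dx%d does not match model window_size %d",
            d[1], d[2], window_size)
    patches <- matrix(patches, d[1] * d[2], d[3])
  } else {
    patches <- as.matrix(patches)
    if (nrow(patches) != window_size^2)
      stopf("triseg_shape_error",
            "patch length %d does not match window_size %d^2",
            nrow(patches), window_size)
  }
  patches
}

#' @export
forward_windows.triseg_net <- function(model, patches, batch_size = 256L) {
  cfg <- model$config
  pm <- as_patch_matrix(patches, cfg$window_size)
  n <- ncol(pm)
  out <- matrix(NA_real_, n, cfg$n_classes)
  if (n == 0L) return(out)
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    B <- end - start + 1L
    A <- matrix(as.numeric(pm[, start:end]), ncol = 1L)
    out[start:end, ] <- nn_forward(model, A, B, train = FALSE)$probs
  }
  out
}

#' Stub model for pipeline tests
#'
#' Wraps an arbitrary function mapping a `win^2 x n` patch matrix to an
#' `n x n_classes` probability matrix, so inference and evaluation stages
#' can run without a trained network.
#'
#' @param fn function of a patch matrix returning class probabilities.
#' @param window_size window side expected by `fn`.
#' @param n_classes number of output classes.
#' @return an object of class `triseg_stub`.
#' @export
stub_model <- function(fn, window_size = 65L, n_classes = 4L) {
  structure(list(fn = fn,
                 config = list(window_size = as.integer(window_size),
                               n_classes = as.integer(n_classes))),
            class = c("triseg_stub", "triseg_model"))
}

#' @export
forward_windows.triseg_stub <- function(model, patches, batch_size = 256L) {
  pm <- as_patch_matrix(patches, model$config$window_size)
  if (ncol(pm) == 0L) return(matrix(NA_real_, 0L, model$config$n_classes))
  probs <- model$fn(pm)
  stopifnot(nrow(probs) == ncol(pm))
  probs
}
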