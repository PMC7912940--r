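test_that("the reference architecture has 2,856,932 trainable parameters", {
  cfg <- network_config()
  expect_identical(count_parameters(cfg), 2856932L)
  ## per-block decomposition of the closed form
  pathway_sub <- sum(sapply(1:3, function(p) {
    k2 <- cfg$pathway_kernels[p]^2; m <- cfg$pathway_maps[p]
    m * (k2 + 1) + m * (k2 * m + 1)
  }))
  expect_equal(pathway_sub, 2492256)
  expect_equal(cfg$concat_maps * (9 * sum(cfg$pathway_maps) + 1), 331904)
  expect_equal((cfg$flat_features + 1) * cfg$n_classes, 32772)
  ## widening the output layer adds exactly one fully connected block
  cfg8 <- network_config(n_classes = 8L)
  expect_equal(count_parameters(cfg8) - count_parameters(cfg), 32772L)
})

test_that("closed-form count equals instantiated layer enumeration", {
  set.seed(1234)
  for (i in 1:20) {
    win <- sample(c(9L, 13L, 17L, 21L), 1)
    n_path <- sample(2:4, 1)
    cfg <- network_config(
      window_size = win,
      pathway_kernels = sample(c(3L, 5L, 7L), n_path, replace = TRUE),
      pathway_maps = sample(2:8, n_path, replace = TRUE),
      concat_maps = sample(2:8, 1),
      n_classes = sample(2:5, 1))
    net <- build_network(cfg, seed = i)
    enumerated <- sum(rapply(net$params, length, how = "unlist"))
    expect_identical(count_parameters(cfg), as.integer(enumerated))
  }
})

test_that("spatial sizes follow ceiling-mode pooling arithmetic", {
  tr <- triseg:::spatial_trace(network_config())
  expect_equal(tr$pathway_sides, c(32L, 16L))
  expect_equal(tr$concat_side, 8L)
  expect_equal(network_config()$flat_features, 8192L)

  tr17 <- triseg:::spatial_trace(toy_net_config(17L))
  expect_equal(tr17$pathway_sides, c(8L, 4L))
  expect_equal(tr17$concat_side, 2L)
  ## forward evaluation agrees with the traced flattened length
  net <- build_network(toy_net_config(17L), seed = 1)
  expect_equal(nrow(net$params$fc$W),
               toy_net_config(17L)$concat_maps * tr17$concat_side^2)
  probs <- forward_windows(net, array(rnorm(17 * 17 * 2), c(17, 17, 2)))
  expect_equal(dim(probs), c(2L, 4L))
})

test_that("softmax outputs are normalized probabilities", {
  net <- build_network(toy_net_config(), seed = 3)
  p <- array(rnorm(13 * 13 * 4), c(13, 13, 4))
  probs <- forward_windows(net, p)
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-5)
  ## model output is input-dependent
  probs2 <- forward_windows(net, p * 2)
  expect_false(isTRUE(all.equal(probs, probs2)))
})

test_that("evaluation-mode inference is deterministic and batch-stable", {
  net <- build_network(toy_net_config(), seed = 4)
  p <- array(rnorm(13 * 13 * 7), c(13, 13, 7))
  o1 <- forward_windows(net, p)
  o2 <- forward_windows(net, p)
  expect_identical(o1, o2)
  perm <- c(3, 1, 7, 2, 6, 5, 4)
  expect_equal(forward_windows(net, p[, , perm]), o1[perm, ])
  expect_equal(forward_windows(net, p, batch_size = 2L), o1)
  expect_equal(nrow(forward_windows(net, array(0, c(13, 13, 0)))), 0L)
})

test_that("mismatched patch sides raise a shape error", {
  net <- build_network(toy_net_config(), seed = 5)
  expect_error(forward_windows(net, array(0, c(9, 9, 2))),
               class = "triseg_shape_error")
})

test_that("backpropagation matches numeric differentiation", {
  ## oracle: central finite differences of the cross-entropy loss
  for (kernels in list(c(3L, 3L, 3L), c(5L, 3L, 3L))) {
    cfg <- network_config(window_size = 9L, pathway_kernels = kernels,
                          pathway_maps = c(3L, 2L, 2L), concat_maps = 3L,
                          dropout_rate = 0)
    net <- build_network(cfg, seed = 2)
    set.seed(42)
    B <- 3L
    A <- matrix(rnorm(81 * B), ncol = 1)
    y <- c(1L, 3L, 2L)
    loss_fn <- function(nn) {
      fw <- nn_forward(nn, A, B)
      -mean(log(fw$probs[cbind(seq_len(B), y + 1L)]))
    }
    fw <- nn_forward(net, A, B, train = TRUE)
    Y <- matrix(0, B, 4); Y[cbind(seq_len(B), y + 1L)] <- 1
    gr <- nn_backward(net, fw$cache, (fw$probs - Y) / B)
    pv <- unlist(net$params, use.names = FALSE)
    gv <- unlist(gr, use.names = FALSE)
    expect_length(gv, length(pv))
    idx <- sort(sample(length(pv), 50))
    eps <- 1e-6
    num <- vapply(idx, function(i) {
      n2 <- net; p <- pv
      p[i] <- p[i] + eps; n2$params <- relist(p, net$params); l1 <- loss_fn(n2)
      p[i] <- p[i] - 2 * eps; n2$params <- relist(p, net$params)
      (l1 - loss_fn(n2)) / (2 * eps)
    }, 0)
    rel <- abs(num - gv[idx]) / pmax(1e-6, abs(num) + abs(gv[idx]))
    expect_lt(max(rel), 1e-5)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(pathway_kernels = c(3L, 3L),
                              pathway_maps = c(4L, 4L, 4L)),
               class = "triseg_config_error")
  expect_error(network_config(n_classes = 1L), class = "triseg_config_error")
  expect_error(network_config(window_size = 16L),
               class = "triseg_config_error")
  expect_error(network_config(window_size = 3L),
               class = "triseg_config_error")
})
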