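## Brute-force oracles: per-pixel counting loops kept deliberately naive.
oracle_ratios <- function(L) {
  tot <- 0; cnt <- c(0, 0, 0)
  for (v in as.vector(L)) {
    if (v > 0) {
      tot <- tot + 1
      cnt[v] <- cnt[v] + 1
    }
  }
  if (tot == 0) c(0, 0, 0) else cnt / tot
}

oracle_metrics <- function(L, mask, lgt) {
  tp <- fp <- fn <- 0; npred <- 0; np1 <- 0
  for (i in seq_len(nrow(L))) for (j in seq_len(ncol(L))) {
    p1 <- L[i, j] == lgt
    t1 <- mask[i, j] == 1
    if (L[i, j] > 0) npred <- npred + 1
    if (p1) np1 <- np1 + 1
    if (p1 && t1) tp <- tp + 1
    if (p1 && !t1) fp <- fp + 1
    if (!p1 && t1) fn <- fn + 1
  }
  list(dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 1,
       pttas = if (npred > 0) np1 / npred else 0)
}

random_label_map <- function(h = 16L, w = 16L) {
  matrix(sample(0:3, h * w, replace = TRUE,
                prob = c(0.7, 0.1, 0.1, 0.1)), h, w)
}

test_that("slice classification follows the thresholded ratio rule", {
  expect_identical(classify_slice(matrix(0L, 4, 4), 0.5)$lp, -1L)

  m <- matrix(0L, 4, 4)
  m[1:6] <- 1L; m[7:8] <- 2L
  r <- classify_slice(m, 0.5)
  expect_equal(r$ratios, c(0.75, 0.25, 0))
  expect_identical(r$lp, 1L)
  expect_identical(classify_slice(m, 0.8)$lp, -1L)

  m3 <- matrix(c(rep(1L, 2), rep(2L, 2), rep(3L, 2), rep(0L, 3)), 3, 3)
  expect_equal(classify_slice(m3, 0.75)$lp, -1L)
})

test_that("classification matches a brute-force pixel counter on random maps", {
  set.seed(5150)
  for (i in 1:100) {
    L <- random_label_map()
    tau <- sample(c(0, 0.2, 0.5, 0.75), 1)
    got <- classify_slice(L, tau)
    want <- oracle_ratios(L)
    expect_equal(got$ratios, want)
    f <- ifelse(want > tau, want, 0)
    expect_identical(got$lp,
                     if (all(f == 0)) -1L else as.integer(which.max(f)))
    ## conservation: class counts sum to the tumor-labeled count
    expect_equal(sum(sapply(1:3, function(l) sum(L == l))), sum(L > 0))
    if (sum(L > 0) > 0) expect_equal(sum(got$ratios), 1)
    ## threshold-free limit: argmax of the ratios
    expect_identical(classify_slice(L, 0)$lp,
                     if (sum(L > 0) == 0) -1L else
                       as.integer(which.max(want)))
  }
})

test_that("segmentation metrics reproduce hand-counted toy layouts", {
  ## 5x5 toy: tp = 4, fp = 2, fn = 1
  mask <- matrix(0L, 5, 5); mask[1:5] <- 1L
  L <- matrix(0L, 5, 5)
  L[1:4] <- 2L          # 4 true positives (class 2)
  L[6:7] <- 2L          # 2 false positives
  rec <- list(label = 2L, mask = mask)
  sm <- slice_metrics(L, rec)
  expect_equal(sm$dice, 8 / 11)
  expect_equal(sm$sensitivity, 4 / 5)
  expect_equal(sm$pttas, 1)

  ## perfect prediction
  perfect <- mask * 2L
  smp <- slice_metrics(perfect, rec)
  expect_equal(c(smp$dice, smp$sensitivity, smp$pttas), c(1, 1, 1))

  ## all predicted tumor pixels carry the wrong class
  wrong <- mask * 3L
  smw <- slice_metrics(wrong, rec)
  expect_equal(smw$dice, 0)
  expect_equal(smw$pttas, 0)
})

test_that("metrics agree with the brute-force counter on random maps", {
  set.seed(2112)
  for (i in 1:100) {
    L <- random_label_map()
    mask <- matrix(as.integer(runif(256) < 0.2), 16, 16)
    if (sum(mask) == 0) mask[1] <- 1L
    lgt <- sample(1:3, 1)
    got <- slice_metrics(L, list(label = lgt, mask = mask))
    want <- oracle_metrics(L, mask, lgt)
    expect_equal(got[c("dice", "sensitivity", "pttas")], want)
    expect_true(all(unlist(want) >= 0 & unlist(want) <= 1))
    ## pttas equals the un-thresholded true-class ratio
    expect_equal(got$pttas, oracle_ratios(L)[lgt])
  }
})

test_that("macro averages reproduce the printed truncated summaries", {
  expect_equal(macro_average(c(0.894, 0.779, 0.813), truncate = TRUE), 0.828)
  expect_equal(macro_average(c(0.961, 0.907, 0.954), truncate = TRUE), 0.940)
  expect_equal(macro_average(c(0.938, 0.986, 0.979), truncate = TRUE), 0.967)
  expect_equal(macro_average(c(0.5, 0.5, 0.5)), 0.5)
  expect_error(macro_average(numeric(0)), class = "triseg_validation_error")
})

test_that("confusion accuracy arithmetic matches the reference table", {
  ## published confusion counts: rows 659/4/3 nc 42; 7/1414/1 nc 4;
  ## 1/3/911 nc 15 -> accuracy 2984/3064 -> 0.973 truncated
  truths <- c(rep(1L, 708), rep(2L, 1426), rep(3L, 930))
  preds <- c(rep(1L, 659), rep(2L, 4), rep(3L, 3), rep(-1L, 42),
             rep(1L, 7), rep(2L, 1414), rep(3L, 1), rep(-1L, 4),
             rep(1L, 1), rep(2L, 3), rep(3L, 911), rep(-1L, 15))
  conf <- build_confusion(truths, preds)
  expect_equal(conf$accuracy, 0.973)
  expect_equal(unname(conf$per_class_sensitivity), c(0.93, 0.99, 0.98))
  expect_equal(unname(conf$non_classified), c(42L, 4L, 15L))
  expect_equal(unname(rowSums(conf$confusion)), c(708L, 1426L, 930L))

  toy <- build_confusion(c(1L, 1L, 2L, 2L), c(1L, 1L, 1L, 2L))
  expect_equal(toy$accuracy_exact, 0.75)

  all_right <- build_confusion(rep(1:3, 2), rep(1:3, 2))
  expect_equal(all_right$accuracy, 1)
  expect_true(all(all_right$confusion[, 1:3][lower.tri(diag(3))] == 0))
})

test_that("threshold-precision curve equals per-tau reclassification", {
  set.seed(7)
  truths <- sample(1:3, 5, replace = TRUE)
  ratios <- t(apply(matrix(runif(15), 5), 1, function(r) r / sum(r)))
  taus <- seq(0, 0.9, by = 0.1)
  curve <- threshold_precision_curve(truths, ratios, taus)
  for (i in seq_along(taus)) {
    lp <- apply(ratios, 1, function(r) {
      f <- ifelse(r > taus[i], r, 0)
      if (all(f == 0)) -1L else which.max(f)
    })
    expect_equal(curve$precision[i], mean(lp == truths))
    expect_equal(curve$n_classified[i], sum(lp != -1L))
  }
  ## classified count is non-increasing in the threshold
  expect_true(all(diff(curve$n_classified) <= 0))

  sure <- matrix(rep(c(1, 0, 0), each = 4), 4)
  flat <- threshold_precision_curve(rep(1L, 4), sure, seq(0, 0.95, 0.05))
  expect_true(all(flat$precision == 1))
})

test_that("overlay rendering follows the red/green/yellow convention", {
  rec <- tiny_dataset()$records[[1]]
  perfect <- rec$mask * rec$label
  ov <- render_overlay(perfect, rec, "segmentation")
  fg <- rec$mask == 1L
  expect_true(all(ov[, , 1][fg] == 1 & ov[, , 2][fg] == 1))  # yellow
  pure_red <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 0
  pure_green <- ov[, , 2] == 1 & ov[, , 1] == 0 & ov[, , 3] == 0
  expect_false(any(pure_red))
  expect_false(any(pure_green))

  empty <- matrix(0L, nrow(rec$mask), ncol(rec$mask))
  ov2 <- render_overlay(empty, rec, "segmentation")
  expect_true(all(ov2[, , 2][fg] == 1 & ov2[, , 1][fg] == 0))

  disjoint <- matrix(0L, nrow(rec$mask), ncol(rec$mask))
  disjoint[1:3, 1:3] <- rec$label
  ov3 <- render_overlay(disjoint, rec, "segmentation")
  expect_true(any(ov3[, , 1] == 1 & ov3[, , 2] == 0))
  expect_true(any(ov3[, , 2] == 1 & ov3[, , 1] == 0))
  expect_false(any(ov3[, , 1] == 1 & ov3[, , 2] == 1))

  tags <- render_overlay(rec$mask * 3L, rec, "class-tags")
  expect_true(all(tags[, , 3][fg] == 1 & tags[, , 1][fg] == 0))
})

test_that("metric histograms bin counts over the unit interval", {
  h <- metric_histogram(c(0.02, 0.51, 0.52, 0.99), seq(0, 1, 0.5))
  expect_equal(h$count, c(1L, 3L))
  expect_equal(sum(metric_histogram(runif(50))$count), 50L)
})
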