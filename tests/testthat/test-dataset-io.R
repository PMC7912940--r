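test_that("write_record / read_record round-trips a record field by field", {
  rec <- tiny_dataset()$records[[1]]
  path <- withr::local_tempfile(fileext = ".rds")
  write_record(rec, path)
  back <- read_record(path)
  expect_identical(back$pid, rec$pid)
  expect_identical(back$label, rec$label)
  expect_equal(back$image, rec$image)
  expect_identical(back$mask, rec$mask)
  expect_equal(sort_points(unname(back$border)),
               sort_points(unname(rec$border)))
  expect_identical(sum(back$mask), sum(rec$mask))
})

test_that("borders stored in (x, y) order are auto-flipped on read", {
  rec <- tiny_dataset()$records[[2]]
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(pid = rec$pid, label = rec$label, image = rec$image,
               tumorBorder = cbind(rec$border[, 2] - 1L,
                                   rec$border[, 1] - 1L),  # swapped axes
               tumorMask = rec$mask), path)
  back <- read_record(path)
  expect_equal(sort_points(unname(back$border)),
               sort_points(unname(rec$border)))
})

test_that("malformed records are rejected with informative errors", {
  rec <- tiny_dataset()$records[[1]]
  path <- withr::local_tempfile(fileext = ".rds")

  bad <- rec; bad$label <- 4L
  saveRDS(list(pid = bad$pid, label = 4L, image = bad$image,
               tumorBorder = bad$border - 1L, tumorMask = bad$mask), path)
  expect_error(read_record(path), class = "triseg_validation_error")

  saveRDS(list(pid = rec$pid, label = rec$label, image = rec$image,
               tumorBorder = rec$border - 1L,
               tumorMask = matrix(0L, nrow(rec$mask), ncol(rec$mask))), path)
  expect_error(read_record(path), "foreground",
               class = "triseg_validation_error")

  saveRDS(list(pid = rec$pid, label = rec$label, image = rec$image,
               tumorBorder = rec$border - 1L), path)
  expect_error(read_record(path), "tumorMask", class = "triseg_format_error")

  saveRDS(list(pid = rec$pid, label = rec$label,
               image = rec$image[, -1],
               tumorBorder = rec$border - 1L, tumorMask = rec$mask), path)
  expect_error(read_record(path), "shape", class = "triseg_validation_error")
})

test_that("HDF5 containers are recognized and rejected with a hint", {
  path <- withr::local_tempfile(fileext = ".mat")
  writeBin(c(as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a)),
             raw(64)), path)
  expect_error(read_record(path), "HDF5", class = "triseg_format_error")
})

test_that("write_dataset produces a manifest matching the records", {
  ds <- tiny_dataset()$records
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_equal(nrow(read.csv(file.path(dir, "manifest.csv"))), length(ds))
  back <- read_dataset(dir)
  expect_equal(length(back), length(ds))
  expect_identical(vapply(back, `[[`, 0L, "label"),
                   vapply(ds, `[[`, 0L, "label"))
})

test_that("stratified folds partition balanced phantoms exactly", {
  ds <- tiny_dataset()$records
  labels <- vapply(ds, `[[`, 0L, "label")
  folds <- make_stratified_folds(labels, k = 5L, seed = 3L,
                                 patient_aware = FALSE)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f$test_indices, 3L)
    expect_equal(as.vector(table(labels[f$test_indices])), c(1L, 1L, 1L))
    expect_length(intersect(f$train_indices, f$test_indices), 0L)
    expect_setequal(c(f$train_indices, f$test_indices), seq_along(ds))
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test_indices")), seq_along(ds))
})

test_that("fold sizes for the 3064-slice class mix are all 612 or 613", {
  labels <- rep(1:3, times = c(708L, 1426L, 930L))
  folds <- make_stratified_folds(labels, k = 5L, seed = 1L,
                                 patient_aware = FALSE)
  sizes <- vapply(folds, function(f) length(f$test_indices), 0L)
  expect_true(all(sizes %in% c(612L, 613L)))
  expect_equal(sum(sizes), 3064L)
  ## per-class proportions within one record of the global proportion
  for (f in folds) {
    tab <- table(factor(labels[f$test_indices], levels = 1:3))
    expect_true(all(abs(tab - c(708, 1426, 930) / 5) <= 1))
  }
})

test_that("folds are deterministic under the seed and patient-aware", {
  ds <- tiny_dataset()$records
  labels <- vapply(ds, `[[`, 0L, "label")
  pids <- vapply(ds, `[[`, "", "pid")
  f1 <- make_stratified_folds(labels, pids, k = 5L, seed = 11L)
  f2 <- make_stratified_folds(labels, pids, k = 5L, seed = 11L)
  expect_identical(f1, f2)
  ## all slices of one patient share a test set
  for (p in unique(pids)) {
    idx <- which(pids == p)
    fold_of <- vapply(idx, function(i)
      which(vapply(f1, function(f) i %in% f$test_indices, TRUE)), 0L)
    expect_length(unique(fold_of), 1L)
  }
})

test_that("a class rarer than k folds cannot be stratified", {
  expect_error(make_stratified_folds(c(1, 1, 2, 2, 3), k = 2L,
                                     patient_aware = FALSE),
               class = "triseg_stratification_error")
})

test_that("fold index files round-trip and are validated", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "folds.json")
  folds <- make_stratified_folds(rep(1:3, each = 10L), k = 5L, seed = 2L,
                                 patient_aware = FALSE)
  write_fold_indices(folds, path)
  back <- load_fold_indices(path, 30L)
  expect_equal(lapply(back, `[[`, "test_indices"),
               lapply(folds, `[[`, "test_indices"))
  expect_equal(vapply(back, function(f) length(f$train_indices), 0L),
               rep(24L, 5L))

  jsonlite::write_json(list(0:5, c(6:9, 30L)), path)
  expect_error(load_fold_indices(path, 30L), "outside",
               class = "triseg_validation_error")

  jsonlite::write_json(list(0:5, 5:9), path)
  expect_error(load_fold_indices(path, 10L), class = "triseg_validation_error")

  jsonlite::write_json(list(0:3, 4:7), path)
  expect_error(load_fold_indices(path, 10L), "cover",
               class = "triseg_validation_error")
})
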