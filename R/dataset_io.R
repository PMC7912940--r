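#' Read a slice record
#'
#' Reads one record from the fixture container (R serialization, one record
#' per file with fields `pid`, `label`, `image`, `tumorBorder`,
#' `tumorMask`). Border coordinates are stored 0-based and converted to the
#' package's 1-based (row, col) convention; if more than half of the stored
#' border points miss the mask foreground under that reading, the
#' interpretation is flipped to (col, row) before validation, since some
#' sources store (x, y) order. Files carrying the HDF5 magic signature
#' (MATLAB v7.3 containers of the real dataset) are recognized and rejected
#' with a conversion hint.
#'
#' @param path file written by [write_record()].
#' @return a validated slice record.
#' @export
read_record <- function(path) {
  if (!file.exists(path))
    stopf("triseg_format_error", "no such record file: %s", path)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 4L &&
      identical(magic[1:4], as.raw(c(0x89, 0x48, 0x44, 0x46))))
    stopf("triseg_format_error",
          paste0("%s is an HDF5 container; convert it to the fixture ",
                 "format with write_record() first"), path)
  raw <- readRDS(path)
  for (f in c("pid", "label", "image", "tumorBorder", "tumorMask"))
    if (is.null(raw[[f]]))
      stopf("triseg_format_error", "record %s missing field '%s'", path, f)
  label <- as.integer(raw$label)
  if (!isTRUE(label %in% 1:3))
    stopf("triseg_validation_error", "label must be in {1,2,3}, got %s",
          raw$label)
  mask <- raw$tumorMask
  storage.mode(mask) <- "integer"
  border0 <- raw$tumorBorder
  border <- cbind(row = as.integer(border0[, 1]) + 1L,
                  col = as.integer(border0[, 2]) + 1L)
  if (nrow(border) > 0) {
    inb <- border[, 1] >= 1 & border[, 1] <= nrow(mask) &
      border[, 2] >= 1 & border[, 2] <= ncol(mask)
    hit <- function(b, ok) if (!any(ok)) 0 else
      mean(mask[b[ok, , drop = FALSE]] == 1L)
    if (hit(border, inb) < 0.5) {
      flipped <- border[, 2:1, drop = FALSE]
      colnames(flipped) <- c("row", "col")
      inb2 <- flipped[, 1] >= 1 & flipped[, 1] <= nrow(mask) &
        flipped[, 2] >= 1 & flipped[, 2] <= ncol(mask)
      if (hit(flipped, inb2) >= 0.5) border <- flipped
    }
  }
  new_slice_record(pid = as.character(raw$pid), label = label,
                   image = raw$image, mask = mask, border = border)
}

#' Write a slice record
#'
#' Inverse of [read_record()]; border coordinates are serialized 0-based.
#'
#' @param record a valid slice record.
#' @param path destination file.
#' @export
write_record <- function(record, path) {
  validate_slice_record(record)
  saveRDS(list(pid = record$pid, label = record$label, image = record$image,
               tumorBorder = cbind(record$border[, 1] - 1L,
                                   record$border[, 2] - 1L),
               tumorMask = record$mask),
          path)
  invisible(path)
}

#' Write a dataset directory
#'
#' One record file per slice plus a `manifest.csv` (pid, label, filename).
#'
#' @param records list of slice records.
#' @param dir destination directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fns <- sprintf("rec_%04d.rds", seq_along(records))
  for (i in seq_along(records))
    write_record(records[[i]], file.path(dir, fns[i]))
  manifest <- data.frame(pid = vapply(records, `[[`, "", "pid"),
                         label = vapply(records, `[[`, 0L, "label"),
                         filename = fns)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of slice records in manifest order.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stopf("triseg_format_error", "no manifest.csv in %s", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(manifest$filename, function(f) read_record(file.path(dir, f)))
}

new_fold_spec <- function(fold_id, test_idx, n) {
  list(fold_id = as.integer(fold_id),
       train_indices = setdiff(seq_len(n), sort(test_idx)),
       test_indices = sort(as.integer(test_idx)))
}

check_fold_partition <- function(folds, n) {
  tests <- lapply(folds, `[[`, "test_indices")
  all_test <- unlist(tests)
  if (anyDuplicated(all_test))
    stopf("triseg_validation_error",
          "fold test sets overlap (record %d in more than one test set)",
          all_test[duplicated(all_test)][1])
  if (!setequal(all_test, seq_len(n)))
    stopf("triseg_validation_error",
          "fold test sets do not cover all %d records", n)
  for (f in folds)
    if (length(intersect(f$train_indices, f$test_indices)) > 0)
      stopf("triseg_validation_error", "fold %d train/test sets overlap",
            f$fold_id)
  invisible(folds)
}

#' Stratified (optionally patient-aware) k-fold split
#'
#' Builds `k` folds whose test sets partition the records with per-class
#' proportions as close as integer arithmetic allows (within one record of
#' the global proportion; slices are dealt per class with remainders
#' assigned to the currently smallest folds). With `patient_aware = TRUE`,
#' all slices sharing a pid land in the same test set: patients are
#' assigned greedily (largest slice groups first, seeded shuffle for
#' ties) to the fold with the fewest slices of that class, so exact
#' stratification is best-effort when patient groups are uneven.
#'
#' @param labels per-record class labels in `{1, 2, 3}`.
#' @param pids per-record patient ids (required when `patient_aware`).
#' @param k number of folds.
#' @param seed RNG seed.
#' @param patient_aware keep each patient's slices in a single test set.
#' @return list of `k` fold specs, each with `fold_id`, `train_indices`,
#'   `test_indices`.
#' @export
make_stratified_folds <- function(labels, pids = NULL, k = 5L, seed = 1L,
                                  patient_aware = !is.null(pids)) {
  n <- length(labels)
  if (k < 2L) stopf("triseg_validation_error", "k must be >= 2")
  tab <- table(labels)
  if (any(tab < k))
    stopf("triseg_stratification_error",
          "class %s has %d record(s), fewer than k = %d",
          names(tab)[which.min(tab)], min(tab), k)
  if (patient_aware && is.null(pids))
    stopf("triseg_validation_error", "patient_aware requires pids")

  assign_fold <- integer(n)
  with_seed(seed, {
    if (patient_aware) {
      class_counts <- matrix(0L, k, length(unique(labels)),
                             dimnames = list(NULL, sort(unique(labels))))
      for (cls in sort(unique(labels))) {
        idx_c <- which(labels == cls)
        groups <- split(idx_c, pids[idx_c])
        groups <- groups[sample(length(groups))]
        groups <- groups[order(-lengths(groups))]
        for (g in groups) {
          key <- as.character(cls)
          f <- order(class_counts[, key], rowSums(class_counts))[1]
          assign_fold[g] <- f
          class_counts[f, key] <- class_counts[f, key] + length(g)
        }
      }
    } else {
      totals <- integer(k)
      for (cls in sort(unique(labels))) {
        idx_c <- sample(which(labels == cls))
        base <- length(idx_c) %/% k
        rem <- length(idx_c) %% k
        sizes <- rep(base, k)
        if (rem > 0) {
          recipients <- order(totals, seq_len(k))[seq_len(rem)]
          sizes[recipients] <- sizes[recipients] + 1L
        }
        stops <- cumsum(sizes)
        starts <- c(1L, head(stops, -1) + 1L)
        for (f in seq_len(k))
          if (sizes[f] > 0) assign_fold[idx_c[starts[f]:stops[f]]] <- f
        totals <- totals + sizes
      }
    }
  })
  folds <- lapply(seq_len(k), function(f)
    new_fold_spec(f, which(assign_fold == f), n))
  check_fold_partition(folds, n)
}

#' Load fold indices from a JSON file
#'
#' The file holds `k` arrays of 0-based test-set record indices; train sets
#' are the complements. Validates range and the partition property.
#'
#' @param path JSON file with a list of index arrays.
#' @param n_records number of records the indices refer to.
#' @return list of fold specs.
#' @export
load_fold_indices <- function(path, n_records) {
  lists <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.matrix(lists)) lists <- split(lists, row(lists))
  if (!is.list(lists)) lists <- list(as.vector(lists))
  folds <- lapply(seq_along(lists), function(f) {
    idx0 <- as.integer(lists[[f]])
    if (any(idx0 < 0L | idx0 >= n_records))
      stopf("triseg_validation_error",
            "fold %d contains index outside [0, %d)", f, n_records)
    new_fold_spec(f, idx0 + 1L, n_records)
  })
  check_fold_partition(folds, n_records)
}

#' Write fold indices as JSON (0-based test sets)
#'
#' @param folds list of fold specs.
#' @param path destination JSON file.
#' @export
write_fold_indices <- function(folds, path) {
  lists <- lapply(folds, function(f) f$test_indices - 1L)
  jsonlite::write_json(lists, path)
  invisible(path)
}
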