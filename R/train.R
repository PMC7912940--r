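#' Training configuration
#'
#' Reference schedule: 80 epochs of SGD with momentum 0.9, starting
#' learning rate 0.005, and a stepwise exponential decay (factor
#' `lr_decay_factor`) every 20 epochs. Loss is categorical cross-entropy
#' over the four labels. `n_pos` / `n_neg` set the per-slice window
#' sampling protocol (reference: 150 tumor / 325 healthy windows per
#' training slice).
#'
#' @param epochs training epochs.
#' @param lr0 starting learning rate.
#' @param momentum SGD momentum coefficient in \[0, 1).
#' @param lr_decay_every epochs between decays.
#' @param lr_decay_factor multiplicative decay factor in (0, 1\].
#' @param batch_size windows per SGD step.
#' @param n_pos,n_neg windows sampled per training slice.
#' @param seed RNG seed for sampling, shuffling, dropout and weight init.
#' @return an object of class `triseg_train_config`.
#' @export
train_config <- function(epochs = 80L, lr0 = 0.005, momentum = 0.9,
                         lr_decay_every = 20L, lr_decay_factor = 0.1,
                         batch_size = 128L, n_pos = 150L, n_neg = 325L,
                         seed = 1L) {
  if (epochs < 1L) stopf("triseg_config_error", "epochs must be >= 1")
  if (lr0 <= 0) stopf("triseg_config_error", "lr0 must be > 0")
  if (momentum < 0 || momentum >= 1)
    stopf("triseg_config_error", "momentum must be in [0, 1)")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    stopf("triseg_config_error", "lr_decay_factor must be in (0, 1]")
  if (lr_decay_every < 1L)
    stopf("triseg_config_error", "lr_decay_every must be >= 1")
  structure(list(epochs = as.integer(epochs), lr0 = lr0, momentum = momentum,
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 batch_size = as.integer(batch_size),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seed = as.integer(seed)),
            class = "triseg_train_config")
}

#' Stepwise exponential learning-rate schedule
#'
#' `lr0 * factor^floor(epoch / lr_decay_every)` for a 0-based epoch index.
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return learning rate for that epoch.
#' @export
lr_schedule <- function(config, epoch) {
  if (epoch < 0 || epoch >= config$epochs)
    stopf("triseg_validation_error", "epoch %d outside [0, %d)", epoch,
          config$epochs)
  config$lr0 * config$lr_decay_factor^(epoch %/% config$lr_decay_every)
}

sgd_step <- function(params, grads, vel, lr, momentum) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      v2 <- momentum * v + g
      list(p = p - lr * v2, v = v2)
    }
  }
  walk(params, grads, vel)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

#' Train the network on one fold
#'
#' Runs the full training pipeline on a set of training slices: elastic
#' augmentation ([augment_fold()]), per-slice window sampling
#' ([sample_windows()]), pooled standardization ([fit_standardization()]),
#' then shuffled mini-batch SGD with momentum, cross-entropy loss, active
#' dropout and the stepwise learning-rate schedule. Deterministic under
#' `train_cfg$seed`.
#'
#' @param train_records nonempty list of slice records.
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param aug_params an [elastic_params()]; `NULL` disables augmentation.
#' @return list with `model`, `stats` (normalization statistics) and `log`
#'   (data frame: epoch, lr, mean_loss).
#' @export
train_fold <- function(train_records, net_cfg, train_cfg, aug_params = NULL) {
  if (length(train_records) == 0)
    stopf("triseg_validation_error", "train_fold needs a nonempty fold")
  if (!is.null(aug_params))
    train_records <- augment_fold(train_records, aug_params)

  sampled <- lapply(seq_along(train_records), function(i)
    sample_windows(train_records[[i]], n_pos = train_cfg$n_pos,
                   n_neg = train_cfg$n_neg,
                   window_size = net_cfg$window_size,
                   seed = mix_seed(train_cfg$seed, i)))
  patches <- do.call(cbind, lapply(sampled, `[[`, "patches"))
  labels <- unlist(lapply(sampled, `[[`, "labels"))
  stats <- fit_standardization(patches)
  patches <- standardize(patches, stats)

  model <- build_network(net_cfg, seed = mix_seed(train_cfg$seed, 7919L))
  vel <- zero_like(model$params)
  n <- length(labels)
  n_cls <- net_cfg$n_classes
  log_rows <- vector("list", train_cfg$epochs)

  with_seed(mix_seed(train_cfg$seed, 104729L), {
    for (epoch in 0:(train_cfg$epochs - 1L)) {
      lr <- lr_schedule(train_cfg, epoch)
      ord <- sample(n)
      losses <- numeric(0)
      weights <- numeric(0)
      for (start in seq(1L, n, by = train_cfg$batch_size)) {
        end <- min(start + train_cfg$batch_size - 1L, n)
        idx <- ord[start:end]
        B <- length(idx)
        A <- matrix(as.numeric(patches[, idx]), ncol = 1L)
        fw <- nn_forward(model, A, B, train = TRUE)
        y <- labels[idx]
        pk <- fw$probs[cbind(seq_len(B), y + 1L)]
        loss <- -mean(log(pmax(pk, 1e-12)))
        if (!is.finite(loss))
          stopf("triseg_training_error",
                "non-finite loss at epoch %d, batch starting %d", epoch, start)
        Y <- matrix(0, B, n_cls)
        Y[cbind(seq_len(B), y + 1L)] <- 1
        grads <- nn_backward(model, fw$cache, (fw$probs - Y) / B)
        upd <- sgd_step(model$params, grads, vel, lr, train_cfg$momentum)
        model$params <- upd$p
        vel <- upd$v
        losses <- c(losses, loss)
        weights <- c(weights, B)
      }
      log_rows[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr,
        mean_loss = sum(losses * weights) / sum(weights))
    }
  })
  list(model = model, stats = stats, log = do.call(rbind, log_rows))
}

#' Cross-validated train / evaluate run
#'
#' For each fold: trains on the training slices (with augmentation),
#' segments every test slice with [segment_slice()], classifies it with
#' [classify_slice()], and scores it with [slice_metrics()]. The aggregate
#' report concatenates per-slice results over all folds and tallies the
#' confusion matrix over the whole dataset.
#'
#' @param records list of slice records.
#' @param folds fold specs from [make_stratified_folds()] or
#'   [load_fold_indices()].
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()]; per-fold seeds are derived from
#'   `train_cfg$seed`.
#' @param aug_params an [elastic_params()] or `NULL`.
#' @param stride inference stride.
#' @param tau_c confidence threshold for slice classification.
#' @return an evaluation report (class `triseg_report`): list with
#'   `per_slice` data frame, `confusion` summary from [build_confusion()],
#'   `macro` per-class and average Dice/sensitivity/pttas, `ratios`
#'   matrix, and per-fold training logs.
#' @export
run_cross_validation <- function(records, folds, net_cfg, train_cfg,
                                 aug_params = NULL, stride = 1L,
                                 tau_c = 0.75) {
  check_fold_partition(folds, length(records))
  per_slice <- vector("list", length(folds))
  logs <- vector("list", length(folds))
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tc <- train_cfg
    tc$seed <- mix_seed(train_cfg$seed, fold$fold_id)
    ap <- aug_params
    if (!is.null(ap)) ap$seed <- mix_seed(ap$seed, fold$fold_id)
    fit <- tryCatch(
      train_fold(records[fold$train_indices], net_cfg, tc, ap),
      triseg_error = function(e) {
        stopf(class(e)[1], "fold %d: %s", fold$fold_id, conditionMessage(e))
      })
    rows <- lapply(fold$test_indices, function(i) {
      lm <- segment_slice(fit$model, fit$stats, records[[i]]$image,
                          stride = stride)
      cl <- classify_slice(lm, tau_c)
      sm <- slice_metrics(lm, records[[i]])
      data.frame(index = i, fold = fold$fold_id, true = records[[i]]$label,
                 lp = cl$lp, dice = sm$dice, sensitivity = sm$sensitivity,
                 pttas = sm$pttas, r1 = cl$ratios[1], r2 = cl$ratios[2],
                 r3 = cl$ratios[3])
    })
    per_slice[[f]] <- do.call(rbind, rows)
    logs[[f]] <- fit$log
    models[[f]] <- fit
  }
  ps <- do.call(rbind, per_slice)
  ps <- ps[order(ps$index), ]
  rownames(ps) <- NULL
  build_report(ps, tau_c, logs = logs, fits = models)
}

## Assemble an evaluation report from per-slice results.
build_report <- function(per_slice, tau_c, logs = NULL, fits = NULL) {
  conf <- build_confusion(per_slice$true, per_slice$lp)
  macro <- lapply(c(dice = "dice", sensitivity = "sensitivity",
                    pttas = "pttas"), function(mcol) {
    per_class <- vapply(1:3, function(cls)
      mean(per_slice[[mcol]][per_slice$true == cls]), 0)
    list(per_class = per_class,
         average = macro_average(per_class, truncate = TRUE))
  })
  structure(list(per_slice = per_slice, tau_c = tau_c, confusion = conf,
                 macro = macro,
                 ratios = as.matrix(per_slice[, c("r1", "r2", "r3")]),
                 logs = logs, fits = fits),
            class = "triseg_report")
}

#' Serialize an evaluation report to JSON
#'
#' Stable, digit-limited JSON so identical runs produce byte-identical
#' reports. Model fits and logs are omitted.
#'
#' @param report a `triseg_report`.
#' @return a JSON string.
#' @export
report_to_json <- function(report) {
  payload <- list(
    tau_c = report$tau_c,
    accuracy = report$confusion$accuracy,
    accuracy_exact = report$confusion$accuracy_exact,
    confusion = report$confusion$confusion,
    per_class_sensitivity = report$confusion$per_class_sensitivity,
    non_classified = report$confusion$non_classified,
    macro = report$macro,
    per_slice = report$per_slice)
  jsonlite::toJSON(payload, digits = 10, pretty = TRUE, matrix = "rowmajor")
}

#' @export
print.triseg_report <- function(x, ...) {
  cat("triseg evaluation report:", x$confusion$n, "slices, tau_c =",
      x$tau_c, "\n")
  cat("accuracy (truncated):", x$confusion$accuracy, "\n")
  cat("non-classified:", sum(x$confusion$non_classified), "\n")
  cat("macro Dice / Sensitivity / pttas:",
      x$macro$dice$average, "/", x$macro$sensitivity$average, "/",
      x$macro$pttas$average, "\n")
  print(x$confusion$confusion)
  invisible(x)
}
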