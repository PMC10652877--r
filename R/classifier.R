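# Supervised classification of seizure time series with an MLSTM-FCN
# (two stacked LSTM layers + fully-convolutional branch with squeeze-excite),
# evaluated by repeated leave-one-out cross-validation.

#' Classifier configuration
#'
#' Architecture follows the MLSTM-FCN family: a recurrent branch with
#' `rnn_layers = 2` stacked LSTM layers of `rnn_hidden = 200` units and a
#' convolutional branch of three temporal convolution blocks (kernel sizes
#' 8/5/3) with squeeze-excite attention, concatenated into a softmax head.
#' Both branches use dropout 0.05. The training schedule (epochs, batch size,
#' learning rate) is an engineering choice.
#'
#' @param rnn_hidden LSTM hidden units per layer.
#' @param rnn_dropout,fcn_dropout Dropout probabilities in `[0, 1)`.
#' @param channels Input channels (currently `"motion"` and/or `"delta"`).
#' @param max_len Series longer than this are uniformly resampled down;
#'   shorter ones are zero-padded (true length kept).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param conv_filters Filters of the three convolution blocks.
#' @param se_reduction Squeeze-excite bottleneck reduction factor.
#' @param base_seed Base seed; repeat `r` of [repeated_cv()] uses
#'   `base_seed + r`.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(rnn_hidden = 200L, rnn_dropout = 0.05,
                              fcn_dropout = 0.05, channels = "motion",
                              max_len = 600L, epochs = 50L, batch_size = 16L,
                              learning_rate = 1e-3,
                              conv_filters = c(128L, 256L, 128L),
                              se_reduction = 16L, base_seed = 1L) {
  stopifnot(rnn_hidden >= 1, rnn_dropout >= 0, rnn_dropout < 1,
            fcn_dropout >= 0, fcn_dropout < 1, length(channels) >= 1,
            max_len >= 8, epochs >= 1, batch_size >= 1, learning_rate > 0,
            length(conv_filters) == 3)
  structure(list(rnn_layers = 2L, rnn_hidden = as.integer(rnn_hidden),
                 rnn_dropout = rnn_dropout, fcn_dropout = fcn_dropout,
                 channels = channels, max_len = as.integer(max_len),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 conv_filters = as.integer(conv_filters),
                 kernels = c(8L, 5L, 3L),
                 se_reduction = as.integer(se_reduction),
                 base_seed = as.integer(base_seed)),
            class = "classifier_config")
}

# z-score one series; constant series become zeros (shared degenerate
# convention with the feature module)
zscore_series <- function(x, clip_id = "?") {
  s <- stats::sd(x)
  if (s == 0) {
    warning("constant signal in clip ", clip_id, ": z-score undefined, ",
            "using zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# uniform resampling to exactly n_out samples (linear interpolation)
resample_series <- function(x, n_out) {
  if (length(x) == n_out) return(x)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
}

#' Assemble clips into a padded series batch
#'
#' Each requested channel is z-scored per clip; series longer than
#' `config$max_len` are uniformly resampled down to `max_len`, shorter series
#' are zero-padded at the tail with the true length recorded. Burn-in frames
#' are excluded before any of this.
#'
#' @param signals Motion-signal tibble covering all clips (`fps` attribute
#'   required when the `"delta"` channel is requested).
#' @param manifest Manifest with `clip_id`, `label` and (for
#'   patient-stratified CV) `patient_id`.
#' @param config A [classifier_config()].
#' @return A `series_batch`: `tensors` (n x channels x max_len array),
#'   `lengths`, `labels` (factor), `clip_id`, `patient_id`, `classes`.
#' @export
prepare_batch <- function(signals, manifest, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  known <- c("motion", "delta")
  if (!all(config$channels %in% known)) {
    stop("unknown channel(s): ",
         paste(setdiff(config$channels, known), collapse = ", "),
         " (available: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  fps <- attr(signals, "fps")
  ids <- manifest$clip_id
  n <- length(ids)
  C <- length(config$channels)
  Tmax <- config$max_len
  tensors <- array(0, dim = c(n, C, Tmax))
  lengths <- integer(n)
  by_clip <- split(signals, signals$clip_id)
  for (i in seq_len(n)) {
    s <- by_clip[[ids[i]]]
    if (is.null(s)) stop("clip ", ids[i], " missing from signals", call. = FALSE)
    x0 <- s$motion[!s$burnin]
    for (ci in seq_len(C)) {
      ch <- config$channels[ci]
      x <- switch(ch,
        motion = x0,
        delta = delta_series(x0, fps = fps, lag_s = 1))
      if (length(x) < 2) {
        stop("clip ", ids[i], ": channel '", ch, "' has fewer than 2 samples",
             call. = FALSE)
      }
      x <- zscore_series(x, ids[i])
      if (length(x) > Tmax) x <- resample_series(x, Tmax)
      tensors[i, ci, seq_along(x)] <- x
      lengths[i] <- length(x)   # channels share the grid except delta's lag
    }
  }
  structure(list(tensors = tensors, lengths = lengths,
                 labels = factor(manifest$label),
                 clip_id = ids,
                 patient_id = manifest$patient_id %||% ids,
                 classes = sort(unique(as.character(manifest$label))),
                 config = config),
            class = "series_batch")
}

#' @export
print.series_batch <- function(x, ...) {
  d <- dim(x$tensors)
  cat("<series_batch> ", d[1], " clips x ", d[2], " channel(s) x ", d[3],
      " samples; classes: ", paste(levels(x$labels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build (initialise) an MLSTM-FCN model
#'
#' Returns the seeded initial parameter set of the two-branch network; the
#' same `(config, n_classes, seed)` triple always yields identical
#' parameters.
#'
#' @param config A [classifier_config()].
#' @param n_classes Number of output classes (>= 2).
#' @param n_channels Number of input channels.
#' @param seed Integer seed for the initialisation.
#' @return An `mlstm_model` (list of parameter matrices).
#' @export
build_model <- function(config, n_classes, n_channels = length(config$channels),
                        seed = config$base_seed) {
  stopifnot(inherits(config, "classifier_config"), n_classes >= 2)
  H <- config$rnn_hidden
  C <- n_channels
  Fs <- config$conv_filters
  ks <- config$kernels
  r1 <- max(4L, Fs[1] %/% config$se_reduction)
  r2 <- max(4L, Fs[2] %/% config$se_reduction)
  with_seed(seed, {
    k <- 1 / sqrt(H)
    b1 <- rep(0, 4 * H); b1[(H + 1):(2 * H)] <- 1   # forget-gate bias
    b2 <- b1
    he <- function(fan_in, nr, nc) {
      matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
    }
    params <- list(
      W1 = matrix(stats::runif((C + H) * 4 * H, -k, k), C + H, 4 * H),
      b1 = b1,
      W2 = matrix(stats::runif(2 * H * 4 * H, -k, k), 2 * H, 4 * H),
      b2 = b2,
      Wc1 = he(ks[1] * C, ks[1] * C, Fs[1]), bc1 = rep(0, Fs[1]),
      g1 = rep(1, Fs[1]), be1 = rep(0, Fs[1]),
      Ws1a = glorot(Fs[1], r1), bs1a = rep(0, r1),
      Ws1b = glorot(r1, Fs[1]), bs1b = rep(0, Fs[1]),
      Wc2 = he(ks[2] * Fs[1], ks[2] * Fs[1], Fs[2]), bc2 = rep(0, Fs[2]),
      g2 = rep(1, Fs[2]), be2 = rep(0, Fs[2]),
      Ws2a = glorot(Fs[2], r2), bs2a = rep(0, r2),
      Ws2b = glorot(r2, Fs[2]), bs2b = rep(0, Fs[2]),
      Wc3 = he(ks[3] * Fs[2], ks[3] * Fs[2], Fs[3]), bc3 = rep(0, Fs[3]),
      g3 = rep(1, Fs[3]), be3 = rep(0, Fs[3]),
      Wh = glorot(H + Fs[3], n_classes), bh = rep(0, n_classes),
      rm1 = rep(0, Fs[1]), rv1 = rep(1, Fs[1]),
      rm2 = rep(0, Fs[2]), rv2 = rep(1, Fs[2]),
      rm3 = rep(0, Fs[3]), rv3 = rep(1, Fs[3]))
    structure(list(params = params, config = config,
                   n_classes = as.integer(n_classes), seed = as.integer(seed)),
              class = "mlstm_model")
  })
}

#' @export
print.mlstm_model <- function(x, ...) {
  cat("<mlstm_model> 2xLSTM(", x$config$rnn_hidden, ") + FCN(",
      paste(x$config$conv_filters, collapse = "/"), ") -> ", x$n_classes,
      " classes\n", sep = "")
  invisible(x)
}

#' Train an MLSTM-FCN on a series batch
#'
#' @param model An [build_model()] initialisation.
#' @param batch A [prepare_batch()] result (or a subset, see
#'   [subset_batch()]).
#' @param seed Seed for shuffling and dropout; defaults to the model's seed.
#' @return The trained `mlstm_model` with a `losses` element.
#' @export
train_model <- function(model, batch, seed = model$seed) {
  stopifnot(inherits(model, "mlstm_model"), inherits(batch, "series_batch"))
  cfg <- model$config
  y <- as.integer(factor(as.character(batch$labels), levels = batch$classes)) - 1L
  fit <- cpp_mlstm_train(batch$tensors, batch$lengths, y, model$params,
                         cfg$epochs, cfg$batch_size, cfg$learning_rate,
                         cfg$rnn_dropout, cfg$fcn_dropout, as.integer(seed))
  model$params <- fit$params
  model$losses <- fit$losses
  model$classes <- batch$classes
  model
}

#' Predict class probabilities for a series batch
#' @param object A trained `mlstm_model`.
#' @param batch A `series_batch`.
#' @param ... Unused.
#' @return Matrix of softmax probabilities (clips x classes).
#' @export
predict.mlstm_model <- function(object, batch, ...) {
  p <- cpp_mlstm_predict(batch$tensors, batch$lengths, object$params)
  colnames(p) <- object$classes %||% batch$classes
  rownames(p) <- batch$clip_id
  p
}

#' Subset a series batch by clip indices
#' @param batch A `series_batch`.
#' @param idx Integer or logical index over clips.
#' @export
subset_batch <- function(batch, idx) {
  out <- batch
  out$tensors <- batch$tensors[idx, , , drop = FALSE]
  out$lengths <- batch$lengths[idx]
  out$labels <- batch$labels[idx]
  out$clip_id <- batch$clip_id[idx]
  out$patient_id <- batch$patient_id[idx]
  out
}

#' Leave-one-out cross-validation
#'
#' Holds out one unit at a time (a seizure clip, or a whole patient), trains
#' from a fresh seeded initialisation on the remainder, and predicts the
#' held-out clips. The fold seed is derived deterministically from `seed` and
#' the fold index.
#'
#' @param batch A [prepare_batch()] result.
#' @param config A [classifier_config()].
#' @param unit `"seizure"` (leave one clip out) or `"patient"`.
#' @param seed Integer seed.
#' @return Tibble with `clip_id`, `truth`, `predicted`, `fold`.
#' @export
loocv <- function(batch, config = batch$config,
                  unit = c("seizure", "patient"), seed = config$base_seed) {
  unit <- match.arg(unit)
  units <- if (unit == "seizure") batch$clip_id else unique(batch$patient_id)
  stopifnot(length(units) >= 2)
  cls_units <- if (unit == "seizure") {
    table(batch$labels)
  } else {
    table(batch$labels[!duplicated(batch$patient_id)])
  }
  rows <- vector("list", length(units))
  for (k in seq_along(units)) {
    hold <- if (unit == "seizure") batch$clip_id == units[k]
            else batch$patient_id == units[k]
    train_b <- subset_batch(batch, !hold)
    test_b <- subset_batch(batch, hold)
    if (length(unique(as.character(train_b$labels))) < length(batch$classes)) {
      warning("fold ", k, ": class missing from training fold; fold still run",
              call. = FALSE)
    }
    fold_seed <- derive_seed(seed, k)
    model <- build_model(config, n_classes = length(batch$classes),
                         n_channels = dim(batch$tensors)[2], seed = fold_seed)
    model <- train_model(model, train_b, seed = fold_seed)
    p <- predict(model, test_b)
    rows[[k]] <- tibble::tibble(
      clip_id = test_b$clip_id,
      truth = as.character(test_b$labels),
      predicted = batch$classes[max.col(p, ties.method = "first")],
      fold = k)
  }
  dplyr::bind_rows(rows)
}

#' Classification metrics of one prediction set
#'
#' Per-class accuracy is the recall of that class (correct of that class over
#' all of that class); per-class F1 is the one-vs-rest harmonic mean of
#' precision and recall; overall accuracy is total correct over total; overall
#' F1 is the macro average. All values are percentages. A class with zero true
#' instances yields `NA` metrics and is excluded from the macro average with a
#' warning.
#'
#' @param truth,predicted Aligned class vectors.
#' @param classes Class order for the output (default: sorted union).
#' @return List: `per_class_accuracy`, `per_class_f1` (named vectors, %),
#'   `overall_accuracy`, `overall_f1` (%).
#' @export
evaluate_metrics <- function(truth, predicted,
                             classes = sort(unique(c(truth, predicted)))) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  truth <- as.character(truth); predicted <- as.character(predicted)
  acc <- f1 <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    n_true <- sum(truth == cl)
    if (n_true == 0) {
      warning("class '", cl, "' has no true instances: metrics undefined",
              call. = FALSE)
      next
    }
    tp <- sum(truth == cl & predicted == cl)
    recall <- tp / n_true
    acc[cl] <- 100 * recall
    n_pred <- sum(predicted == cl)
    precision <- if (n_pred == 0) 0 else tp / n_pred
    f1[cl] <- if (precision + recall == 0) 0 else
      100 * 2 * precision * recall / (precision + recall)
  }
  list(per_class_accuracy = acc,
       per_class_f1 = f1,
       overall_accuracy = 100 * mean(truth == predicted),
       overall_f1 = mean(f1, na.rm = TRUE))
}

#' Repeated leave-one-out cross-validation
#'
#' Deep-network training is stochastic (random initialisation, shuffling,
#' dropout), so a single cross-validation run is itself a random variable.
#' Repeating the whole LOOCV `n_repeats` times (repeat `r` seeded with
#' `base_seed + r`) gives a mean and a normal-approximation confidence
#' half-width `z(1 - alpha/2) * sd / sqrt(n_repeats)` for every metric.
#'
#' @param batch A [prepare_batch()] result.
#' @param config A [classifier_config()].
#' @param n_repeats Number of CV repetitions (>= 2).
#' @param alpha Confidence level is `1 - alpha`.
#' @param unit See [loocv()].
#' @return A `cv_result`: per-repeat metric matrices, their means and CI
#'   half-widths, plus the per-repeat prediction tables.
#' @export
repeated_cv <- function(batch, config = batch$config, n_repeats = 100L,
                        alpha = 0.05, unit = c("seizure", "patient")) {
  unit <- match.arg(unit)
  stopifnot(n_repeats >= 2)
  classes <- batch$classes
  acc <- f1 <- matrix(NA_real_, n_repeats, length(classes),
                      dimnames = list(NULL, classes))
  overall_acc <- overall_f1 <- numeric(n_repeats)
  preds <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    pr <- loocv(batch, config, unit = unit, seed = config$base_seed + r)
    m <- evaluate_metrics(pr$truth, pr$predicted, classes)
    acc[r, ] <- m$per_class_accuracy
    f1[r, ] <- m$per_class_f1
    overall_acc[r] <- m$overall_accuracy
    overall_f1[r] <- m$overall_f1
    preds[[r]] <- dplyr::mutate(pr, repeat_id = r)
  }
  z <- stats::qnorm(1 - alpha / 2)
  ci <- function(x) z * stats::sd(x) / sqrt(length(x))
  structure(list(
    n_repeats = as.integer(n_repeats), alpha = alpha, classes = classes,
    unit = unit,
    per_class_accuracy = acc, per_class_f1 = f1,
    overall_accuracy = overall_acc, overall_f1 = overall_f1,
    mean_per_class_accuracy = colMeans(acc),
    mean_per_class_f1 = colMeans(f1),
    ci_per_class_accuracy = apply(acc, 2, ci),
    ci_per_class_f1 = apply(f1, 2, ci),
    mean_overall_accuracy = mean(overall_acc),
    mean_overall_f1 = mean(overall_f1),
    ci_overall_accuracy = ci(overall_acc),
    ci_overall_f1 = ci(overall_f1),
    predictions = dplyr::bind_rows(preds)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$n_repeats, " repeats, leave-one-", x$unit,
      "-out\n", sep = "")
  cat(sprintf("  overall accuracy %.2f%% (+/- %.2f), f1 %.2f%% (+/- %.2f)\n",
              x$mean_overall_accuracy, x$ci_overall_accuracy,
              x$mean_overall_f1, x$ci_overall_f1))
  for (cl in x$classes) {
    cat(sprintf("  %-13s accuracy %6.2f%% (+/- %.2f), f1 %6.2f%% (+/- %.2f)\n",
                cl, x$mean_per_class_accuracy[cl], x$ci_per_class_accuracy[cl],
                x$mean_per_class_f1[cl], x$ci_per_class_f1[cl]))
  }
  invisible(x)
}

#' Tidy per-class cross-validation metrics
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per class and metric.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(class = x$classes, metric = "accuracy",
                   mean = unname(x$mean_per_class_accuracy),
                   ci_halfwidth = unname(x$ci_per_class_accuracy)),
    tibble::tibble(class = x$classes, metric = "f1",
                   mean = unname(x$mean_per_class_f1),
                   ci_halfwidth = unname(x$ci_per_class_f1)))
}

#' One-row cross-validation summary
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(n_repeats = x$n_repeats, alpha = x$alpha, unit = x$unit,
                 overall_accuracy = x$mean_overall_accuracy,
                 overall_accuracy_ci = x$ci_overall_accuracy,
                 overall_f1 = x$mean_overall_f1,
                 overall_f1_ci = x$ci_overall_f1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Persist a cross-validation result as JSON (plus a markdown table)
#'
#' @param result A `cv_result`.
#' @param path JSON output path.
#' @param markdown Optional path for a rendered markdown table.
#' @export
write_cv_json <- function(result, path, markdown = NULL) {
  out <- list(
    n_repeats = result$n_repeats, alpha = result$alpha, unit = result$unit,
    classes = result$classes,
    mean_per_class_accuracy = as.list(result$mean_per_class_accuracy),
    ci_per_class_accuracy = as.list(result$ci_per_class_accuracy),
    mean_per_class_f1 = as.list(result$mean_per_class_f1),
    ci_per_class_f1 = as.list(result$ci_per_class_f1),
    mean_overall_accuracy = result$mean_overall_accuracy,
    ci_overall_accuracy = result$ci_overall_accuracy,
    mean_overall_f1 = result$mean_overall_f1,
    ci_overall_f1 = result$ci_overall_f1)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(markdown)) {
    lines <- c(
      "| metric | " %+% paste(result$classes, collapse = " | ") %+% " | overall |",
      "|---|" %+% paste(rep("---|", length(result$classes) + 1), collapse = ""),
      "| mean accuracy (%) | " %+%
        paste(sprintf("%.2f", result$mean_per_class_accuracy), collapse = " | ") %+%
        " | " %+% sprintf("%.2f", result$mean_overall_accuracy) %+% " |",
      "| accuracy CI (+/-) | " %+%
        paste(sprintf("%.2f", result$ci_per_class_accuracy), collapse = " | ") %+%
        " | " %+% sprintf("%.2f", result$ci_overall_accuracy) %+% " |",
      "| mean f1 (%) | " %+%
        paste(sprintf("%.2f", result$mean_per_class_f1), collapse = " | ") %+%
        " | " %+% sprintf("%.2f", result$mean_overall_f1) %+% " |",
      "| f1 CI (+/-) | " %+%
        paste(sprintf("%.2f", result$ci_per_class_f1), collapse = " | ") %+%
        " | " %+% sprintf("%.2f", result$ci_overall_f1) %+% " |")
    writeLines(lines, markdown)
  }
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
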