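tiny_config <- function(...) {
  args <- list(rnn_hidden = 6L, conv_filters = c(4L, 6L, 5L),
               se_reduction = 2L, max_len = 8L, epochs = 5L,
               batch_size = 4L, learning_rate = 5e-3, base_seed = 11L)
  over <- list(...)
  args[names(over)] <- over
  do.call(classifier_config, args)
}

# signals for n synthetic clips: "flat" = noise, "sine" = strong oscillation
toy_signals <- function(n_per_class, len = 40, fps = 10, seed = 5) {
  with_seed(seed, {
    rows <- list()
    manifest <- list()
    idx <- 0
    for (cl in c("flat", "sine")) {
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1
        id <- sprintf("%s%02d", cl, i)
        x <- if (cl == "flat") rnorm(len, 0, 0.05) else
          sin(2 * pi * 3 * seq_len(len) / fps) + rnorm(len, 0, 0.05)
        rows[[idx]] <- tibble::tibble(
          clip_id = id, frame = seq_len(len), time_s = (seq_len(len) - 1) / fps,
          motion = x, burnin = FALSE)
        manifest[[idx]] <- tibble::tibble(clip_id = id, patient_id = id,
                                          label = cl)
      }
    }
    sig <- dplyr::bind_rows(rows)
    attr(sig, "fps") <- fps
    list(signals = sig, manifest = dplyr::bind_rows(manifest))
  })
}

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  model <- build_model(cfg, n_classes = 2, n_channels = 1, seed = 3)
  set.seed(4)
  X <- array(rnorm(3 * 1 * 8), dim = c(3, 1, 8))
  len <- c(8L, 5L, 6L)
  y <- c(0L, 1L, 0L)
  out <- cpp_mlstm_loss_grad(X, len, y, model$params)
  eps <- 1e-5
  for (nm in c("W1", "b1", "W2", "b2", "Wc1", "bc1", "g1", "be1",
               "Ws1a", "bs1b", "Wc2", "g2", "Ws2b", "Wc3", "be3",
               "Wh", "bh")) {
    p <- model$params[[nm]]
    picks <- unique(pmin(length(p), c(1, ceiling(length(p) / 2), length(p))))
    for (j in picks) {
      pp <- model$params
      pp[[nm]][j] <- p[j] + eps
      lp <- cpp_mlstm_loss_grad(X, len, y, pp)$loss
      pp[[nm]][j] <- p[j] - eps
      lm <- cpp_mlstm_loss_grad(X, len, y, pp)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- out$grads[[nm]][j]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-4), 5e-4,
                label = paste0("grad ", nm, "[", j, "]"))
    }
  }
})

test_that("model construction is seeded and the head is a softmax", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, n_classes = 3, n_channels = 1, seed = 9)
  m2 <- build_model(cfg, n_classes = 3, n_channels = 1, seed = 9)
  expect_identical(m1$params, m2$params)
  expect_equal(ncol(m1$params$Wh), 3)
  set.seed(10)
  X <- array(rnorm(4 * 1 * 8), dim = c(4, 1, 8))
  p <- cpp_mlstm_predict(X, rep(8L, 4), m1$params)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("batch preparation pads, resamples and records true lengths", {
  toy <- toy_signals(2, len = 40, fps = 10)
  cfg <- tiny_config()           # max_len 8 < 40: resampled down
  b <- prepare_batch(toy$signals, toy$manifest, cfg)
  expect_equal(dim(b$tensors), c(4, 1, 8))
  expect_equal(b$lengths, rep(8L, 4))

  cfg2 <- classifier_config(max_len = 80L)   # 40 < 80: padded
  b2 <- prepare_batch(toy$signals, toy$manifest, cfg2)
  expect_equal(b2$lengths, rep(40L, 4))
  expect_equal(b2$tensors[1, 1, 41:80], rep(0, 40))
  # z-scored content on the valid region
  expect_equal(mean(b2$tensors[1, 1, 1:40]), 0, tolerance = 1e-12)
  expect_equal(sd(b2$tensors[1, 1, 1:40]), 1, tolerance = 1e-12)

  # exactly max_len: unchanged except z-scoring
  cfg3 <- classifier_config(max_len = 40L)
  b3 <- prepare_batch(toy$signals, toy$manifest, cfg3)
  x <- toy$signals$motion[toy$signals$clip_id == toy$manifest$clip_id[1]]
  expect_equal(b3$tensors[1, 1, ], (x - mean(x)) / sd(x), tolerance = 1e-12)

  # constant clip: zeros with a warning
  flat <- toy_signals(1, len = 20)
  flat$signals$motion <- 0.3
  w <- capture_warnings(bf <- prepare_batch(flat$signals, flat$manifest, cfg2))
  expect_true(all(grepl("constant signal", w)))
  expect_equal(max(abs(bf$tensors)), 0)
})

test_that("LOOCV predicts every clip exactly once and separates easy classes", {
  toy <- toy_signals(5)
  cfg <- tiny_config(max_len = 20L, epochs = 15L, learning_rate = 1e-2)
  b <- prepare_batch(toy$signals, toy$manifest, cfg)
  pr <- loocv(b, cfg, unit = "seizure", seed = 21)
  expect_equal(nrow(pr), 10)
  expect_setequal(pr$clip_id, toy$manifest$clip_id)
  expect_equal(anyDuplicated(pr$clip_id), 0L)
  expect_equal(mean(pr$truth == pr$predicted), 1)   # trivially separable
})

test_that("training and LOOCV are deterministic for a fixed seed", {
  toy <- toy_signals(3)
  cfg <- tiny_config(epochs = 3L)
  b <- prepare_batch(toy$signals, toy$manifest, cfg)
  p1 <- loocv(b, cfg, seed = 33)
  p2 <- loocv(b, cfg, seed = 33)
  expect_identical(p1, p2)
  m <- build_model(cfg, 2, seed = 5)
  t1 <- train_model(m, b, seed = 6)
  t2 <- train_model(m, b, seed = 6)
  expect_identical(t1$params, t2$params)
})

test_that("metrics reproduce the hand-counted confusion example", {
  truth <- c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C")
  pred <- c("A", "A", "A", "B", "B", "B", "B", "A", "C", "C")
  m <- evaluate_metrics(truth, pred)
  expect_equal(unname(m$per_class_accuracy), c(75, 75, 100))
  expect_equal(m$overall_accuracy, 80)
  # one-vs-rest f1 by hand: A: p=3/4, r=3/4 -> 75; B: p=3/4, r=3/4 -> 75;
  # C: p=1, r=1 -> 100; macro = 83.33...
  expect_equal(unname(m$per_class_f1), c(75, 75, 100))
  expect_equal(m$overall_f1, mean(c(75, 75, 100)))

  perfect <- evaluate_metrics(truth, truth)
  expect_true(all(unlist(perfect[c("per_class_accuracy", "per_class_f1")]) == 100))
  expect_equal(perfect$overall_accuracy, 100)

  onesided <- evaluate_metrics(c("A", "A", "B", "B"), rep("A", 4))
  expect_equal(unname(onesided$per_class_accuracy), c(100, 0))

  expect_warning(z <- evaluate_metrics(c("A", "A"), c("A", "B"),
                                       classes = c("A", "B")),
                 "no true instances")
  expect_true(is.na(z$per_class_f1["B"]))
  expect_equal(z$overall_f1, z$per_class_f1[["A"]])
})

test_that("metric bounds hold on random prediction vectors", {
  with_seed(77, {
    for (i in 1:20) {
      cls <- LETTERS[1:3]
      truth <- sample(cls, 30, replace = TRUE)
      pred <- sample(cls, 30, replace = TRUE)
      m <- suppressWarnings(evaluate_metrics(truth, pred, cls))
      v <- unlist(m)
      expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 100))
      expect_lte(m$overall_f1, max(m$per_class_f1, na.rm = TRUE))
    }
  })
})

test_that("repeated CV aggregates match independent recomputation", {
  toy <- toy_signals(3)
  cfg <- tiny_config(epochs = 2L, base_seed = 100L)
  b <- prepare_batch(toy$signals, toy$manifest, cfg)
  cv <- repeated_cv(b, cfg, n_repeats = 3, alpha = 0.05)
  # means recomputed independently from the per-repeat matrices
  expect_equal(unname(cv$mean_per_class_accuracy),
               unname(apply(cv$per_class_accuracy, 2, mean)))
  expect_equal(cv$mean_overall_accuracy, mean(cv$overall_accuracy))
  # CI half-width: closed form z * sd / sqrt(n)
  z <- qnorm(0.975)
  expect_equal(cv$ci_overall_accuracy,
               z * sd(cv$overall_accuracy) / sqrt(3), tolerance = 1e-9)
  expect_equal(unname(cv$ci_per_class_f1),
               unname(apply(cv$per_class_f1, 2, function(x)
                 z * sd(x) / sqrt(3))), tolerance = 1e-9)
  # every clip predicted once per repeat
  tab <- table(cv$predictions$repeat_id, cv$predictions$clip_id)
  expect_true(all(tab == 1))
  # deterministic-per-seed repeats that coincide give zero-width intervals
  cv2 <- list(overall = c(90, 90))
  expect_equal(z * sd(cv2$overall) / sqrt(2), 0)
  td <- tidy(cv)
  expect_equal(nrow(td), 4)
  expect_true(all(c("class", "metric", "mean", "ci_halfwidth") %in% names(td)))
  g <- glance(cv)
  expect_equal(g$n_repeats, 3L)
})

test_that("cv results round-trip to JSON and markdown", {
  toy <- toy_signals(3)
  cfg <- tiny_config(epochs = 2L)
  b <- prepare_batch(toy$signals, toy$manifest, cfg)
  cv <- repeated_cv(b, cfg, n_repeats = 2)
  jp <- withr::local_tempfile(fileext = ".json")
  mp <- withr::local_tempfile(fileext = ".md")
  write_cv_json(cv, jp, markdown = mp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$mean_overall_accuracy, cv$mean_overall_accuracy)
  expect_equal(back$n_repeats, 2L)
  expect_true(any(grepl("mean accuracy", readLines(mp))))
})
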