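test_that("signal, embedding and CV plots build", {
  fx <- cohort_features_fixture()
  p1 <- plot_motion(fx$signals[fx$signals$clip_id %in%
                                 fx$manifest$clip_id[1:2], ])
  expect_s3_class(p1, "ggplot")

  X <- feature_matrix(fx$temporal)
  tr <- fit_pca(X)
  emb <- project_pca(tr, X, clip_id = fx$temporal$clip_id, phase = "train",
                     label = fx$temporal$label)
  cl <- agglomerate(emb, k = 2)
  p2 <- plot_embedding(emb, cl)
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p2))
  # axes carry no units, only component names
  expect_equal(p2$labels$x, "PC1")
  expect_equal(p2$labels$y, "PC2")

  osc <- tibble::tibble(clip_id = "c1", window_end_s = 1:5,
                        freq_hz = c(0, 0, 3, 3.5, 3),
                        osc_fraction = c(0, 0, 0.8, 0.9, 0.7))
  attr(osc, "threshold_hz") <- 2.5
  expect_s3_class(plot_oscillation(osc), "ggplot")
})

test_that("autoplot renders cross-validation results", {
  toy <- with_seed(8, {
    truth <- rep(c("hyperkinetic", "tonic"), each = 10)
    structure(list(
      n_repeats = 2L, alpha = 0.05, classes = c("hyperkinetic", "tonic"),
      unit = "seizure",
      mean_per_class_accuracy = c(hyperkinetic = 95, tonic = 88),
      mean_per_class_f1 = c(hyperkinetic = 93, tonic = 90),
      ci_per_class_accuracy = c(hyperkinetic = 1, tonic = 2),
      ci_per_class_f1 = c(hyperkinetic = 1.5, tonic = 1),
      mean_overall_accuracy = 91, mean_overall_f1 = 91.5,
      ci_overall_accuracy = 1, ci_overall_f1 = 1), class = "cv_result")
  })
  p <- ggplot2::autoplot(toy)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
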