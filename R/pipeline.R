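# End-to-end orchestration: synthetic cohort -> motion signals -> catch22
# features (temporal by default) -> feature selection -> train-frozen PCA ->
# agglomerative clusters, plus repeated leave-one-out CV of the MLSTM-FCN.
# Everything is driven by one integer seed, so a full run is reproducible
# byte for byte.

#' Extract motion signals for every clip of a cohort
#'
#' @param clips Named list of `seizure_clip` objects.
#' @param ... Passed to [extract_motion_signal()].
#' @return Combined motion-signal tibble (with `fps` attribute).
#' @export
extract_cohort_signals <- function(clips, ...) {
  sigs <- dplyr::bind_rows(lapply(clips, extract_motion_signal, ...))
  attr(sigs, "fps") <- clips[[1]]$fps
  sigs
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, extracts motion signals, featurizes them with the
#' catch22 statistics (lag-delta mode by default), reduces the statistics by
#' backward elimination, fits the 2-D PCA on the training split and projects
#' the testing split through the frozen transform, discovers clusters by
#' agglomerative clustering, and (optionally) evaluates the MLSTM-FCN under
#' repeated leave-one-seizure-out cross-validation.
#'
#' @param spec Cohort spec tibble ([cohort_spec()], [clinical_cohort_spec()]).
#' @param seed Single integer driving every random component.
#' @param out_dir Optional directory for result files (`manifest.csv`,
#'   `features.csv`, `selection.json`, `pca.json`, `embedding.csv`,
#'   `cvresult.json`, `cvresult.md`).
#' @param cohort_args List of extra arguments for [generate_cohort()].
#' @param signal_args List of extra arguments for [extract_motion_signal()].
#' @param mode Feature mode, `"temporal"` (default) or `"static"`.
#' @param target_k Features kept by backward elimination; `NULL` skips
#'   selection and embeds all non-constant statistics.
#' @param cluster_k,linkage Clustering parameters, see [agglomerate()].
#' @param config [classifier_config()] for the CV stage; its `base_seed` is
#'   re-derived from `seed`.
#' @param n_repeats Number of CV repetitions; 0 skips the classifier stage.
#' @param alpha CI level parameter for [repeated_cv()].
#' @param cv_unit `"seizure"` or `"patient"`.
#' @return A `seizure_pipeline` list: `manifest`, `signals`, `features`,
#'   `selection`, `pca`, `embedding`, `clusters` (clustering of all clips),
#'   `purity_majority_classes` (purity of a clustering of the hyperkinetic
#'   and tonic clips alone — tonic-clonic clips carry no information about
#'   whether the two majority classes separate), `cv`.
#' @export
run_pipeline <- function(spec, seed,
                         out_dir = NULL,
                         cohort_args = list(),
                         signal_args = list(),
                         mode = c("temporal", "static"),
                         target_k = 5L,
                         cluster_k = 2L,
                         linkage = "ward",
                         config = classifier_config(),
                         n_repeats = 10L,
                         alpha = 0.05,
                         cv_unit = "seizure") {
  mode <- match.arg(mode)
  co <- do.call(generate_cohort,
                c(list(spec = spec, seed = derive_seed(seed, 1L)), cohort_args))
  manifest <- co$manifest
  signals <- do.call(extract_cohort_signals, c(list(clips = co$clips),
                                               signal_args))
  feats <- suppressWarnings(featurize_cohort(signals, manifest, mode = mode))
  feats <- drop_constant_features(feats, quiet = TRUE)
  selection <- NULL
  if (!is.null(target_k)) {
    n_feat <- ncol(feature_matrix(feats))
    if (target_k < n_feat) {
      train_feats <- feats[feats$split == "train", ]
      if (!nrow(train_feats)) train_feats <- feats
      selection <- select_features(train_feats, target_k = target_k)
      feats_used <- feats[, c("clip_id", "label", "split", "mode",
                              selection$kept_names)]
    } else {
      feats_used <- feats
    }
  } else {
    feats_used <- feats
  }
  is_train <- feats_used$split == "train"
  if (!any(is_train)) is_train <- rep(TRUE, nrow(feats_used))
  X <- feature_matrix(feats_used)
  pca <- fit_pca(X[is_train, , drop = FALSE])
  emb_train <- project_pca(pca, X[is_train, , drop = FALSE],
                           clip_id = feats_used$clip_id[is_train],
                           phase = "train", label = feats_used$label[is_train])
  emb <- emb_train
  if (any(!is_train)) {
    emb_test <- project_pca(pca, X[!is_train, , drop = FALSE],
                            clip_id = feats_used$clip_id[!is_train],
                            phase = "test", label = feats_used$label[!is_train])
    emb <- dplyr::bind_rows(emb_train, emb_test)
  }
  clusters <- agglomerate(emb, k = cluster_k, linkage = linkage)
  emb$cluster <- clusters$assignments
  # separability of the two majority classes: tonic-clonic clips are excluded
  # (they are expected to mingle with the hyperkinetic region, and in some
  # cohorts they form their own tight cluster, which says nothing about
  # whether hyperkinetic and tonic separate)
  maj <- emb$label %in% c("hyperkinetic", "tonic")
  purity_major <- if (sum(maj) > cluster_k) {
    agglomerate(emb[maj, ], k = cluster_k, linkage = linkage)$purity
  } else NA_real_
  cv <- NULL
  if (n_repeats > 0) {
    config$base_seed <- derive_seed(seed, 2L)
    batch <- suppressWarnings(prepare_batch(signals, manifest, config))
    cv <- suppressWarnings(
      repeated_cv(batch, config, n_repeats = n_repeats, alpha = alpha,
                  unit = cv_unit))
  }
  out <- structure(list(manifest = manifest, signals = signals,
                        features = feats, selection = selection, pca = pca,
                        embedding = emb, clusters = clusters,
                        purity_majority_classes = purity_major, cv = cv,
                        seed = seed),
                   class = "seizure_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.seizure_pipeline <- function(x, ...) {
  cat("<seizure_pipeline> seed ", x$seed, ": ", nrow(x$manifest), " clips\n",
      sep = "")
  cat("  cluster purity (hyperkinetic/tonic): ",
      signif(x$purity_majority_classes, 3), "\n", sep = "")
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}

#' Write pipeline results to a directory
#' @param pipeline A `seizure_pipeline`.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pipeline$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  write_motion_csv(pipeline$signals, file.path(dir, "signals.csv"))
  write_features_csv(pipeline$features, file.path(dir, "features.csv"))
  if (!is.null(pipeline$selection)) {
    write_selection_json(pipeline$selection, file.path(dir, "selection.json"))
  }
  write_pca_json(pipeline$pca, file.path(dir, "pca.json"))
  utils::write.csv(pipeline$embedding, file.path(dir, "embedding.csv"),
                   row.names = FALSE)
  if (!is.null(pipeline$cv)) {
    write_cv_json(pipeline$cv, file.path(dir, "cvresult.json"),
                  markdown = file.path(dir, "cvresult.md"))
  }
  invisible(dir)
}
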