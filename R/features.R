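# Signal featurization: catch22 statistics of the motion series, either on
# the raw signal (static mode) or on its lag-delta series (temporal mode),
# plus the backward feature-elimination procedure that reduces the 22
# statistics to a compact subset before the PCA step.

#' Lag-delta (difference) series
#'
#' Temporal features are computed on the delta series: the difference between
#' the current value and the value a fixed lag earlier (default 1 s), i.e.
#' `out[i] = values[i + L] - values[i]` with `L = round(lag_s * fps)`.
#'
#' @param values Numeric series.
#' @param fps Sampling rate of the series (samples per second).
#' @param lag_s Lag in seconds.
#' @return Numeric series of length `length(values) - L`.
#' @export
delta_series <- function(values, fps, lag_s = 1) {
  L <- as.integer(round(lag_s * fps))
  stopifnot(L >= 1)
  n <- length(values)
  if (n <= L) {
    stop("series too short for lag: need at least ", L + 1,
         " samples (lag L = ", L, "), got ", n, call. = FALSE)
  }
  values[(L + 1):n] - values[1:(n - L)]
}

#' Featurize one clip's signals into a fixed-length vector
#'
#' Static mode applies [catch22_features()] to the raw motion series;
#' temporal mode applies it to the lag-delta series ([delta_series()]).
#' Burn-in frames of the background model are excluded by default. If an
#' oscillation signal is supplied, its per-window frequency series is
#' featurized too and appended with an `osc_` prefix (off by default: the
#' motion signal alone carries the cluster structure).
#'
#' @param motion Motion-signal tibble from [extract_motion_signal()].
#' @param mode `"static"` or `"temporal"`.
#' @param lag_s Delta lag in seconds (temporal mode).
#' @param oscillation Optional oscillation tibble from
#'   [extract_oscillation_signal()]; when given, its `freq_hz` series is
#'   appended as extra features.
#' @param drop_burnin Exclude background-model burn-in frames.
#' @return One-row tibble: `clip_id`, `mode`, then one column per statistic.
#' @export
featurize_clip <- function(motion, mode = c("static", "temporal"), lag_s = 1,
                           oscillation = NULL, drop_burnin = TRUE) {
  mode <- match.arg(mode)
  fps <- attr(motion, "fps")
  stopifnot(!is.null(fps))
  clip_id <- motion$clip_id[1]
  x <- if (drop_burnin) motion$motion[!motion$burnin] else motion$motion
  series <- switch(mode, static = x, temporal = delta_series(x, fps, lag_s))
  vals <- catch22_features(series)
  row <- tibble::as_tibble(as.list(vals))
  if (!is.null(oscillation)) {
    ov <- catch22_features(oscillation$freq_hz)
    names(ov) <- paste0("osc_", names(ov))
    row <- dplyr::bind_cols(row, tibble::as_tibble(as.list(ov)))
  }
  dplyr::bind_cols(tibble::tibble(clip_id = clip_id, mode = mode), row)
}

#' Featurize every clip of a cohort
#'
#' @param signals Motion-signal tibble covering several clips (rows of
#'   [extract_motion_signal()] outputs bound together; the `fps` attribute
#'   must apply to all clips).
#' @param manifest Cohort manifest; `label` and `split` are joined onto the
#'   feature table.
#' @inheritParams featurize_clip
#' @return Tibble: `clip_id`, `label`, `split`, `mode`, feature columns.
#' @export
featurize_cohort <- function(signals, manifest, mode = c("static", "temporal"),
                             lag_s = 1, drop_burnin = TRUE) {
  mode <- match.arg(mode)
  fps <- attr(signals, "fps")
  rows <- lapply(split(signals, signals$clip_id), function(s) {
    attr(s, "fps") <- fps
    featurize_clip(s, mode = mode, lag_s = lag_s, drop_burnin = drop_burnin)
  })
  feats <- dplyr::bind_rows(rows)
  out <- dplyr::inner_join(
    dplyr::select(manifest, "clip_id", "label", "split"), feats,
    by = "clip_id")
  tibble::as_tibble(out)
}

#' Drop zero-variance feature columns
#'
#' Standardised PCA is undefined for constant features; this removes them
#' (with a message naming the casualties) before embedding or selection.
#'
#' @param features Feature tibble or numeric matrix.
#' @param quiet Suppress the message.
#' @return Same type as the input, minus constant feature columns.
#' @export
drop_constant_features <- function(features, quiet = FALSE) {
  meta <- intersect(names(features), c("clip_id", "label", "split", "mode"))
  if (is.data.frame(features)) {
    cols <- setdiff(names(features), meta)
    const <- cols[vapply(features[cols], function(x) stats::sd(x) == 0, TRUE)]
    if (length(const) && !quiet) {
      message("dropping constant feature(s): ", paste(const, collapse = ", "))
    }
    features[, setdiff(names(features), const)]
  } else {
    sds <- apply(features, 2, stats::sd)
    if (any(sds == 0) && !quiet) {
      message("dropping constant feature(s): ",
              paste(colnames(features)[sds == 0], collapse = ", "))
    }
    features[, sds > 0, drop = FALSE]
  }
}

feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("clip_id", "label", "split", "mode"))
  X <- as.matrix(features[, cols])
  rownames(X) <- features$clip_id
  X
}

#' Backward feature elimination against a stable cluster diagram
#'
#' Incrementally removes statistics that are redundant for the 2-D cluster
#' diagram: at each step the candidate whose removal (a) perturbs the current
#' PCA embedding least (symmetric Procrustes disparity after optimal
#' rotation/scaling) and (b) does not reduce class separability (mean
#' silhouette width of the true labels in the embedding) by more than
#' `sil_tol` is dropped, until `target_k` features remain. A column exactly
#' equal to another remaining column is redundant by definition and is always
#' removed first. When no candidate
#' passes the separability guard, the one minimising disparity plus excess
#' silhouette drop (weighted 1:1) is dropped. Ties break lexicographically by
#' feature name, so the selection is deterministic for a given input.
#'
#' @param features Feature tibble (as from [featurize_cohort()]) or numeric
#'   matrix.
#' @param labels True class per row (taken from `features$label` if present).
#' @param target_k Number of features to keep.
#' @param sil_tol Tolerated per-step silhouette drop.
#' @return A `feature_selection` object: `kept_names` and `trace` (tibble
#'   with one row per removal: `removed`, `disparity`, `silhouette`).
#' @export
select_features <- function(features, labels = NULL, target_k = 5L,
                            sil_tol = 0.02) {
  if (is.data.frame(features) && is.null(labels) && "label" %in% names(features)) {
    labels <- features$label
  }
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  stopifnot(!is.null(labels), length(labels) == nrow(X))
  if (nrow(X) < 10) stop("need >= 10 clips", call. = FALSE)
  if (length(unique(labels)) < 2) stop("need >= 2 classes", call. = FALSE)
  if (target_k >= ncol(X)) {
    stop("target_k (", target_k, ") must be smaller than the feature count (",
         ncol(X), ")", call. = FALSE)
  }
  lab_int <- as.integer(factor(labels))
  embed <- function(cols) {
    tr <- fit_pca(X[, cols, drop = FALSE])
    co <- project_pca(tr, X[, cols, drop = FALSE], phase = "train")
    cbind(co$pc1, co$pc2)
  }
  silhouette_of <- function(coords) {
    mean(cluster::silhouette(lab_int, stats::dist(coords))[, "sil_width"])
  }
  keep <- sort(colnames(X))
  trace <- list()
  cur_emb <- embed(keep)
  cur_sil <- silhouette_of(cur_emb)
  while (length(keep) > target_k) {
    # a column exactly equal to another remaining column adds no information:
    # redundant by definition, removed before anything informative is touched
    dup <- NULL
    for (j in seq_along(keep)[-1]) {
      if (any(vapply(keep[seq_len(j - 1)],
                     function(g) identical(X[, keep[j]], X[, g]), TRUE))) {
        dup <- keep[j]
        break
      }
    }
    if (!is.null(dup)) {
      cols <- setdiff(keep, dup)
      emb <- embed(cols)
      trace[[length(trace) + 1]] <- tibble::tibble(
        removed = dup,
        disparity = vegan::procrustes(cur_emb, emb, symmetric = TRUE)$ss,
        silhouette = silhouette_of(emb))
      keep <- cols
      cur_emb <- embed(keep)
      cur_sil <- silhouette_of(cur_emb)
      next
    }
    cand <- vapply(keep, function(f) {
      cols <- setdiff(keep, f)
      emb <- embed(cols)
      disp <- vegan::procrustes(cur_emb, emb, symmetric = TRUE)$ss
      c(disp = disp, sil = silhouette_of(emb))
    }, c(disp = 0, sil = 0))
    disp <- cand["disp", ]; sil <- cand["sil", ]
    drop_amt <- cur_sil - sil
    ok <- drop_amt <= sil_tol
    score <- if (any(ok)) ifelse(ok, disp, Inf)
             else disp + (drop_amt - sil_tol)
    f_rm <- keep[which.min(score)]   # keep is sorted: ties break by name
    trace[[length(trace) + 1]] <- tibble::tibble(
      removed = f_rm, disparity = disp[[f_rm]], silhouette = sil[[f_rm]])
    keep <- setdiff(keep, f_rm)
    cur_emb <- embed(keep)
    cur_sil <- silhouette_of(cur_emb)
  }
  structure(list(kept_names = keep, trace = dplyr::bind_rows(trace)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> kept ", length(x$kept_names), " features:\n  ",
      paste(x$kept_names, collapse = "\n  "), "\n", sep = "")
  invisible(x)
}

#' Persist / restore a feature selection as JSON
#' @param selection A `feature_selection` object.
#' @param path JSON file path.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(list(kept_names = selection$kept_names,
                            trace = selection$trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kept_names = j$kept_names,
                 trace = tibble::as_tibble(j$trace)),
            class = "feature_selection")
}

#' Write / read a feature table as CSV
#' @param features Feature tibble from [featurize_cohort()].
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
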