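# Train-frozen 2-D PCA embedding and agglomerative cluster discovery.
# The PCA is fitted on the training cohort only; testing clips are projected
# through the frozen transform (standardised with the training means/scales,
# never refitted). Embedding axes are unitless.

#' Fit a 2-D PCA transform on training features
#'
#' Features are standardised (z-scored with training statistics) before the
#' rotation is computed, i.e. correlation PCA: the catch22 statistics live on
#' heterogeneous scales. Component signs follow a fixed convention — the
#' largest-magnitude loading of each component is positive — so embeddings
#' are reproducible run to run.
#'
#' @param train_features Numeric matrix or data frame (rows = clips, columns
#'   = features), no missing values, at least 3 rows and 2 columns.
#' @return A `pca2` object: `feature_names`, `means`, `scales`, `rotation`
#'   (k x 2), `explained_variance` (descending).
#' @export
fit_pca <- function(train_features) {
  X <- as.matrix(train_features)
  stopifnot(nrow(X) >= 3, ncol(X) >= 2, !anyNA(X))
  mns <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         " (sanitise features upstream)", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, mns), 2, sds, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(feature_names = colnames(X), means = mns, scales = sds,
                 rotation = rot,
                 explained_variance = pc$sdev[1:2]^2,
                 all_variances = pc$sdev^2),
            class = "pca2")
}

#' @export
print.pca2 <- function(x, ...) {
  cat("<pca2> ", length(x$feature_names), " features -> 2 components; ",
      "explained variance ", paste(signif(x$explained_variance, 4),
                                   collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project features through a frozen PCA transform
#'
#' Standardises with the *training* means and scales (never refit) and
#' applies the stored rotation — the frozen-transform contract for scoring
#' testing patients against a training-phase embedding.
#'
#' @param transform A [fit_pca()] object.
#' @param features Matrix or data frame with the transform's feature columns.
#' @param clip_id,label Optional per-row annotations carried into the output.
#' @param phase `"train"` or `"test"` tag for plotting.
#' @return Tibble with `clip_id`, `pc1`, `pc2`, `phase`, `label`.
#' @export
project_pca <- function(transform, features, clip_id = NULL, phase = "test",
                        label = NULL) {
  stopifnot(inherits(transform, "pca2"))
  X <- as.matrix(features)
  if (ncol(X) != length(transform$feature_names)) {
    stop("feature dimension mismatch: transform expects ",
         length(transform$feature_names), " columns, got ", ncol(X),
         call. = FALSE)
  }
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), transform$feature_names)) {
    stopifnot(setequal(colnames(X), transform$feature_names))
    X <- X[, transform$feature_names, drop = FALSE]
  }
  Z <- sweep(sweep(X, 2, transform$means), 2, transform$scales, "/")
  coords <- Z %*% transform$rotation
  tibble::tibble(
    clip_id = clip_id %||% rownames(X) %||% as.character(seq_len(nrow(X))),
    pc1 = coords[, 1], pc2 = coords[, 2],
    phase = phase,
    label = label %||% NA_character_)
}

#' Persist / restore a PCA transform as JSON
#' @param transform A `pca2` object.
#' @param path JSON file path.
#' @export
write_pca_json <- function(transform, path) {
  jsonlite::write_json(list(
    feature_names = transform$feature_names,
    means = unname(transform$means), scales = unname(transform$scales),
    rotation = transform$rotation,
    explained_variance = transform$explained_variance), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_names = j$feature_names,
                 means = setNames(j$means, j$feature_names),
                 scales = setNames(j$scales, j$feature_names),
                 rotation = matrix(unlist(j$rotation),
                                   ncol = 2,
                                   dimnames = list(j$feature_names, NULL)),
                 explained_variance = j$explained_variance),
            class = "pca2")
}

#' Discover clusters in a 2-D embedding by agglomerative clustering
#'
#' Bottom-up merging under Euclidean distance (Ward, average or complete
#' linkage) until `k` clusters remain. When true seizure labels are supplied,
#' each cluster is mapped to its majority class and the purity (fraction of
#' clips matching their cluster's majority class) is reported.
#'
#' @param points Two-column matrix of coordinates, or an embedding tibble
#'   with `pc1`/`pc2` columns (as from [project_pca()]).
#' @param k Number of clusters (>= 2, < number of points).
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @param labels Optional true class per point.
#' @return A `seizure_clusters` object: `assignments`, `k`, `linkage`,
#'   `label_map`, `purity`, `tree` (the hclust object).
#' @export
agglomerate <- function(points, k = 2L, linkage = c("ward", "average",
                                                    "complete"),
                        labels = NULL) {
  linkage <- match.arg(linkage)
  if (is.data.frame(points) && all(c("pc1", "pc2") %in% names(points))) {
    if (is.null(labels) && "label" %in% names(points)) labels <- points$label
    points <- cbind(points$pc1, points$pc2)
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= k) stop("need more points (", n, ") than clusters (", k, ")",
                   call. = FALSE)
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  tree <- stats::hclust(stats::dist(points), method = method)
  assign <- stats::cutree(tree, k = k)
  label_map <- NULL
  purity <- NA_real_
  if (!is.null(labels)) {
    label_map <- vapply(split(as.character(labels), assign), function(l) {
      names(sort(table(l), decreasing = TRUE))[1]
    }, "")
    purity <- mean(as.character(labels) == label_map[as.character(assign)])
  }
  structure(list(assignments = assign, k = as.integer(k), linkage = linkage,
                 label_map = label_map, purity = purity, tree = tree),
            class = "seizure_clusters")
}

#' @export
print.seizure_clusters <- function(x, ...) {
  cat("<seizure_clusters> k = ", x$k, " (", x$linkage, " linkage)",
      if (!is.na(x$purity)) paste0(", purity ", signif(x$purity, 3)),
      "\n", sep = "")
  invisible(x)
}
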