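test_that("PCA components are orthonormal and ordered", {
  set.seed(50)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tr <- fit_pca(X)
  G <- t(tr$rotation) %*% tr$rotation
  expect_lt(max(abs(G - diag(2))), 1e-10)
  expect_gte(tr$explained_variance[1], tr$explained_variance[2])
  expect_gte(tr$explained_variance[2], 0)
})

test_that("PCA agrees with the covariance-eigendecomposition oracle", {
  set.seed(51)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tr <- fit_pca(X)
  Z <- scale(X)
  eig <- eigen(cov(Z), symmetric = TRUE)
  expect_equal(tr$explained_variance, eig$values[1:2], tolerance = 1e-9)
  for (j in 1:2) {
    v <- eig$vectors[, j]
    dotp <- abs(sum(v * tr$rotation[, j]))
    expect_equal(dotp, 1, tolerance = 1e-9)   # equal up to sign
  }
})

test_that("exactly planar data embeds isometrically with zero residual", {
  set.seed(52)
  T2 <- matrix(rnorm(40 * 2), 40, 2)
  W <- matrix(rnorm(10), 2, 5)
  X <- T2 %*% W
  colnames(X) <- paste0("f", 1:5)
  tr <- fit_pca(X)
  expect_lt(max(tr$all_variances[3:5]), 1e-18)
  emb <- project_pca(tr, X, phase = "train")
  Z <- scale(X)
  expect_equal(as.vector(dist(cbind(emb$pc1, emb$pc2))), as.vector(dist(Z)),
               tolerance = 1e-9)
})

test_that("the frozen transform projects by training statistics only", {
  set.seed(53)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  tr <- fit_pca(X)
  emb <- project_pca(tr, X, phase = "train")
  expect_lt(max(abs(c(mean(emb$pc1), mean(emb$pc2)))), 1e-9)
  # a clip exactly at the training mean lands at the origin
  mid <- matrix(tr$means, 1, dimnames = list(NULL, paste0("f", 1:4)))
  at0 <- project_pca(tr, mid)
  expect_lt(max(abs(c(at0$pc1, at0$pc2))), 1e-12)
  # identical rows project identically whatever the phase tag
  e1 <- project_pca(tr, X[7, , drop = FALSE], phase = "train")
  e2 <- project_pca(tr, X[7, , drop = FALSE], phase = "test")
  expect_identical(c(e1$pc1, e1$pc2), c(e2$pc1, e2$pc2))
  # projection does not mutate the transform
  tr2 <- fit_pca(X)
  invisible(project_pca(tr, matrix(rnorm(8), 2, 4)))
  expect_identical(tr[c("means", "scales", "rotation")],
                   tr2[c("means", "scales", "rotation")])
  expect_error(project_pca(tr, X[, 1:3]), "mismatch")
})

test_that("zero-variance features are rejected by name", {
  X <- cbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  expect_error(fit_pca(X), "zero-variance.*b")
})

test_that("PCA transforms survive a JSON round trip", {
  set.seed(54)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  tr <- fit_pca(X)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_json(tr, path)
  back <- read_pca_json(path)
  e1 <- project_pca(tr, X); e2 <- project_pca(back, X)
  expect_equal(e2$pc1, e1$pc1, tolerance = 1e-12)
  expect_equal(e2$pc2, e1$pc2, tolerance = 1e-12)
})

test_that("well-separated blobs are recovered exactly (ARI = 1)", {
  set.seed(55)
  P <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(60, 20, 1), 30, 2))  # 10 sigma apart and beyond
  truth <- rep(1:2, each = 30)
  for (link in c("ward", "average", "complete")) {
    cl <- agglomerate(P, k = 2, linkage = link, labels = truth)
    expect_equal(mclust::adjustedRandIndex(cl$assignments, truth), 1,
                 label = paste("ARI with", link))
    expect_equal(cl$purity, 1)
  }
})

test_that("average-linkage merges match the brute-force oracle at n = 6", {
  set.seed(56)
  for (rep in 1:5) {
    P <- matrix(runif(12), 6, 2)
    parts <- bf_average_partitions(P)
    cl <- agglomerate(P, k = 2, linkage = "average")
    for (k in 5:1) {
      oracle <- parts[[6 - k]]
      mine <- cutree(cl$tree, k = k)
      expect_true(same_partition(oracle, mine),
                  label = paste("partition at k =", k, "rep", rep))
    }
  }
})

test_that("purity is 1 for a clustering equal to the labels and bounded", {
  P <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2),
             matrix(rnorm(20, 10, 0.5), 10, 2))
  lab <- rep(c("x", "y"), each = 10)
  cl <- agglomerate(P, k = 2, labels = lab)
  expect_equal(cl$purity, 1)
  expect_error(agglomerate(P[1:2, ], k = 2), "more points")
})

test_that("hyperkinetic and tonic clips form separable clusters", {
  feats <- cohort_features_fixture()$temporal
  tr <- fit_pca(feature_matrix(feats))
  emb <- project_pca(tr, feature_matrix(feats), clip_id = feats$clip_id,
                     phase = "train", label = feats$label)
  cl <- agglomerate(emb, k = 2, linkage = "ward")
  expect_gte(cl$purity, 0.9)
})
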