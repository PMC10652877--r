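motion_tbl <- function(x, fps, clip_id = "clip", burnin = 0L) {
  out <- tibble::tibble(clip_id = clip_id, frame = seq_along(x),
                        time_s = (seq_along(x) - 1) / fps, motion = x,
                        burnin = seq_along(x) <= burnin)
  attr(out, "fps") <- fps
  out
}

test_that("delta series obeys its algebraic identities", {
  expect_equal(delta_series(rep(4, 50), fps = 10, lag_s = 1), rep(0, 40))
  # ramp with slope m at lag L: constant m*L, checked by direct loop
  m <- 0.37; L <- 12
  x <- m * seq_len(60)
  d <- delta_series(x, fps = 12, lag_s = 1)
  direct <- sapply(seq_len(60 - L), function(i) x[i + L] - x[i])
  expect_equal(d, direct)
  expect_equal(d, rep(m * L, 48), tolerance = 1e-12)
  expect_length(delta_series(rnorm(90), fps = 30, lag_s = 1), 60)
  expect_error(delta_series(rnorm(30), fps = 30, lag_s = 1), "at least 31")
})

test_that("delta series is linear: delta(a*x + b) = a*delta(x)", {
  x <- rnorm(80)
  a <- -2.5; b <- 3
  expect_equal(delta_series(a * x + b, fps = 20),
               a * delta_series(x, fps = 20), tolerance = 1e-12)
})

test_that("static featurization of a constant hold is the degenerate vector", {
  sig <- motion_tbl(rep(0, 120), fps = 20)
  expect_warning(fv <- featurize_clip(sig, mode = "static"), "constant")
  expect_equal(unname(as.numeric(fv[, catch22_names()])), rep(0, 22))
  expect_equal(fv$mode, "static")
})

test_that("temporal mode is exactly catch22 after the delta series", {
  x <- abs(rnorm(150, 0.1, 0.05))
  sig <- motion_tbl(x, fps = 25)
  fv <- featurize_clip(sig, mode = "temporal", lag_s = 1)
  direct <- catch22_features(delta_series(x, fps = 25, lag_s = 1))
  expect_identical(unname(as.numeric(fv[, catch22_names()])), unname(direct))
})

test_that("burn-in frames are excluded from featurization by default", {
  x <- c(rep(0.9, 40), abs(rnorm(100, 0.1, 0.02)))
  sig <- motion_tbl(x, fps = 20, burnin = 40L)
  fv <- featurize_clip(sig, mode = "static")
  direct <- catch22_features(x[-(1:40)])
  expect_identical(unname(as.numeric(fv[, catch22_names()])), unname(direct))
})

test_that("temporal features separate hyperkinetic from tonic cohorts", {
  feats <- cohort_features_fixture()$temporal
  X <- feats[, intersect(catch22_names(), names(feats))]
  lab <- feats$label
  sep <- vapply(X, function(col) {
    g1 <- col[lab == "hyperkinetic"]; g2 <- col[lab == "tonic"]
    sp <- sqrt((var(g1) + var(g2)) / 2)
    if (sp == 0) return(0)
    abs(mean(g1) - mean(g2)) / sp
  }, 1)
  expect_gt(max(sep), 1)
})

test_that("backward elimination removes an exact duplicate column first", {
  set.seed(41)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  X <- cbind(f1 = rnorm(n) + (lab == "a") * 3, f2 = rnorm(n), f3 = rnorm(n),
             f4 = rnorm(n), f5 = rnorm(n), f6 = rnorm(n))
  X <- cbind(X, f1dup = X[, "f1"])
  sel <- select_features(X, labels = lab, target_k = 5)
  expect_true(sel$trace$removed[1] %in% c("f1", "f1dup"))
  expect_length(sel$kept_names, 5)
  expect_equal(nrow(sel$trace), 2)
})

test_that("selection size, trace length and preconditions hold", {
  set.seed(42)
  X <- matrix(rnorm(40 * 9), 40, 9,
              dimnames = list(NULL, paste0("f", 1:9)))
  lab <- rep(c("a", "b"), each = 20)
  X[lab == "b", 1:2] <- X[lab == "b", 1:2] + 2
  sel <- select_features(X, labels = lab, target_k = 4)
  expect_length(sel$kept_names, 4)
  expect_equal(nrow(sel$trace), 5)
  expect_true(all(sel$kept_names %in% colnames(X)))
  expect_error(select_features(X, labels = lab, target_k = 9), "smaller")
  expect_error(select_features(X[1:8, ], labels = lab[1:8], target_k = 3),
               ">= 10 clips")
  expect_error(select_features(X, labels = rep("a", 40), target_k = 3),
               ">= 2 classes")
})

test_that("selection is deterministic run-to-run", {
  feats <- cohort_features_fixture()$temporal
  s1 <- select_features(feats, target_k = 5)
  s2 <- select_features(feats, target_k = 5)
  expect_identical(s1$kept_names, s2$kept_names)
  expect_identical(s1$trace, s2$trace)
})

test_that("feature tables and selections round-trip through disk", {
  feats <- cohort_features_fixture()$temporal
  fp <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(feats, fp)
  expect_equal(as.data.frame(read_features_csv(fp)), as.data.frame(feats),
               tolerance = 1e-12)
  sel <- select_features(feats, target_k = 5)
  sp <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, sp)
  back <- read_selection_json(sp)
  expect_identical(back$kept_names, sel$kept_names)
})
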