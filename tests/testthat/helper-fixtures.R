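# Shared fixtures: small, fast synthetic inputs built in code.

# Small default-shaped archetype clip (scaled-down frame for test speed).
fixture_clip <- function(label, seed, duration_s = 6, fps = 25,
                         frame_size = c(80, 100), noise_sigma = 2, ...) {
  generate_clip(archetype_params(label, duration_s = duration_s, fps = fps,
                                 frame_size = frame_size,
                                 noise_sigma = noise_sigma, seed = seed, ...))
}

# Ellipse body rendered over a flat background at explicit centre positions.
# Returns a seizure_clip with exact ground truth; noiseless by default.
render_path_clip <- function(centers, axes = c(8, 6), frame_size = c(48, 64),
                             fps = 25, bg = 60, body = 200, noise = 0,
                             clip_id = "path") {
  h <- frame_size[1]; w <- frame_size[2]; n <- nrow(centers)
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  frames <- array(0, dim = c(h, w, n))
  for (t in seq_len(n)) {
    d2 <- ((Y - centers[t, 1]) / axes[1])^2 + ((X - centers[t, 2]) / axes[2])^2
    img <- matrix(bg, h, w)
    img[d2 <= 1] <- body
    if (noise > 0) img <- img + rnorm(h * w, 0, noise)
    frames[, , t] <- img
  }
  seizure_clip(frames, fps, clip_id,
               truth = list(label = "hyperkinetic", center = centers,
                            axes = axes, params = NULL))
}

# Body that teleports to a fresh location every `hold` frames.
jump_centers <- function(n_jumps = 8, hold = 40, frame_size = c(48, 64),
                         margin = 12, seed = 7) {
  with_seed(seed, {
    pos <- cbind(runif(n_jumps, margin, frame_size[1] - margin),
                 runif(n_jumps, margin, frame_size[2] - margin))
    pos[rep(seq_len(n_jumps), each = hold), , drop = FALSE]
  })
}

# Body circling at constant speed (continuous motion fixture).
circle_centers <- function(n, frame_size = c(48, 64), radius = 12,
                           px_per_frame = 3) {
  cy <- frame_size[1] / 2; cx <- frame_size[2] / 2
  ang <- cumsum(rep(px_per_frame / radius, n))
  cbind(cy + radius * sin(ang), cx + radius * cos(ang))
}

# Per-frame motion masks straight from the mixture model (no filter chain).
raw_masks <- function(clip, ...) {
  n <- n_frames(clip)
  model <- bg_model(clip_frame(clip, 1), ...)
  masks <- vector("list", n)
  masks[[1]] <- matrix(0L, dim(clip$frames)[1], dim(clip$frames)[2])
  for (t in seq(2, n)) {
    up <- update_background(model, clip_frame(clip, t))
    model <- up$model
    masks[[t]] <- up$mask
  }
  masks
}

# Lazily-built shared fixtures (computed once per test run).
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small two-class cohort carried through signal extraction + featurization.
cohort_features_fixture <- function() {
  cached_fixture("cohort_features", {
    spec <- cohort_spec(
      patient_id = c("p1", "p2", "p3", "p4"),
      label = c("hyperkinetic", "hyperkinetic", "tonic", "tonic"),
      n_clips = c(4, 4, 4, 4))
    co <- generate_cohort(spec, seed = 303, duration_range = c(7, 9),
                          fps = 20, frame_size = c(64, 80))
    sigs <- dplyr::bind_rows(lapply(co$clips, function(cl) {
      extract_motion_signal(cl, learning_rate = 0.05)
    }))
    attr(sigs, "fps") <- 20
    feats_t <- suppressWarnings(
      featurize_cohort(sigs, co$manifest, mode = "temporal"))
    feats_s <- suppressWarnings(
      featurize_cohort(sigs, co$manifest, mode = "static"))
    list(manifest = co$manifest, signals = sigs,
         temporal = drop_constant_features(feats_t, quiet = TRUE),
         static = drop_constant_features(feats_s, quiet = TRUE))
  })
}

# Cheap content checksum for comparing clip stacks across runs.
digest_frames <- function(clip) {
  v <- as.integer(clip$frames)
  paste(length(v), sum(as.double(v)), sum(as.double(v) * seq_along(v) %% 97))
}

iou <- function(a, b) {
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) return(NA_real_)
  i / u
}

# Brute-force average-linkage oracle: merge the closest pair of clusters
# (mean pairwise distance) until one remains; record the partition after
# each merge.
bf_average_partitions <- function(P) {
  D <- as.matrix(dist(P))
  clusters <- as.list(seq_len(nrow(P)))
  parts <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    assign <- integer(nrow(P))
    for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
    parts[[length(parts) + 1]] <- assign
  }
  parts
}

same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}


# The scaled-down study cohort (majority classes 30+30 clips, 12 tonic-clonic
# across 12 patients, mirroring the clinical imbalance) carried through
# signal extraction and 10-repeat leave-one-seizure-out CV.
acceptance_cohort_cv <- function() {
  cached_fixture("acceptance_cv", {
    spec <- cohort_spec(
      patient_id = c(sprintf("h%02d", 1:5), sprintf("t%02d", 1:3),
                     sprintf("c%02d", 1:4)),
      label = c(rep("hyperkinetic", 5), rep("tonic", 3),
                rep("tonic_clonic", 4)),
      n_clips = c(rep(6, 5), c(10, 10, 10), rep(3, 4)))
    co <- generate_cohort(spec, seed = 4101, duration_range = c(12, 20),
                          fps = 25, frame_size = c(80, 100))
    sigs <- extract_cohort_signals(co$clips)
    cfg <- classifier_config(max_len = 24L, epochs = 2L, batch_size = 24L,
                             learning_rate = 3e-3, base_seed = 4200L)
    batch <- suppressWarnings(prepare_batch(sigs, co$manifest, cfg))
    cv <- suppressWarnings(repeated_cv(batch, cfg, n_repeats = 10L))
    list(manifest = co$manifest, signals = sigs, cv = cv)
  })
}
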