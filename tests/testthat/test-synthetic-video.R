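test_that("archetype parameter validation rejects impossible clips", {
  expect_error(archetype_params("tonic", tonic_fraction = 0), "tonic_fraction")
  expect_error(archetype_params("tonic_clonic", fps = 10, clonic_freq_hz = 3,
                                frame_size = c(80, 100)),
               "Nyquist")
  expect_error(archetype_params("hyperkinetic", frame_size = c(60, 80),
                                amplitude_px = 200),
               "leave the frame")
})

test_that("clip geometry honours duration, fps and pixel range", {
  p <- archetype_params("hyperkinetic", duration_s = 3.3, fps = 25,
                        frame_size = c(60, 80), seed = 1)
  clip <- generate_clip(p)
  expect_equal(n_frames(clip), round(3.3 * 25))
  f <- clip_frame(clip, 5)
  expect_true(all(f >= 0 & f <= 255))
  expect_equal(dim(f), c(60, 80))
  expect_equal(nrow(clip$truth$center), n_frames(clip))
})

test_that("noiseless zero-amplitude tonic clip is a static hold", {
  p <- archetype_params("tonic", duration_s = 4, fps = 20,
                        frame_size = c(60, 80), amplitude_px = 0,
                        drift_px_per_s = 0, noise_sigma = 0, seed = 3)
  clip <- generate_clip(p)
  ramp <- p$fps  # frames in the 1-s ramp
  for (t in seq(ramp + 2, n_frames(clip))) {
    expect_identical(clip$frames[, , t], clip$frames[, , t - 1])
  }
})

test_that("clonic-phase truth centre crosses its windowed mean 2f times/s", {
  f <- 3
  p <- archetype_params("tonic_clonic", duration_s = 20, fps = 30,
                        frame_size = c(120, 160), clonic_freq_hz = f,
                        tonic_fraction = 0.5, seed = 11)
  clip <- generate_clip(p)
  n <- n_frames(clip)
  clonic <- clip$truth$center[(floor(n / 2) + 1):n, ]
  # project displacement on its principal axis, then count per-window
  # mean-crossings by direct iteration
  sc <- prcomp(clonic)$x[, 1]
  fps <- p$fps
  crossings <- sapply(seq(1, length(sc) - fps + 1, by = fps), function(i) {
    w <- sc[i:(i + fps - 1)] - mean(sc[i:(i + fps - 1)])
    sum(diff(sign(w)) != 0)
  })
  expect_gt(mean(crossings), 2 * f - 1)
  expect_lt(mean(crossings), 2 * f + 1)
})

test_that("clip generation is bit-identical under a fixed seed", {
  p <- archetype_params("hyperkinetic", duration_s = 2, fps = 20,
                        frame_size = c(48, 64), seed = 42)
  c1 <- generate_clip(p); c2 <- generate_clip(p)
  expect_identical(c1$frames, c2$frames)
  expect_identical(c1$truth$center, c2$truth$center)
})

test_that("ground-truth displacement separates hyperkinetic from tonic", {
  disp <- function(clip) {
    d <- diff(clip$truth$center)
    mean(sqrt(rowSums(d^2)))
  }
  hk <- sapply(1:3, function(s) disp(fixture_clip("hyperkinetic", seed = s)))
  to <- sapply(1:3, function(s) disp(fixture_clip("tonic", seed = s)))
  expect_gt(mean(hk), mean(to))
})

test_that("cohort generation mirrors the requested class counts and splits", {
  spec <- clinical_cohort_spec("train")
  expect_equal(sum(spec$n_clips), 129)
  co <- generate_cohort(spec, seed = 5, duration_range = c(1, 2), fps = 16,
                        frame_size = c(24, 32), noise_sigma = 0)
  expect_equal(nrow(co$manifest), 129)
  expect_equal(as.integer(table(co$manifest$label)[c("hyperkinetic", "tonic",
                                                     "tonic_clonic")]),
               c(73L, 44L, 12L))
  expect_false(anyDuplicated(co$manifest$clip_id) > 0)

  one <- generate_cohort(cohort_spec("p1", "tonic", 1, split = "test"),
                         seed = 1, duration_range = c(1, 1), fps = 16,
                         frame_size = c(24, 32))
  expect_equal(nrow(one$manifest), 1)
  expect_equal(one$manifest$split, "test")
})

test_that("cohort generation is deterministic and validates its spec", {
  spec <- cohort_spec(c("a", "a", "b"),
                      c("hyperkinetic", "tonic_clonic", "tonic"),
                      c(2, 1, 2))
  g <- function() generate_cohort(spec, seed = 9, duration_range = c(1, 2),
                                  fps = 16, frame_size = c(24, 32))
  c1 <- g(); c2 <- g()
  expect_identical(c1$manifest, c2$manifest)
  sums <- function(co) vapply(co$clips, function(cl) digest_frames(cl), "")
  expect_identical(sums(c1), sums(c2))

  expect_error(generate_cohort(spec[0, ], seed = 1), "empty")
  expect_error(cohort_spec(c("a", "a"), c("tonic", "tonic"), c(1, 1),
                           split = c("train", "test")),
               "exactly one split")
  expect_error(cohort_spec("a", "absence", 1), "labels")
})

test_that("clips round-trip through the frame-stack archive", {
  clip <- fixture_clip("tonic_clonic", seed = 8, duration_s = 2,
                       frame_size = c(40, 56), fps = 16)
  dir <- withr::local_tempdir()
  path <- write_clip(clip, dir)
  back <- read_clip(path)
  expect_identical(back$frames, clip$frames)
  expect_equal(back$fps, clip$fps)
  expect_equal(back$truth$label, "tonic_clonic")
  expect_equal(back$truth$center, clip$truth$center, tolerance = 1e-8)
})
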