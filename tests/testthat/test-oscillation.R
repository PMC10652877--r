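# Brute-force oracle: count sign changes of the discrete velocity sequence
# of a 1-D path (zero steps carry no direction and are dropped).
sign_change_count <- function(x) {
  v <- diff(x)
  v <- v[v != 0]
  if (length(v) < 2) return(0L)
  sum(diff(sign(v)) != 0)
}

sin_path <- function(freq_hz, fps = 30, duration_s = 1, amp = 10, y0 = 5) {
  t <- seq(0, duration_s - 1 / fps, by = 1 / fps)
  cbind(x = amp * sin(2 * pi * freq_hz * t), y = y0)
}

test_that("reversal counting matches the forced hand examples", {
  expect_equal(count_reversals(cbind(x = c(0, 1, 0), y = c(0, 0, 0))), 1L)
  line <- cbind(x = seq(0, 29), y = seq(0, 29) * 0.5)
  expect_equal(count_reversals(line), 0L)
  expect_equal(count_reversals(sin_path(3)), 6L)
})

test_that("reversal window must be covered by the path", {
  p <- list(point_id = 1L, start_frame = 10L, positions = sin_path(2))
  expect_equal(count_reversals(p, window = c(10L, 39L)), 4L)
  expect_error(count_reversals(p, window = c(5L, 34L)), "not covered")
  expect_error(count_reversals(p, window = c(20L, 49L)), "not covered")
})

test_that("reversal counts equal the brute-force velocity-sign oracle", {
  for (f in c(1, 2, 3, 5)) {
    p <- sin_path(f)
    expect_equal(count_reversals(p), sign_change_count(p[, "x"]),
                 info = paste("freq", f))
  }
})

test_that("estimated frequency is accurate and monotone over {1,2,3,5} Hz", {
  est <- sapply(c(1, 2, 3, 5), function(f) count_reversals(sin_path(f)) / 2)
  expect_true(all(abs(est - c(1, 2, 3, 5)) <= 0.5))
  expect_true(all(diff(est) >= 0))
})

test_that("the 2.5 Hz filter flags exactly the 3 and 5 Hz paths", {
  flagged <- sapply(c(1, 2, 3, 5), function(f) count_reversals(sin_path(f)) / 2 >= 2.5)
  expect_equal(flagged, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("reversal counts are invariant to translation and scaling", {
  p <- sin_path(3, fps = 25)
  base <- count_reversals(p)
  expect_equal(count_reversals(sweep(p, 2, c(40, -17), "+")), base)
  expect_equal(count_reversals(p * 3.7), base)
  expect_equal(count_reversals(p * 0.2, min_step_px = 0.1), base)
})

test_that("uniform clips yield no paths", {
  frames <- array(77, dim = c(32, 40, 10))
  clip <- seizure_clip(frames, fps = 10, clip_id = "flat")
  expect_length(track_paths(clip), 0)
})

test_that("tracked paths follow the true body displacement", {
  # smooth 1.5 Hz horizontal sweep of a blob; compare per-frame x-steps of the
  # longest path with the ground-truth steps
  fps <- 25
  t <- seq(0, 3 - 1 / fps, by = 1 / fps)
  centers <- cbind(24 + 0 * t, 28 + 8 * sin(2 * pi * 1.5 * t))
  clip <- render_path_clip(centers, axes = c(9, 7), frame_size = c(48, 64),
                           fps = fps)
  paths <- track_paths(clip)
  expect_gt(length(paths), 0)
  len <- vapply(paths, function(p) nrow(p$positions), 1L)
  p <- paths[[which.max(len)]]
  span <- p$start_frame + seq_len(nrow(p$positions)) - 1L
  dx_true <- diff(centers[span, 2])
  dx_path <- diff(p$positions[, "x"])
  expect_gte(cor(dx_path, dx_true), 0.8)
})

test_that("seeded clips give identical path sets on repeat runs", {
  clip <- fixture_clip("tonic_clonic", seed = 14, duration_s = 3,
                       frame_size = c(60, 80), fps = 20)
  p1 <- track_paths(clip); p2 <- track_paths(clip)
  expect_identical(p1, p2)
})

test_that("oscillation windows separate tonic hold from clonic phase", {
  fps <- 20
  clip <- fixture_clip("tonic_clonic", seed = 5, duration_s = 8, fps = fps,
                       frame_size = c(80, 100), noise_sigma = 1)
  osc <- extract_oscillation_signal(clip)
  expect_true(all(osc$freq_hz >= 0))
  expect_true(all(osc$osc_fraction >= 0 & osc$osc_fraction <= 1))
  # tonic phase: windows fully inside the hold (after the 1-s ramp)
  tonic_w <- osc$window_end_s > 1 & osc$window_end_s <= 4
  clonic_w <- osc$window_end_s > 5
  expect_equal(sum(osc$osc_fraction[tonic_w]), 0)
  expect_gt(max(osc$osc_fraction[clonic_w]), 0)
  expect_lte(abs(median(osc$freq_hz[clonic_w]) - 3), 0.5)

  hold <- fixture_clip("tonic", seed = 6, duration_s = 4, fps = fps,
                       frame_size = c(80, 100), noise_sigma = 1)
  osc0 <- extract_oscillation_signal(hold)
  expect_true(all(osc0$freq_hz[osc0$window_end_s > 1.5] < 0.5))
  expect_equal(sum(osc0$osc_fraction[osc0$window_end_s > 1.5]), 0)
})

test_that("the ictal filter separates 2 Hz from 3 Hz clonic clips", {
  flag <- function(freq) {
    clip <- generate_clip(archetype_params(
      "tonic_clonic", duration_s = 6, fps = 20, frame_size = c(80, 100),
      clonic_freq_hz = freq, tonic_fraction = 1 / 3, noise_sigma = 1,
      seed = 77))
    osc <- extract_oscillation_signal(clip, threshold_hz = 2.5)
    any(osc$osc_fraction > 0.5)
  }
  expect_false(flag(2))
  expect_true(flag(3))
})
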