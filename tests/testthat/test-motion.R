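test_that("motion_value is the foreground proportion with binary guards", {
  m <- matrix(0L, 10, 10); m[1:13] <- 1L
  expect_equal(motion_value(m), 0.13)
  expect_equal(motion_value(matrix(0L, 4, 4)), 0)
  expect_equal(motion_value(matrix(1L, 4, 4)), 1)
  expect_error(motion_value(matrix(integer(0), 0, 0)), "empty")
  expect_error(motion_value(matrix(c(0, 2), 1, 2)), "binary")
})

test_that("a fresh model labels its first frame background; shapes guarded", {
  f <- matrix(50, 20, 30)
  model <- bg_model(f)
  expect_error(update_background(model, matrix(50, 30, 20)), "shape")
  up <- update_background(model, f)
  expect_true(all(up$mask == 0))
})

test_that("a static scene stays all-background after burn-in", {
  p <- archetype_params("tonic", duration_s = 3, fps = 20,
                        frame_size = c(40, 56), amplitude_px = 0,
                        drift_px_per_s = 0, noise_sigma = 0, seed = 2)
  sig <- extract_motion_signal(generate_clip(p))
  expect_true(all(sig$motion >= 0 & sig$motion <= 1))
  expect_equal(sum(sig$motion[!sig$burnin]), 0)
  expect_equal(sum(sig$motion), 0)  # noiseless static: zero everywhere
})

test_that("a block jumping into a static area is foreground on arrival", {
  h <- 30; w <- 40
  bg <- matrix(60, h, w)
  frames <- array(60, dim = c(h, w, 41))
  frames[5:14, 5:14, 1:30] <- 200            # block rests 30 frames
  frames[18:27, 25:34, 31:41] <- 200         # then jumps to a fresh area
  model <- bg_model(frames[, , 1])
  for (t in 2:30) {
    model <- update_background(model, frames[, , t])$model
  }
  up <- update_background(model, frames[, , 31])
  arrived <- matrix(FALSE, h, w); arrived[18:27, 25:34] <- TRUE
  expect_true(all(up$mask[arrived] == 1))
  vacated <- matrix(FALSE, h, w); vacated[5:14, 5:14] <- TRUE
  expect_true(all(up$mask[!arrived & !vacated] == 0))
})

test_that("foreground masks match ground-truth changed pixels at jumps", {
  hold <- 40
  centers <- jump_centers(n_jumps = 8, hold = hold)
  clip <- render_path_clip(centers)
  masks <- raw_masks(clip, learning_rate = 0.05)
  arrival <- seq(hold + 1, nrow(centers), by = hold)
  ious <- sapply(arrival, function(t) {
    iou(masks[[t]] == 1, truth_changed_mask(clip, t))
  })
  expect_gte(median(ious), 0.7)
})

test_that("median motion tracks the truth changed-pixel fraction", {
  # continuously circling body; fast-adaptation regime so the model's
  # foreground approximates the instantaneous changed-pixel set
  clip <- render_path_clip(circle_centers(120), clip_id = "circle")
  sig <- extract_motion_signal(clip, mask_filters = list(),
                               learning_rate = 0.5)
  truth_frac <- sapply(2:120, function(t) mean(truth_changed_mask(clip, t)))
  keep <- !sig$burnin
  med_m <- median(sig$motion[keep])
  med_t <- median(truth_frac[keep[-1]])
  expect_gt(med_m, 0.75 * med_t)
  expect_lt(med_m, 1.25 * med_t)
})

test_that("hyperkinetic clips carry more motion than tonic clips", {
  m <- function(label, s) {
    sig <- extract_motion_signal(fixture_clip(label, seed = s, duration_s = 5),
                                 learning_rate = 0.05)
    mean(sig$motion[!sig$burnin])
  }
  expect_gt(m("hyperkinetic", 21), m("tonic", 21))
  expect_gt(m("hyperkinetic", 22), m("tonic", 22))
})

test_that("mean motion is monotone in body area", {
  mk <- function(body) {
    p <- archetype_params("hyperkinetic", duration_s = 4, fps = 20,
                          frame_size = c(80, 100), body_size = body,
                          amplitude_px = 12, noise_sigma = 0, seed = 31)
    sig <- extract_motion_signal(generate_clip(p), learning_rate = 0.05)
    mean(sig$motion[!sig$burnin])
  }
  expect_gte(mk(c(34, 22)), mk(c(22, 14)))
})

test_that("motion signals round-trip through CSV", {
  sig <- extract_motion_signal(fixture_clip("tonic", seed = 4, duration_s = 3,
                                            frame_size = c(40, 56)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_motion_csv(sig, path)
  back <- read_motion_csv(path)
  expect_equal(back$motion, sig$motion)
  expect_equal(back$frame, sig$frame)
  expect_equal(attr(back, "fps"), attr(sig, "fps"))
})
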