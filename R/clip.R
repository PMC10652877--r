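#' Kinematic parameters for a synthetic seizure clip
#'
#' Bundles and validates the parameters of one synthetic clip of a single
#' moving body filmed by a static camera. Three kinematic archetypes are
#' supported, matching the motor semiology they emulate:
#'
#' * `hyperkinetic` — large-amplitude erratic motion: the body follows a
#'   mean-reverting (Ornstein-Uhlenbeck style) random-walk velocity so speed
#'   and direction change irregularly while the body stays in frame.
#' * `tonic` — sustained stiffening: a one-second ramp into a displaced
#'   posture, then a near-static hold with at most `drift_px_per_s` drift.
#' * `tonic_clonic` — tonic kinematics for the first `tonic_fraction` of the
#'   clip, then rhythmic (clonic) sinusoidal oscillation at `clonic_freq_hz`
#'   along a fixed axis with amplitude `amplitude_px`.
#'
#' Amplitude and body-size defaults are expressed for a 240x320 frame and
#' scale proportionally with frame height.
#'
#' @param label One of `"hyperkinetic"`, `"tonic"`, `"tonic_clonic"`.
#' @param duration_s Clip duration in seconds (> 0).
#' @param fps Frame rate in frames per second.
#' @param frame_size Integer `(height, width)` of the frame in pixels.
#' @param body_size `(height, width)` of the moving elliptical body in pixels.
#' @param amplitude_px Peak displacement of the body centre in pixels.
#' @param drift_px_per_s Slow postural drift speed (tonic hold phase).
#' @param clonic_freq_hz Oscillation frequency of the clonic phase in Hz.
#' @param tonic_fraction Fraction of the clip before clonic onset
#'   (`tonic_clonic` only), strictly between 0 and 1.
#' @param noise_sigma Standard deviation of i.i.d. per-pixel Gaussian sensor
#'   noise (8-bit intensity units).
#' @param seed Integer seed making the clip fully reproducible; `NULL` draws
#'   from the caller's RNG stream.
#' @return An `archetype_params` object (named list).
#' @export
#' @examples
#' p <- archetype_params("tonic", duration_s = 5, frame_size = c(60, 80))
#' clip <- generate_clip(p)
archetype_params <- function(label = c("hyperkinetic", "tonic", "tonic_clonic"),
                             duration_s = 30,
                             fps = 30,
                             frame_size = c(240L, 320L),
                             body_size = NULL,
                             amplitude_px = NULL,
                             drift_px_per_s = NULL,
                             clonic_freq_hz = 3,
                             tonic_fraction = 0.5,
                             noise_sigma = 2,
                             seed = NULL) {
  label <- match.arg(label)
  stopifnot(duration_s > 0, fps > 0, clonic_freq_hz >= 0,
            tonic_fraction > 0, tonic_fraction < 1, noise_sigma >= 0,
            length(frame_size) == 2, all(frame_size >= 16))
  frame_size <- as.integer(round(frame_size))
  sc <- frame_size[1] / 240                     # scale defaults with frame height
  if (is.null(body_size)) body_size <- round(c(80, 50) * sc)
  if (is.null(amplitude_px)) {
    amplitude_px <- switch(label,
      hyperkinetic = 45 * sc, tonic = 20 * sc, tonic_clonic = 12 * sc)
  }
  if (is.null(drift_px_per_s)) {
    drift_px_per_s <- switch(label, hyperkinetic = 0, tonic = 0.5 * sc,
                             tonic_clonic = 0.5 * sc)
  }
  stopifnot(all(body_size >= 2), amplitude_px >= 0, drift_px_per_s >= 0)
  if (label == "tonic_clonic" && fps < 4 * clonic_freq_hz) {
    stop("fps (", fps, ") must be at least 4 x clonic_freq_hz (",
         clonic_freq_hz, " Hz) to represent the clonic oscillation ",
         "(Nyquist-style sampling constraint)", call. = FALSE)
  }
  p <- structure(list(
    label = label, duration_s = duration_s, fps = fps,
    frame_size = frame_size, body_size = as.numeric(body_size),
    amplitude_px = amplitude_px, drift_px_per_s = drift_px_per_s,
    clonic_freq_hz = clonic_freq_hz, tonic_fraction = tonic_fraction,
    noise_sigma = noise_sigma, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "archetype_params")
  check_body_fits(p)
  p
}

# Reject parameter sets whose body could leave the frame.
check_body_fits <- function(p) {
  max_disp <- switch(p$label,
    hyperkinetic = p$amplitude_px,
    tonic        = p$amplitude_px + p$drift_px_per_s * p$duration_s,
    tonic_clonic = 2 * p$amplitude_px +
      p$drift_px_per_s * p$duration_s * p$tonic_fraction)
  half <- p$body_size / 2
  room <- p$frame_size / 2 - half - 2          # 2 px margin
  if (any(room < max_disp)) {
    stop("body would leave the frame: displacement bound ", round(max_disp, 1),
         " px exceeds available room (", paste(round(room, 1), collapse = ", "),
         ") px; shrink amplitude/body or enlarge the frame", call. = FALSE)
  }
  invisible(p)
}

# Ground-truth body-centre trajectory, one (y, x) row per frame.
archetype_centers <- function(p, n_frames) {
  rest <- (p$frame_size + 1) / 2
  t_s <- (seq_len(n_frames) - 1) / p$fps
  off <- switch(p$label,
    hyperkinetic = ou_offsets(n_frames, 1 / p$fps, p$amplitude_px),
    tonic        = tonic_offsets(t_s, p),
    tonic_clonic = {
      o <- tonic_offsets(t_s, p)
      k0 <- floor(p$tonic_fraction * n_frames) + 1    # first clonic frame index
      if (k0 <= n_frames) {
        axis <- runif(1, 0, 2 * pi)
        u <- c(sin(axis), cos(axis))
        ph <- 2 * pi * p$clonic_freq_hz * (t_s[k0:n_frames] - t_s[k0])
        o[k0:n_frames, ] <- rep(o[k0, ], each = n_frames - k0 + 1) +
          outer(p$amplitude_px * sin(ph), u)
      }
      o
    })
  sweep(off, 2, rest, "+")
}

# Mean-reverting random-walk velocity; displacement clamped to the amplitude box.
ou_offsets <- function(n, dt, amplitude) {
  if (amplitude == 0) return(matrix(0, n, 2))
  theta <- 3; kappa <- 4
  sigma <- amplitude * 2.5
  eps <- matrix(rnorm(2 * n), n, 2)
  x <- v <- matrix(0, n, 2)
  for (t in seq_len(n - 1)) {
    v[t + 1, ] <- v[t, ] * (1 - theta * dt) - kappa * dt * x[t, ] +
      sigma * sqrt(dt) * eps[t, ]
    x[t + 1, ] <- pmin(pmax(x[t, ] + v[t + 1, ] * dt, -amplitude), amplitude)
  }
  x
}

# One-second half-cosine ramp into a displaced posture, then hold + slow drift.
tonic_offsets <- function(t_s, p) {
  phi <- runif(1, 0, 2 * pi)
  psi <- runif(1, 0, 2 * pi)
  ramp <- p$amplitude_px * 0.5 * (1 - cos(pi * pmin(t_s, 1)))
  cbind(ramp * sin(phi) + p$drift_px_per_s * t_s * sin(psi),
        ramp * cos(phi) + p$drift_px_per_s * t_s * cos(psi))
}

#' Generate one synthetic seizure clip
#'
#' Renders the archetype kinematics of [archetype_params()] into an 8-bit
#' grayscale frame sequence: a graded-intensity ellipse (the body) over a
#' static textured background, plus optional per-pixel Gaussian sensor noise.
#' Ground truth (per-frame body centre, body axes, label) is stored alongside
#' the pixels so downstream signal extractors can be validated against it.
#'
#' @param params An [archetype_params()] object.
#' @param clip_id Identifier for the clip; defaults to a label/seed-derived id.
#' @return A `seizure_clip`: list with `frames` (raw array height x width x n),
#'   `fps`, `clip_id` and `truth` (label, `center` n x 2 matrix of (y, x),
#'   `axes` semi-axes, `params`).
#' @export
generate_clip <- function(params, clip_id = NULL) {
  stopifnot(inherits(params, "archetype_params"))
  p <- params
  n <- round(p$duration_s * p$fps)
  stopifnot(n >= 1)
  h <- p$frame_size[1]; w <- p$frame_size[2]
  if (is.null(clip_id)) {
    clip_id <- paste0(p$label, "-", p$seed %||% sample.int(1e6, 1))
  }
  with_seed(p$seed, {
    centers <- archetype_centers(p, n)
    bg <- 60 + 12 * outer(sin(2 * pi * seq_len(h) / 29),
                          cos(2 * pi * seq_len(w) / 41)) +
      matrix(rnorm(h * w, 0, 6), h, w)
    bg <- pmin(pmax(bg, 10), 245)
    Y <- matrix(seq_len(h), h, w)
    X <- matrix(seq_len(w), h, w, byrow = TRUE)
    ay <- p$body_size[1] / 2; ax <- p$body_size[2] / 2
    frames <- array(as.raw(0), dim = c(h, w, n))
    for (t in seq_len(n)) {
      d2 <- ((Y - centers[t, 1]) / ay)^2 + ((X - centers[t, 2]) / ax)^2
      img <- bg
      inside <- d2 <= 1
      img[inside] <- 225 - 95 * d2[inside]
      if (p$noise_sigma > 0) img <- img + rnorm(h * w, 0, p$noise_sigma)
      frames[, , t] <- as.raw(pmin(pmax(round(img), 0), 255))
    }
    structure(list(
      frames = frames, fps = p$fps, clip_id = clip_id,
      truth = list(label = p$label, center = centers, axes = c(ay, ax),
                   params = p)),
      class = "seizure_clip")
  })
}

#' Construct a clip from an existing frame stack
#'
#' Low-level constructor for frame sequences coming from somewhere other than
#' the synthetic generator (e.g. decoded video). Pixel values are clamped to
#' 0..255 and stored as 8-bit.
#'
#' @param frames Numeric or raw array `height x width x n_frames`.
#' @param fps Frame rate in frames per second.
#' @param clip_id Clip identifier.
#' @param truth Optional ground-truth list (`label`, `center`, `axes`).
#' @return A `seizure_clip`.
#' @export
seizure_clip <- function(frames, fps, clip_id, truth = NULL) {
  stopifnot(length(dim(frames)) == 3, fps > 0)
  if (!is.raw(frames)) {
    d <- dim(frames)
    frames <- array(as.raw(pmin(pmax(round(frames), 0), 255)), dim = d)
  }
  structure(list(frames = frames, fps = fps, clip_id = as.character(clip_id),
                 truth = truth),
            class = "seizure_clip")
}

#' @export
print.seizure_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat("<seizure_clip> ", x$clip_id, ": ", d[3], " frames ", d[1], "x", d[2],
      " @ ", x$fps, " fps",
      if (!is.null(x$truth)) paste0(" [", x$truth$label, "]"), "\n", sep = "")
  invisible(x)
}

#' Number of frames in a clip
#' @param clip A `seizure_clip`.
#' @export
n_frames <- function(clip) dim(clip$frames)[3]

#' Extract one frame as a numeric matrix (0..255)
#' @param clip A `seizure_clip`.
#' @param t Frame index (1-based).
#' @export
clip_frame <- function(clip, t) {
  d <- dim(clip$frames)
  stopifnot(t >= 1, t <= d[3])
  matrix(as.integer(clip$frames[, , t]), d[1], d[2])
}

#' Ground-truth body mask for one frame
#'
#' Recomputed from the stored centre trajectory and body axes (masks are not
#' materialised per frame to keep long clips small in memory).
#' @inheritParams clip_frame
#' @return Logical matrix, `TRUE` inside the body.
#' @export
truth_mask <- function(clip, t) {
  tr <- clip$truth
  stopifnot(!is.null(tr))
  h <- dim(clip$frames)[1]; w <- dim(clip$frames)[2]
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((Y - tr$center[t, 1]) / tr$axes[1])^2 +
    ((X - tr$center[t, 2]) / tr$axes[2])^2 <= 1
}

#' Ground-truth changed-pixel mask between consecutive frames
#'
#' Symmetric difference of the body masks at `t - 1` and `t`; the reference
#' against which foreground masks from background subtraction are scored.
#' @inheritParams clip_frame
#' @export
truth_changed_mask <- function(clip, t) {
  stopifnot(t >= 2)
  xor(truth_mask(clip, t - 1), truth_mask(clip, t))
}

#' Write / read a clip as a lossless frame-stack archive
#'
#' Frames are stored as an uncompressed multi-page 8-bit grayscale TIFF with a
#' JSON sidecar holding frame rate and ground truth.
#'
#' @param clip A `seizure_clip`.
#' @param dir Output directory (created if missing).
#' @return `write_clip()` returns the TIFF path invisibly; `read_clip()`
#'   returns a `seizure_clip`.
#' @export
write_clip <- function(clip, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(clip$frames)
  pages <- lapply(seq_len(d[3]), function(t) clip_frame(clip, t) / 255)
  tif <- file.path(dir, paste0(clip$clip_id, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 8, compression = "none")
  meta <- list(clip_id = clip$clip_id, fps = clip$fps,
               label = clip$truth$label,
               center = clip$truth$center, axes = clip$truth$axes)
  jsonlite::write_json(meta, file.path(dir, paste0(clip$clip_id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' @rdname write_clip
#' @param path Path to a `.tif` written by `write_clip()` (its `.json` sidecar
#'   is read from the same stem when present).
#' @export
read_clip <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(as.raw(0), dim = c(h, w, length(pages)))
  for (t in seq_along(pages)) {
    frames[, , t] <- as.raw(round(pages[[t]] * 255))
  }
  side <- sub("\\.tif$", ".json", path)
  truth <- NULL; fps <- 30; clip_id <- sub("\\.tif$", "", basename(path))
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fps <- meta$fps; clip_id <- meta$clip_id
    truth <- list(label = meta$label,
                  center = matrix(unlist(meta$center), ncol = 2),
                  axes = as.numeric(meta$axes), params = NULL)
  }
  structure(list(frames = frames, fps = fps, clip_id = clip_id, truth = truth),
            class = "seizure_clip")
}
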