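#' Adaptive Gaussian-mixture background model
#'
#' Per-pixel mixture of up to `K` Gaussians over grayscale intensity,
#' maintained online in the style of adaptive background-subtraction models:
#' each pixel keeps `(weight, mean, variance)` per component, weights decay at
#' `learning_rate` and the matched component is pulled towards the incoming
#' intensity with an ownership-scaled rate. A pixel is labelled foreground
#' when no *background-weighted* component (weight at least `bg_weight`)
#' matches the incoming intensity within `variance_threshold` (a squared
#' Mahalanobis cutoff, 16 being roughly a 4-sigma gate).
#'
#' @param frame Numeric matrix (grayscale, 0..255) used to initialise the
#'   model: component 1 is set to the frame with weight 1, so a fresh model
#'   labels its first frame all-background.
#' @param K Maximum number of mixture components per pixel.
#' @param learning_rate Per-frame learning rate alpha.
#' @param variance_threshold Squared-Mahalanobis match cutoff.
#' @param var_min,var_init,var_max Variance floor, initial variance for newly
#'   spawned components, and variance cap.
#' @param bg_weight Minimum component weight to count as background evidence.
#' @return A `bg_model` object.
#' @export
bg_model <- function(frame, K = 3L, learning_rate = 0.01,
                     variance_threshold = 16, var_min = 4,
                     var_init = 100, var_max = 400, bg_weight = 0.2) {
  stopifnot(is.matrix(frame), K >= 1, learning_rate > 0, learning_rate <= 1,
            variance_threshold > 0, var_min > 0)
  npix <- length(frame)
  w <- matrix(0, npix, K); w[, 1] <- 1
  mu <- matrix(0, npix, K); mu[, 1] <- as.vector(frame)
  s2 <- matrix(var_init, npix, K)
  structure(list(w = w, mu = mu, s2 = s2, dim = dim(frame), K = K,
                 alpha = learning_rate, thr = variance_threshold,
                 var_min = var_min, var_init = var_init, var_max = var_max,
                 bg_weight = bg_weight, n_seen = 1L),
            class = "bg_model")
}

#' Online background update and foreground mask
#'
#' Performs one online update of the mixture with the incoming frame and
#' returns the binary foreground mask decided *against the pre-update model*
#' (so a change is flagged on its arrival frame).
#'
#' @param model A [bg_model()].
#' @param frame Numeric matrix matching the model's frame shape.
#' @return List with `model` (updated) and `mask` (integer 0/1 matrix).
#' @export
update_background <- function(model, frame) {
  stopifnot(inherits(model, "bg_model"))
  if (!identical(dim(frame), model$dim)) {
    stop("frame shape ", paste(dim(frame), collapse = "x"),
         " does not match model shape ", paste(model$dim, collapse = "x"),
         call. = FALSE)
  }
  x <- as.vector(frame)
  w <- model$w; mu <- model$mu; s2 <- model$s2
  npix <- length(x); K <- model$K
  d <- mu - x
  m2 <- d * d / s2
  active <- w > 0
  # foreground decision: no background-weighted component matches
  fg <- rowSums((m2 < model$thr) & (w >= model$bg_weight)) == 0
  # best-matching active component per pixel
  penal <- m2 + ifelse(active, 0, Inf)
  best <- max.col(-penal, ties.method = "first")
  ib <- cbind(seq_len(npix), best)
  matched <- penal[ib] < model$thr
  # weight decay + ownership bump for the matched component
  w <- (1 - model$alpha) * w
  w[ib[matched, , drop = FALSE]] <- w[ib[matched, , drop = FALSE]] + model$alpha
  # matched component pulled towards x
  rho <- pmin(model$alpha / pmax(w[ib], model$alpha), 1)
  dm <- x - mu[ib]
  mu[ib[matched, , drop = FALSE]] <- mu[ib][matched] + (rho * dm)[matched]
  s2new <- s2[ib] + rho * (dm * dm - s2[ib])
  s2[ib[matched, , drop = FALSE]] <-
    pmin(pmax(s2new[matched], model$var_min), model$var_max)
  # unmatched pixels: replace the weakest component with a fresh one
  if (any(!matched)) {
    weakest <- max.col(-w, ties.method = "first")
    iw <- cbind(which(!matched), weakest[!matched])
    w[iw] <- model$alpha
    mu[iw] <- x[!matched]
    s2[iw] <- model$var_init
  }
  w <- w / rowSums(w)
  model$w <- w; model$mu <- mu; model$s2 <- s2
  model$n_seen <- model$n_seen + 1L
  mask <- matrix(as.integer(fg), model$dim[1], model$dim[2])
  list(model = model, mask = mask)
}

#' Proportion of moving pixels in a binary mask
#'
#' The per-frame sample of the one-dimensional motion signal: the number of
#' foreground pixels divided by the number of pixels.
#'
#' @param mask Binary (0/1 or logical) matrix.
#' @return A proportion in `[0, 1]`.
#' @export
motion_value <- function(mask) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  mean(v)
}

#' Morphological-opening mask filter
#'
#' Default element of the mask-filter chain: a 3x3 box opening that removes
#' isolated single-pixel responses. The filter chain is the pluggable slot
#' where a depth/disparity-based mask pruner would sit on stereo hardware.
#'
#' @param size Box kernel size in pixels (odd).
#' @return A function mapping a binary mask matrix to a binary mask matrix.
#' @export
mask_open <- function(size = 3L) {
  brush <- EBImage::makeBrush(size, shape = "box")
  function(mask) {
    out <- EBImage::opening(mask, brush)
    matrix(as.integer(out > 0.5), nrow(mask), ncol(mask))
  }
}

#' Extract the motion signal from a clip
#'
#' Runs background subtraction over the clip and reduces each foreground mask
#' (after the mask-filter chain) to the proportion of moving pixels. The first
#' `ceiling(2 / learning_rate)` frames are flagged as burn-in: they are kept
#' in the signal but excluded from featurization by default.
#'
#' @param clip A `seizure_clip`.
#' @param mask_filters List of binary-mask transforms applied in order; the
#'   default is a single 3x3 morphological opening. Use `list()` to disable.
#' @param ... Passed to [bg_model()] (e.g. `learning_rate`, `K`).
#' @return A tibble with columns `clip_id`, `frame`, `time_s`, `motion`,
#'   `burnin`; attribute `fps` carries the frame rate.
#' @export
extract_motion_signal <- function(clip, mask_filters = list(mask_open(3L)),
                                  ...) {
  stopifnot(inherits(clip, "seizure_clip"), n_frames(clip) >= 1)
  n <- n_frames(clip)
  model <- bg_model(clip_frame(clip, 1), ...)
  burn <- as.integer(ceiling(2 / model$alpha))
  motion <- numeric(n)
  motion[1] <- 0   # fresh model: first frame is all background by convention
  if (n >= 2) {
    for (t in 2:n) {
      up <- update_background(model, clip_frame(clip, t))
      model <- up$model
      mask <- up$mask
      for (f in mask_filters) mask <- f(mask)
      motion[t] <- motion_value(mask)
    }
  }
  out <- tibble::tibble(
    clip_id = clip$clip_id,
    frame = seq_len(n),
    time_s = (seq_len(n) - 1) / clip$fps,
    motion = motion,
    burnin = seq_len(n) <= burn)
  attr(out, "fps") <- clip$fps
  out
}

#' Write / read motion signals as CSV
#'
#' Column layout: `clip_id,t_frame,time_s,motion` (plus `burnin`).
#' @param signal Tibble from [extract_motion_signal()] (rows of several clips
#'   may be bound together).
#' @param path Output CSV path.
#' @export
write_motion_csv <- function(signal, path) {
  out <- data.frame(clip_id = signal$clip_id, t_frame = signal$frame,
                    time_s = signal$time_s, motion = signal$motion,
                    burnin = signal$burnin)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @param fps Frame rate to attach to the tibble read back.
#' @export
read_motion_csv <- function(path, fps = NULL) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(clip_id = m$clip_id, frame = m$t_frame,
                        time_s = m$time_s, motion = m$motion,
                        burnin = as.logical(m$burnin))
  if (is.null(fps) && nrow(out) > 1) {
    dt <- diff(out$time_s[out$clip_id == out$clip_id[1]])
    fps <- 1 / stats::median(dt)
  }
  attr(out, "fps") <- fps
  out
}
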