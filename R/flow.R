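# Sparse optical-flow path tracking and direction-reversal oscillation
# detection. Paths are histories of trackable corner points; rhythmic (clonic)
# movement shows up as repeated >90-degree direction reversals, two per cycle.

# --- image helpers -----------------------------------------------------------

grad_x <- function(I) {
  n <- ncol(I)
  (I[, c(2:n, n)] - I[, c(1, 1:(n - 1))]) / 2
}
grad_y <- function(I) {
  n <- nrow(I)
  (I[c(2:n, n), ] - I[c(1, 1:(n - 1)), ]) / 2
}

downsample2 <- function(I) {
  h <- nrow(I) %/% 2; w <- ncol(I) %/% 2
  I <- I[seq_len(2 * h), seq_len(2 * w)]
  (I[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] + I[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
   I[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] + I[seq(2, 2 * h, 2), seq(2, 2 * w, 2)]) / 4
}

build_pyramid <- function(I, levels = 3L) {
  out <- vector("list", levels)
  for (l in seq_len(levels)) {
    out[[l]] <- list(I = I, gx = grad_x(I), gy = grad_y(I))
    if (l < levels) I <- downsample2(I)
  }
  out
}

# Bilinear sample of image `I` at (y + dy, x + dx) window offsets.
bilinear <- function(I, ys, xs) {
  h <- nrow(I); w <- ncol(I)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  y0 <- pmin(pmax(y0, 1), h - 1); x0 <- pmin(pmax(x0, 1), w - 1)
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  I[i00] * (1 - fy) * (1 - fx) + I[i10] * fy * (1 - fx) +
    I[i01] * (1 - fy) * fx + I[i11] * fy * fx
}

# --- corner detection --------------------------------------------------------

#' Detect trackable corner features (minimum-eigenvalue criterion)
#'
#' Shi-Tomasi style corner detector: the smaller eigenvalue of the locally
#' summed structure tensor, thresholded at `quality` times its maximum, with
#' greedy minimum-distance suppression.
#'
#' @param frame Numeric grayscale matrix.
#' @param max_points Maximum number of corners returned.
#' @param quality Relative quality threshold in (0, 1].
#' @param min_distance Minimum pixel distance between returned corners.
#' @return Matrix with columns `x`, `y` (pixel coordinates, x = column).
#' @export
detect_corners <- function(frame, max_points = 25L, quality = 0.1,
                           min_distance = 5) {
  gx <- grad_x(frame); gy <- grad_y(frame)
  box <- EBImage::makeBrush(5, "box")
  sxx <- EBImage::filter2(gx * gx, box)
  syy <- EBImage::filter2(gy * gy, box)
  sxy <- EBImage::filter2(gx * gy, box)
  tr <- sxx + syy
  det4 <- (sxx - syy)^2 + 4 * sxy^2
  lmin <- (tr - sqrt(pmax(det4, 0))) / 2
  # ignore a border where windows would leave the frame
  b <- 6L
  lmin[c(seq_len(b), nrow(lmin) - seq_len(b) + 1), ] <- 0
  lmin[, c(seq_len(b), ncol(lmin) - seq_len(b) + 1)] <- 0
  mx <- max(lmin)
  if (mx <= 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  cand <- which(lmin >= quality * mx, arr.ind = TRUE)
  ord <- order(lmin[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) == 0 ||
        min((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2) >= min_distance^2) {
      keep <- rbind(keep, p)
      if (nrow(keep) >= max_points) break
    }
  }
  out <- cbind(x = keep[, 2], y = keep[, 1])
  rownames(out) <- NULL
  out
}

# --- pyramidal Lucas-Kanade --------------------------------------------------

# Track one point from pyramid `pa` to pyramid `pb`.
# Returns c(x, y) of the new position or NULL when tracking fails.
lk_track_point <- function(pa, pb, x, y, half = 4L, max_iter = 5L,
                           max_residual = 25) {
  levels <- length(pa)
  off <- as.vector(outer(rep(1, 2 * half + 1), -half:half))  # x offsets grid
  offy <- as.vector(outer(-half:half, rep(1, 2 * half + 1)))
  v <- c(0, 0)
  for (l in levels:1) {
    s <- 2^(l - 1)
    px <- x / s; py <- y / s
    I <- pa[[l]]$I
    h <- nrow(I); w <- ncol(I)
    if (px - half < 1 || px + half > w || py - half < 1 || py + half > h) {
      if (l > 1) { v <- v * 2; next } else return(NULL)
    }
    tw <- bilinear(I, py + offy, px + off)
    gxw <- bilinear(pa[[l]]$gx, py + offy, px + off)
    gyw <- bilinear(pa[[l]]$gy, py + offy, px + off)
    G <- matrix(c(sum(gxw^2), sum(gxw * gyw), sum(gxw * gyw), sum(gyw^2)), 2)
    if (abs(det(G)) < 1e-6) {
      if (l > 1) { v <- v * 2; next } else return(NULL)
    }
    J <- pb[[l]]$I
    for (it in seq_len(max_iter)) {
      qx <- px + v[1]; qy <- py + v[2]
      if (qx - half < 1 || qx + half > w || qy - half < 1 || qy + half > h) {
        return(NULL)
      }
      jw <- bilinear(J, qy + offy, qx + off)
      it_err <- jw - tw
      bvec <- -c(sum(gxw * it_err), sum(gyw * it_err))
      dv <- solve(G, bvec)
      v <- v + dv
      if (sum(dv^2) < 1e-4) break
    }
    if (l > 1) v <- v * 2
  }
  qx <- x + v[1]; qy <- y + v[2]
  I1 <- pb[[1]]$I
  if (qx - half < 1 || qx + half > ncol(I1) || qy - half < 1 ||
      qy + half > nrow(I1)) {
    return(NULL)
  }
  res <- mean(abs(bilinear(I1, qy + offy, qx + off) -
                  bilinear(pa[[1]]$I, y + offy, x + off)))
  if (res > max_residual) return(NULL)
  c(qx, qy)
}

#' Track sparse feature paths through a clip
#'
#' Detects corner features and follows each frame-to-frame with pyramidal
#' Lucas-Kanade refinement, building a path history. A path ends the moment
#' tracking fails (no interpolation across gaps); new features are detected
#' whenever the active set runs low. Untrackable clips (uniform frames) yield
#' an empty list.
#'
#' @param clip A `seizure_clip`.
#' @param max_points Target number of simultaneously tracked points.
#' @param quality,min_distance Corner-detection parameters, see
#'   [detect_corners()].
#' @param levels Pyramid levels.
#' @return List of paths; each path is a list with `point_id`, `start_frame`
#'   and `positions` (matrix with columns `x`, `y`, one row per consecutive
#'   frame).
#' @export
track_paths <- function(clip, max_points = 25L, quality = 0.1,
                        min_distance = 5, levels = 3L) {
  stopifnot(inherits(clip, "seizure_clip"), n_frames(clip) >= 2)
  n <- n_frames(clip)
  pyr <- build_pyramid(clip_frame(clip, 1), levels)
  active <- list()   # each: list(point_id, start_frame, positions)
  done <- list()
  next_id <- 1L
  spawn <- function(frame_mat, t, active) {
    pts <- detect_corners(frame_mat, max_points = max_points,
                          quality = quality, min_distance = min_distance)
    if (nrow(pts) == 0) return(active)
    cur <- do.call(rbind, lapply(active, function(p) p$positions[nrow(p$positions), ]))
    for (i in seq_len(nrow(pts))) {
      if (length(active) >= max_points) break
      if (!is.null(cur) && nrow(cur) > 0 &&
          min((cur[, 1] - pts[i, 1])^2 + (cur[, 2] - pts[i, 2])^2) < min_distance^2) {
        next
      }
      active[[length(active) + 1]] <- list(
        point_id = next_id, start_frame = t,
        positions = matrix(pts[i, ], 1, 2, dimnames = list(NULL, c("x", "y"))))
      next_id <<- next_id + 1L
      cur <- rbind(cur, pts[i, ])
    }
    active
  }
  active <- spawn(clip_frame(clip, 1), 1L, active)
  for (t in 2:n) {
    pyr_next <- build_pyramid(clip_frame(clip, t), levels)
    still <- list()
    for (p in active) {
      last <- p$positions[nrow(p$positions), ]
      q <- lk_track_point(pyr, pyr_next, last[1], last[2])
      if (is.null(q)) {
        if (nrow(p$positions) >= 2) done[[length(done) + 1]] <- p
      } else {
        p$positions <- rbind(p$positions, q)
        still[[length(still) + 1]] <- p
      }
    }
    active <- still
    if (length(active) < max_points / 2) {
      active <- spawn(clip_frame(clip, t), t, active)
    }
    pyr <- pyr_next
  }
  for (p in active) if (nrow(p$positions) >= 2) done[[length(done) + 1]] <- p
  done[order(vapply(done, function(p) p$point_id, 1L))]
}

# --- reversal rule -----------------------------------------------------------

#' Count direction reversals along a tracked path
#'
#' A reversal is each change of movement direction of more than 90 degrees
#' between successive displacement vectors. Steps shorter than `min_step_px`
#' are treated as tracker jitter and skipped; direction is compared between
#' the retained steps in order.
#'
#' @param path A path from [track_paths()] (list with `positions`,
#'   `start_frame`), or a bare two-column position matrix.
#' @param window Integer `c(first, last)` frame indices (inclusive) the count
#'   applies to; the path must cover the window without gaps. Defaults to the
#'   whole path.
#' @param min_step_px Minimum displacement magnitude for a step to carry
#'   direction information.
#' @return Integer reversal count.
#' @export
count_reversals <- function(path, window = NULL, min_step_px = 0.5) {
  pos <- if (is.matrix(path)) path else path$positions
  start <- if (is.matrix(path)) 1L else path$start_frame
  stopifnot(nrow(pos) >= 2)
  if (!is.null(window)) {
    i1 <- window[1] - start + 1L
    i2 <- window[2] - start + 1L
    if (i1 < 1 || i2 > nrow(pos)) {
      stop("window [", window[1], ", ", window[2],
           "] not covered by path (unbroken span required)", call. = FALSE)
    }
    pos <- pos[i1:i2, , drop = FALSE]
  }
  d <- diff(pos)
  mag <- sqrt(rowSums(d^2))
  d <- d[mag >= min_step_px, , drop = FALSE]
  if (nrow(d) < 2) return(0L)
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  sum(dots < 0)
}

#' Extract the oscillation signal from a clip
#'
#' Splits the clip into non-overlapping 1-second windows. In each window only
#' paths unbroken across the whole window qualify; each contributes an
#' oscillation frequency of `reversals / 2` Hz (one cycle contains two
#' direction reversals). The window frequency is the median across qualifying
#' paths and `osc_fraction` is the fraction of qualifying paths at or above
#' `threshold_hz` — 2.5 Hz being the conventional filter separating ictal
#' (clonic) oscillation from slower paroxysmal movement.
#'
#' @param clip A `seizure_clip` of at least one second.
#' @param threshold_hz Ictal-oscillation filter frequency (Hz).
#' @param min_step_px See [count_reversals()].
#' @param paths Optional precomputed result of [track_paths()].
#' @param ... Passed to [track_paths()].
#' @return Tibble with `clip_id`, `window_end_s`, `freq_hz`, `osc_fraction`,
#'   `n_paths`; attribute `threshold_hz`.
#' @export
extract_oscillation_signal <- function(clip, threshold_hz = 2.5,
                                       min_step_px = 0.5, paths = NULL, ...) {
  fps <- as.integer(round(clip$fps))
  n <- n_frames(clip)
  stopifnot(n >= fps)
  if (is.null(paths)) paths <- track_paths(clip, ...)
  n_win <- n %/% fps
  starts <- (seq_len(n_win) - 1L) * fps + 1L
  rows <- lapply(seq_len(n_win), function(wi) {
    w <- c(starts[wi], starts[wi] + fps - 1L)
    freqs <- numeric(0)
    for (p in paths) {
      pend <- p$start_frame + nrow(p$positions) - 1L
      if (p$start_frame <= w[1] && pend >= w[2]) {
        freqs <- c(freqs, count_reversals(p, w, min_step_px) / 2)
      }
    }
    tibble::tibble(
      clip_id = clip$clip_id,
      window_end_s = w[2] / clip$fps,
      freq_hz = if (length(freqs)) median(freqs) else 0,
      osc_fraction = if (length(freqs)) mean(freqs >= threshold_hz) else 0,
      n_paths = length(freqs))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold_hz") <- threshold_hz
  out
}

#' Write / read oscillation signals as CSV
#'
#' Column layout: `clip_id,window_end_s,freq_hz,osc_fraction`.
#' @param signal Tibble from [extract_oscillation_signal()].
#' @param path Output CSV path.
#' @export
write_oscillation_csv <- function(signal, path) {
  utils::write.csv(
    data.frame(clip_id = signal$clip_id, window_end_s = signal$window_end_s,
               freq_hz = signal$freq_hz, osc_fraction = signal$osc_fraction),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oscillation_csv
#' @export
read_oscillation_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
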