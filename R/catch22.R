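# The catch22 canonical time-series statistics, computed on the z-scored
# series. Each statistic follows the published definition; where the original
# leaves micro-choices open (histogram edge handling, Welch segmenting) one
# convention is fixed here and documented in the methods vignette. The test
# suite pins every statistic against an independent reference implementation.

#' Names of the 22 canonical time-series statistics
#' @return Character vector of length 22 in canonical order.
#' @export
catch22_names <- function() c(
  "DN_HistogramMode_5",
  "DN_HistogramMode_10",
  "CO_f1ecac",
  "CO_FirstMin_ac",
  "CO_HistogramAMI_even_2_5",
  "CO_trev_1_num",
  "MD_hrv_classic_pnn40",
  "SB_BinaryStats_mean_longstretch1",
  "SB_TransitionMatrix_3ac_sumdiagcov",
  "PD_PeriodicityWang_th0_01",
  "CO_Embed2_Dist_tau_d_expfit_meandiff",
  "IN_AutoMutualInfoStats_40_gaussian_fmmi",
  "FC_LocalSimple_mean1_tauresrat",
  "DN_OutlierInclude_p_001_mdrmd",
  "DN_OutlierInclude_n_001_mdrmd",
  "SP_Summaries_welch_rect_area_5_1",
  "SB_BinaryStats_diff_longstretch0",
  "SB_MotifThree_quantile_hh",
  "SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1",
  "SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1",
  "SP_Summaries_welch_rect_centroid",
  "FC_LocalSimple_mean3_stderr")

# autocorrelation at lags 1..lag_max, denominator-N convention
ac_fun <- function(y, lag_max) {
  drop(stats::acf(y, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)[-1]
}

# first lag at which the autocorrelation is <= 0 (default: series length)
first_zero_ac <- function(y) {
  n <- length(y)
  a <- ac_fun(y, n - 1)
  k <- which(a <= 0)
  if (length(k)) k[1] else n
}

longest_run <- function(b) {
  if (!length(b) || !any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}

# equiprobable 3-symbol coarse-graining by rank
symbolize3 <- function(z) {
  m <- length(z)
  r <- rank(z, ties.method = "first")
  1L + (r > ceiling(m / 3)) + (r > ceiling(2 * m / 3))
}

hist_counts <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  tabulate(idx, nbins = length(edges) - 1L)
}

c22_histogram_mode <- function(y, nbins) {
  edges <- seq(min(y), max(y), length.out = nbins + 1)
  if (edges[1] == edges[nbins + 1]) return(edges[1])
  counts <- hist_counts(y, edges)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  mean(centers[counts == max(counts)])
}

c22_f1ecac <- function(y) {
  n <- length(y)
  a <- c(1, ac_fun(y, n - 1))
  thr <- exp(-1)
  for (k in seq_len(n - 1)) {
    if (a[k + 1] < thr) {
      return((k - 1) + (a[k] - thr) / (a[k] - a[k + 1]))
    }
  }
  n
}

c22_first_min_ac <- function(y) {
  n <- length(y)
  a <- ac_fun(y, n - 1)
  for (k in 2:(length(a) - 1)) {
    if (a[k] < a[k - 1] && a[k] < a[k + 1]) return(k)
  }
  n
}

c22_histogram_ami <- function(y, tau = 2, nbins = 5) {
  n <- length(y)
  edges <- seq(min(y) - 0.1, max(y) + 0.1, length.out = nbins + 1)
  i1 <- findInterval(y[1:(n - tau)], edges, rightmost.closed = TRUE)
  i2 <- findInterval(y[(tau + 1):n], edges, rightmost.closed = TRUE)
  joint <- matrix(0, nbins, nbins)
  for (k in seq_along(i1)) joint[i1[k], i2[k]] <- joint[i1[k], i2[k]] + 1
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

c22_trev <- function(y) mean(diff(y)^3)

c22_pnn40 <- function(y) mean(abs(diff(y)) > 0.04)

c22_transition_matrix <- function(y) {
  tau <- first_zero_ac(y)
  z <- y[seq(1, length(y), by = tau)]
  m <- length(z)
  if (m < 4) return(NaN)
  sym <- symbolize3(z)
  tm <- matrix(0, 3, 3)
  for (i in seq_len(m - 1)) tm[sym[i], sym[i + 1]] <- tm[sym[i], sym[i + 1]] + 1
  tm <- tm / (m - 1)
  sum(diag(stats::cov(tm)))
}

# least-squares cubic spline detrend with one interior knot at the midpoint
spline_detrend <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  mid <- (n + 1) / 2
  B <- cbind(1, x, x^2, x^3, pmax(x - mid, 0)^3)
  y - drop(B %*% qr.coef(qr(B), y))
}

c22_periodicity_wang <- function(y, th = 0.01) {
  n <- length(y)
  r <- spline_detrend(y)
  K <- max(3, floor(n / 3))
  if (stats::var(r) == 0) return(0)
  a <- ac_fun(r, K)
  peak_lag <- 0
  for (k in 2:(K - 1)) {
    if (a[k] > a[k - 1] && a[k] > a[k + 1] && a[k] > 0) {
      troughs <- which(diff(sign(diff(a[1:k]))) > 0) + 1   # local minima < k
      if (length(troughs)) {
        tr <- max(troughs)
        if (a[k] - a[tr] >= th) { peak_lag <- k; break }
      }
    }
  }
  peak_lag
}

c22_embed2_expfit <- function(y) {
  n <- length(y)
  tau <- min(first_zero_ac(y), floor(n / 10))
  tau <- max(tau, 1)
  a <- y[1:(n - tau)]
  b <- y[(tau + 1):n]
  d <- sqrt(diff(a)^2 + diff(b)^2)
  m <- length(d)
  l <- mean(d)
  w <- 3.5 * stats::sd(d) / m^(1 / 3)
  if (w <= 0 || max(d) == min(d)) return(NaN)
  nb <- ceiling((max(d) - min(d)) / w)
  edges <- seq(min(d), max(d), length.out = nb + 1)
  counts <- hist_counts(d, edges)
  bw <- edges[2] - edges[1]
  obs <- counts / (m * bw)
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  expfit <- exp(-centers / l) / l
  mean(abs(obs - expfit))
}

c22_ami_fmmi <- function(y) {
  L <- min(40, floor(length(y) / 2))
  a <- ac_fun(y, L)
  ami <- -0.5 * log(pmax(1 - a^2, .Machine$double.eps))
  for (k in 2:(L - 1)) {
    if (ami[k] < ami[k - 1] && ami[k] < ami[k + 1]) return(k)
  }
  L
}

c22_tauresrat <- function(y) {
  res <- diff(y)
  first_zero_ac(res) / first_zero_ac(y)
}

c22_outlier_include_mdrmd <- function(w) {
  n <- length(w)
  inc <- 0.01
  if (max(w) < inc) return(0)
  thr <- seq(0, max(w), by = inc)
  stats4 <- counts <- numeric(length(thr))
  for (j in seq_along(thr)) {
    idx <- which(w >= thr[j])
    counts[j] <- length(idx)
    stats4[j] <- median(idx) / ((n + 1) / 2) - 1
  }
  keep <- counts > 2
  if (!any(keep)) return(0)
  median(stats4[keep])
}

# Welch periodogram, rectangular window, 8 segments with 50% overlap,
# angular frequency units (fs = 2*pi). Returns list(f, S).
welch_rect <- function(y) {
  n <- length(y)
  nseg <- max(8L, floor(n / 4.5))
  nseg <- min(nseg, n)
  nov <- floor(nseg / 2)
  step <- nseg - nov
  nfft <- max(256L, 2^ceiling(log2(nseg)))
  fs <- 2 * pi
  starts <- seq(1, n - nseg + 1, by = step)
  P <- rep(0, nfft %/% 2 + 1)
  for (s in starts) {
    seg <- y[s:(s + nseg - 1)]
    X <- stats::fft(c(seg, rep(0, nfft - nseg)))
    pxx <- (Mod(X)^2 / (fs * nseg))[1:(nfft %/% 2 + 1)]
    pxx[2:(nfft %/% 2)] <- 2 * pxx[2:(nfft %/% 2)]
    P <- P + pxx
  }
  P <- P / length(starts)
  list(f = fs * (0:(nfft %/% 2)) / nfft, S = P)
}

c22_welch_area51 <- function(y) {
  w <- welch_rect(y)
  df <- w$f[2] - w$f[1]
  sum(w$S[seq_len(length(w$S) %/% 5)]) * df
}

c22_welch_centroid <- function(y) {
  w <- welch_rect(y)
  cs <- cumsum(w$S)
  w$f[which(cs > cs[length(cs)] / 2)[1]]
}

c22_motif_three <- function(y) {
  sym <- symbolize3(y)
  n <- length(sym)
  p <- table(factor(sym[-n], levels = 1:3), factor(sym[-1], levels = 1:3)) / (n - 1)
  p <- as.vector(p)
  -sum(p[p > 0] * log(p[p > 0]))
}

# shared scaffolding for the two fluctuation-analysis statistics
fluct_prop_r1 <- function(z, how) {
  n <- length(z)
  taus <- unique(round(exp(seq(log(5), log(floor(n / 2)), length.out = 50))))
  taus <- taus[taus >= 5 & taus <= floor(n / 2)]
  ntt <- length(taus)
  min_pts <- 6
  if (ntt < 2 * min_pts) return(NaN)
  FF <- vapply(taus, function(tau) {
    nwin <- n %/% tau
    x <- seq_len(tau)
    sx <- sum(x); sxx <- sum(x^2)
    vals <- vapply(seq_len(nwin), function(wi) {
      seg <- z[((wi - 1) * tau + 1):(wi * tau)]
      sy <- sum(seg); sxy <- sum(x * seg)
      det <- tau * sxx - sx^2
      b <- (tau * sxy - sx * sy) / det
      a <- (sy - b * sx) / tau
      res <- seg - a - b * x
      if (how == "rsrange") (max(res) - min(res))^2 else mean(res^2)
    }, 1)
    sqrt(mean(vals))
  }, 1)
  if (any(FF <= 0)) return(NaN)
  lt <- log(taus); lf <- log(FF)
  sse_lin <- function(xx, yy) {
    fit <- stats::lm.fit(cbind(1, xx), yy)
    sum(fit$residuals^2)
  }
  scores <- vapply(min_pts:(ntt - min_pts + 1), function(i) {
    sse_lin(lt[1:i], lf[1:i]) / i +
      sse_lin(lt[i:ntt], lf[i:ntt]) / (ntt - i + 1)
  }, 1)
  i_best <- (min_pts:(ntt - min_pts + 1))[which.min(scores)]
  i_best / ntt
}

c22_fluct_rsrange <- function(y) fluct_prop_r1(cumsum(y), "rsrange")

c22_fluct_dfa <- function(y) {
  z <- cumsum(y[seq(1, length(y), by = 2)])
  fluct_prop_r1(z, "dfa")
}

c22_local_simple_mean3_stderr <- function(y) {
  n <- length(y)
  pred <- (y[1:(n - 3)] + y[2:(n - 2)] + y[3:(n - 1)]) / 3
  stats::sd(y[4:n] - pred)
}

#' Compute the 22 canonical time-series statistics
#'
#' The series is z-scored first, so every statistic is invariant to location
#' and scale. A constant (zero-variance) series has no defined z-score and
#' returns the all-zero vector with a warning; individual statistics that come
#' back non-finite are replaced by 0, also with a warning.
#'
#' @param values Numeric series of at least 30 samples.
#' @return Named numeric vector of length 22 (names from [catch22_names()]).
#' @export
catch22_features <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 30) {
    stop("series too short for stable statistics: need >= 30 samples, got ",
         length(values), call. = FALSE)
  }
  if (anyNA(values)) stop("series contains NA", call. = FALSE)
  nm <- catch22_names()
  if (stats::sd(values) == 0) {
    warning("constant series: z-score undefined, returning all-zero features",
            call. = FALSE)
    return(setNames(rep(0, 22), nm))
  }
  y <- (values - mean(values)) / stats::sd(values)
  out <- c(
    c22_histogram_mode(y, 5),
    c22_histogram_mode(y, 10),
    c22_f1ecac(y),
    c22_first_min_ac(y),
    c22_histogram_ami(y),
    c22_trev(y),
    c22_pnn40(y),
    as.numeric(longest_run(y > mean(y))),
    c22_transition_matrix(y),
    c22_periodicity_wang(y),
    c22_embed2_expfit(y),
    c22_ami_fmmi(y),
    c22_tauresrat(y),
    c22_outlier_include_mdrmd(y),
    c22_outlier_include_mdrmd(-y),
    c22_welch_area51(y),
    as.numeric(longest_run(!(diff(y) > 0))),
    c22_motif_three(y),
    c22_fluct_rsrange(y),
    c22_fluct_dfa(y),
    c22_welch_centroid(y),
    c22_local_simple_mean3_stderr(y))
  bad <- !is.finite(out)
  if (any(bad)) {
    warning("non-finite statistics replaced by 0: ",
            paste(nm[bad], collapse = ", "), call. = FALSE)
    out[bad] <- 0
  }
  setNames(out, nm)
}
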