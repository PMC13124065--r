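# univariate_metrics module: Welch spectra, multiscale SD, MSE / MSEn.

#' Welch power spectral density of a segment
#'
#' Averaged modified periodograms: Hann-tapered windows (default 1 s, 50%
#' overlap), one-sided density in signal-units^2 / Hz. With mean-centered
#' segments the integral of the density over frequency recovers each
#' channel's variance (Parseval, taper-loss corrected).
#'
#' @param seg an `eeg_segment`.
#' @param window_s taper window length in seconds (default 1, i.e. a 1-Hz
#'   frequency grid).
#' @param overlap fractional overlap between windows (default 0.5).
#' @return a `spectrum_table`: list with `freq` (Hz), `power`
#'   (channels x freq matrix) and `settings`.
#' @export
power_spectrum <- function(seg, window_s = 1, overlap = 0.5) {
  nwin <- as.integer(round(window_s * seg$rate))
  n_t <- ncol(seg$samples)
  if (n_t < 2L * nwin)
    stop_param("segment (", n_t, " samples) shorter than 2 estimator windows (",
               2L * nwin, ")")
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq(1L, n_t - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))   # Hann
  u <- sum(w^2)
  nf <- nwin %/% 2L
  freq <- seq_len(nf) * seg$rate / nwin
  pow <- matrix(0, nrow(seg$samples), nf,
                dimnames = list(seg$channel_labels, NULL))
  for (s in starts) {
    xw <- seg$samples[, s:(s + nwin - 1L), drop = FALSE] * rep(w, each = nrow(pow))
    ft <- t(stats::mvfft(t(xw)))
    p <- Mod(ft[, 2L:(nf + 1L), drop = FALSE])^2
    p <- p * 2 / (seg$rate * u)                 # one-sided density
    if (nwin %% 2L == 0L) p[, nf] <- p[, nf] / 2 # Nyquist bin not doubled
    pow <- pow + p
  }
  pow <- pow / length(starts)
  structure(list(freq = freq, power = pow,
                 settings = list(window_s = window_s, overlap = overlap,
                                 taper = "hann", rate = seg$rate)),
            class = "spectrum_table")
}

#' Coarse-grain a series by non-overlapping block averaging
#'
#' The classic multiscale-entropy coarse-graining: element `j` of the output
#' is the mean of the `s` consecutive input samples starting at
#' `(j-1)*s + 1`; output length is `floor(length(x)/s)`.
#'
#' @param x numeric series.
#' @param scale_factor positive integer block size.
#' @return coarse-grained series.
#' @export
coarse_grain <- function(x, scale_factor) {
  s <- as.integer(scale_factor)
  if (s < 1L || s > length(x))
    stop_param("scale factor must be in [1, length(x)]")
  if (s == 1L) return(x)
  n <- length(x) %/% s
  colMeans(matrix(x[seq_len(n * s)], nrow = s))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)` where `B` counts template pairs of length `m`
#' within Chebyshev distance `r` (self-matches excluded, Richman-Moorman
#' convention: both template sets range over the first `n - m` points) and
#' `A` the same for length `m + 1`.
#'
#' @param x numeric series.
#' @param m template length (samples).
#' @param r absolute tolerance (same units as `x`).
#' @return the entropy value, or `NA` (with a warning) when no template pair
#'   matches at either length, in which case the statistic is undefined.
#' @export
sample_entropy <- function(x, m = 2, r) {
  if (length(x) <= m + 1L) stop_param("series too short for template length m = ", m)
  if (!is.numeric(r) || r <= 0) stop_param("tolerance r must be > 0")
  counts <- sampen_counts_cpp(as.numeric(x), as.integer(m), as.numeric(r))
  if (counts[1L] == 0 || counts[2L] == 0) {
    warning("sample entropy undefined: no matching template pairs (A = ",
            counts[2L], ", B = ", counts[1L], ")")
    return(NA_real_)
  }
  -log(counts[2L] / counts[1L])
}

resolve_scales <- function(scale_factors, rate) {
  data.frame(factor = as.integer(scale_factors),
             scale_s = as.integer(scale_factors) / rate)
}

#' Multiscale entropy curves (MSE and MSEn)
#'
#' Per channel and scale: coarse-grain then sample entropy. In `"scale1_sd"`
#' mode (classic MSE) the tolerance is fixed at `r_frac` times the SD of the
#' original series for all scales; in `"per_scale_sd"` mode (MSEn) the
#' tolerance tracks each coarse series' own SD — equivalent to z-scoring
#' every coarse series — removing the confound of SD shrinking with scale.
#'
#' @param seg an `eeg_segment`.
#' @param scale_factors integer coarse-graining factors (default 1:25; at
#'   250 samples/s these cover 4-100 ms).
#' @param m template length.
#' @param r_frac tolerance as a fraction of the reference SD.
#' @param r_mode `"scale1_sd"` (MSE) or `"per_scale_sd"` (MSEn).
#' @return a `multiscale_curve`: list with `scales` (data.frame factor /
#'   seconds), `values` (channels x scales, `NA` where undefined), `metric`.
#' @export
multiscale_entropy <- function(seg, scale_factors = 1:25, m = 2, r_frac = 0.5,
                               r_mode = c("scale1_sd", "per_scale_sd")) {
  r_mode <- match.arg(r_mode)
  scales <- resolve_scales(scale_factors, seg$rate)
  n_keep <- ncol(seg$samples) %/% max(scales$factor)
  if (n_keep < 10 * (m + 1))
    stop_param("largest scale leaves fewer than 10*(m+1) coarse samples")
  vals <- matrix(NA_real_, nrow(seg$samples), nrow(scales),
                 dimnames = list(seg$channel_labels, NULL))
  for (ch in seq_len(nrow(seg$samples))) {
    x <- seg$samples[ch, ]
    sd1 <- sd(x)
    for (k in seq_len(nrow(scales))) {
      cx <- coarse_grain(x, scales$factor[k])
      ref <- if (r_mode == "scale1_sd") sd1 else sd(cx)
      if (!is.finite(ref) || ref <= 0) next      # flagged missing
      vals[ch, k] <- suppressWarnings(sample_entropy(cx, m = m, r = r_frac * ref))
    }
  }
  structure(list(scales = scales, values = vals,
                 metric = if (r_mode == "scale1_sd") "MSE" else "MSEn",
                 params = list(m = m, r_frac = r_frac, r_mode = r_mode)),
            class = "multiscale_curve")
}

#' Multiscale standard deviation
#'
#' SD of the coarse-grained series per channel and scale.
#'
#' @inheritParams multiscale_entropy
#' @return a `multiscale_curve` with metric `"sigma"`.
#' @export
multiscale_std <- function(seg, scale_factors = 1:25) {
  scales <- resolve_scales(scale_factors, seg$rate)
  vals <- matrix(NA_real_, nrow(seg$samples), nrow(scales),
                 dimnames = list(seg$channel_labels, NULL))
  for (ch in seq_len(nrow(seg$samples)))
    for (k in seq_len(nrow(scales)))
      vals[ch, k] <- sd(coarse_grain(seg$samples[ch, ], scales$factor[k]))
  structure(list(scales = scales, values = vals, metric = "sigma",
                 params = list()),
            class = "multiscale_curve")
}

#' Tidy a multiscale curve or spectrum table
#'
#' @param x a `multiscale_curve` or `spectrum_table`.
#' @return long-format data.frame (channel, scale/freq, metric, value).
#' @export
tidy_metric <- function(x) {
  if (inherits(x, "spectrum_table")) {
    data.frame(channel = rep(rownames(x$power), times = ncol(x$power)),
               freq = rep(x$freq, each = nrow(x$power)),
               metric = "P", value = as.vector(x$power),
               stringsAsFactors = FALSE)
  } else {
    data.frame(channel = rep(rownames(x$values), times = ncol(x$values)),
               scale_s = rep(x$scales$scale_s, each = nrow(x$values)),
               metric = x$metric, value = as.vector(x$values),
               stringsAsFactors = FALSE)
  }
}
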