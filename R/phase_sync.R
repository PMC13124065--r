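# phase_sync module: Morlet phase extraction, sliding circular-correlation
# networks, and the phase-synchronization norm.

#' Morlet wavelet configuration
#'
#' Complex Morlet kernels with cycle number `c`: temporal SD
#' `sigma_t = c / (2*pi*f)` and spectral SD `sigma_f = f / c`, so that
#' `sigma_t * sigma_f = 1/(2*pi)` identically. The amplitude normalization is
#' chosen so a unit-amplitude sinusoid at the center frequency yields unit
#' coefficient magnitude.
#'
#' @param freqs center frequencies in Hz (default 2-20 Hz in steps of 2).
#' @param cycles cycle number (default 7).
#' @return a `wavelet_config` list with derived `sigma_t`, `sigma_f`.
#' @export
wavelet_config <- function(freqs = seq(2, 20, by = 2), cycles = 7) {
  stopifnot(all(freqs > 0), cycles > 0)
  structure(list(freqs = freqs, cycles = cycles,
                 sigma_t = cycles / (2 * pi * freqs),
                 sigma_f = freqs / cycles),
            class = "wavelet_config")
}

morlet_kernel <- function(f, cycles, rate) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * rate)
  t <- (-half:half) / rate
  env <- exp(-t^2 / (2 * sigma_t^2))
  # unit response to a unit cosine at f: the positive-frequency component
  # carries half the amplitude, hence the factor 2
  (2 / sum(env)) * env * exp(1i * 2 * pi * f * t)
}

#' Time-frequency phase via continuous Morlet transform
#'
#' Convolves each channel with the complex Morlet kernel at each center
#' frequency (frequency-domain multiplication, zero padding) and returns the
#' wrapped phase of the coefficients. Coefficient magnitudes of a
#' unit-amplitude sinusoid at the center frequency are ~1 away from segment
#' edges.
#'
#' @param seg an `eeg_segment`.
#' @param cfg a [wavelet_config()].
#' @param keep_coefficients also return the complex coefficients.
#' @return a `tf_phase`: list with `phase` (array channels x time x freq,
#'   radians in (-pi, pi]), `freqs`, `rate`, and optionally `coefficients`.
#' @export
morlet_phase <- function(seg, cfg = wavelet_config(), keep_coefficients = FALSE) {
  n_ch <- nrow(seg$samples); n_t <- ncol(seg$samples)
  kernels <- lapply(cfg$freqs, morlet_kernel, cycles = cfg$cycles, rate = seg$rate)
  klen <- vapply(kernels, length, 0L)
  if (max(klen) > n_t)
    stop_param("lowest-frequency kernel (", max(klen),
               " samples) longer than segment (", n_t, ")")
  nfft <- stats::nextn(n_t + max(klen) - 1L, 2L)
  xf <- stats::mvfft(rbind(t(seg$samples), matrix(0, nfft - n_t, n_ch)))
  phase <- array(NA_real_, dim = c(n_ch, n_t, length(cfg$freqs)),
                 dimnames = list(seg$channel_labels, NULL, NULL))
  coefs <- if (keep_coefficients)
    array(NA_complex_, dim = dim(phase)) else NULL
  for (k in seq_along(kernels)) {
    ker <- kernels[[k]]
    half <- (length(ker) - 1L) %/% 2L
    kf <- fft(c(ker, rep(0, nfft - length(ker))))
    conv <- stats::mvfft(xf * kf, inverse = TRUE) / nfft
    idx <- (half + 1L):(half + n_t)               # 'same' alignment
    cc <- t(conv[idx, , drop = FALSE])
    if (keep_coefficients) coefs[, , k] <- cc
    phase[, , k] <- wrap_phase(Arg(cc))
  }
  structure(list(phase = phase, freqs = cfg$freqs, rate = seg$rate,
                 coefficients = coefs, cfg = cfg),
            class = "tf_phase")
}

#' Circular correlation coefficient of two phase windows
#'
#' `CCorr = sum(sin(phi_i - mi) * sin(phi_j - mj)) /
#'  sqrt(sum(sin^2(phi_i - mi)) * sum(sin^2(phi_j - mj)))`, where `mi`, `mj`
#' are per-window phase references. The default reference is the arithmetic
#' sample mean of the wrapped phase (as in the defining equation); the
#' circular mean is available as an alternative convention.
#'
#' @param phi_i,phi_j equal-length phase windows (radians).
#' @param mean_type `"arithmetic"` (default) or `"circular"`.
#' @return value in [-1, 1], or `NA` when a window has zero circular
#'   variance (constant phase), where the statistic is undefined.
#' @export
ccorr <- function(phi_i, phi_j, mean_type = c("arithmetic", "circular")) {
  mean_type <- match.arg(mean_type)
  if (length(phi_i) != length(phi_j) || length(phi_i) < 3L)
    stop_param("phase windows must have equal length >= 3")
  phi_i <- wrap_phase(phi_i); phi_j <- wrap_phase(phi_j)
  ref <- function(p) if (mean_type == "arithmetic") mean(p)
                     else atan2(mean(sin(p)), mean(cos(p)))
  si <- sin(phi_i - ref(phi_i)); sj <- sin(phi_j - ref(phi_j))
  den <- sqrt(sum(si^2) * sum(sj^2))
  if (den == 0) return(NA_real_)
  sum(si * sj) / den
}

#' Sliding-window synchronization networks
#'
#' Circular correlation for every unordered channel pair in a sliding window
#' over the phase series of each frequency. Window centers are at
#' `start + floor((L-1)/2)`; with step 1 a segment of `N_t` samples yields
#' `N_t - L + 1` centers (the "full-overlap" EEG convention; the simulation
#' pipeline uses a 250-sample window with a 25-sample step).
#'
#' @param tf a `tf_phase` from [morlet_phase()], or a plain channels x time
#'   phase matrix (taken as a single frequency, with `rate` required).
#' @param window_samples window length L in samples (default 251).
#' @param step_samples step between window starts (default 1).
#' @param rate sampling rate; only needed when `tf` is a plain matrix.
#' @param mean_type phase reference convention, see [ccorr()].
#' @return a `sync_series`: list with `values` (list per frequency of
#'   `N_con x n_windows` matrices, `NA` where undefined), `centers_s`,
#'   `center_idx`, `freqs`, `map` (connection index to channel pair),
#'   `window_samples`, `step_samples`, `segment_length_s`.
#' @export
sliding_sync <- function(tf, window_samples = 251L, step_samples = 1L,
                         rate = NULL, mean_type = c("arithmetic", "circular")) {
  mean_type <- match.arg(mean_type)
  if (is.matrix(tf)) {
    stopifnot(!is.null(rate))
    tf <- list(phase = array(tf, dim = c(nrow(tf), ncol(tf), 1L),
                             dimnames = list(rownames(tf), NULL, NULL)),
               freqs = NA_real_, rate = rate)
  }
  L <- as.integer(window_samples); step <- as.integer(step_samples)
  n_ch <- dim(tf$phase)[1L]; n_t <- dim(tf$phase)[2L]
  if (L > n_t) stop_param("window (", L, ") longer than segment (", n_t, ")")
  if (step < 1L) stop_param("step must be >= 1")
  labels <- dimnames(tf$phase)[[1L]] %||% paste0("ch", seq_len(n_ch))
  map <- connection_map(labels)
  starts <- seq(1L, n_t - L + 1L, by = step)
  center_idx <- starts + (L - 1L) %/% 2L
  vals <- lapply(seq_along(tf$freqs), function(k)
    sliding_ccorr_cpp(tf$phase[, , k, drop = TRUE], L, step,
                      mean_type == "circular"))
  structure(list(values = vals, freqs = tf$freqs,
                 centers_s = (center_idx - 1L) / tf$rate,
                 center_idx = center_idx, map = map,
                 window_samples = L, step_samples = step,
                 rate = tf$rate, segment_length_s = n_t / tf$rate),
            class = "sync_series")
}

#' Normalized Euclidean norm of the synchronization network over time
#'
#' `|PS(t,f)| = sqrt(mean_k CCorr_k(t,f)^2)` over all connections; always in
#' [0, 1]. Windows with more than `max_undefined` (default 5%) undefined
#' connections are flagged `NA`.
#'
#' @param ss a `sync_series`.
#' @param max_undefined maximum tolerated fraction of undefined connections
#'   per window.
#' @return matrix frequencies x windows of `|PS|` values.
#' @export
ps_norm_series <- function(ss, max_undefined = 0.05) {
  out <- matrix(NA_real_, length(ss$freqs), length(ss$centers_s))
  for (k in seq_along(ss$freqs)) {
    v <- ss$values[[k]]
    bad <- colMeans(is.na(v))
    ok <- bad <= max_undefined
    out[k, ok] <- sqrt(colMeans(v[, ok, drop = FALSE]^2, na.rm = TRUE))
  }
  out
}

#' Time mean and SD of the synchronization norm per frequency
#'
#' @param series matrix frequencies x windows from [ps_norm_series()], or a
#'   single numeric series.
#' @return data.frame with columns `freq_index`, `mu`, `sigma` (sample SD),
#'   `n_windows`; `NA` where fewer than 2 unflagged windows remain.
#' @export
ps_norm_stats <- function(series) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1L)
  stats <- t(apply(series, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(c(NA_real_, NA_real_, length(x)))
    c(mean(x), sd(x), length(x))
  }))
  data.frame(freq_index = seq_len(nrow(series)), mu = stats[, 1L],
             sigma = stats[, 2L], n_windows = as.integer(stats[, 3L]))
}
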