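# psd_dynamics module: correlation-distance matrices of synchronization
# networks and jump-length statistics across timescales.

#' Phase-synchronization-dynamics (correlation-distance) matrix
#'
#' `D[t1, t2] = 1 - corr(PS(t1), PS(t2))` where each `PS(t)` is the vector
#' of connection-wise circular correlations at window center `t`. The
#' correlation is taken across connections, so `D` depends only on the
#' topology, not the magnitude, of the networks. Symmetric, zero diagonal,
#' entries in [0, 2]; windows whose network vector is constant (or flagged
#' upstream) give `NA` rows/columns.
#'
#' @param ss a `sync_series` from [sliding_sync()].
#' @param freq_index which frequency bin (default all).
#' @return a `psd_matrix` (single frequency) or list of them: list with `D`,
#'   `centers_s`, `step_s`, `segment_length_s`, `freq`.
#' @export
psd_matrix <- function(ss, freq_index = seq_along(ss$freqs)) {
  one <- function(k) {
    v <- ss$values[[k]]                 # n_con x n_win
    if (ncol(v) < 2L) stop_param("need >= 2 windows for a PSD matrix")
    sds <- apply(v, 2L, sd, na.rm = TRUE)
    const <- !is.finite(sds) | sds == 0 | colSums(!is.na(v)) < 2L
    if (any(const))
      message(sum(const), " constant/undefined network vector(s) flagged in PSD matrix")
    D <- 1 - suppressWarnings(cor(v, use = "pairwise.complete.obs"))
    D[const, ] <- NA_real_; D[, const] <- NA_real_
    diag(D)[!const] <- 0
    structure(list(D = D, centers_s = ss$centers_s,
                   step_s = ss$step_samples / ss$rate,
                   segment_length_s = ss$segment_length_s,
                   freq = ss$freqs[k]),
              class = "psd_matrix")
  }
  if (length(freq_index) == 1L) one(freq_index) else lapply(freq_index, one)
}

#' Jump lengths at one timescale
#'
#' The `tau`-diagonal of the PSD matrix: correlation distances between
#' networks separated by lag `tau`, ordered by time. Pairs whose window
#' centers fall within `edge_s` (default 0.5 s) of the segment boundaries
#' are trimmed (edge-contaminated wavelet windows); `trim = "printed"`
#' instead applies the literal published range `t in [0.5*tau + step, T - 0.5]`.
#'
#' @param psd a `psd_matrix`.
#' @param tau timescale in seconds; must lie on the window-center grid.
#' @param edge_s edge trim in seconds.
#' @param trim `"edges"` (geometric reading) or `"printed"`.
#' @return numeric vector of jump lengths (possibly length 0).
#' @export
jump_lengths <- function(psd, tau, edge_s = 0.5, trim = c("edges", "printed")) {
  trim <- match.arg(trim)
  d <- tau / psd$step_s
  if (abs(d - round(d)) > 1e-6)
    stop_param("tau = ", tau, " s is not a multiple of the window-center step (",
               psd$step_s, " s)")
  d <- as.integer(round(d))
  n <- ncol(psd$D)
  if (d < 1L || d >= n) return(numeric(0))
  t1 <- seq_len(n - d)
  jl <- psd$D[cbind(t1, t1 + d)]
  ctr <- psd$centers_s
  keep <- if (trim == "edges") {
    ctr[t1] >= edge_s & ctr[t1 + d] <= psd$segment_length_s - edge_s
  } else {
    mid <- (ctr[t1] + ctr[t1 + d]) / 2
    mid >= 0.5 * tau + psd$step_s & mid <= psd$segment_length_s - 0.5
  }
  jl[keep]
}

#' Mean, SD and kurtosis of a jump-length sequence
#'
#' Sample mean; sample SD; Pearson (non-excess) kurtosis `m4 / m2^2` with
#' population central moments, so a normal sample gives ~3. Kurtosis is `NA`
#' for constant sequences (zero second moment).
#'
#' @param jl numeric vector, length >= 4 for a defined kurtosis.
#' @return named numeric vector `c(mu, sigma, k, n)`.
#' @export
jl_stats <- function(jl) {
  jl <- jl[!is.na(jl)]
  n <- length(jl)
  if (n == 0L) return(c(mu = NA_real_, sigma = NA_real_, k = NA_real_, n = 0))
  mu <- mean(jl)
  sigma <- if (n >= 2L) sd(jl) else NA_real_
  k <- NA_real_
  if (n >= 4L) {
    m2 <- mean((jl - mu)^2)
    if (m2 > 0) k <- mean((jl - mu)^4) / m2^2
  }
  c(mu = mu, sigma = sigma, k = k, n = n)
}

#' Default jump-length timescale grid
#'
#' EEG convention: 1.004 to 2.000 s in steps of one window-center step
#' (0.004 s at 250 samples/s with full overlap, 250 values); simulation
#' convention: 1 to 2 s in 0.1 s steps.
#'
#' @param step_s window-center step in seconds.
#' @param tau_min,tau_max range in seconds.
#' @return numeric vector of timescales.
#' @export
tau_grid <- function(step_s = 0.004, tau_min = 1 + step_s, tau_max = 2) {
  seq(tau_min, tau_max, by = step_s)
}

#' Jump-length statistics over a timescale x frequency grid
#'
#' @param psd a `psd_matrix` or list of them (one per frequency).
#' @param taus timescales in seconds (default [tau_grid()] at the matrix's
#'   own step).
#' @param ... passed to [jump_lengths()].
#' @return a `jl_grid` data.frame with columns `freq`, `tau`, `mu`, `sigma`,
#'   `k`, `n`.
#' @export
jl_grid <- function(psd, taus = NULL, ...) {
  if (inherits(psd, "psd_matrix")) psd <- list(psd)
  out <- do.call(rbind, lapply(psd, function(p) {
    tg <- taus %||% tau_grid(step_s = p$step_s,
                             tau_min = if (abs(p$step_s - 0.1) < 1e-9) 1 else 1 + p$step_s)
    stats <- t(vapply(tg, function(tau) jl_stats(jump_lengths(p, tau, ...)),
                      c(mu = 0, sigma = 0, k = 0, n = 0)))
    data.frame(freq = p$freq, tau = tg, stats, row.names = NULL)
  }))
  class(out) <- c("jl_grid", "data.frame")
  out
}

#' Summarize a jl_grid over timescales
#'
#' Mean of each statistic over the timescale grid, per frequency.
#'
#' @param grid a `jl_grid`.
#' @return data.frame with one row per frequency.
#' @export
jl_summary <- function(grid) {
  agg <- aggregate(cbind(mu, sigma, k) ~ freq, data = grid, FUN = mean,
                   na.action = stats::na.omit)
  agg
}
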