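# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

#' Number of undirected channel pairs
#'
#' @param n_channels number of channels/nodes.
#' @return `n_channels * (n_channels - 1) / 2`.
#' @export
n_connections <- function(n_channels) {
  stopifnot(n_channels >= 2)
  n_channels * (n_channels - 1L) / 2L
}

#' Connection index map for an ordered channel set
#'
#' Enumerates all unordered channel pairs in column-major lower-triangle
#' order, the order used by every sliding-synchronization matrix in the
#' package.
#'
#' @param channels character vector of channel labels (or an integer count).
#' @return data.frame with columns `connection`, `ch_i`, `ch_j`.
#' @export
connection_map <- function(channels) {
  if (is.numeric(channels) && length(channels) == 1L)
    channels <- paste0("ch", seq_len(channels))
  n <- length(channels)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  data.frame(connection = seq_len(nrow(idx)),
             ch_i = channels[idx[, 2L]],
             ch_j = channels[idx[, 1L]],
             i = idx[, 2L], j = idx[, 1L],
             stringsAsFactors = FALSE)
}

#' Sliding-window length in samples
#'
#' @param window_s window length in seconds (default 1.004, which at 250
#'   samples/s gives the canonical 251-sample window).
#' @param rate sampling rate in samples/s.
#' @return integer number of samples.
#' @export
window_samples <- function(window_s = 1.004, rate = 250) {
  as.integer(round(window_s * rate))
}

#' Bootstrap-ratio reliability threshold
#'
#' Two-tailed standard-normal critical value; the default `p = 0.01`
#' corresponds to the 99th two-tailed percentile, 2.5758.
#'
#' @param p two-tailed tail probability.
#' @return positive critical value.
#' @export
bsr_threshold <- function(p = 0.01) qnorm(1 - p / 2)

# Draw reproducible child seeds below 2^31 from a master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # map -pi to pi so phases lie in (-pi, pi]
  out[out == -pi] <- pi
  out
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)
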