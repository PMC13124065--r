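# synthetic_data module: seeded cohorts and segments with known structure.

#' Synthetic cohort specification
#'
#' Defaults emulate the empirical study design: 4 age-like groups x 3
#' conditions, 24-31 subjects per group, 5-25 artifact-free 10-s segments per
#' subject and condition at 250 samples/s, 19 channels, oscillations at
#' 2-20 Hz over a 1/f background. Planted effects: a per-group gain on the
#' slow (2-8 Hz) oscillation amplitudes declining monotonically with age, and
#' per-group network-state dwell statistics with the "young-adult" group
#' dwelling longest and most variably (the inverted-U).
#'
#' @param n_groups,n_conditions design size.
#' @param subjects_per_group scalar or per-group vector.
#' @param segments_range min/max segments per subject x condition.
#' @param n_channels,rate,segment_length_s segment geometry.
#' @param freqs oscillation center frequencies (Hz).
#' @param slow_band_gain per-group power gain applied to 2-8 Hz oscillations.
#' @param dwell_mean_s,dwell_cv per-group mean and coefficient of variation
#'   of network-state dwell times (s).
#' @param n_states number of latent coupling topologies.
#' @param noise_1f_exponent spectral exponent of the background noise.
#' @param snr oscillation-to-background power ratio.
#' @param group_labels,condition_labels label sets.
#' @param seed master seed; every segment seed derives from it.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_groups = 4, n_conditions = 3,
                       subjects_per_group = c(24, 28, 31, 28),
                       segments_range = c(5, 25),
                       n_channels = 19, rate = 250, segment_length_s = 10,
                       freqs = c(4, 6, 10),
                       slow_band_gain = c(2.0, 1.6, 1.2, 1.0),
                       dwell_mean_s = c(0.6, 0.8, 1.5, 0.9),
                       dwell_cv = c(0.5, 0.5, 1.0, 0.6),
                       n_states = 3,
                       noise_1f_exponent = 1, snr = 4,
                       group_labels = c("YC", "OC", "YA", "OA")[seq_len(n_groups)],
                       condition_labels = c("REC", "UOT", "AOT")[seq_len(n_conditions)],
                       seed = 1L) {
  rep_g <- function(x) if (length(x) == 1L) rep(x, n_groups) else x
  subjects_per_group <- rep_g(subjects_per_group)
  slow_band_gain <- rep_g(slow_band_gain)
  dwell_mean_s <- rep_g(dwell_mean_s)
  dwell_cv <- rep_g(dwell_cv)
  stopifnot(length(subjects_per_group) == n_groups,
            length(slow_band_gain) == n_groups,
            length(dwell_mean_s) == n_groups,
            length(dwell_cv) == n_groups,
            all(subjects_per_group >= 1), all(segments_range >= 1),
            all(slow_band_gain > 0), n_channels >= 2, rate > 0,
            all(dwell_mean_s > 2 / min(freqs)) || TRUE)
  if (any(dwell_mean_s <= 2 / min(freqs)))
    stop_param("dwell times must exceed 2 / lowest frequency (",
               signif(2 / min(freqs), 3), " s)")
  structure(list(n_groups = n_groups, n_conditions = n_conditions,
                 subjects_per_group = subjects_per_group,
                 segments_range = segments_range, n_channels = n_channels,
                 rate = rate, segment_length_s = segment_length_s,
                 freqs = freqs, slow_band_gain = slow_band_gain,
                 dwell_mean_s = dwell_mean_s, dwell_cv = dwell_cv,
                 n_states = n_states, noise_1f_exponent = noise_1f_exponent,
                 snr = snr, group_labels = group_labels,
                 condition_labels = condition_labels, seed = as.integer(seed)),
            class = "synth_spec")
}

#' IID Gaussian segment
#'
#' Independent standard-normal samples per channel, mean-centered.
#'
#' @param n_channels,n_samples,rate geometry.
#' @param seed integer seed; output is deterministic given it.
#' @param ... metadata passed to [segment()].
#' @return an `eeg_segment`.
#' @export
gen_iid_gaussian_segment <- function(n_channels, n_samples, rate, seed, ...) {
  stopifnot(n_channels >= 1, n_samples >= 1)
  set.seed(as.integer(seed))
  segment(matrix(rnorm(n_channels * n_samples), nrow = n_channels),
          rate = rate, ...)
}

# Convert a connection-weight vector (length n*(n-1)/2, order of
# connection_map) into a channel partition: connected components of the
# graph with edges where weight >= 0.5.
weights_to_partition <- function(w) {
  n <- (1 + sqrt(1 + 8 * length(w))) / 2
  if (abs(n - round(n)) > 1e-9)
    stop_param("weight vector length is not n*(n-1)/2 for any integer n")
  n <- as.integer(round(n))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  cm <- connection_map(n)
  for (k in seq_along(w)) if (w[k] >= 0.5) {
    ri <- find(cm$i[k]); rj <- find(cm$j[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, 0L)
  as.integer(factor(roots))
}

#' Connection-weight vector implied by a channel partition
#'
#' Weight 1 for pairs in the same community, 0 otherwise, in
#' [connection_map()] order.
#'
#' @param partition integer community label per channel.
#' @return numeric weight vector of length `n*(n-1)/2`.
#' @export
topology_weights <- function(partition) {
  cm <- connection_map(length(partition))
  as.numeric(partition[cm$i] == partition[cm$j])
}

# Random channel partitions used as latent coupling topologies.
random_topologies <- function(n_channels, n_states, n_communities = 3, seed = 1L) {
  set.seed(as.integer(seed))
  lapply(seq_len(n_states), function(s) {
    repeat {
      p <- sample.int(n_communities, n_channels, replace = TRUE)
      if (length(unique(p)) > 1L) return(as.integer(factor(p)))
    }
  })
}

# 1/f^alpha noise by spectral shaping of white noise; unit variance.
colored_noise <- function(n, alpha) {
  z <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))                       # avoid division by 0 at DC
  f <- pmin(f, n - f + 1)                         # two-sided frequency index
  shaped <- Re(fft(z * f^(-alpha / 2), inverse = TRUE)) / n
  shaped <- shaped - mean(shaped)
  shaped / sd(shaped)
}

#' Segment with switching phase-coupling topology
#'
#' Channels are sums of band-limited oscillations; channels in the same
#' community of the active topology share a latent slowly-wandering phase
#' (plus small independent phase jitter), so their circular correlation is
#' high while cross-community pairs are unsynchronized. The active topology
#' switches at gamma-distributed dwell times. A 1/f background is added at
#' the requested signal-to-noise ratio.
#'
#' @param topologies list; each element either an integer community label per
#'   channel, or a connection-weight vector (converted via thresholding at
#'   0.5 to communities).
#' @param dwell_mean_s,dwell_cv mean and coefficient of variation of dwell
#'   times (s); must satisfy `dwell_mean_s < length_s`.
#' @param freqs oscillation center frequencies (Hz).
#' @param noise_1f_exponent background spectral exponent.
#' @param snr oscillation-to-background power ratio (`Inf` for no noise).
#' @param rate,length_s segment geometry.
#' @param seed integer seed.
#' @param slow_band_gain power gain for components with `freqs` in [2, 8] Hz
#'   (amplitudes scale with its square root).
#' @param wander_sd per-sample SD (radians) of the shared latent phase walk.
#' @param jitter_sd innovation SD of the per-channel AR(1) phase jitter.
#' @param ... metadata passed to [segment()].
#' @return an `eeg_segment`; attribute `"state"` holds the active-topology
#'   index per sample.
#' @export
gen_switching_segment <- function(topologies, dwell_mean_s, dwell_cv = 0.5,
                                  freqs = c(4, 6, 10), noise_1f_exponent = 1,
                                  snr = 4, rate = 250, length_s = 10, seed = 1L,
                                  slow_band_gain = 1, wander_sd = 0.05,
                                  jitter_sd = 0.06, ...) {
  if (length(topologies) < 1L) stop_param("need at least one topology")
  if (dwell_mean_s >= length_s)
    stop_param("dwell_mean_s (", dwell_mean_s, ") must be < length_s (", length_s, ")")
  # a vector of community labels (integers >= 1, some > 1) is a partition;
  # anything in [0,1] (weights, possibly fractional) is a connection vector
  topologies <- lapply(topologies, function(tp) {
    if (any(tp != round(tp)) || all(tp %in% c(0, 1)))
      weights_to_partition(tp)
    else as.integer(tp)
  })
  n_ch <- length(topologies[[1L]])
  if (any(vapply(topologies, length, 0L) != n_ch))
    stop_param("all topologies must cover the same channel set")
  n_t <- as.integer(round(length_s * rate))
  set.seed(as.integer(seed))

  # state schedule: gamma dwell times, no immediate repeats
  shape <- 1 / dwell_cv^2; scale <- dwell_mean_s * dwell_cv^2
  state <- integer(n_t)
  t0 <- 1L; cur <- sample.int(length(topologies), 1L)
  while (t0 <= n_t) {
    d <- max(1L, as.integer(round(rgamma(1, shape = shape, scale = scale) * rate)))
    t1 <- min(n_t, t0 + d - 1L)
    state[t0:t1] <- cur
    t0 <- t1 + 1L
    if (length(topologies) > 1L) {
      others <- setdiff(seq_along(topologies), cur)
      cur <- others[sample.int(length(others), 1L)]
    }
  }

  n_comm <- max(vapply(topologies, max, 0L))
  # slow_band_gain is a POWER gain: amplitudes scale with its square root
  amps <- ifelse(freqs >= 2 & freqs <= 8, sqrt(slow_band_gain), 1)
  x <- matrix(0, n_ch, n_t)
  tt <- (seq_len(n_t) - 1L) / rate
  for (fi in seq_along(freqs)) {
    # shared latent phase walk per (topology, community)
    psi <- array(0, dim = c(length(topologies), n_comm, n_t))
    for (s in seq_along(topologies)) for (cc in seq_len(n_comm))
      psi[s, cc, ] <- cumsum(rnorm(n_t, sd = wander_sd))
    for (i in seq_len(n_ch)) {
      eps <- as.numeric(stats::filter(rnorm(n_t, sd = jitter_sd), 0.95,
                                      method = "recursive"))
      comm <- vapply(seq_len(n_t), function(t) psi[state[t], topologies[[state[t]]][i], t], 0)
      x[i, ] <- x[i, ] + amps[fi] * cos(2 * pi * freqs[fi] * tt + comm + eps)
    }
  }
  if (is.finite(snr)) {
    sig_var <- mean(apply(x, 1L, var))
    for (i in seq_len(n_ch))
      x[i, ] <- x[i, ] + colored_noise(n_t, noise_1f_exponent) * sqrt(sig_var / snr)
  }
  seg <- segment(x, rate = rate, ...)
  attr(seg, "state") <- state
  seg
}

#' Generate a full synthetic study cohort
#'
#' Applies the planted per-group effects of the [synth_spec()]: the slow-band
#' gain scales 2-8 Hz oscillation amplitudes and the dwell parameters set the
#' network-switching tempo and its dispersion. Fully reproducible from the
#' spec seed.
#'
#' @param spec a [synth_spec()].
#' @return a `study_dataset`: list with `design` (a [study_design()]),
#'   `segments` (named list, key `"subject.condition"`), `topologies`, and
#'   the provenance `spec`.
#' @export
gen_study <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  topologies <- random_topologies(spec$n_channels, spec$n_states,
                                  seed = spec$seed)
  rows <- list(); segs <- list()
  n_cells <- sum(spec$subjects_per_group) * spec$n_conditions
  seeds <- derive_seeds(spec$seed, n_cells + 1L)
  set.seed(seeds[n_cells + 1L])
  choices <- spec$segments_range[1L]:spec$segments_range[2L]
  counts <- if (length(choices) == 1L) rep(choices, n_cells)
            else sample(choices, n_cells, replace = TRUE)
  cell <- 0L
  for (g in seq_len(spec$n_groups)) {
    for (subj in seq_len(spec$subjects_per_group[g])) {
      sid <- sprintf("%s_s%02d", spec$group_labels[g], subj)
      for (cond in seq_len(spec$n_conditions)) {
        cell <- cell + 1L
        seg_seeds <- derive_seeds(seeds[cell], counts[cell])
        key <- paste(sid, spec$condition_labels[cond], sep = ".")
        segs[[key]] <- lapply(seq_len(counts[cell]), function(k)
          gen_switching_segment(topologies,
                                dwell_mean_s = spec$dwell_mean_s[g],
                                dwell_cv = spec$dwell_cv[g],
                                freqs = spec$freqs,
                                noise_1f_exponent = spec$noise_1f_exponent,
                                snr = spec$snr, rate = spec$rate,
                                length_s = spec$segment_length_s,
                                seed = seg_seeds[k],
                                slow_band_gain = spec$slow_band_gain[g],
                                subject_id = sid,
                                group_label = spec$group_labels[g],
                                condition_label = spec$condition_labels[cond],
                                segment_index = k))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sid, group = spec$group_labels[g],
          condition = spec$condition_labels[cond], stringsAsFactors = FALSE)
      }
    }
  }
  design <- study_design(do.call(rbind, rows), groups = spec$group_labels,
                         conditions = spec$condition_labels)
  structure(list(design = design, segments = segs, topologies = topologies,
                 spec = spec), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d groups x %d conditions, %d (subject,condition) cells, %d segments\n",
              x$spec$n_groups, x$spec$n_conditions, nrow(x$design),
              sum(vapply(x$segments, length, 0L))))
  invisible(x)
}
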