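test_that("iid Gaussian segments are calibrated and deterministic", {
  s1 <- gen_iid_gaussian_segment(2, 10000, 250, seed = 11)
  s2 <- gen_iid_gaussian_segment(2, 10000, 250, seed = 11)
  expect_identical(s1$samples, s2$samples)
  expect_equal(sd(s1$samples[1, ]), 1, tolerance = 0.02)
  expect_lt(abs(cor(s1$samples[1, ], s1$samples[2, ])), 0.05)
})

test_that("topology weight vectors and partitions convert both ways", {
  part <- c(1L, 1L, 2L, 2L, 3L)
  w <- topology_weights(part)
  expect_length(w, 10)
  expect_equal(weights_to_partition <- phasedyn:::weights_to_partition(w), part)
})

test_that("switching segments are deterministic and validate dwell times", {
  tp <- list(c(1, 1, 2, 2), c(1, 2, 1, 2))
  a <- gen_switching_segment(tp, dwell_mean_s = 1, freqs = 10, seed = 9)
  b <- gen_switching_segment(tp, dwell_mean_s = 1, freqs = 10, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_lt(max(abs(rowMeans(a$samples))), 1e-9)
  expect_error(gen_switching_segment(tp, dwell_mean_s = 10, length_s = 10),
               "dwell_mean_s")
  # weight-vector topologies are accepted
  d <- gen_switching_segment(lapply(tp, topology_weights), dwell_mean_s = 1,
                             freqs = 10, seed = 9)
  expect_identical(d$samples, a$samples)
})

test_that("a single noiseless topology keeps network distances low", {
  offdiag <- function(tp, dwell, seed) {
    seg <- gen_switching_segment(tp, dwell_mean_s = dwell, freqs = c(6, 10),
                                 snr = Inf, rate = 250, length_s = 10,
                                 seed = seed)
    tf <- morlet_phase(seg, wavelet_config(freqs = c(6, 10)))
    pm <- psd_matrix(sliding_sync(tf, 251, 10), 2)
    mean(pm$D[upper.tri(pm$D)], na.rm = TRUE)
  }
  for (seed in c(3, 7)) {
    d_stat <- offdiag(list(c(1, 1, 2, 2, 3, 3)), 2, seed)
    d_sw <- offdiag(list(c(1, 1, 2, 2, 3, 3), c(1, 2, 3, 1, 2, 3)), 1, seed)
    expect_lt(d_stat, 0.65)      # frozen coupling: distances stay moderate
    expect_gt(d_sw, d_stat)      # reconfiguring coupling walks further
  }
})

test_that("two alternating topologies are recovered by clustering", {
  seg <- gen_switching_segment(list(c(1, 1, 1, 2, 2, 2), c(1, 2, 1, 2, 1, 2)),
                               dwell_mean_s = 2, dwell_cv = 0.3, freqs = 10,
                               snr = 8, rate = 250, length_s = 10, seed = 11)
  tf <- morlet_phase(seg, wavelet_config(freqs = 10))
  ss <- sliding_sync(tf, 251, 10)
  suppressMessages(pm <- psd_matrix(ss, 1))
  cl <- kmedoids_cluster(pm, k = 2)
  state <- attr(seg, "state")[ss$center_idx]
  # score agreement only on windows that lie fully within one dwell period
  full <- vapply(seq_along(ss$center_idx), function(i) {
    idx <- (ss$center_idx[i] - 125):(ss$center_idx[i] + 125)
    length(unique(attr(seg, "state")[idx])) == 1L
  }, TRUE)
  tab <- table(cl$labels[full], state[full])
  agree <- max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
  expect_gt(agree, 0.8)
})

test_that("cohort generation is reproducible with the designed cell count", {
  spec <- synth_spec(n_groups = 4, n_conditions = 3, subjects_per_group = 6,
                     segments_range = c(1, 2), n_channels = 4,
                     segment_length_s = 4, dwell_mean_s = 1,
                     dwell_cv = 0.5, slow_band_gain = 1, seed = 5)
  ds <- gen_study(spec)
  expect_equal(nrow(ds$design), 72)          # 4 groups x 3 conditions x 6
  expect_true(all(vapply(ds$segments, length, 0L) >= 1))
  ds2 <- gen_study(spec)
  expect_identical(ds$segments[[1]][[1]]$samples, ds2$segments[[1]][[1]]$samples)
  expect_error(synth_spec(freqs = c(4, 10), dwell_mean_s = 0.3), "dwell")
})

test_that("planted slow-band power gain appears in downstream spectra", {
  spec <- synth_spec(n_groups = 2, n_conditions = 1, subjects_per_group = 3,
                     segments_range = c(2, 2), n_channels = 4, rate = 250,
                     segment_length_s = 10, freqs = c(4, 10),
                     slow_band_gain = c(2, 1), dwell_mean_s = c(1, 1),
                     dwell_cv = 0.5, group_labels = c("hi", "lo"),
                     condition_labels = "REC", seed = 21)
  ds <- gen_study(spec)
  p4 <- function(g) {
    keys <- grep(g, names(ds$segments), value = TRUE)
    mean(unlist(lapply(keys, function(k) lapply(ds$segments[[k]], function(s)
      mean(power_spectrum(s)$power[, 4])))))
  }
  ratio <- p4("hi") / p4("lo")
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("longer time-in-state lowers the mean jump length downstream", {
  # Gamma dwells with dispersion cv spend a fraction 1 + cv^2 longer in a
  # state time-weighted, so raising cv at a fixed mean slows the measured
  # network walk; this is the planted "young-adult" dwell effect.
  mu_at <- function(cv, seed) {
    tp <- phasedyn:::random_topologies(8, 3, seed = seed)
    seg <- gen_switching_segment(tp, dwell_mean_s = 1.2, dwell_cv = cv,
                                 freqs = c(4, 10), snr = 4, rate = 250,
                                 length_s = 10, seed = seed)
    tf <- morlet_phase(seg, wavelet_config(freqs = c(4, 10)))
    mean(jl_grid(psd_matrix(sliding_sync(tf, 251, 10)))$mu, na.rm = TRUE)
  }
  short <- vapply(1:4, function(s)
    mean(vapply(0:2, function(k) mu_at(0.3, s + 500 * k), 0)), 0)
  long <- vapply(1:4, function(s)
    mean(vapply(0:2, function(k) mu_at(1.2, s + 700 * k), 0)), 0)
  expect_true(all(short > long))
})
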