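test_that("wavelet configuration satisfies the time-frequency identity", {
  cfg <- wavelet_config()
  expect_length(cfg$freqs, 10)
  expect_equal(cfg$sigma_t * cfg$sigma_f, rep(1 / (2 * pi), 10))
})

test_that("Morlet coefficients track amplitude and phase of sinusoids", {
  seg <- sinusoid_segment(10, rate = 250, length_s = 10)
  tf <- morlet_phase(seg, wavelet_config(freqs = c(8, 10)),
                     keep_coefficients = TRUE)
  mid <- 500:2000
  expect_equal(mean(Mod(tf$coefficients[1, mid, 2])), 1, tolerance = 0.01)
  dphi <- diff(tf$phase[1, mid, 2])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi), 2 * pi * 10 / 250, tolerance = 0.01)
  # quarter-cycle lag between two channels
  seg2 <- sinusoid_segment(10, rate = 250, length_s = 10, n_channels = 2,
                           phase = c(0, -pi / 2))
  tf2 <- morlet_phase(seg2, wavelet_config(freqs = 10))
  dd <- tf2$phase[1, mid, 1] - tf2$phase[2, mid, 1]
  dd <- (dd + pi) %% (2 * pi) - pi
  expect_equal(mean(dd), pi / 2, tolerance = 0.02)
  expect_error(morlet_phase(segment(matrix(rnorm(100), 1), 250),
                            wavelet_config(freqs = 2)), "longer than segment")
})

test_that("wavelet-filtered noise advances phase at the band center", {
  seg <- gen_iid_gaussian_segment(1, 5000, 250, seed = 8)
  tf <- morlet_phase(seg, wavelet_config(freqs = 10))
  dphi <- diff(tf$phase[1, 300:4700, 1])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  circ_mean <- atan2(mean(sin(dphi)), mean(cos(dphi)))
  expect_equal(circ_mean, 2 * pi * 10 / 250, tolerance = 0.15 * 2 * pi * 10 / 250)
})

test_that("circular correlation hits its closed-form limits", {
  set.seed(9)
  # mean-symmetric wrapped phases: the arithmetic window means of the
  # original and the (wrapped) antiphase window coincide, so the antiphase
  # limit is exact
  v <- runif(125, 0.1, 1.2)
  phi <- sample(c(v, -v))
  expect_equal(ccorr(phi, phi), 1)
  expect_equal(ccorr(phi, phi + pi), -1)
  expect_true(is.na(ccorr(rep(0.3, 50), runif(50))))
  expect_error(ccorr(1:5, 1:4), "equal length")
  # matches the independent formula oracle, arithmetic-mean convention pinned
  pj <- runif(250, -1, 1)
  expect_equal(ccorr(phi, pj), ccorr_oracle(phi, pj))
  expect_false(isTRUE(all.equal(ccorr(phi + 2, pj, "arithmetic"),
                                ccorr(phi + 2, pj, "circular"))))
})

test_that("independent phases decorrelate in 251-sample windows", {
  set.seed(10)
  hits <- 0L
  for (trial in 1:1000) {
    v <- ccorr(runif(251, -pi, pi), runif(251, -pi, pi))
    if (abs(v) < 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 950L)
})

test_that("sliding networks enumerate pairs and centers correctly", {
  seg <- gen_iid_gaussian_segment(19, 2500, 250, seed = 11)
  tf <- morlet_phase(seg, wavelet_config(freqs = 10))
  ss <- sliding_sync(tf, window_samples = 251, step_samples = 1)
  expect_equal(nrow(ss$values[[1]]), 171)
  expect_equal(length(ss$centers_s), 2250)      # N_t - L + 1
  expect_equal(ss$center_idx[1], 126)
  seg4 <- gen_iid_gaussian_segment(4, 1000, 250, seed = 12)
  tf4 <- morlet_phase(seg4, wavelet_config(freqs = 10))
  ss4 <- sliding_sync(tf4, 251, 25)
  expect_equal(nrow(ss4$values[[1]]), 6)
  # compiled kernel agrees with the scalar R implementation
  w1 <- tf4$phase[, 1:251, 1]
  expect_equal(ss4$values[[1]][, 1],
               c(ccorr(w1[1, ], w1[2, ]), ccorr(w1[1, ], w1[3, ]),
                 ccorr(w1[1, ], w1[4, ]), ccorr(w1[2, ], w1[3, ]),
                 ccorr(w1[2, ], w1[4, ]), ccorr(w1[3, ], w1[4, ])),
               tolerance = 1e-12)
})

test_that("synchronization norm obeys its bounds and degenerate cases", {
  ss <- list(values = list(matrix(1, 6, 5)), freqs = 10,
             centers_s = (1:5) / 10, center_idx = 1:5,
             window_samples = 3, step_samples = 1, rate = 10,
             segment_length_s = 1)
  class(ss) <- "sync_series"
  expect_true(all(ps_norm_series(ss) == 1))
  ss$values[[1]][] <- 0
  expect_true(all(ps_norm_series(ss) == 0))
  ss$values[[1]][] <- -0.4
  expect_true(all(abs(ps_norm_series(ss) - 0.4) < 1e-12))
  st <- ps_norm_stats(c(0, 1))
  expect_equal(st$mu, 0.5)
  expect_equal(st$sigma, sd(c(0, 1)))          # sample SD convention: 0.7071
  expect_equal(round(st$sigma, 4), 0.7071)
  expect_true(is.na(ps_norm_stats(c(NA, NA, 0.3))$mu))
})

test_that("|PS| lies in [0,1] and time reversal preserves its mean", {
  seg <- gen_switching_segment(list(c(1, 1, 2, 2)), dwell_mean_s = 1,
                               freqs = 10, length_s = 4, seed = 13)
  tf <- morlet_phase(seg, wavelet_config(freqs = 10))
  ss <- sliding_sync(tf, 251, 1)             # step 1: grids coincide on reversal
  ps <- ps_norm_series(ss)
  expect_true(all(ps >= 0 & ps <= 1, na.rm = TRUE))
  segr <- segment(seg$samples[, ncol(seg$samples):1, drop = FALSE], 250)
  tfr <- morlet_phase(segr, wavelet_config(freqs = 10))
  psr <- ps_norm_series(sliding_sync(tfr, 251, 1))
  # away from segment edges (convolution padding) the reversed series is the
  # mirror image of the original
  interior <- 100:(length(ps) - 100)
  expect_equal(ps[interior], rev(psr)[interior], tolerance = 1e-6)
})

test_that("switching coupling raises the norm's temporal variability", {
  stat_seg <- gen_switching_segment(list(c(1, 1, 2, 2, 3, 3)), dwell_mean_s = 2,
                                    freqs = 10, snr = Inf, seed = 14)
  sw_seg <- gen_switching_segment(list(c(1, 1, 2, 2, 3, 3), c(1, 2, 3, 1, 2, 3),
                                       c(3, 1, 1, 2, 2, 3)),
                                  dwell_mean_s = 0.8, freqs = 10, snr = Inf,
                                  seed = 14)
  sig <- function(seg) {
    tf <- morlet_phase(seg, wavelet_config(freqs = 10))
    ps_norm_stats(ps_norm_series(sliding_sync(tf, 251, 10)))$sigma
  }
  expect_gt(sig(sw_seg), sig(stat_seg))
})
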