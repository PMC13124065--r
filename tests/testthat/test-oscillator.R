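test_that("connectome normalization divides by the off-diagonal 95th percentile", {
  m <- matrix(4, 5, 5); diag(m) <- 0
  expect_true(all(normalize_connectome(m)[row(m) != col(m)] == 1))
  set.seed(26)
  w <- matrix(rexp(100), 10, 10); w <- (w + t(w)) / 2; diag(w) <- 0
  norm <- normalize_connectome(w)
  # independent percentile oracle: sorted off-diagonals, linear interpolation
  off <- sort(w[row(w) != col(w)])
  h <- (length(off) - 1) * 0.95 + 1
  q_oracle <- off[floor(h)] + (h - floor(h)) * (off[ceiling(h)] - off[floor(h)])
  expect_equal(norm, w / q_oracle, tolerance = 1e-12)
  expect_error(normalize_connectome(matrix(0, 4, 4)), "all off-diagonal")
  expect_error(normalize_connectome(matrix(-1, 3, 3)), "nonnegative")
})

test_that("the bundled synthetic connectome is a valid weight matrix", {
  w <- synthetic_connectome()
  expect_equal(dim(w), c(10L, 10L))
  expect_true(all(w >= 0))
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
})

test_that("the uncoupled noiseless oscillator rotates linearly", {
  w <- normalize_connectome(synthetic_connectome())
  tr <- simulate_oscillators(osc_params(w, a = 0, K = 0, Q = 0, seed = 1))
  t_s <- (seq_len(ncol(tr$theta)) - 1) / tr$rate
  pred <- sweep(outer(rep(1, 10), 2 * pi * 10 * t_s), 1, tr$theta[, 1], "+")
  expect_lt(max(abs(tr$theta - pred)), 1e-8)
  expect_equal(ncol(tr$theta), 10 * tr$rate)      # duration - transient
})

test_that("positive drift keeps phases strictly increasing at a = 0.5, K = 0", {
  w <- normalize_connectome(synthetic_connectome())
  tr <- simulate_oscillators(osc_params(w, a = 0.5, K = 0, Q = 0, seed = 2))
  expect_true(all(diff(t(tr$theta)) > 0))
})

test_that("simulation is deterministic given the seed", {
  w <- normalize_connectome(synthetic_connectome())
  p <- osc_params(w, a = 0.5, K = 2, Q = 0.01, seed = 3)
  expect_identical(simulate_oscillators(p)$theta, simulate_oscillators(p)$theta)
})

test_that("halving the integration step barely moves noiseless trajectories", {
  w <- normalize_connectome(synthetic_connectome())
  # short horizon: past a few seconds the (chaotic) coupled dynamics
  # amplifies any discretization difference regardless of step size
  run <- function(dt) simulate_oscillators(
    osc_params(w, a = 0.5, K = 2, Q = 0, dt = dt, duration = 3,
               output_rate = 100, seed = 4))
  th1 <- run(0.001)$theta
  th2 <- run(0.0005)$theta
  d <- (th1 - th2 + pi) %% (2 * pi) - pi
  expect_lt(sqrt(mean(d^2)) / (2 * pi), 0.05)     # circular RMS < 5%
})

test_that("the simulation pipeline has the designed geometry", {
  w <- normalize_connectome(synthetic_connectome())
  pipe <- sim_sync_pipeline(simulate_oscillators(osc_params(w, seed = 5)))
  expect_equal(nrow(pipe$sync$values[[1]]), 45)   # 10*9/2 connections
  expect_equal(length(pipe$sync$centers_s), 91)   # (10-1)/0.1 + 1 windows
  expect_equal(dim(pipe$psd$D), c(91L, 91L))
})

test_that("k-medoids recovers planted blocks exactly and degenerates cleanly", {
  bl <- block_distance(c(6, 5, 7))
  psd <- make_psd(bl$D, step_s = 0.1)
  cl <- kmedoids_cluster(psd, k = 3)
  expect_equal(length(unique(cl$labels)), 3)
  # exact block recovery up to label permutation
  expect_equal(length(unique(paste(cl$labels, bl$labels))), 3)
  expect_true(all(cl$medoids %in% seq_len(18)))
  # k equal to the window count: every window its own cluster at zero cost
  cl_n <- kmedoids_cluster(psd, k = 18)
  expect_equal(cl_n$cost, 0)
  expect_equal(sort(unique(cl_n$labels)), 1:18)
  expect_error(kmedoids_cluster(psd, k = 19), "k must be")
  # deterministic under a fixed seed
  expect_identical(kmedoids_cluster(psd, k = 3, seed = 2)$labels,
                   kmedoids_cluster(psd, k = 3, seed = 2)$labels)
  # invariant to window relabeling (up to label permutation)
  set.seed(27)
  perm <- sample(18)
  clp <- kmedoids_cluster(make_psd(bl$D[perm, perm], step_s = 0.1), k = 3)
  expect_equal(length(unique(paste(clp$labels, bl$labels[perm]))), 3)
})

test_that("initial medoids are honoured and cost never beats the optimum", {
  bl <- block_distance(c(4, 4))
  psd <- make_psd(bl$D, step_s = 0.1)
  cl_free <- kmedoids_cluster(psd, k = 2)
  cl_init <- kmedoids_cluster(psd, k = 2, init_medoids = c(1L, 5L))
  expect_lte(cl_free$cost, cl_init$cost + 1e-12)
  expect_equal(length(unique(paste(cl_init$labels, bl$labels))), 2)
})

test_that("medoid embedding maps medoids to 1 and equidistant windows to 0", {
  bl <- block_distance(c(3, 3), within = 0.2, between = 1)
  psd <- make_psd(bl$D, step_s = 0.1)
  emb <- medoid_embedding(psd, c(1L, 4L))
  expect_equal(unname(emb[1, 1]), 1)
  expect_equal(unname(emb[4, 2]), 1)
  # within-block windows load higher on their own medoid
  expect_true(all(emb[1:3, 1] > emb[1:3, 2]))
  expect_true(all(emb[4:6, 2] > emb[4:6, 1]))
  # a window at distance 1 from every medoid sits at the origin
  D <- bl$D; D[2, c(1, 4)] <- 1; D[c(1, 4), 2] <- 1
  expect_true(all(medoid_embedding(make_psd(D, step_s = 0.1), c(1L, 4L))[2, ] == 0))
  expect_error(medoid_embedding(psd, 99L), "out of bounds")
})

test_that("parameter sweeps tabulate cells and survive per-cell failures", {
  w <- normalize_connectome(synthetic_connectome())
  tab <- parameter_sweep(w, a_grid = 0.5, K_grid = 2, n_seeds = 1, seed0 = 10L)
  expect_equal(nrow(tab), 1)
  expect_false(tab$failed)
  expect_true(is.finite(tab$sigma_jl))
  # an impossible cell is marked failed without aborting the sweep
  expect_message(
    tab2 <- parameter_sweep(w, a_grid = c(0.5), K_grid = c(2), n_seeds = 1,
                            duration = 0.5),
    "failed")
  expect_true(tab2$failed)
})
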