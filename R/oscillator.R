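# oscillator_model module: connectome-coupled phase-oscillator network,
# simulation pipeline, k-medoids state clustering and parameter sweeps.

#' Normalize a connectome weight matrix
#'
#' Divides all weights by the 95th percentile (linear interpolation) of the
#' flattened off-diagonal entries.
#'
#' @param w_raw nonnegative square matrix.
#' @param probs percentile used for normalization (default 0.95).
#' @return normalized matrix of the same shape.
#' @export
normalize_connectome <- function(w_raw, probs = 0.95) {
  w_raw <- as.matrix(w_raw)
  if (!is_square(w_raw) || any(w_raw < 0))
    stop_param("connectome must be a nonnegative square matrix")
  off <- w_raw[row(w_raw) != col(w_raw)]
  q <- quantile(off, probs = probs, type = 7, names = FALSE)
  if (q <= 0) stop("connectome normalization undefined: all off-diagonal weights are zero")
  w_raw / q
}

#' Read a whitespace-delimited square connectome matrix
#'
#' @param path text file with an N x N numeric matrix.
#' @return numeric matrix.
#' @export
read_connectome <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (!is_square(m)) stop("format error: connectome file is not square")
  m
}

#' Bundled synthetic 10-node connectome
#'
#' A synthetic symmetric nonnegative weight matrix with a tractography-like
#' log-normal weight distribution (zero diagonal), shipped as plain text in
#' `inst/extdata/connectome10_synthetic.txt`. It is a stand-in constructed
#' for self-contained simulation runs, not an atlas-derived matrix.
#'
#' @return 10 x 10 numeric matrix (raw weights; normalize with
#'   [normalize_connectome()]).
#' @export
synthetic_connectome <- function() {
  read_connectome(system.file("extdata", "connectome10_synthetic.txt",
                              package = "phasedyn", mustWork = TRUE))
}

#' Oscillator-network parameters
#'
#' The network obeys
#' `dtheta_i/dt = omega * (1 - a cos(theta_i)
#'   + (1 - cos(theta_i)) (K/N) sum_j w_ij cos(theta_j) + Q eta_i(t))`
#' with `omega = 2*pi*f`. `a` controls the stability of the phase dynamics
#' (stability decreases as `a` grows), `K` the global coupling, `Q` the white
#' Gaussian noise strength.
#'
#' @param w symmetric nonnegative weight matrix, zero diagonal (normalized).
#' @param f center frequency in Hz (default 10).
#' @param a stability parameter.
#' @param K global coupling.
#' @param Q noise strength (default 0.01).
#' @param dt integration step in seconds (default 0.01, the published Euler
#'   step; see `noise` for the stochastic increment convention).
#' @param duration,transient total and discarded simulated time (s).
#' @param output_rate rate of the returned trajectories (samples/s); default
#'   100 (= 1/dt, no decimation). A finer grid needs a smaller `dt`.
#' @param noise `"literal"` (default) adds `dt * omega * Q * N(0,1)` per step,
#'   the direct Euler discretization of the model equation as written;
#'   `"em"` scales the Gaussian increments by `sqrt(dt)` (Euler-Maruyama SDE
#'   convention, which makes the effective noise intensity dt-invariant but,
#'   at Q = 0.01, roughly tenfold stronger per unit time).
#' @param seed integer seed (initial phases uniform on (-pi, pi] and noise).
#' @return an `osc_params` list.
#' @export
osc_params <- function(w, f = 10, a = 0.5, K = 2, Q = 0.01, dt = 0.01,
                       duration = 11, transient = 1, output_rate = 100,
                       noise = c("literal", "em"), seed = 1L) {
  noise <- match.arg(noise)
  w <- as.matrix(w)
  if (!is_square(w) || any(w < 0) || any(abs(diag(w)) > 1e-12) ||
      max(abs(w - t(w))) > 1e-9)
    stop_param("w must be symmetric nonnegative with zero diagonal")
  stopifnot(dt > 0, duration > transient, output_rate > 0)
  if (abs(1 / (dt * output_rate) - round(1 / (dt * output_rate))) > 1e-9)
    stop_param("1/dt must be an integer multiple of output_rate")
  structure(list(w = w, n = nrow(w), f = f, omega = 2 * pi * f, a = a, K = K,
                 Q = Q, dt = dt, duration = duration, transient = transient,
                 output_rate = output_rate, noise = noise,
                 seed = as.integer(seed)),
            class = "osc_params")
}

#' Simulate the phase-oscillator network
#'
#' Euler(-Maruyama) integration, transient discarded, phases kept on the
#' output-rate grid (every `1/(dt*output_rate)`-th integration sample).
#' Deterministic given the seed.
#'
#' @param params an [osc_params()].
#' @return a `phase_traj`: list with `theta` (nodes x samples, unwrapped),
#'   `rate`, and the `params` record.
#' @export
simulate_oscillators <- function(params) {
  stopifnot(inherits(params, "osc_params"))
  set.seed(params$seed)
  theta0 <- runif(params$n, -pi, pi)
  n_steps <- as.integer(round(params$duration / params$dt))
  traj <- euler_phase_sim_cpp(theta0, params$omega, params$a, params$K,
                              params$w, params$Q, params$dt, n_steps,
                              params$noise == "em")
  dec <- as.integer(round(1 / (params$dt * params$output_rate)))
  keep <- seq(1L, ncol(traj), by = dec)
  theta <- traj[, keep, drop = FALSE]
  drop_n <- as.integer(round(params$transient * params$output_rate))
  n_out <- as.integer(round((params$duration - params$transient) *
                              params$output_rate))
  theta <- theta[, drop_n + seq_len(n_out), drop = FALSE]
  structure(list(theta = theta, rate = params$output_rate, params = params),
            class = "phase_traj")
}

#' Synchronization/PSD pipeline on simulated phases
#'
#' Sliding circular correlation directly on the (wrapped) oscillator phases
#' (no wavelet step), with the simulation conventions: 1-s window in 100-ms
#' steps (100/10 samples at the default 100 samples/s trajectory grid), then
#' the correlation-distance matrix.
#'
#' @param traj a `phase_traj`.
#' @param window_s,step_s window geometry in seconds.
#' @return list with `sync` (a `sync_series`) and `psd` (a `psd_matrix`).
#' @export
sim_sync_pipeline <- function(traj, window_s = 1, step_s = 0.1) {
  phi <- wrap_phase(traj$theta)
  rownames(phi) <- paste0("n", seq_len(nrow(phi)))
  ss <- sliding_sync(phi, window_samples = as.integer(round(window_s * traj$rate)),
                     step_samples = as.integer(round(step_s * traj$rate)),
                     rate = traj$rate)
  ss$freqs <- traj$params$f
  list(sync = ss, psd = psd_matrix(ss, 1L))
}

#' k-medoids clustering of network states from a PSD matrix
#'
#' Partitioning-around-medoids (`cluster::pam`) on the precomputed
#' correlation-distance matrix.
#'
#' @param psd a `psd_matrix`.
#' @param k number of clusters (>= 2).
#' @param init_medoids optional initial medoid window indices.
#' @param seed seed (pam's build step is deterministic; the seed guards any
#'   sampling in large-matrix mode).
#' @return a `cluster_result`: `k`, `medoids` (window indices), `labels`,
#'   `cost` (sum of within-cluster distances to the medoid).
#' @export
kmedoids_cluster <- function(psd, k, init_medoids = NULL, seed = 1L) {
  D <- psd$D
  n <- ncol(D)
  if (k < 2L || k > n) stop_param("k must be in [2, number of windows]")
  if (anyNA(D)) stop_param("PSD matrix has flagged windows; drop them before clustering")
  if (k == n)           # every window its own cluster
    return(structure(list(k = k, medoids = seq_len(n), labels = seq_len(n),
                          cost = 0), class = "cluster_result"))
  set.seed(as.integer(seed))
  fit <- cluster::pam(stats::as.dist(D), k = k, medoids = init_medoids,
                      diss = TRUE, cluster.only = FALSE)
  medoids <- as.integer(fit$id.med)
  labels <- as.integer(fit$clustering)
  cost <- sum(D[cbind(seq_len(n), medoids[labels])])
  structure(list(k = k, medoids = medoids, labels = labels, cost = cost),
            class = "cluster_result")
}

#' Embed windows in medoid-correlation coordinates
#'
#' Coordinate `k` of window `t` is `1 - D[t, m_k]`: the correlation of its
#' network to the k-th medoid's network. A medoid's own coordinate equals 1.
#'
#' @param psd a `psd_matrix`.
#' @param medoids window indices of the medoids.
#' @return windows x k coordinate matrix.
#' @export
medoid_embedding <- function(psd, medoids) {
  n <- ncol(psd$D)
  if (any(medoids < 1L | medoids > n)) stop("medoid index out of bounds")
  emb <- 1 - psd$D[, medoids, drop = FALSE]
  colnames(emb) <- paste0("m", seq_along(medoids))
  emb
}

#' Sweep the (a, K) parameter plane
#'
#' For every (a, K, seed) cell: simulate, run the synchronization/PSD
#' pipeline, and summarize jump-length statistics (mean over the 1-2 s
#' timescale grid). Failed cells are logged and marked, the sweep continues.
#'
#' @param w normalized connectome.
#' @param a_grid,K_grid parameter grids (defaults as in the published sweep).
#' @param n_seeds simulations per cell (seeds 1..n_seeds offset by `seed0`).
#' @param seed0 seed offset.
#' @param ... overrides passed to [osc_params()].
#' @return tidy data.frame (a, K, seed, mu_jl, sigma_jl, k_jl, failed).
#' @export
parameter_sweep <- function(w, a_grid = c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 1),
                            K_grid = c(0, 0.1, 1, 2, 5, 10, 100),
                            n_seeds = 1, seed0 = 0L, ...) {
  stopifnot(length(a_grid) >= 1, length(K_grid) >= 1)
  grid <- expand.grid(a = a_grid, K = K_grid, seed = seed0 + seq_len(n_seeds))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    out <- tryCatch({
      p <- osc_params(w, a = row$a, K = row$K, seed = row$seed, ...)
      pipe <- sim_sync_pipeline(simulate_oscillators(p))
      g <- jl_grid(pipe$psd)
      s <- jl_summary(g)
      data.frame(row, mu_jl = s$mu, sigma_jl = s$sigma, k_jl = s$k,
                 failed = FALSE)
    }, error = function(e) {
      message("sweep cell (a=", row$a, ", K=", row$K, ", seed=", row$seed,
              ") failed: ", conditionMessage(e))
      data.frame(row, mu_jl = NA_real_, sigma_jl = NA_real_, k_jl = NA_real_,
                 failed = TRUE)
    })
    out
  })
  do.call(rbind, res)
}
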