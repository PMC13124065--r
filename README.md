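# phasedyn

Switching dynamics of EEG phase-synchronization networks, with
mean-centered Task-PLS inference and a connectome-coupled phase-oscillator
model.

## The problem

Across the lifespan, brain signal variability changes along two distinct
trajectories: slow-frequency power and long-timescale variability decline
monotonically with age, while the *temporal organization* of functional
network reconfiguration — how the pattern of inter-channel phase
synchronization dwells and jumps over seconds — follows an inverted U, with
young adults showing the slowest yet most heterogeneous network switching.
Averaged, stationary EEG summaries cannot see the second trajectory;
time-resolved network metrics can. `phasedyn` is an R implementation of
that analysis chain for anyone studying time-resolved EEG functional
connectivity in cohort designs: segment-level variability metrics,
millisecond-resolved synchronization networks, their switching statistics,
multivariate group×condition inference, and a generative oscillator model
that reproduces the dynamic regimes.

## The metrics

For each artifact-free, mean-centered 10-s segment (250 samples/s):

* **Univariate**: Welch power spectrum `P`; multiscale SD `σ(s)`; multiscale
  sample entropy with fixed tolerance (*MSE*) and with per-scale tolerance
  (*MSEn*), over coarse-graining factors 1–25.
* **Phase synchronization**: complex Morlet phase `φ(t,f)` (cycle number 7,
  f = 2–20 Hz); the circular correlation coefficient over a sliding 1.004-s
  window (251 samples, full overlap) for all channel pairs
  (19 channels → 171 connections):

      CCorr_ij = Σ sin(φ_i − φ̄_i) sin(φ_j − φ̄_j) /
                 sqrt( Σ sin²(φ_i − φ̄_i) · Σ sin²(φ_j − φ̄_j) )

  and the network norm `|PS(t,f)| = sqrt(mean_k CCorr_k²)` with its time
  mean `μ|PS|` and SD `σ|PS|`.
* **Switching dynamics**: the correlation-distance matrix
  `PSD(t1,t2,f) = 1 − corr(PS(t1,f), PS(t2,f))` between the networks at
  every pair of window centers; its τ-diagonals are jump-length sequences
  `JL(τ,f)` (τ = 1.004–2.000 s), summarized by mean `μ_JL` (reconfiguration
  speed), SD `σ_JL` (heterogeneity) and Pearson kurtosis `k_JL`
  (leptokurtic ⇒ switching: many tiny and a few huge jumps).
* **Inference**: mean-centered Task-PLS — SVD of the grand-mean-centered
  group×condition cell-mean matrix (a 4×3 design gives 11 latent
  variables), permutation test on singular values, bootstrap ratios
  (threshold 2.5758 ≈ two-tailed 99%) and 95% CIs for normalized brain
  scores.
* **Model**: N = 10 phase oscillators,
  `dθ_i/dt = ω(1 − a·cosθ_i + (1−cosθ_i)(K/N)Σ w_ij cosθ_j + Q·η_i)`,
  coupled by a 95th-percentile-normalized connectome; (a, K) sweeps,
  k-medoids clustering of network states, medoid-correlation embedding.

Because no public recording accompanies the original analysis, the package
ships a seeded synthetic-cohort generator (`synth_spec()` / `gen_study()`)
with planted slow-band power and network-dwell effects, so the entire chain
is testable end to end.

## Worked example

Generate a small synthetic cohort in which the "YA"-like group has the
longest, most dispersed network dwell times, run the switching-dynamics
pipeline, and test the group contrast:

```r
library(phasedyn)

spec <- synth_spec(n_groups = 4, n_conditions = 2, subjects_per_group = 6,
                   segments_range = c(3, 3), n_channels = 8,
                   freqs = c(4, 10), condition_labels = c("REC", "AOT"),
                   seed = 42)
ds <- gen_study(spec)
ds
#> <study_dataset> 4 groups x 2 conditions, 48 (subject,condition) cells, 144 segments

m <- study_metrics(ds, cfg = wavelet_config(freqs = c(4, 10)),
                   window_samples = 251L, step_samples = 10L)
block <- data_block_from_tidy(m$mu_jl)
fit <- mc_task_pls(block, ds$design, n_perm = 500, n_boot = 300, seed = 1)
fit
#> <pls_model> 7 LVs over 50 elements
#>  LV singular_value cov_explained  perm_p
#>   1       0.884300     7.686e-01 0.02994
#>   2       0.433700     1.849e-01 0.10180
#>   3       0.204700     4.120e-02 0.00998
#>   ...

group_score_ci(fit, lv = 1)
#>   group    mean     lo     hi
#> 1    YC -0.0632 -0.229  0.102
#> 2    OC  0.1012 -0.109  0.286
#> 3    YA -0.4359 -0.631 -0.257
#> 4    OA  0.3979  0.206  0.579
```

The first latent variable is significant (permutation p ≈ 0.03) and
explains ~77% of the covariance between the μ_JL grid and the design. Its
group-level brain-score interval for YA, [−0.63, −0.26], does not overlap
any other group's — the planted long-dwell group is reliably separated, on
the side of *smaller* mean jump lengths, i.e. slower network switching.

The simulation side:

```r
w <- normalize_connectome(synthetic_connectome())
sweep <- parameter_sweep(w, a_grid = 0.5, K_grid = c(0.1, 2, 100), n_seeds = 5)
aggregate(sigma_jl ~ K, data = sweep, FUN = mean)
#>       K   sigma_jl
#> 1   0.1 0.05349881
#> 2   2.0 0.20357094
#> 3 100.0 0.14125475
```

Jump-length variability peaks at intermediate coupling (K = 2): weak
coupling keeps the network near one attractor (suppressed dynamics), strong
coupling saturates it into fast, small reconfigurations, and the
intermediate, metastable regime produces the heterogeneous switching that
mirrors the young-adult dynamics.

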