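---
title: "Quantifying switching dynamics of EEG phase-synchronization networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying switching dynamics of EEG phase-synchronization networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasedyn)
```

## The problem

Scalp EEG is rich in moment-to-moment variability that averaged, stationary
summaries (band power, channel SD) cannot fully describe. A complementary
view treats the brain as moving through a repertoire of transient
synchronization "states": at each moment the channels form a weighted
network of pairwise phase synchronization, and over seconds this network
reconfigures — sometimes dwelling, sometimes jumping. `phasedyn` implements
an analysis chain that quantifies both the stationary facets of EEG
variability (spectra, multiscale SD and entropy) and the *dynamics* of the
synchronization network itself, and ties either kind of metric to a
group-by-condition study design through mean-centered Task Partial Least
Squares (mc-Task-PLS). A companion generative model — a small network of
connectome-coupled phase oscillators — reproduces the dynamic regime the
empirical metrics are sensitive to.

The chain is:

1. ingest multichannel recordings, select a montage, downsample, and cut
   artifact-free mean-centered segments (`read_recording()`,
   `select_channels()`, `downsample()`, `make_segments()`);
2. per segment, extract instantaneous phase with complex Morlet wavelets
   (`morlet_phase()`) and compute the circular correlation coefficient for
   every channel pair in a sliding window (`sliding_sync()`) — the
   "functional network movie";
3. summarize the movie two ways: the magnitude of synchronization over time
   (`ps_norm_series()` / `ps_norm_stats()`), and the correlation-distance
   matrix between the network at every pair of time windows
   (`psd_matrix()`), whose lag diagonals are sequences of "jump lengths" —
   how far the network topology moved over that timescale
   (`jump_lengths()`, `jl_grid()`);
4. feed the per-subject metric grids into mc-Task-PLS (`mc_task_pls()`)
   with permutation and bootstrap inference;
5. optionally, simulate the phase-oscillator network (`osc_params()`,
   `simulate_oscillators()`, `parameter_sweep()`) and cluster its network
   states (`kmedoids_cluster()`, `medoid_embedding()`).

## Phase synchronization and its dynamics

**Phase extraction.** Each channel is convolved with complex Morlet kernels
of cycle number `c = 7` at center frequencies 2–20 Hz in 2 Hz steps (ten
bins). The kernel at frequency $f$ has temporal SD $\sigma_t = c/(2\pi f)$
and spectral SD $\sigma_f = f/c$, so $\sigma_t\sigma_f = 1/(2\pi)$.
Amplitude normalization is chosen so a unit-amplitude sinusoid at $f$ yields
unit coefficient magnitude; the phase $\varphi(t,f)$ is the argument of the
coefficient. Convolution runs in the frequency domain with zero padding;
windows contaminated by segment edges are excluded later by the jump-length
trimming rule rather than by shortening the phase series.

**Circular correlation (CCorr).** For channels $i, j$ and a window of
length $L$ centered at $t$,

$$\mathrm{CCorr}_{ij}(t,f) =
\frac{\sum \sin(\varphi_i - \bar\varphi_i)\,\sin(\varphi_j - \bar\varphi_j)}
     {\sqrt{\sum \sin^2(\varphi_i - \bar\varphi_i)\,
            \sum \sin^2(\varphi_j - \bar\varphi_j)}},$$

with $\bar\varphi$ a per-window phase reference. The reference is the
*arithmetic sample mean* of the wrapped phase, which is what the defining
equation states; the circular mean — the convention of the circular
statistics literature — is available via `mean_type = "circular"` in
`ccorr()`/`sliding_sync()`. The two differ when phases wrap within a
window; the arithmetic default is pinned by regression tests. Values are 1
for in-phase, −1 for antiphase, near 0 for unsynchronized pairs. A window
with zero deviation energy (constant phase) makes the statistic undefined;
such values are flagged `NA`, never silently replaced. The EEG convention is
a 1.004 s window (251 samples at 250 samples/s) sliding one sample at a
time; 19 montage channels give 171 connections.

**Network norm.** $|PS(t,f)| = \sqrt{N_{con}^{-1}\sum_k
\mathrm{CCorr}^2_k(t,f)}$ summarizes overall synchronization magnitude; its
time mean $\mu_{|PS|}$ and SD $\sigma_{|PS|}$ per frequency are stationary
network metrics.

**Switching dynamics.** The topology-only reconfiguration is measured by
the correlation distance between the connection vectors at two windows:
$PSD(t_1,t_2,f) = 1 - \mathrm{corr}(PS(t_1,f), PS(t_2,f))$, a symmetric
zero-diagonal matrix with entries in $[0,2]$ that is invariant to uniform
rescaling of the networks. The $\tau$-diagonal is the jump-length sequence
$JL(\tau,f)$; the package summarizes it by its mean (speed of network
reconfiguration), SD (heterogeneity of reconfiguration), and Pearson
kurtosis $m_4/m_2^2$ with population moments (a normal sequence gives 3;
values above 3 — over-represented very small and very large jumps — are the
signature of switching between dwells). No small-sample kurtosis correction
is applied: the EEG sequences are ~2000 points long, and the uncorrected
ratio is the convention under which "normal = 3" holds exactly in
expectation at large n.

**Timescale grid and edge trimming.** Timescales default to
$\tau \in [1.004, 2.000]$ s in one window-center step (0.004 s at full
overlap; 250 values), i.e. lags spanning roughly one to two windows of
non-overlap. Jump lengths keep only pairs whose *both* window centers lie
at least 0.5 s from the segment boundaries — the geometric reading of the
published trimming range, which excludes wavelet edge effects
symmetrically; the literal printed range is available via
`trim = "printed"` in `jump_lengths()`.

## Univariate variability metrics

Per segment and channel the package computes: a Welch power spectrum
(averaged modified periodograms, Hann taper, 1 s windows, 50% overlap, so a
1 Hz grid; the integrated density recovers the channel variance);
multiscale SD (SD of the block-averaged series at coarse-graining factors
1–25, i.e. 4–100 ms at 250 samples/s); and multiscale sample entropy.
Coarse-graining is classic non-overlapping block averaging — the
"downsampling with a low-pass FIR" description of that operation — and
`sample_entropy()` uses the Richman–Moorman counting convention (both
template sets span the first $n-m$ points, self-matches excluded), so a
constant series gives exactly 0. The tolerance is $r = r_{frac}\cdot SD$
with $m = 2$, $r_{frac} = 0.5$ by default; the defaults are configuration,
not constants, because the reference parameterization is not fixed by the
analysis itself. Two tolerance modes produce the two entropy curves: *MSE*
fixes $r$ at scale 1 ($r_{frac}\times$ SD of the raw series), *MSEn*
re-anchors $r$ to each coarse scale's own SD, equivalent to z-scoring every
coarse series; MSEn thereby removes the trivial entropy decline that
follows from block-averaging shrinking the SD. Undefined entropies (no
template matches) propagate as flagged missing values into the PLS stage.

## Mean-centered Task-PLS

For each metric, rows are (subject, condition) observations and columns are
metric elements (channel × scale, frequency, or τ × frequency). Cell means
over subjects are computed per group × condition cell, the grand mean over
cells is removed column-wise, and the centered cell matrix is decomposed by
SVD into paired task saliences (contrast over cells), brain saliences
(element loadings) and singular values; a `g` groups × `c` conditions
design yields `g·c − 1` latent variables, and LV `l` accounts for
$S_l^2/\sum S^2$ of the covariance. Inference:

* **Permutation test** on the singular values: observation rows are
  reassigned to cells without replacement (default unrestricted
  exchangeability; `scheme = "within_subject"` shuffles condition labels
  within subjects when group membership should be preserved), with the
  add-one estimator $p = (\#\{S^{perm} \ge S^{obs}\} + 1)/(n_{perm}+1)$ so
  p is never exactly zero. Default 1000 permutations.
* **Bootstrap** for element reliability: subjects are resampled with
  replacement within each cell; each replicate's saliences are aligned to
  the observed solution by Procrustes rotation before accumulating, because
  SVD axes reflect and rotate across resamples. The bootstrap ratio
  (observed scaled salience / SD of aligned replicates) is compared to
  2.5758, the two-tailed 99% normal critical value. Default 500 replicates.
  95% percentile CIs are reported for normalized cell-mean brain scores
  (cell scores mean-centered across cells and divided by the singular
  value), and `group_score_ci()` aggregates the replicate draws to
  group-level intervals — two groups whose intervals do not overlap are
  reliably separated by the contrast.
* **Missing elements** are excluded pairwise from cell means; elements
  missing in more than 20% of rows are dropped with a message.

## The phase-oscillator network model

Ten oscillators with center frequency $f = 10$ Hz obey

$$\frac{d\theta_i}{dt} = \omega\Big(1 - a\cos\theta_i +
(1-\cos\theta_i)\,\frac{K}{N}\sum_{j\ne i} w_{ij}\cos\theta_j +
Q\,\eta_i(t)\Big),$$

with $\omega = 2\pi f$, stability parameter $a$ (stability decreases as $a$
grows), global coupling $K$, white Gaussian noise of strength $Q = 0.01$,
and symmetric nonnegative weights $w_{ij}$ normalized by the 95th
percentile (linear interpolation) of the off-diagonal entries. The bundled
10-node matrix is synthetic, with a tractography-like log-normal weight
distribution; any whitespace-delimited square matrix can be supplied
instead.

**Numerical convention.** The equation places the noise inside the
$\omega(\cdot)$ factor without fixing a discretization. The package's
default integrates with the plain Euler scheme at $dt = 10$ ms and adds
$dt\,\omega Q\,\eta$ per step — the direct discretization of the equation
as written. The alternative Euler–Maruyama reading (increment
$\omega Q\sqrt{dt}\,\eta$, `noise = "em"`), whose noise intensity is
dt-invariant, injects roughly ten times more phase diffusion per unit time
at $Q = 0.01$ (≈0.63 rad/s vs ≈0.063 rad/s). We examined both: under the
literal convention the network exhibits the metastable regime of interest —
state dwells of ~1 s punctuated by reconfigurations, with the variability
of jump lengths peaking at intermediate coupling ($K = 2$) and suppressed
at weak ($K = 0.1$) and strong ($K = 100$) coupling — whereas the stronger
EM noise washes the dwell structure out. The literal convention is
therefore the default; `dt`, `output_rate` and `noise` remain parameters.
Initial phases are uniform on $(-\pi,\pi]$, seeded; the first second is
discarded as transient.

The simulated phases enter the same synchronization pipeline directly (no
wavelet step; the state variable *is* a phase), with a 1 s window sliding
in 100 ms steps and $\tau \in [1,2]$ s, giving 45 connections and 91 window
centers for a 10 s trajectory. `parameter_sweep()` covers the published
$(a, K)$ grids ($a \in \{0, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 1\}$,
$K \in \{0, 0.1, 1, 2, 5, 10, 100\}$); `kmedoids_cluster()` (backed by
`cluster::pam` on the precomputed distance matrix) extracts network states,
and `medoid_embedding()` maps each window to its correlation with the
medoid networks, so a medoid's own coordinate is exactly 1.

## The synthetic cohort generator

Because no public recording accompanies the analysis, `gen_study()`
produces seeded cohorts with the statistical structure the pipeline
assumes: 4 age-like groups × 3 conditions, 24–31 subjects per group, 5–25
ten-second segments per subject × condition at 250 samples/s, and 19
channels by default. Channels are sums of band-limited oscillations over a
spectrally shaped $1/f$ background (exponent 1, SNR 4 by default). Pairwise
coupling follows a latent topology: channels in the same community share a
slowly wandering phase (random walk, SD 0.05 rad/sample) plus small
independent AR(1) phase jitter, so within-community circular correlation is
high and cross-community pairs are unsynchronized. The active topology
switches at gamma-distributed dwell times (mean/CV parameterization —
strictly positive and with independently tunable dispersion, which is what
the planted dwell-dispersion effect manipulates).

Two effects are planted. A per-group *power gain* on the 2–8 Hz components
(defaults 2.0, 1.6, 1.2, 1.0 across the four groups) emulates the monotonic
decline of slow power with age: a gain ratio of 2 between extreme groups
yields a downstream 4 Hz power ratio near 2 (slightly diluted by the
shared background). Per-group *dwell parameters* (means 0.6, 0.8, 1.5,
0.9 s; CVs 0.5, 0.5, 1.0, 0.6) emulate the inverted-U of network-switching
tempo: the young-adult-like third group dwells longest and most variably,
hence the lowest mean jump length with the most heterogeneous dynamics.
The dwell means sit between roughly half a second and 1.5 s — the order of
the timescale window the jump-length analysis probes — and respect the
constraint that a dwell must exceed two cycles of the slowest oscillation
to be visible to the phase estimator. Note that what the mean jump length
tracks is the *time-weighted* dwell, `mean * (1 + cv^2)` for gamma dwells
(time in a state is dominated by the long dwells): raising the dispersion
at a fixed mean slows the measured network walk, and dwells much shorter
than the 1-s window are blurred by window averaging rather than producing
ever-faster walks. The young-adult-like group's weighted dwell (3.0 s) is
2.5-4x that of the other groups (0.75-1.2 s), which is what makes its mean
jump length order lowest.

What the generator does **not** emulate: volume conduction and a common
reference (which inflate zero-lag correlations in real scalp data),
realistic spectra beyond a single $1/f$ exponent, artifacts, or
channel-position geometry. Passing tests on synthetic cohorts therefore
demonstrates that the pipeline recovers planted effects of realistic size
through the full metric-plus-inference chain, not that any particular
empirical effect exists in real recordings.

## Numerical choices and degenerate inputs

* Downsampling uses a zero-phase FIR low-pass (cutoff 0.8× the target
  Nyquist, forward–backward filtering) before decimation, avoiding phase
  distortion that would bias phase-based metrics.
* Undefined values (constant phase windows, constant network vectors,
  entropies without template matches, kurtosis of constant sequences) are
  flagged `NA` and propagate explicitly; `ps_norm_series()` tolerates at
  most 5% undefined connections per window before flagging the window.
* SVD sign convention: the largest-magnitude element of each brain salience
  is positive; bootstrap replicates are Procrustes-aligned to the observed
  axes before variability is measured.
* Quantiles (connectome normalization, bootstrap CIs) use R's default
  linear-interpolation definition (type 7).
* `kmedoids_cluster()` with `k` equal to the number of windows returns the
  trivial partition at zero cost; `k` beyond that is an error.
* Tests and the acceptance script run the cohort analysis at reduced size —
  8 channels, two frequency bins (4 and 10 Hz), 12 subjects per group, 5
  segments per cell, a 10-sample sliding step, and 300 permutations /
  bootstrap replicates — which we chose as the smallest design at which the
  planted contrasts are recovered with comfortable margins; the model
  defaults (19 channels, 10 bins, full overlap, 1000/500 resamples) are
  what an empirical analysis would use.

## Known limitations

* The EDF and BrainVision readers are minimal (16-bit continuous EDF;
  binary multiplexed BrainVision in float32/int16) — enough for typical
  exports, not for annotation channels or variable-rate signals.
* With full-overlap windows the jump-length sequences are strongly
  autocorrelated; their summary statistics are well-defined, but no
  effective-sample-size correction is attempted (none is part of the
  analysis the package implements).
* The permutation scheme treats all rows as exchangeable by default; where
  subjects contribute repeated conditions, the within-subject scheme is
  provided but the joint subject-and-group exchangeability structure is not
  modeled further.
* The oscillator model is a minimal mechanism probe: ten nodes, one
  frequency, phase-only dynamics. It reproduces regime orderings, not
  quantitative EEG values.
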