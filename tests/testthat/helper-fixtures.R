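# Shared fixtures and independent oracles (brute-force implementations kept
# deliberately naive; they check the optimized paths).

sinusoid_segment <- function(freq, rate = 250, length_s = 10, n_channels = 1,
                             phase = 0, amp = 1) {
  tt <- (seq_len(round(rate * length_s)) - 1) / rate
  x <- do.call(rbind, lapply(seq_len(n_channels), function(i)
    amp * cos(2 * pi * freq * tt + phase[min(i, length(phase))])))
  segment(x, rate = rate, center = FALSE)
}

# O(n^2) all-pairs sample-entropy oracle (Richman-Moorman counting).
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  B <- 0; A <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Direct circular-correlation formula (arithmetic window mean), kept
# independent of the package implementation.
ccorr_oracle <- function(pi_, pj_) {
  si <- sin(pi_ - mean(pi_)); sj <- sin(pj_ - mean(pj_))
  sum(si * sj) / sqrt(sum(si^2) * sum(sj^2))
}

# Construct a psd_matrix object directly from a distance matrix.
make_psd <- function(D, step_s = 1, segment_length_s = nrow(D) * step_s + 2,
                     centers_s = NULL, freq = 10) {
  n <- nrow(D)
  structure(list(D = D,
                 centers_s = centers_s %||% (seq_len(n) * step_s),
                 step_s = step_s, segment_length_s = segment_length_s,
                 freq = freq), class = "psd_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Block-structured distance matrix: small within, large between.
block_distance <- function(sizes, within = 0.1, between = 1) {
  lab <- rep(seq_along(sizes), sizes)
  D <- matrix(between, length(lab), length(lab))
  D[outer(lab, lab, "==")] <- within
  diag(D) <- 0
  list(D = D, labels = lab)
}

# Small pure-noise PLS data block for calibration tests.
noise_block <- function(n_groups = 4, n_conditions = 3, n_subj = 5,
                        n_elem = 20, seed = 1) {
  set.seed(seed)
  groups <- paste0("G", seq_len(n_groups))
  conds <- paste0("C", seq_len(n_conditions))
  rows <- expand.grid(subject = seq_len(n_subj), group = groups,
                      condition = conds, stringsAsFactors = FALSE)
  rows$subject <- paste(rows$group, rows$subject, sep = "_")
  x <- matrix(rnorm(nrow(rows) * n_elem), nrow(rows), n_elem)
  list(block = data_block(x, rows$subject, rows$group, rows$condition,
                          paste0("e", seq_len(n_elem))),
       design = study_design(rows[, c("subject", "group", "condition")],
                             groups = groups, conditions = conds))
}

# Planted monotonic group effect on the first n_hit elements.
planted_block <- function(effect = 2, n_groups = 4, n_conditions = 3,
                          n_subj = 5, n_elem = 20, n_hit = 5, seed = 1) {
  nb <- noise_block(n_groups, n_conditions, n_subj, n_elem, seed)
  g_idx <- match(nb$block$group, attr(nb$design, "groups"))
  shift <- effect * (g_idx - mean(g_idx)) / stats::sd(g_idx)
  nb$block$x[, seq_len(n_hit)] <- nb$block$x[, seq_len(n_hit)] + shift
  # cell-level contrast in design_cells order (group-major)
  nb$planted <- scale(rep(seq_len(n_groups), each = n_conditions))[, 1]
  nb
}
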