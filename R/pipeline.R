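# pipeline_cli module: end-to-end orchestration from a single config, with
# manifests and reproducible seeds. The function interface (run_analysis /
# run_simulation_study) is the entry point; configs are plain lists or JSON.

config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 268435456   # djb2 mod 2^28
  sprintf("%07x", h)
}

#' Synchronization-dynamics metrics for one segment
#'
#' Runs the full per-segment pipeline: Morlet phase at each frequency,
#' sliding circular-correlation networks, the synchronization-norm series
#' and its time statistics, and jump-length statistics on the
#' timescale x frequency grid.
#'
#' @param seg an `eeg_segment`.
#' @param cfg a [wavelet_config()].
#' @param window_samples,step_samples sliding-window geometry.
#' @param taus jump-length timescales (s); default [tau_grid()] at the
#'   window-center step.
#' @param edge_s edge trim for jump lengths (s).
#' @return list with `ps` (data.frame freq, mu, sigma) and `jl` (a
#'   [jl_grid()] data.frame).
#' @export
segment_sync_metrics <- function(seg, cfg = wavelet_config(),
                                 window_samples = 251L, step_samples = 1L,
                                 taus = NULL, edge_s = 0.5) {
  tf <- morlet_phase(seg, cfg)
  ss <- sliding_sync(tf, window_samples = window_samples,
                     step_samples = step_samples)
  ps <- ps_norm_stats(ps_norm_series(ss))
  ps <- data.frame(freq = cfg$freqs, mu = ps$mu, sigma = ps$sigma)
  grid <- jl_grid(psd_matrix(ss), taus = taus, edge_s = edge_s)
  list(ps = ps, jl = grid)
}

#' Segment-level metric tables for a whole study dataset
#'
#' Computes [segment_sync_metrics()] for every segment and returns tidy
#' per-metric tables ready for [data_block_from_tidy()] /
#' [mc_task_pls()] (replicate segments are averaged there).
#'
#' @param dataset a `study_dataset` from [gen_study()] (or an equivalent
#'   list with `design` and `segments`).
#' @param ... passed to [segment_sync_metrics()].
#' @return named list of tidy data.frames (`mu_ps`, `sigma_ps`, `mu_jl`,
#'   `sigma_jl`, `k_jl`), each with columns subject, group, condition,
#'   segment, element, value.
#' @export
study_metrics <- function(dataset, ...) {
  rows <- list(ps = list(), jl = list())
  for (key in names(dataset$segments)) {
    for (seg in dataset$segments[[key]]) {
      m <- segment_sync_metrics(seg, ...)
      meta <- data.frame(subject = seg$subject_id, group = seg$group_label,
                         condition = seg$condition_label,
                         segment = seg$segment_index, stringsAsFactors = FALSE)
      rows$ps[[length(rows$ps) + 1L]] <- cbind(meta, m$ps)
      rows$jl[[length(rows$jl) + 1L]] <- cbind(meta, m$jl)
    }
  }
  ps <- do.call(rbind, rows$ps)
  jl <- do.call(rbind, rows$jl)
  tidy <- function(df, col, elem) {
    out <- df[, c("subject", "group", "condition", "segment")]
    out$element <- elem
    out$value <- df[[col]]
    out
  }
  list(mu_ps = tidy(ps, "mu", sprintf("f%g", ps$freq)),
       sigma_ps = tidy(ps, "sigma", sprintf("f%g", ps$freq)),
       mu_jl = tidy(jl, "mu", sprintf("f%g_tau%.3f", jl$freq, jl$tau)),
       sigma_jl = tidy(jl, "sigma", sprintf("f%g_tau%.3f", jl$freq, jl$tau)),
       k_jl = tidy(jl, "k", sprintf("f%g_tau%.3f", jl$freq, jl$tau)))
}

read_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$seed)) stop_param("config validation: 'seed' is required")
  config
}

#' Run the full analysis pipeline from a config
#'
#' Synthesizes (or ingests) a cohort, computes the synchronization-dynamics
#' metrics for every segment, fits one mean-centered Task-PLS per metric and
#' writes tidy tables, PLS summaries and a manifest to `out_dir`.
#'
#' Config fields: `seed` (required); `synth` (arguments to [synth_spec()])
#' or `design_csv` (+ recordings referenced by its `path` column);
#' `wavelet` (`freqs`, `cycles`); `window_samples`, `step_samples`, `taus`;
#' `pls` (`n_perm`, `n_boot`); `metrics` (subset of names returned by
#' [study_metrics()]); `out_dir` (optional; no files written when absent).
#'
#' @param config list or path to a JSON config.
#' @return list with `metrics` (tidy tables), `pls` (one `pls_model` per
#'   metric) and `manifest`, invisibly written to `out_dir` if given.
#' @export
run_analysis <- function(config) {
  config <- read_config(config)
  if (!is.null(config$synth)) {
    spec <- do.call(synth_spec, c(config$synth, list(seed = config$seed)))
    dataset <- gen_study(spec)
  } else if (!is.null(config$design_csv)) {
    design <- read_design(config$design_csv)
    segs <- list()
    for (r in seq_len(nrow(design))) {
      rec <- read_recording(design$path[r], subject_id = design$subject[r],
                            group_label = design$group[r],
                            condition_label = design$condition[r])
      if (!is.null(config$channels)) rec <- select_channels(rec, config$channels)
      if (!is.null(config$rate) && config$rate != rec$rate)
        rec <- downsample(rec, config$rate)
      key <- paste(design$subject[r], design$condition[r], sep = ".")
      segs[[key]] <- make_segments(rec, config$segment_length_s %||% 10)
    }
    dataset <- list(design = design, segments = segs)
  } else stop_param("config validation: provide 'synth' or 'design_csv'")
  wl <- config$wavelet %||% list()
  cfg <- wavelet_config(freqs = wl$freqs %||% seq(2, 20, by = 2),
                        cycles = wl$cycles %||% 7)
  metrics <- study_metrics(dataset, cfg = cfg,
                           window_samples = config$window_samples %||% 251L,
                           step_samples = config$step_samples %||% 1L,
                           taus = config$taus)
  which_metrics <- config$metrics %||% names(metrics)
  pls_cfg <- config$pls %||% list()
  pls_seeds <- derive_seeds(config$seed, length(which_metrics))
  fits <- list()
  for (i in seq_along(which_metrics)) {
    m <- which_metrics[i]
    block <- data_block_from_tidy(cbind(metrics[[m]]))
    fits[[m]] <- mc_task_pls(block, dataset$design,
                             n_perm = pls_cfg$n_perm %||% 1000,
                             n_boot = pls_cfg$n_boot %||% 500,
                             seed = pls_seeds[i])
  }
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   n_segments = sum(vapply(dataset$segments, length, 0L)),
                   metrics = which_metrics,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res <- list(dataset = dataset, metrics = metrics, pls = fits,
              manifest = manifest)
  if (!is.null(config$out_dir)) write_analysis(res, config$out_dir)
  invisible(res)
}

write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(res$metrics))
    write.csv(res$metrics[[m]], file.path(out_dir, paste0("metric_", m, ".csv")),
              row.names = FALSE)
  for (m in names(res$pls)) {
    fit <- res$pls[[m]]
    summ <- data.frame(lv = seq_along(fit$s), singular_value = fit$s,
                       cov_explained = fit$cov_explained, perm_p = fit$perm_p)
    write.csv(summ, file.path(out_dir, paste0("pls_", m, "_lv.csv")),
              row.names = FALSE)
    write.csv(as.data.frame(fit$boot$ratios),
              file.path(out_dir, paste0("pls_", m, "_bsr.csv")))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the oscillator simulation study from a config
#'
#' Parameter sweep over the (a, K) plane plus (optionally) clustering and
#' medoid embedding of a focal cell.
#'
#' Config fields: `seed` (required); `connectome` (path; default the bundled
#' synthetic matrix); `a_grid`, `K_grid`, `n_seeds`; `focal` (list `a`, `K`,
#' `k`, optional `init_medoids`) for the clustering step; `sim` (overrides
#' for [osc_params()]); `out_dir`.
#'
#' @param config list or path to a JSON config.
#' @return list with `sweep` (tidy table), optional `cluster`, `embedding`,
#'   `psd`, and `manifest`.
#' @export
run_simulation_study <- function(config) {
  config <- read_config(config)
  w_raw <- if (is.null(config$connectome)) synthetic_connectome()
           else read_connectome(config$connectome)
  w <- normalize_connectome(w_raw)
  sim <- config$sim %||% list()
  sweep <- do.call(parameter_sweep,
                   c(list(w = w,
                          a_grid = config$a_grid %||% c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 1),
                          K_grid = config$K_grid %||% c(0, 0.1, 1, 2, 5, 10, 100),
                          n_seeds = config$n_seeds %||% 1,
                          seed0 = config$seed), sim))
  out <- list(sweep = sweep)
  if (!is.null(config$focal)) {
    fc <- config$focal
    p <- do.call(osc_params, c(list(w = w, a = fc$a %||% 0.5, K = fc$K %||% 2,
                                    seed = config$seed), sim))
    pipe <- sim_sync_pipeline(simulate_oscillators(p))
    cl <- kmedoids_cluster(pipe$psd, k = fc$k %||% 3,
                           init_medoids = fc$init_medoids, seed = config$seed)
    out$psd <- pipe$psd
    out$cluster <- cl
    out$embedding <- medoid_embedding(pipe$psd, cl$medoids)
  }
  out$manifest <- list(config_hash = config_hash(config), seed = config$seed,
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(sweep, file.path(config$out_dir, "sweep.csv"), row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
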