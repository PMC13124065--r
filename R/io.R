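# io_design module: recordings, channel selection, resampling, segmentation.

#' Standard 19-electrode 10-20 montage
#'
#' Default channel selection used before the phase-synchronization analysis
#' (19 channels give 171 unordered pairs). Configurable in every function
#' that takes a channel list.
#' @export
MONTAGE_1020_19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                     "T7", "C3", "Cz", "C4", "T8",
                     "P7", "P3", "Pz", "P4", "P8", "O1", "O2")

#' Construct a multichannel recording
#'
#' @param samples channels x time numeric matrix (microvolts).
#' @param rate sampling rate, samples/s.
#' @param channel_labels character vector, one label per channel row.
#' @param subject_id,group_label,condition_label metadata strings.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(samples, rate, channel_labels,
                      subject_id = NA_character_, group_label = NA_character_,
                      condition_label = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples))
    stop_param("recording samples must be a numeric matrix without missing values")
  if (length(channel_labels) != nrow(samples))
    stop_param("number of channel labels (", length(channel_labels),
               ") does not match number of channel rows (", nrow(samples), ")")
  if (!is.numeric(rate) || rate <= 0) stop_param("rate must be > 0")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate = rate,
                 channel_labels = as.character(channel_labels),
                 subject_id = subject_id, group_label = group_label,
                 condition_label = condition_label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, ncol(x$samples) / x$rate))
  invisible(x)
}

#' Construct an analysis segment
#'
#' A fixed-length, mean-centered multichannel epoch: the atomic analysis
#' unit. Each channel is centered to zero mean.
#'
#' @param samples channels x time matrix.
#' @inheritParams recording
#' @param segment_index integer position of the segment within its recording.
#' @param center mean-center each channel (default TRUE).
#' @return object of class `eeg_segment`.
#' @export
segment <- function(samples, rate, channel_labels = rownames(samples),
                    subject_id = NA_character_, group_label = NA_character_,
                    condition_label = NA_character_, segment_index = 1L,
                    center = TRUE) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (center) samples <- samples - rowMeans(samples)
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate = rate, n_t = ncol(samples),
                 channel_labels = as.character(channel_labels),
                 subject_id = subject_id, group_label = group_label,
                 condition_label = condition_label,
                 segment_index = as.integer(segment_index)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz [%s/%s/%s #%d]\n",
              nrow(x$samples), x$n_t, x$rate, x$subject_id, x$group_label,
              x$condition_label, x$segment_index))
  invisible(x)
}

#' Read a multichannel recording from disk
#'
#' Supported formats: 16-bit EDF, BrainVision (`.vhdr` + binary `.eeg`,
#' multiplexed IEEE float 32 or signed int 16), and a plain numeric
#' channels x time matrix (CSV, no header) with a JSON sidecar
#' `{"rate": ..., "labels": [...]}` of the same basename.
#'
#' @param path file path.
#' @param format_hint one of "auto", "csv", "edf", "brainvision".
#' @param ... metadata passed to [recording()].
#' @return an `eeg_recording` with channels in file order.
#' @export
read_recording <- function(path, format_hint = c("auto", "csv", "edf", "brainvision"), ...) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  if (format_hint == "auto") {
    format_hint <- switch(tolower(tools::file_ext(path)),
                          edf = "edf", vhdr = "brainvision", csv = "csv",
                          stop_param("cannot infer format of '", path,
                                     "'; pass format_hint"))
  }
  switch(format_hint,
         edf = read_edf(path, ...),
         brainvision = read_brainvision(path, ...),
         csv = read_matrix_recording(path, ...))
}

read_matrix_recording <- function(path, ...) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("format error: missing JSON sidecar '", sidecar, "' for plain-matrix recording")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$rate) || is.null(meta$labels))
    stop("format error: sidecar must provide 'rate' and 'labels'")
  x <- as.matrix(read.csv(path, header = FALSE))
  dimnames(x) <- NULL
  if (nrow(x) != length(meta$labels))
    stop("format error: ", length(meta$labels), " labels for ", nrow(x), " channel rows")
  recording(x, rate = meta$rate, channel_labels = meta$labels, ...)
}

#' Write a plain-matrix recording (CSV + JSON sidecar)
#'
#' @param rec an `eeg_recording`.
#' @param path output CSV path; the sidecar takes the same basename.
#' @return `path`, invisibly.
#' @export
write_matrix_recording <- function(rec, path) {
  utils::write.table(rec$samples, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(rate = rec$rate, labels = rec$channel_labels),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Subset and reorder channels
#'
#' @param rec an `eeg_recording` or `eeg_segment`.
#' @param names ordered channel labels to keep; defaults to the 19-channel
#'   10-20 montage [MONTAGE_1020_19].
#' @return object of the same class with channels in the requested order.
#' @export
select_channels <- function(rec, names = MONTAGE_1020_19) {
  missing <- setdiff(names, rec$channel_labels)
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  rec$samples <- rec$samples[match(names, rec$channel_labels), , drop = FALSE]
  rec$channel_labels <- as.character(names)
  rec
}

#' Anti-aliased integer-factor downsampling
#'
#' Zero-phase FIR low-pass (cutoff 0.8 x target Nyquist, `filtfilt`) followed
#' by decimation. The source rate must be an integer multiple of the target.
#'
#' @param rec an `eeg_recording`.
#' @param target_rate desired rate, samples/s.
#' @param fir_order FIR filter order (default 64).
#' @return downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_rate, fir_order = 64) {
  q <- rec$rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop_param("rate ", rec$rate, " is not an integer multiple of target ", target_rate)
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  b <- signal::fir1(fir_order, 0.8 / q, type = "low")
  filt <- t(apply(rec$samples, 1L, function(ch) signal::filtfilt(b, ch)))
  keep <- seq(1L, ncol(rec$samples), by = q)
  rec$samples <- filt[, keep, drop = FALSE]
  rownames(rec$samples) <- rec$channel_labels
  rec$rate <- target_rate
  rec
}

#' Cut a recording into fixed-length mean-centered segments
#'
#' Consecutive, non-overlapping segments from the start of the recording;
#' the trailing remainder is dropped. Each channel is mean-centered within
#' its segment. Samples overlapping an optional artifact mask exclude the
#' whole segment.
#'
#' @param rec an `eeg_recording`.
#' @param segment_length_s segment length in seconds (default 10).
#' @param artifact_mask optional logical vector (length = recording samples);
#'   TRUE marks artifact samples.
#' @return list of `eeg_segment`; empty (with a warning) if the recording is
#'   shorter than one segment.
#' @export
make_segments <- function(rec, segment_length_s = 10, artifact_mask = NULL) {
  n_t <- as.integer(round(segment_length_s * rec$rate))
  total <- ncol(rec$samples)
  n_seg <- total %/% n_t
  if (n_seg == 0L) {
    warning("recording (", total, " samples) shorter than one segment (", n_t, ")")
    return(list())
  }
  out <- vector("list", n_seg)
  kept <- 0L
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1L) * n_t + 1L):(s * n_t)
    if (!is.null(artifact_mask) && any(artifact_mask[idx])) next
    kept <- kept + 1L
    out[[kept]] <- segment(rec$samples[, idx, drop = FALSE], rate = rec$rate,
                           channel_labels = rec$channel_labels,
                           subject_id = rec$subject_id,
                           group_label = rec$group_label,
                           condition_label = rec$condition_label,
                           segment_index = kept)
  }
  out[seq_len(kept)]
}

#' Read a study-design table
#'
#' CSV with header columns `subject,group,condition` and optionally `path`.
#'
#' @param path CSV path.
#' @param groups,conditions optional explicit factor orderings; default is
#'   order of first appearance.
#' @return a `study_design`: data.frame plus ordered `groups`/`conditions`
#'   attributes.
#' @export
read_design <- function(path, groups = NULL, conditions = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  study_design(df, groups = groups, conditions = conditions)
}

#' Construct a study design
#'
#' @param df data.frame with columns `subject`, `group`, `condition` (and
#'   optionally `path`).
#' @inheritParams read_design
#' @export
study_design <- function(df, groups = NULL, conditions = NULL) {
  need <- c("subject", "group", "condition")
  if (!all(need %in% names(df)))
    stop_param("design table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("subject", "condition")]))
    stop_param("duplicate (subject, condition) rows in design")
  groups <- groups %||% unique(df$group)
  conditions <- conditions %||% unique(df$condition)
  if (length(groups) * length(conditions) < 2L)
    stop_param("design needs groups x conditions >= 2 (>=1 degree of freedom)")
  structure(df, class = c("study_design", "data.frame"),
            groups = as.character(groups), conditions = as.character(conditions))
}

design_cells <- function(design) {
  g <- attr(design, "groups"); cn <- attr(design, "conditions")
  data.frame(group = rep(g, each = length(cn)),
             condition = rep(cn, times = length(g)),
             stringsAsFactors = FALSE)
}
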