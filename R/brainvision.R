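# Minimal BrainVision reader (multiplexed binary, IEEE_FLOAT_32 / INT_16).

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list(); channels <- character()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("^\\[|\\]$", "", ln); next }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (section == "Channel Infos") channels[key] <- val else kv[[paste(section, key)]] <- val
  }
  list(kv = kv, channels = channels)
}

#' Read a BrainVision recording
#'
#' Supports binary, multiplexed data in IEEE_FLOAT_32 or INT_16 format.
#'
#' @param path path to the `.vhdr` header file.
#' @param ... metadata passed to [recording()].
#' @return an `eeg_recording`.
#' @export
read_brainvision <- function(path, ...) {
  hdr <- parse_vhdr(path)
  kv <- hdr$kv
  get <- function(k) kv[[k]] %||% stop("format error: missing '", k, "' in ", path)
  if (toupper(get("Common Infos DataFormat")) != "BINARY")
    stop("format error: only BINARY BrainVision data supported")
  if (toupper(get("Common Infos DataOrientation")) != "MULTIPLEXED")
    stop("format error: only MULTIPLEXED orientation supported")
  n_ch <- as.integer(get("Common Infos NumberOfChannels"))
  rate <- 1e6 / as.numeric(get("Common Infos SamplingInterval"))
  fmt <- toupper(get("Binary Infos BinaryFormat"))
  # channel lines: <name>,<ref>,<resolution>,<unit>
  parts <- strsplit(hdr$channels, ",", fixed = TRUE)
  labels <- vapply(parts, `[`, "", 1L)
  resol <- suppressWarnings(vapply(parts, function(p) as.numeric(p[3L]), 0))
  resol[is.na(resol)] <- 1
  if (length(labels) != n_ch)
    stop("format error: ", length(labels), " channel lines for NumberOfChannels=", n_ch)
  datafile <- file.path(dirname(path), get("Common Infos DataFile"))
  if (!file.exists(datafile)) stop("cannot read BrainVision data file: ", datafile)
  sz <- file.size(datafile)
  con <- file(datafile, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    n_val <- sz %/% 4L
    x <- readBin(con, "double", n = n_val, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    n_val <- sz %/% 2L
    x <- readBin(con, "integer", n = n_val, size = 2L, signed = TRUE, endian = "little")
  } else stop("format error: unsupported BinaryFormat ", fmt)
  n_t <- n_val %/% n_ch
  m <- matrix(x[seq_len(n_t * n_ch)], nrow = n_ch)   # multiplexed: channels fastest
  m <- m * resol
  recording(m, rate = rate, channel_labels = labels, ...)
}

#' Write an `eeg_recording` in BrainVision format (float32, multiplexed)
#'
#' @param rec an `eeg_recording`.
#' @param path path of the `.vhdr` file to create; `.eeg`/`.vmrk` share the
#'   basename.
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  base <- tools::file_path_sans_ext(basename(path))
  dir <- dirname(path)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(rec$samples)),
           paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$samples)), rec$channel_labels))
  writeLines(hdr, path)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", base, ".eeg")),
             file.path(dir, paste0(base, ".vmrk")))
  con <- file(file.path(dir, paste0(base, ".eeg")), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 4L, endian = "little")
  invisible(path)
}
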