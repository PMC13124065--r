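# Minimal 16-bit EDF reader/writer (continuous recordings, no annotations).

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a (16-bit) EDF recording
#'
#' Minimal continuous-EDF reader: all signals must share one sampling rate.
#'
#' @param path EDF file.
#' @param ... metadata passed to [recording()].
#' @return an `eeg_recording` with samples rescaled to physical units.
#' @export
read_edf <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (version != "0") stop("format error: not an EDF file (version '", version, "')")
  invisible(readBin(con, "raw", 160L))            # patient + recording id
  invisible(readBin(con, "raw", 16L))             # date + time
  invisible(read_ascii(con, 8L))                  # header bytes
  invisible(readBin(con, "raw", 44L))             # reserved
  n_rec <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("format error: bad signal count in EDF header")
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16L)
  invisible(field(80L))                           # transducer
  invisible(field(8L))                            # physical dimension
  pmin <- as.numeric(field(8L)); pmax <- as.numeric(field(8L))
  dmin <- as.numeric(field(8L)); dmax <- as.numeric(field(8L))
  invisible(field(80L))                           # prefiltering
  spr <- as.integer(field(8L))                    # samples per record
  invisible(field(32L))                           # reserved
  if (length(unique(spr)) != 1L)
    stop("format error: signals with heterogeneous sampling rates not supported")
  rate <- spr[1L] / rec_dur
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      gain <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      out[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- (dig - dmin[s]) * gain + pmin[s]
    }
  }
  recording(out, rate = rate, channel_labels = labels, ...)
}

pad_ascii <- function(x, w) {
  x <- substr(format(x, scientific = FALSE, trim = TRUE), 1L, w)
  formatC(x, width = w, flag = "-")
}

#' Write an `eeg_recording` as 16-bit EDF
#'
#' One data record per second (trailing remainder padded with the physical
#' minimum is avoided by requiring whole-second recordings).
#'
#' @param rec an `eeg_recording`; its duration must be a whole number of
#'   seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  if (n %% rec$rate != 0)
    stop_param("EDF writer requires a whole number of seconds")
  n_rec <- as.integer(n / rec$rate)
  spr <- as.integer(rec$rate)
  phys_lo <- apply(rec$samples, 1L, min)
  phys_hi <- apply(rec$samples, 1L, max)
  flat <- phys_hi - phys_lo < 1e-12
  phys_hi[flat] <- phys_lo[flat] + 1      # avoid zero gain for constant channels
  dmin <- -32768L; dmax <- 32767L
  hdr_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, width) writeBin(charToRaw(pad_ascii(x, width)), con)
  w("0", 8L); w("X", 80L); w("X", 80L)
  w("01.01.20", 8L); w("00.00.00", 8L)
  w(hdr_bytes, 8L); w("", 44L); w(n_rec, 8L); w(1, 8L); w(ns, 4L)
  for (lab in rec$channel_labels) w(lab, 16L)
  for (i in seq_len(ns)) w("", 80L)
  for (i in seq_len(ns)) w("uV", 8L)
  for (i in seq_len(ns)) w(signif(phys_lo[i], 7), 8L)
  for (i in seq_len(ns)) w(signif(phys_hi[i], 7), 8L)
  for (i in seq_len(ns)) w(dmin, 8L)
  for (i in seq_len(ns)) w(dmax, 8L)
  for (i in seq_len(ns)) w("", 80L)
  for (i in seq_len(ns)) w(spr, 8L)
  for (i in seq_len(ns)) w("", 32L)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      x <- rec$samples[s, ((r - 1L) * spr + 1L):(r * spr)]
      # re-read header-precision physical range so write/read round-trips
      lo <- as.numeric(pad_ascii(signif(phys_lo[s], 7), 8L))
      hi <- as.numeric(pad_ascii(signif(phys_hi[s], 7), 8L))
      dig <- as.integer(round((x - lo) / (hi - lo) * (dmax - dmin) + dmin))
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
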