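# Minimal European Data Format (EDF) support: 256-byte ASCII header,
# 256 bytes per signal of signal headers, then data records of little-endian
# 16-bit integers with linear physical scaling. Continuous recordings only,
# no annotation channels.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

.edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 8)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' The record duration is 1 s, so the sampling rate must be a whole number
#' and the signal is truncated to a whole number of seconds. Samples are
#' quantized onto a 16-bit grid spanning the per-channel amplitude range;
#' for signals already on an integer grid the round trip is exact.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  nrec <- floor(ncol(rec$samples) / fs)
  if (nrec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (nrec * fs != ncol(rec$samples))
    warning("signal truncated to ", nrec, " whole seconds for EDF export")
  ns <- nrow(rec$samples)
  x <- rec$samples[, seq_len(nrec * fs), drop = FALSE]

  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  gain <- (pmax - pmin) / (dmax - dmin)
  dig <- round((x - pmin) / gain) + dmin
  # re-derive the stored physical extrema from their 8-char ASCII rendering so
  # that reading back applies the identical affine map
  pmin_s <- vapply(pmin, .edf_num, character(1), width = 8)
  pmax_s <- vapply(pmax, .edf_num, character(1), width = 8)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(.edf_pad("0", 8))
  wr(.edf_pad(rec$subject_id, 80))
  wr(.edf_pad("wsqeeg export", 80))
  wr(.edf_pad("01.01.00", 8)); wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(256 * (1 + ns), 8))
  wr(.edf_pad("", 44))
  wr(.edf_pad(nrec, 8)); wr(.edf_pad(1, 8)); wr(.edf_pad(ns, 4))
  for (lb in rec$channel_labels) wr(.edf_pad(lb, 16))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(pmin_s[i])
  for (i in seq_len(ns)) wr(pmax_s[i])
  for (i in seq_len(ns)) wr(.edf_pad(dmin, 8))
  for (i in seq_len(ns)) wr(.edf_pad(dmax, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad(fs, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, idx, drop = FALSE])       # one signal after another
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param subject_id optional subject id; defaults to the patient field.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                   # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1] / recdur
  gain <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2L,
                   endian = "little", signed = TRUE)
    if (length(raw) < ns * spr[1]) stop("truncated EDF data record")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    out[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t(block)
  }
  out <- out * gain + (pmin - gain * dmin)
  eeg_recording(out, fs = fs, channel_labels = normalize_channel_labels(labels),
                subject_id = if (is.null(subject_id)) patient else subject_id)
}
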