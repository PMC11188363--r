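#' The 19 electrodes of the international 10-20 system
#'
#' Canonical montage used throughout the package, in the conventional
#' (legacy) naming with temporal electrodes T3/T4/T5/T6.
#'
#' @return Character vector of 19 channel labels.
#' @export
canonical_montage <- function() {
  c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "C3", "C4", "T3", "T4",
    "P3", "P4", "T5", "T6", "O1", "O2", "Fz", "Cz", "Pz")
}

# modern 10-10 synonyms mapped onto the legacy temporal names
.label_synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize channel labels to canonical 10-20 spelling
#'
#' Matching is case-insensitive and the modern temporal names T7/T8/P7/P8
#' are accepted as synonyms of T3/T4/T5/T6. Labels that do not belong to
#' the montage are returned with their original spelling.
#'
#' @param labels character vector of channel labels.
#' @return character vector of the same length.
#' @export
normalize_channel_labels <- function(labels) {
  canon <- canonical_montage()
  out <- vapply(labels, function(lb) {
    key <- toupper(trimws(lb))
    syn <- names(.label_synonyms)
    if (key %in% syn) return(unname(.label_synonyms[key]))
    hit <- match(key, toupper(canon))
    if (!is.na(hit)) canon[hit] else trimws(lb)
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Construct an EEG recording object
#'
#' @param samples numeric matrix, channels x time points (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `samples`.
#' @param reference_state `"original"` or `"common_average"`.
#' @param subject_id subject identifier string.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels,
                          reference_state = c("original", "common_average"),
                          subject_id = "") {
  reference_state <- match.arg(reference_state)
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (ncol(samples) < 1L) stop("recording must contain at least one sample")
  if (length(channel_labels) != nrow(samples))
    stop("one channel label per signal row is required")
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (anyNA(samples)) stop("missing samples are not supported")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels,
                 reference_state = reference_state,
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$reference_state))
  invisible(x)
}

#' Compare a recording's channel set against the 19-electrode 10-20 montage
#'
#' Order does not matter; labels are compared after canonicalization.
#' Problems are reported, never thrown.
#'
#' @param rec an `eeg_recording`.
#' @return Character vector of findings, `"missing: <label>"` or
#'   `"extra: <label>"`; empty when the montage is complete and exact.
#' @export
check_montage <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  have <- normalize_channel_labels(rec$channel_labels)
  want <- canonical_montage()
  miss <- setdiff(want, have)
  extra <- rec$channel_labels[!have %in% want]
  c(if (length(miss)) paste0("missing: ", miss),
    if (length(extra)) paste0("extra: ", extra))
}

#' Frequency band scheme for EEG analysis
#'
#' Default bands follow the clinical convention with half-open intervals:
#' delta \[1,4), theta \[4,8), alpha \[8,13), beta \[13,30) Hz inside a total
#' analysis band of \[1,45) Hz. Cross-frequency band pairs and the three
#' coherence bands (delta/theta combined, alpha, beta) are carried along.
#'
#' @param bands named list of `c(low, high)` Hz intervals.
#' @param total total analysis interval in Hz.
#' @param band_pairs list of 2-element character vectors naming band pairs.
#' @param coherence_bands named list of intervals for bi-channel coherence.
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(bands = list(delta = c(1, 4), theta = c(4, 8),
                                     alpha = c(8, 13), beta = c(13, 30)),
                        total = c(1, 45),
                        band_pairs = list(c("delta", "theta"), c("delta", "alpha"),
                                          c("delta", "beta"), c("theta", "alpha"),
                                          c("theta", "beta"), c("alpha", "beta")),
                        coherence_bands = list(delta_theta = c(1, 8),
                                               alpha = c(8, 13),
                                               beta = c(13, 30))) {
  for (b in bands) {
    stopifnot(length(b) == 2L, b[1] < b[2])
    if (b[1] < total[1] || b[2] > total[2]) stop("band outside total interval")
  }
  iv <- do.call(rbind, bands)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("bands must not overlap")
  for (p in band_pairs)
    if (!all(p %in% names(bands))) stop("band pair refers to unknown band")
  structure(list(bands = bands, total = total, band_pairs = band_pairs,
                 coherence_bands = coherence_bands),
            class = "band_scheme")
}
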