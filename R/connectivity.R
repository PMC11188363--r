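#' Magnitude-squared coherence spectrum of two signals
#'
#' Welch-style estimator: Hamming-tapered, mean-removed windows; the
#' cross-spectrum and both auto-spectra are averaged over windows before
#' forming `|Pxy|^2 / (Px Py)`, which is bounded in \[0, 1\]. At least two
#' windows are required (a single window gives identically 1).
#'
#' @param x,y equal-length numeric signals.
#' @param fs sampling rate, Hz.
#' @param window_s window length in seconds.
#' @param overlap window overlap fraction.
#' @return List with `freqs`, `coh` (values in \[0, 1\]) and `n_windows`.
#' @export
msc_spectrum <- function(x, y, fs, window_s = 2, overlap = 0.5) {
  if (length(x) != length(y)) stop("signals must have equal length")
  rec <- eeg_recording(rbind(x, y), fs, c("x", "y"))
  ep <- segment_epochs(rec, epoch_s = window_s, overlap_frac = overlap)
  if (n_epochs(ep) < 2L)
    stop("coherence needs at least two windows; single-window coherence is 1")
  Fx <- .windowed_fft(epoch_matrix(ep, 1L), fs)
  Fy <- .windowed_fft(epoch_matrix(ep, 2L), fs)
  Pxy <- rowMeans(Fx$X * Conj(Fy$X))
  Px <- rowMeans(abs(Fx$X)^2)
  Py <- rowMeans(abs(Fy$X)^2)
  coh <- ifelse(Px * Py > 0, abs(Pxy)^2 / (Px * Py), NA_real_)
  list(freqs = Fx$freqs, coh = pmin(1, coh), n_windows = n_epochs(ep))
}

#' Band-averaged coherence of two signals
#'
#' Mean of the magnitude-squared coherence over the bins with
#' `band[1] <= f < band[2]`.
#'
#' @inheritParams msc_spectrum
#' @param band `c(low, high)` in Hz.
#' @return Scalar in \[0, 1\].
#' @export
band_coherence <- function(x, y, fs, band, window_s = 2, overlap = 0.5) {
  cs <- msc_spectrum(x, y, fs, window_s, overlap)
  sel <- cs$freqs >= band[1] & cs$freqs < band[2]
  if (!any(sel)) stop("no frequency bins inside the band")
  mean(cs$coh[sel], na.rm = TRUE)
}

# all-pairs band coherences for one segment: windowed FFTs are computed once
# per channel and reused over the 171 pairs.
.segment_band_coherence <- function(rec, coherence_bands, window_s, overlap,
                                    trim_s) {
  ep <- segment_epochs(rec, epoch_s = window_s, overlap_frac = overlap,
                       trim_s = trim_s)
  if (n_epochs(ep) < 2L) stop("segment too short for coherence estimation")
  nch <- length(rec$channel_labels)
  Fs <- lapply(seq_len(nch), function(ch)
    .windowed_fft(epoch_matrix(ep, ch), rec$fs))
  freqs <- Fs[[1]]$freqs
  Pauto <- vapply(Fs, function(f) rowMeans(abs(f$X)^2), numeric(length(freqs)))
  sel <- lapply(coherence_bands, function(b) freqs >= b[1] & freqs < b[2])
  pairs <- utils::combn(nch, 2L)
  out <- matrix(NA_real_, length(coherence_bands), ncol(pairs),
                dimnames = list(names(coherence_bands), NULL))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    Pxy <- rowMeans(Fs[[i]]$X * Conj(Fs[[j]]$X))
    coh <- abs(Pxy)^2 / (Pauto[, i] * Pauto[, j])
    out[, k] <- vapply(sel, function(s) mean(pmin(1, coh[s])), numeric(1))
  }
  list(values = out, pairs = pairs)
}

#' Bi-channel coherence features for one subject
#'
#' Whole-segment Welch coherence with 2-s Hamming windows for every
#' unordered channel pair, averaged over the bins of each coherence band
#' (delta/theta combined, alpha, beta by default) and across segments.
#' Global features are unweighted means over the pairs. Names:
#' `coh.<band>.<chA>-<chB>` (channels in montage order) and
#' `coh.<band>.global`.
#'
#' @param segments list of preprocessed [eeg_recording()] segments.
#' @param scheme a [band_scheme()].
#' @param config a [qeeg_config()] list.
#' @return Named numeric vector of features.
#' @export
connectivity_features <- function(segments, scheme = band_scheme(),
                                  config = qeeg_config()) {
  labels <- segments[[1]]$channel_labels
  acc <- NULL; nseg <- 0L
  for (rec in segments) {
    sc <- .segment_band_coherence(rec, scheme$coherence_bands,
                                  config$epoch$length_s,
                                  config$coh$window_overlap,
                                  config$epoch$trim_s)
    acc <- if (is.null(acc)) sc$values else acc + sc$values
    pairs <- sc$pairs
    nseg <- nseg + 1L
  }
  m <- acc / nseg
  pair_lab <- paste0(labels[pairs[1, ]], "-", labels[pairs[2, ]])
  vals <- c()
  for (bn in rownames(m)) {
    v <- m[bn, ]
    names(v) <- paste0("coh.", bn, ".", pair_lab)
    vals <- c(vals, v, structure(mean(v, na.rm = TRUE),
                                 names = paste0("coh.", bn, ".global")))
  }
  vals
}
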