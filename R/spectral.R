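# Windowed one-sided FFT of an L x K epoch matrix: per-window mean removal,
# Hamming taper. Returns complex matrix (nfreq x K) plus the frequency grid
# and the taper power for PSD scaling.
.windowed_fft <- function(M, fs, detrend = TRUE) {
  L <- nrow(M)
  w <- signal::hamming(L)
  if (detrend) M <- sweep(M, 2L, colMeans(M))
  X <- stats::mvfft(M * w)
  nf <- L %/% 2L + 1L
  list(X = X[seq_len(nf), , drop = FALSE],
       freqs = (seq_len(nf) - 1L) * fs / L,
       U = sum(w^2), L = L)
}

.psd_scale <- function(fr, fs) {
  s <- rep(2 / (fs * fr$U), length(fr$freqs))
  s[1] <- s[1] / 2                                   # DC not doubled
  if (fr$L %% 2L == 0L) s[length(s)] <- s[length(s)] / 2  # Nyquist bin
  s
}

#' Welch power spectral density estimate
#'
#' Averages Hamming-tapered, mean-removed periodograms over the epochs of an
#' [segment_epochs()] result (or over internally segmented windows of a plain
#' numeric signal). With 2-s windows at 250 Hz the frequency resolution is
#' 0.5 Hz. One-sided density in units^2/Hz.
#'
#' @param x an `epoch_set` or a numeric vector.
#' @param channel channel label or index (epoch-set input only).
#' @param fs sampling rate (vector input only).
#' @param window_s,overlap window length (s) and overlap fraction used to
#'   segment a vector input.
#' @return An object of class `eeg_spectrum`: list with `freqs`, `power`,
#'   `n_windows`, `channel`.
#' @export
welch_psd <- function(x, channel = 1L, fs = NULL, window_s = 2,
                      overlap = 0.25) {
  if (inherits(x, "epoch_set")) {
    M <- epoch_matrix(x, channel)
    fs <- x$fs
    lab <- if (is.character(channel)) channel else x$channel_labels[channel]
  } else {
    if (is.null(fs)) stop("fs required for vector input")
    rec <- eeg_recording(matrix(x, nrow = 1L), fs, "x1")
    ep <- segment_epochs(rec, epoch_s = window_s, overlap_frac = overlap)
    M <- epoch_matrix(ep, 1L)
    lab <- "x1"
  }
  fr <- .windowed_fft(M, fs)
  pw <- rowMeans(abs(fr$X)^2) * .psd_scale(fr, fs)
  structure(list(freqs = fr$freqs, power = pw, n_windows = ncol(M),
                 channel = lab),
            class = "eeg_spectrum")
}

#' Sum of spectral power over a frequency band
#'
#' Sums PSD values over the bins with `band[1] <= f < band[2]` (half-open,
#' matching the band scheme convention).
#'
#' @param spec an `eeg_spectrum`.
#' @param band `c(low, high)` in Hz.
#' @return Nonnegative scalar.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "eeg_spectrum"), length(band) == 2L)
  sel <- spec$freqs >= band[1] & spec$freqs < band[2]
  if (!any(sel)) {
    warning("no frequency bins inside [", band[1], ", ", band[2], ") Hz")
    return(0)
  }
  sum(spec$power[sel])
}

#' Relative band power
#'
#' Band power divided by the power in the total analysis band (1-45 Hz by
#' default); scale-invariant, in \[0, 1\].
#'
#' @param spec an `eeg_spectrum`.
#' @param band `c(low, high)` in Hz.
#' @param total total band, default `c(1, 45)`.
#' @return Scalar in \[0, 1\].
#' @export
relative_power <- function(spec, band, total = c(1, 45)) {
  tot <- band_power(spec, total)
  if (tot <= 0) stop("zero total power in the analysis band")
  band_power(spec, band) / tot
}

# Per-channel relative powers for one preprocessed segment; rows = bands.
.segment_relative_powers <- function(rec, scheme, epoch_s, overlap, trim_s) {
  ep <- segment_epochs(rec, epoch_s = epoch_s, overlap_frac = overlap,
                       trim_s = trim_s)
  nb <- length(scheme$bands)
  out <- matrix(NA_real_, nb, length(rec$channel_labels),
                dimnames = list(names(scheme$bands), rec$channel_labels))
  for (ch in seq_along(rec$channel_labels)) {
    spec <- welch_psd(ep, ch)
    tot <- band_power(spec, scheme$total)
    if (tot > 0)
      out[, ch] <- vapply(scheme$bands, function(b) band_power(spec, b),
                          numeric(1)) / tot
  }
  out
}

#' Relative band-power features for one subject
#'
#' Computes Welch relative power per channel and band on every preprocessed
#' segment, averages across segments, and appends per-band global features
#' (the unweighted mean over channels, skipping channels with undefined
#' values). Feature names are `rp.<band>.<channel>` and `rp.<band>.global`.
#'
#' @param segments list of preprocessed [eeg_recording()] segments.
#' @param scheme a [band_scheme()].
#' @param config a [qeeg_config()] list.
#' @return Named numeric vector of features.
#' @export
spectral_features <- function(segments, scheme = band_scheme(),
                              config = qeeg_config()) {
  acc <- NULL
  for (rec in segments) {
    rp <- .segment_relative_powers(rec, scheme,
                                   config$epoch$length_s,
                                   config$epoch$overlap$spectral,
                                   config$epoch$trim_s)
    acc <- if (is.null(acc)) list(rp) else c(acc, list(rp))
  }
  num <- Reduce(`+`, lapply(acc, function(a) ifelse(is.na(a), 0, a)))
  den <- Reduce(`+`, lapply(acc, function(a) (!is.na(a)) + 0))
  m <- num / den
  m[den == 0] <- NA_real_
  vals <- c()
  for (b in rownames(m)) {
    v <- m[b, ]
    names(v) <- paste0("rp.", b, ".", colnames(m))
    vals <- c(vals, v, structure(mean(v, na.rm = TRUE),
                                 names = paste0("rp.", b, ".global")))
  }
  vals
}
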