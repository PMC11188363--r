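#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous across-channel mean from every channel.
#' Idempotent; preserves all pairwise channel differences exactly.
#'
#' @param rec an [eeg_recording()] with at least two channels.
#' @return The re-referenced recording with `reference_state = "common_average"`.
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2L)
    stop("common average reference requires at least two channels")
  rec$samples <- sweep(rec$samples, 2L, colMeans(rec$samples))
  rec$reference_state <- "common_average"
  rec
}

# Hamming-window FIR band-pass design. Order by the classic transition-width
# heuristic 3.3/(df/fs) for the narrower (lower) transition band, forced even
# so the filter has integer group delay.
.design_fir_bandpass <- function(fs, low_hz, high_hz) {
  df <- min(low_hz, max(1, (fs / 2 - high_hz) / 2))  # transition width, Hz
  ord <- ceiling(3.3 / (df / fs))
  if (ord %% 2L == 1L) ord <- ord + 1L
  signal::fir1(ord, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

# Zero-phase FIR application. The designed filter is linear-phase (symmetric
# taps), so a single pass with group-delay compensation is exactly zero-phase;
# edges are reflect-padded to suppress start-up transients. FFT convolution.
.filter_zero_phase <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  half <- (nh - 1L) %/% 2L
  if (n <= nh) stop("signal too short for the designed filter order")
  pad <- min(n - 1L, nh)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  m <- length(xp) + nh - 1L
  nf <- stats::nextn(m, 2)
  Y <- stats::fft(c(xp, rep(0, nf - length(xp)))) *
       stats::fft(c(h, rep(0, nf - nh)))
  y <- Re(stats::fft(Y, inverse = TRUE)) / nf
  y[(pad + half + 1L):(pad + half + n)]
}

#' Band-limit a recording with a zero-phase Hamming FIR filter
#'
#' Designs a Hamming-windowed linear-phase FIR band-pass (order from the
#' standard 3.3/transition-width rule) and applies it with group-delay
#' compensation and reflected-edge padding, so the output is zero-phase.
#' Pass-band ripple is below 1 percent and DC is removed.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below Nyquist.
#' @return The filtered recording.
#' @export
bandlimit_fir <- function(rec, low_hz = 1, high_hz = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (high_hz >= rec$fs / 2) stop("high_hz must be below the Nyquist frequency")
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  h <- .design_fir_bandpass(rec$fs, low_hz, high_hz)
  if (ncol(rec$samples) <= length(h))
    stop("signal too short for the designed filter order (", length(h) - 1L,
         " taps)")
  for (i in seq_len(nrow(rec$samples)))
    rec$samples[i, ] <- .filter_zero_phase(rec$samples[i, ], h)
  rec
}

#' Split a recording into fixed-length overlapping epochs
#'
#' Consecutive epoch start indices differ by `round(L * (1 - overlap_frac))`
#' samples; a trailing partial epoch is dropped. The returned object holds
#' the (possibly edge-trimmed) sample matrix plus the start-index bookkeeping
#' so that epochs are materialized lazily via [epoch_matrix()].
#'
#' @param rec an [eeg_recording()].
#' @param epoch_s epoch length in seconds.
#' @param overlap_frac overlap fraction in \[0, 1).
#' @param trim_s seconds removed from each end of the recording before
#'   epoching (edge-transient guard; 0 by default).
#' @return An object of class `epoch_set` with elements `samples`, `starts`,
#'   `L`, `fs`, `overlap_frac`, `channel_labels`.
#' @export
segment_epochs <- function(rec, epoch_s = 2, overlap_frac = 0.25, trim_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0,1)")
  L <- round(epoch_s * rec$fs)
  if (L < 2L) stop("epoch must contain at least 2 samples")
  x <- rec$samples
  drop <- round(trim_s * rec$fs)
  if (drop > 0) {
    if (ncol(x) <= 2L * drop + L) stop("recording too short after edge trimming")
    x <- x[, (drop + 1L):(ncol(x) - drop), drop = FALSE]
  }
  n <- ncol(x)
  if (n < L) stop("recording shorter than one epoch")
  step <- max(1L, round(L * (1 - overlap_frac)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  structure(list(samples = x, starts = starts, L = L, fs = rec$fs,
                 overlap_frac = overlap_frac,
                 channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' Number of epochs in an epoch set
#' @param ep an `epoch_set`.
#' @export
n_epochs <- function(ep) length(ep$starts)

#' Materialize the epochs of one channel as a matrix
#'
#' @param ep an `epoch_set`.
#' @param channel channel label or index.
#' @return Numeric matrix, `L` x number of epochs (one epoch per column).
#' @export
epoch_matrix <- function(ep, channel) {
  if (is.character(channel)) {
    channel <- match(channel, ep$channel_labels)
    if (is.na(channel)) stop("channel not present")
  }
  x <- ep$samples[channel, ]
  idx <- outer(0:(ep$L - 1L), ep$starts, `+`)
  matrix(x[idx], nrow = ep$L)
}
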