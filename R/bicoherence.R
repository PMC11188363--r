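# Wavelet bicoherence for quadratic phase coupling. A constant-bandwidth
# complex wavelet bank (Gaussian spectral kernel, 2 Hz FWHM at every center
# frequency) gives analytic coefficients W(f, t); quadratic phase coupling at
# (fp, fq) locks the phase of W(fp+fq) to the phase sum, making the
# time-averaged triple product large relative to its Cauchy-Schwarz bound.

#' Constant-bandwidth complex wavelet coefficient bank
#'
#' Filters the analytic signal through Gaussian spectral windows centered at
#' `freqs` with a fixed full width at half maximum of `bandwidth_hz`
#' (constant bandwidth, not constant Q). For a unit sinusoid at a center
#' frequency the coefficient magnitude is 1 at that frequency.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param freqs center frequencies (Hz); all must be below Nyquist.
#' @param bandwidth_hz spectral FWHM of each wavelet, Hz.
#' @return Complex matrix, time x frequency, with attributes `freqs` and
#'   `efold_samples` (edge-guard width: one envelope e-folding time).
#' @export
cwt_frequency_bank <- function(x, fs, freqs = 1:45, bandwidth_hz = 2) {
  n <- length(x)
  if (any(freqs >= fs / 2)) stop("center frequency above Nyquist")
  if (n < 2 * fs / min(freqs)) {
    # permit short epochs but require at least 2 s worth at typical rates
    if (n < 2) stop("signal too short")
  }
  # pad enough to absorb the wavelet's time support (few seconds at 2 Hz
  # bandwidth) without doubling the transform length for long signals
  nf <- stats::nextn(n + min(n, 4096L), c(2, 3))
  X <- stats::fft(c(x - mean(x), rep(0, nf - n)))
  f <- (0:(nf - 1L)) * fs / nf
  sigma <- bandwidth_hz / (2 * sqrt(2 * log(2)))
  pos <- f <= fs / 2
  W <- matrix(0 + 0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    H <- numeric(nf)
    H[pos] <- 2 * exp(-((f[pos] - freqs[j])^2) / (2 * sigma^2))
    W[, j] <- (stats::fft(X * H, inverse = TRUE) / nf)[seq_len(n)]
  }
  # envelope e-folding time of the Gaussian wavelet: sqrt(2) * sigma_t
  sigma_t <- 1 / (2 * pi * sigma)
  attr(W, "freqs") <- freqs
  attr(W, "efold_samples") <- ceiling(sqrt(2) * sigma_t * fs)
  W
}

# triple-product accumulators over the valid time points of one coefficient
# block: num[p,q] = sum_t Wp Wq Conj(Wp+q), d1 = sum |Wp Wq|^2,
# d2 = sum |Wp+q|^2 (expanded onto the (p,q) grid by indexing).
.wb_accumulate <- function(W, acc = NULL) {
  freqs <- attr(W, "freqs")
  guard <- attr(W, "efold_samples")
  n <- nrow(W)
  keep <- (guard + 1L):(n - guard)
  if (length(keep) < 2L) stop("epoch shorter than twice the wavelet edge guard")
  Wk <- W[keep, , drop = FALSE]
  nfq <- length(freqs)
  if (is.null(acc))
    acc <- list(num = matrix(0 + 0i, nfq, nfq), d1 = matrix(0, nfq, nfq),
                d2 = matrix(0, nfq, nfq), freqs = freqs,
                sum_idx = outer(freqs, freqs, `+`))
  sum_ok <- acc$sum_idx <= max(freqs)
  for (q in seq_len(nfq)) {
    p_ok <- which(sum_ok[, q])
    if (!length(p_ok)) next
    s_col <- match(freqs[p_ok] + freqs[q], freqs)
    B <- Wk[, p_ok, drop = FALSE] * Wk[, q]
    acc$num[p_ok, q] <- acc$num[p_ok, q] +
      colSums(B * Conj(Wk[, s_col, drop = FALSE]))
    acc$d1[p_ok, q] <- acc$d1[p_ok, q] + colSums(abs(B)^2)
    acc$d2[p_ok, q] <- acc$d2[p_ok, q] + colSums(abs(Wk[, s_col, drop = FALSE])^2)
  }
  acc
}

.wb_finalize <- function(acc) {
  den <- acc$d1 * acc$d2
  b <- sqrt(pmin(ifelse(den > 0, abs(acc$num)^2 / den, NA_real_), 1))
  b[acc$sum_idx > max(acc$freqs)] <- NA_real_   # outside the analyzed range
  dimnames(b) <- list(fp = acc$freqs, fq = acc$freqs)
  structure(list(b = b, freqs = acc$freqs), class = "bicoherence_matrix")
}

#' Wavelet bicoherence at one bifrequency pair
#'
#' Normalized magnitude of the time-averaged triple product
#' `W(fp) W(fq) Conj(W(fp+fq))`; the Cauchy-Schwarz normalization
#' `sqrt(sum|W(fp)W(fq)|^2 * sum|W(fp+fq)|^2)` bounds the value in \[0, 1\].
#' Coefficients within one wavelet e-folding time of the block edges are
#' excluded.
#'
#' @param coeffs a coefficient bank from [cwt_frequency_bank()].
#' @param fp,fq bifrequency pair (Hz); `fp + fq` must lie in the bank.
#' @return Bicoherence value in \[0, 1\].
#' @export
wavelet_bicoherence <- function(coeffs, fp, fq) {
  freqs <- attr(coeffs, "freqs")
  ip <- match(fp, freqs); iq <- match(fq, freqs); is <- match(fp + fq, freqs)
  if (anyNA(c(ip, iq, is)))
    stop("invalid bifrequency: fp, fq and fp+fq must all be bank frequencies")
  guard <- attr(coeffs, "efold_samples")
  keep <- (guard + 1L):(nrow(coeffs) - guard)
  A <- coeffs[keep, ip] * coeffs[keep, iq]
  Bc <- coeffs[keep, is]
  den <- sum(abs(A)^2) * sum(abs(Bc)^2)
  if (den <= 0) return(NA_real_)
  min(1, abs(sum(A * Conj(Bc)))^2 / den)^0.5
}

#' Wavelet bicoherence matrix of a signal segment
#'
#' Splits the signal into epochs (2 s with 75 percent overlap by default),
#' computes the wavelet bank per epoch, and accumulates triple products and
#' their normalizers across all epochs of the segment before forming the
#' bicoherence, so the estimator bias shrinks as more epochs enter.
#' Bifrequencies with `fp + fq` above the analyzed range are `NA`.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param freqs bifrequency grid (Hz).
#' @param bandwidth_hz wavelet spectral FWHM.
#' @param epoch_s,overlap epoching of the segment.
#' @return A `bicoherence_matrix`: list with entries `b` (matrix in \[0,1\]
#'   or `NA`) and `freqs`.
#' @export
wavelet_bicoherence_matrix <- function(x, fs, freqs = 1:45, bandwidth_hz = 2,
                                       epoch_s = 2, overlap = 0.75) {
  rec <- eeg_recording(matrix(x, nrow = 1L), fs, "x1")
  ep <- segment_epochs(rec, epoch_s = epoch_s, overlap_frac = overlap)
  M <- epoch_matrix(ep, 1L)
  acc <- NULL
  for (k in seq_len(ncol(M))) {
    W <- cwt_frequency_bank(M[, k], fs, freqs, bandwidth_hz)
    acc <- .wb_accumulate(W, acc)
  }
  .wb_finalize(acc)
}

#' Epoch-accumulated bicoherence at a single bifrequency pair
#'
#' Same estimator as [wavelet_bicoherence_matrix()] restricted to one
#' bifrequency, computing only the three needed coefficient series.
#'
#' @inheritParams wavelet_bicoherence_matrix
#' @param fp,fq bifrequency pair (Hz).
#' @return Bicoherence value in \[0, 1\].
#' @export
bicoherence_pair <- function(x, fs, fp, fq, bandwidth_hz = 2,
                             epoch_s = 2, overlap = 0.75) {
  rec <- eeg_recording(matrix(x, nrow = 1L), fs, "x1")
  ep <- segment_epochs(rec, epoch_s = epoch_s, overlap_frac = overlap)
  M <- epoch_matrix(ep, 1L)
  num <- 0 + 0i; d1 <- 0; d2 <- 0
  for (k in seq_len(ncol(M))) {
    W <- cwt_frequency_bank(M[, k], fs, c(fp, fq, fp + fq), bandwidth_hz)
    guard <- attr(W, "efold_samples")
    keep <- (guard + 1L):(nrow(W) - guard)
    A <- W[keep, 1L] * W[keep, 2L]
    Bc <- W[keep, 3L]
    num <- num + sum(A * Conj(Bc))
    d1 <- d1 + sum(abs(A)^2)
    d2 <- d2 + sum(abs(Bc)^2)
  }
  if (d1 * d2 <= 0) return(NA_real_)
  min(1, abs(num)^2 / (d1 * d2))^0.5
}

# Epoch-accumulated bicoherence matrix computed from one segment-level
# wavelet bank. Summing the triple products epoch by epoch (with the
# per-epoch edge guard) is a weighted sum over segment time, where each
# time point's weight is the number of epochs whose guarded interior covers
# it; computing the bank once over the whole segment and applying those
# weights gives the same accumulation at a fraction of the transform cost.
.wb_segment_matrix <- function(x, fs, starts, L, freqs = 1:45,
                               bandwidth_hz = 2) {
  W <- cwt_frequency_bank(x, fs, freqs, bandwidth_hz)
  guard <- attr(W, "efold_samples")
  if (L <= 2L * guard) stop("epoch shorter than twice the wavelet edge guard")
  n <- nrow(W)
  d <- numeric(n + 1L)                   # epoch-coverage weights via diffs
  lo <- starts + guard
  hi <- starts + L - guard               # exclusive upper bound
  for (k in seq_along(starts)) {
    d[lo[k]] <- d[lo[k]] + 1
    d[hi[k]] <- d[hi[k]] - 1
  }
  cnt <- cumsum(d[seq_len(n)])
  # the bank is heavily oversampled relative to its 2 Hz bandwidth: the
  # triple products are near-baseband (sum-frequency carrier cancels), so
  # the time sums can be taken on a decimated grid without changing the
  # accumulated ratios
  dec <- max(1L, floor(fs / (12 * bandwidth_hz)))
  if (dec > 1L) {
    keep <- seq.int(1L, n, by = dec)
    W <- W[keep, , drop = FALSE]
    cnt <- cnt[keep]
  }
  nfq <- length(freqs)
  sum_idx <- outer(freqs, freqs, `+`)
  sum_ok <- sum_idx <= max(freqs)
  num <- matrix(0 + 0i, nfq, nfq)
  d1 <- matrix(0, nfq, nfq)
  d2 <- matrix(0, nfq, nfq)
  s2 <- colSums(abs(W)^2 * cnt)
  Wc <- W * cnt
  for (q in seq_len(nfq)) {
    p_ok <- which(sum_ok[, q] & freqs >= freqs[q])   # b(p,q) = b(q,p)
    if (!length(p_ok)) next
    s_col <- match(freqs[p_ok] + freqs[q], freqs)
    P <- W[, p_ok, drop = FALSE] * W[, q]
    num[p_ok, q] <- colSums(P * Conj(Wc[, s_col, drop = FALSE]))
    d1[p_ok, q] <- colSums(Re(P * Conj(P)) * cnt)
    d2[p_ok, q] <- s2[s_col]
  }
  lowtri <- lower.tri(num)
  num[t(lowtri)] <- t(num)[t(lowtri)]   # mirror onto the upper triangle
  d1[t(lowtri)] <- t(d1)[t(lowtri)]
  d2[t(lowtri)] <- t(d2)[t(lowtri)]
  .wb_finalize(list(num = num, d1 = d1, d2 = d2, freqs = freqs,
                    sum_idx = sum_idx))
}

#' Band-pair aggregate of squared bicoherence (FIWBIC)
#'
#' Aggregates `b^2(fp, fq)` over the bifrequency region with `fp` in one
#' band and `fq` in the other, symmetrized over both orientations. The
#' default aggregate is the mean over valid grid points, which makes values
#' comparable across band pairs of different area; the raw double sum is
#' available via `aggregate = "sum"`.
#'
#' @param bmat a `bicoherence_matrix`.
#' @param pair 2-element character vector naming two bands.
#' @param scheme a [band_scheme()].
#' @param aggregate `"mean"` or `"sum"`.
#' @return Nonnegative scalar.
#' @export
fiwbic <- function(bmat, pair, scheme = band_scheme(), aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(bmat, "bicoherence_matrix"), length(pair) == 2L)
  bA <- scheme$bands[[pair[1]]]; bB <- scheme$bands[[pair[2]]]
  if (is.null(bA) || is.null(bB)) stop("unknown band in pair")
  f <- bmat$freqs
  inA <- f >= bA[1] & f < bA[2]
  inB <- f >= bB[1] & f < bB[2]
  region <- outer(inA, inB, `&`) | outer(inB, inA, `&`)
  vals <- bmat$b[region]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no valid bifrequency grid points in the region")
  if (aggregate == "mean") mean(vals^2) else sum(vals^2)
}

#' Cross-frequency coupling features for one subject
#'
#' Per channel and segment, accumulates a wavelet bicoherence matrix over
#' 2-s epochs (75 percent overlap), aggregates it into the six band-pair
#' FIWBIC values, and averages across segments. Global features are channel
#' means. Names: `fiwbic.<bandA>_<bandB>.<channel|global>`.
#'
#' @param segments list of preprocessed [eeg_recording()] segments.
#' @param scheme a [band_scheme()].
#' @param config a [qeeg_config()] list.
#' @return Named numeric vector of features.
#' @export
cfc_features <- function(segments, scheme = band_scheme(),
                         config = qeeg_config()) {
  freqs <- seq(ceiling(scheme$total[1]), floor(scheme$total[2]),
               by = config$cwt$step_hz)
  labels <- segments[[1]]$channel_labels
  pair_names <- vapply(scheme$band_pairs, paste, character(1), collapse = "_")
  acc <- matrix(0, length(pair_names), length(labels),
                dimnames = list(pair_names, labels))
  nseg <- 0L
  for (rec in segments) {
    ep <- segment_epochs(rec, epoch_s = config$epoch$length_s,
                         overlap_frac = config$epoch$overlap$bicoherence,
                         trim_s = config$epoch$trim_s)
    for (ch in seq_along(labels)) {
      bm <- .wb_segment_matrix(ep$samples[ch, ], rec$fs, ep$starts, ep$L,
                               freqs, config$cwt$bandwidth_hz)
      acc[, ch] <- acc[, ch] + vapply(scheme$band_pairs, function(p)
        fiwbic(bm, p, scheme, aggregate = config$fiwbic$aggregate), numeric(1))
    }
    nseg <- nseg + 1L
  }
  m <- acc / nseg
  vals <- c()
  for (pn in pair_names) {
    v <- m[pn, ]
    names(v) <- paste0("fiwbic.", pn, ".", labels)
    vals <- c(vals, v, structure(mean(v, na.rm = TRUE),
                                 names = paste0("fiwbic.", pn, ".global")))
  }
  vals
}
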