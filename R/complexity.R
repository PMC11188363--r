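# Four signal-complexity estimators. ApEn and SaEn use Chebyshev distances
# in delay-embedded phase space with tolerance r expressed as a fraction of
# the segment's standard deviation; PeEn is the Shannon entropy of ordinal
# patterns; WaEn the Shannon entropy of relative dyadic wavelet sub-band
# energies.

# Chebyshev distance matrix between all m-length templates of x, built by a
# running elementwise max over diagonal shifts of the pointwise |xi - xj|.
.cheb_template_dist <- function(D, n, m) {
  nt <- n - m + 1L
  C <- D[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1L) for (k in seq_len(m - 1L))
    C <- pmax(C, D[(1L + k):(nt + k), (1L + k):(nt + k), drop = FALSE])
  C
}

#' Approximate entropy
#'
#' Classic definition: `ApEn = Phi_m(r) - Phi_{m+1}(r)` where `Phi_m` is the
#' mean log fraction of templates within Chebyshev distance `r` (self-matches
#' included) and `r = r_frac * sd(x)`.
#'
#' @param x numeric signal.
#' @param m embedding dimension (default 2).
#' @param r_frac tolerance as a fraction of the standard deviation (default 0.2).
#' @return Nonnegative scalar (0 for a constant signal).
#' @export
approximate_entropy <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  if (n < m + 10L) stop("signal too short for ApEn at m = ", m)
  s <- stats::sd(x)
  if (s == 0) return(0)
  r <- r_frac * s
  D <- abs(outer(x, x, `-`))
  phi <- function(mm) {
    C <- .cheb_template_dist(D, n, mm)
    mean(log(rowMeans(C <= r)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` and `A` count template pairs (i != j) within
#' Chebyshev distance `r = r_frac * sd(x)` at lengths `m` and `m + 1`,
#' computed over the `n - m` templates that exist at both lengths, with
#' self-matches excluded. When no length-`m+1` pair matches the value is
#' undefined and `NA` is returned with a warning.
#'
#' @inheritParams approximate_entropy
#' @return Nonnegative scalar, `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  if (n < m + 10L) stop("signal too short for SaEn at m = ", m)
  r <- r_frac * stats::sd(x)
  D <- abs(outer(x, x, `-`))
  nt <- n - m
  Cm <- .cheb_template_dist(D, n, m)[seq_len(nt), seq_len(nt)]
  Cm1 <- .cheb_template_dist(D, n, m + 1L)
  B <- sum(Cm <= r) - nt
  A <- sum(Cm1 <= r) - nt
  if (A == 0 || B == 0) {
    warning("sample entropy undefined: no template matches at length m+1")
    return(NA_real_)
  }
  -log(A / B)
}

# ordinal pattern codes of a series; ties ranked by order of appearance
# (earlier index gets the lower rank). Returns integer codes in base `order`.
.ordinal_codes <- function(x, order, delay) {
  n <- length(x)
  np <- n - (order - 1L) * delay
  if (np < 1L) return(integer(0))
  E <- vapply(0:(order - 1L), function(j) x[(1L + j * delay):(np + j * delay)],
              numeric(np))
  if (np == 1L) E <- matrix(E, nrow = 1L)
  code <- numeric(np)
  for (j in seq_len(order)) {
    rj <- numeric(np)
    for (k in seq_len(order)) {
      if (k == j) next
      rj <- rj + ((E[, k] < E[, j]) | (E[, k] == E[, j] & k < j))
    }
    code <- code + rj * order^(j - 1L)
  }
  as.integer(code)
}

#' Permutation entropy
#'
#' Shannon entropy of the empirical distribution of ordinal patterns of
#' length `order` taken at lag `delay`. Ties are broken by order of
#' appearance (the earlier sample ranks lower). Bounded by
#' `log(order!)` in the chosen base.
#'
#' @param x numeric signal.
#' @param order pattern length (default 3).
#' @param delay lag between pattern samples (default 1).
#' @param log_base logarithm base; `exp(1)` for nats (default), 2 for bits.
#' @return Scalar in `[0, log(order!)]`.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L, log_base = exp(1)) {
  if (length(x) < (order - 1L) * delay + 2L)
    stop("signal too short for the requested pattern length")
  code <- .ordinal_codes(x, order, delay)
  p <- tabulate(code + 1L, nbins = order^order)
  p <- p[p > 0] / length(code)
  -sum(p * log(p)) / log(log_base)
}

# db4 (8-tap Daubechies) scaling filter; wavelet filter by QMF relation.
.db4_dec_lo <- c(-0.010597401784997278, 0.032883011666982945,
                 0.030841381835986965, -0.18703481171888114,
                 -0.02798376941698385, 0.63088076792959036,
                 0.71484657055254153, 0.23037781330885523)

.dwt_step <- function(x, h) {
  L <- length(h)
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  n <- length(x)
  xe <- c(x, x[seq_len(L - 1L)])          # periodic extension
  y <- as.vector(embed(xe, L) %*% rev(h))  # y[t] = sum_m h[m] xe[t+m-1]
  y[seq.int(1L, n, by = 2L)]
}

#' Dyadic discrete wavelet decomposition energies
#'
#' Mallat cascade with the db4 filter pair and periodic extension (odd
#' lengths padded by repeating the last sample). Returns the energy of each
#' detail level plus the final approximation.
#'
#' @param x numeric signal with `length(x) >= 2^levels`.
#' @param levels decomposition depth.
#' @return Numeric vector of `levels + 1` energies (details 1..levels, then
#'   the approximation).
#' @export
dwt_energies <- function(x, levels = 5L) {
  if (length(x) < 2^levels) stop("signal shorter than 2^levels samples")
  h <- .db4_dec_lo
  g <- rev(h) * (-1)^(seq_along(h) - 1L)   # highpass by alternating signs
  en <- numeric(levels + 1L)
  a <- x
  for (lv in seq_len(levels)) {
    d <- .dwt_step(a, g)
    a <- .dwt_step(a, h)
    en[lv] <- sum(d^2)
  }
  en[levels + 1L] <- sum(a^2)
  en
}

#' Wavelet entropy
#'
#' Shannon entropy of the relative energies of the `levels` detail sub-bands
#' plus the final approximation of a dyadic db4 decomposition; divided by
#' `log(levels + 1)` when `normalized`, so the value lies in \[0, 1\].
#'
#' @param x numeric signal.
#' @param levels decomposition depth (default 5).
#' @param mother wavelet family identifier; only `"db4"` is built in.
#' @param normalized divide by the maximal entropy (default TRUE).
#' @return Nonnegative scalar.
#' @export
wavelet_entropy <- function(x, levels = 5L, mother = "db4", normalized = TRUE) {
  if (mother != "db4") stop("unsupported mother wavelet: ", mother)
  en <- dwt_energies(x, levels)
  tot <- sum(en)
  if (tot <= 0) stop("zero total energy")
  e <- en[en > 0] / tot
  H <- -sum(e * log(e))
  if (normalized) H / log(levels + 1) else H
}

# windowed permutation entropy via cumulative pattern counts: codes are
# computed once per channel, per-epoch counts come from cumsum differences.
.peen_epoch_mean <- function(x, starts, L, order, delay, log_base) {
  code <- .ordinal_codes(x, order, delay)
  npat_epoch <- L - (order - 1L) * delay
  lev <- sort(unique(code))
  cs <- apply(outer(code, lev, `==`), 2L, cumsum)
  lo <- starts - 1L
  hi <- starts + npat_epoch - 1L
  cnt <- cs[hi, , drop = FALSE] -
    rbind(matrix(0, 1L, length(lev)), cs[, , drop = FALSE])[lo + 1L, , drop = FALSE]
  p <- cnt / npat_epoch
  H <- -rowSums(ifelse(p > 0, p * log(p), 0)) / log(log_base)
  mean(H)
}

#' Signal-complexity features for one subject
#'
#' Computes the configured entropy estimators per 2-s epoch and channel,
#' averages across all epochs of all segments, and appends global
#' (channel-mean) values. `r` for ApEn/SaEn is recomputed from each epoch's
#' own standard deviation. Names: `ent.<apen|saen|peen|waen>.<channel|global>`.
#'
#' @param segments list of preprocessed [eeg_recording()] segments.
#' @param scheme a [band_scheme()] (unused, kept for a uniform interface).
#' @param config a [qeeg_config()] list; `config$ent$estimators` selects a
#'   subset of `c("apen", "saen", "peen", "waen")`.
#' @return Named numeric vector of features.
#' @export
complexity_features <- function(segments, scheme = band_scheme(),
                                config = qeeg_config()) {
  est <- config$ent$estimators
  labels <- segments[[1]]$channel_labels
  sums <- matrix(0, length(est), length(labels),
                 dimnames = list(est, labels))
  cnts <- matrix(0, length(est), length(labels),
                 dimnames = list(est, labels))
  for (rec in segments) {
    ep <- segment_epochs(rec, epoch_s = config$epoch$length_s,
                         overlap_frac = config$epoch$overlap$entropy,
                         trim_s = config$epoch$trim_s)
    K <- n_epochs(ep)
    for (ch in seq_along(labels)) {
      if ("peen" %in% est) {
        v <- .peen_epoch_mean(ep$samples[ch, ], ep$starts, ep$L,
                              config$ent$peen$order, config$ent$peen$delay,
                              config$ent$peen$log_base)
        sums["peen", ch] <- sums["peen", ch] + v * K
        cnts["peen", ch] <- cnts["peen", ch] + K
      }
      slow <- intersect(est, c("apen", "saen", "waen"))
      if (length(slow)) {
        M <- epoch_matrix(ep, ch)
        for (k in seq_len(K)) {
          xk <- M[, k]
          for (e in slow) {
            v <- switch(e,
              apen = approximate_entropy(xk, config$ent$apen$m,
                                         config$ent$apen$r_frac),
              saen = suppressWarnings(
                sample_entropy(xk, config$ent$saen$m, config$ent$saen$r_frac)),
              waen = wavelet_entropy(xk, config$ent$waen$levels,
                                     config$ent$waen$mother,
                                     config$ent$waen$normalized))
            if (!is.na(v)) {
              sums[e, ch] <- sums[e, ch] + v
              cnts[e, ch] <- cnts[e, ch] + 1
            }
          }
        }
      }
    }
  }
  m <- sums / cnts
  m[cnts == 0] <- NA_real_
  vals <- c()
  for (e in est) {
    v <- m[e, ]
    names(v) <- paste0("ent.", e, ".", labels)
    vals <- c(vals, v, structure(mean(v, na.rm = TRUE),
                                 names = paste0("ent.", e, ".global")))
  }
  vals
}
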