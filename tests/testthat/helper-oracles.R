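# Independent brute-force reference implementations, written directly from
# the textbook definitions. These stay deliberately naive (explicit template
# enumeration) and are never shared with the package implementations.

apen_oracle <- function(x, m, r_frac) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1L
    tmpl <- t(vapply(seq_len(nt), function(i) x[i:(i + mm - 1L)],
                     numeric(mm)))
    cnt <- vapply(seq_len(nt), function(i)
      sum(apply(abs(sweep(tmpl, 2L, tmpl[i, ])), 1L, max) <= r), numeric(1))
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1L)
}

saen_oracle <- function(x, m, r_frac) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  nt <- n - m
  count_pairs <- function(mm) {
    tmpl <- t(vapply(seq_len(nt), function(i) x[i:(i + mm - 1L)],
                     numeric(mm)))
    s <- 0L
    for (i in seq_len(nt)) {
      d <- apply(abs(sweep(tmpl, 2L, tmpl[i, ])), 1L, max)
      s <- s + sum(d <= r) - 1L   # drop the self-match
    }
    s
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

peen_oracle <- function(x, order, delay = 1L, log_base = exp(1)) {
  np <- length(x) - (order - 1L) * delay
  pats <- vapply(seq_len(np), function(i)
    paste(rank(x[seq(i, by = delay, length.out = order)],
               ties.method = "first"), collapse = "-"), character(1))
  p <- as.numeric(table(pats)) / np
  -sum(p * log(p)) / log(log_base)
}

# Benjamini-Hochberg by direct step-up scan: adjusted value for the i-th
# order statistic is min over j >= i of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# small helpers shared across test files
sine_recording <- function(f, duration_s = 10, fs = 250, nch = 1,
                           labels = paste0("x", seq_len(nch))) {
  tvec <- (0:(duration_s * fs - 1)) / fs
  eeg_recording(matrix(rep(sin(2 * pi * f * tvec), nch), nrow = nch,
                       byrow = TRUE), fs, labels)
}

tiny_cohort_config <- function(seed = 1, n_ws = 2, n_ctrl = 2,
                               segment_s = 20) {
  generator_config(n_ws = n_ws, n_ctrl = n_ctrl, segment_s = segment_s,
                   ws_segments = 1, ctrl_segments = 1, seed = seed)
}
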