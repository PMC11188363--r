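test_that("the wavelet bank is tuned, linear in amplitude, and tracks chirps", {
  fs <- 250
  tvec <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * tvec)
  W <- cwt_frequency_bank(x, fs)
  mid <- 500:2000
  amp <- colMeans(abs(W[mid, ]))
  expect_equal(which.max(amp), 10L)
  expect_gt(amp[10], 0.95)
  W3 <- cwt_frequency_bank(-3 * x, fs)
  expect_equal(abs(W3[mid, ]), 3 * abs(W[mid, ]), tolerance = 1e-12)
  # ridge of a 5 -> 15 Hz chirp moves monotonically upward
  ch <- make_fixture("chirp", list(f0 = 5, f1 = 15, duration_s = 40), seed = 1)
  Wc <- cwt_frequency_bank(ch$samples[1, ], fs)
  probe <- round(seq(2000, nrow(Wc) - 2000, length.out = 8))
  ridge <- apply(abs(Wc[probe, ]), 1, which.max)
  expect_true(all(diff(ridge) >= 0))
  expect_gt(ridge[8], ridge[1])
  expect_error(cwt_frequency_bank(x, fs, freqs = c(10, 130)), "Nyquist")
})

test_that("bicoherence is bounded, scale invariant, and flags invalid pairs", {
  set.seed(6)
  x <- rnorm(2000)
  W <- cwt_frequency_bank(x, 250)
  b <- wavelet_bicoherence(W, 6, 10)
  expect_gte(b, 0); expect_lte(b, 1)
  W2 <- cwt_frequency_bank(5.5 * x, 250)
  expect_equal(wavelet_bicoherence(W2, 6, 10), b, tolerance = 1e-9)
  expect_error(wavelet_bicoherence(W, 40, 10), "invalid bifrequency")
  bm <- wavelet_bicoherence_matrix(x, 250)
  expect_true(all(bm$b[!is.na(bm$b)] >= 0 & bm$b[!is.na(bm$b)] <= 1))
  expect_true(is.na(bm$b["30", "30"]))           # fp + fq beyond 45 Hz
  expect_false(is.na(bm$b["6", "10"]))
})

test_that("quadratic phase coupling is detected and bias shrinks with epochs", {
  qc <- make_fixture("qpc_triplet", list(f1 = 6, f2 = 10, strength = 1,
                                         duration_s = 60), seed = 11)
  expect_gt(bicoherence_pair(qc$samples[1, ], 250, 6, 10), 0.8)
  qu <- make_fixture("qpc_triplet", list(f1 = 6, f2 = 10, strength = 1,
                                         duration_s = 60, coupled = FALSE),
                     seed = 11)
  expect_lt(bicoherence_pair(qu$samples[1, ], 250, 6, 10), 0.3)
  # estimator floor on white noise decreases monotonically with epoch count
  set.seed(12)
  wn <- rnorm(64 * 500)
  floors <- vapply(c(4, 16, 64), function(K)
    bicoherence_pair(wn[seq_len(K * 500)], 250, 6, 10, overlap = 0),
    numeric(1))
  expect_true(all(diff(floors) < 0))
})

test_that("FIWBIC aggregates the band-pair region of squared bicoherence", {
  freqs <- 1:45
  ones <- matrix(1, 45, 45, dimnames = list(fp = freqs, fq = freqs))
  ones[outer(freqs, freqs, `+`) > 45] <- NA
  bm1 <- structure(list(b = ones, freqs = freqs), class = "bicoherence_matrix")
  expect_equal(fiwbic(bm1, c("theta", "alpha")), 1)
  bm0 <- structure(list(b = ones * 0, freqs = freqs),
                   class = "bicoherence_matrix")
  expect_equal(fiwbic(bm0, c("theta", "alpha")), 0)
  # symmetric in the pair orientation; sum mode scales with region size
  set.seed(7)
  noisy <- wavelet_bicoherence_matrix(rnorm(5000), 250)
  expect_equal(fiwbic(noisy, c("theta", "alpha")),
               fiwbic(noisy, c("alpha", "theta")))
  expect_gt(fiwbic(noisy, c("delta", "theta"), aggregate = "sum"),
            fiwbic(noisy, c("delta", "theta")))
  expect_error(fiwbic(noisy, c("theta", "gamma")), "unknown band")
})

test_that("coupled signals score higher FIWBIC than uncoupled ones", {
  on <- make_fixture("qpc_triplet", list(f1 = 6, f2 = 10, strength = 1,
                                         duration_s = 40), seed = 21)
  off <- make_fixture("qpc_triplet", list(f1 = 6, f2 = 10, strength = 1,
                                          duration_s = 40, coupled = FALSE),
                      seed = 21)
  f_on <- fiwbic(wavelet_bicoherence_matrix(on$samples[1, ], 250),
                 c("theta", "alpha"))
  f_off <- fiwbic(wavelet_bicoherence_matrix(off$samples[1, ], 250),
                  c("theta", "alpha"))
  expect_gt(f_on, f_off)
})

test_that("per-subject coupling features are identical for identical channels", {
  qc <- make_fixture("qpc_triplet", list(f1 = 6, f2 = 10, strength = 0.8,
                                         duration_s = 16), seed = 8)
  x <- qc$samples[1, ]
  rec <- eeg_recording(rbind(x, x), 250, c("C3", "C4"))
  cfgc <- qeeg_config(); cfgc$epoch$trim_s <- 0
  v <- cfc_features(list(rec), config = cfgc)
  expect_length(v, 6 * 3)                        # 2 channels + global, 6 pairs
  expect_equal(v[["fiwbic.theta_alpha.C3"]], v[["fiwbic.theta_alpha.C4"]])
  expect_equal(v[["fiwbic.theta_alpha.global"]],
               v[["fiwbic.theta_alpha.C3"]])
  expect_true(all(v >= 0 & v <= 1))
})
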