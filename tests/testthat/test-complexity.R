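test_that("regularity statistics vanish on constant input and order signals", {
  const <- rep(2.5, 300)
  expect_equal(approximate_entropy(const), 0)
  expect_equal(sample_entropy(const), 0)
  expect_equal(permutation_entropy(const, 3, 1), 0)
  expect_equal(permutation_entropy(seq_len(100), 3, 1), 0)   # monotone
  # a sinusoid is more regular than white noise
  tvec <- (0:999) / 250
  set.seed(17)
  expect_lt(approximate_entropy(sin(2 * pi * 5 * tvec)),
            approximate_entropy(rnorm(1000)))
  expect_lt(sample_entropy(sin(2 * pi * 5 * tvec)),
            sample_entropy(rnorm(1000)))
})

test_that("embedding entropies agree with brute-force template counting", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- rnorm(150)
    expect_equal(approximate_entropy(x, 2, 0.2), apen_oracle(x, 2, 0.2),
                 tolerance = 1e-12)
    expect_equal(sample_entropy(x, 2, 0.2), saen_oracle(x, 2, 0.2),
                 tolerance = 1e-12)
    expect_equal(permutation_entropy(x, 3, 1), peen_oracle(x, 3, 1),
                 tolerance = 1e-12)
  }
  expect_error(approximate_entropy(rnorm(5)), "too short")
})

test_that("sample entropy is NA with a warning when nothing matches at m+1", {
  set.seed(30)
  x <- runif(15)                # tolerance far below any pairwise distance
  expect_warning(v <- sample_entropy(x, 2, 1e-9), "undefined")
  expect_true(is.na(v))
})

test_that("entropies respect their invariances", {
  set.seed(18)
  x <- rnorm(300)
  # additive shifts change nothing
  expect_equal(approximate_entropy(x + 100), approximate_entropy(x))
  expect_equal(sample_entropy(x + 100), sample_entropy(x))
  expect_equal(permutation_entropy(x + 100, 3), permutation_entropy(x, 3))
  expect_equal(wavelet_entropy(x + 0), wavelet_entropy(x))
  # r scales with SD, so linear rescaling leaves ApEn/SaEn unchanged
  expect_equal(sample_entropy(4.2 * x), sample_entropy(x))
  expect_equal(approximate_entropy(4.2 * x), approximate_entropy(x))
  # ordinal patterns are invariant to any strictly monotone transform
  expect_equal(permutation_entropy(exp(x), 3), permutation_entropy(x, 3))
  # bound by log(order!)
  for (ord in 2:4)
    expect_lte(permutation_entropy(x, ord), log(factorial(ord)) + 1e-12)
})

test_that("ordinal patterns break ties by order of appearance", {
  # with ties ranked by first appearance, (1,1) counts as an up-pattern
  expect_equal(permutation_entropy(c(1, 1, 1, 2, 1), 2, 1),
               peen_oracle(c(1, 1, 1, 2, 1), 2, 1))
  expect_equal(permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), 2, 1,
                                   log_base = 2),
               peen_oracle(c(4, 7, 9, 10, 6, 11, 3), 2, 1, 2))
})

test_that("the dyadic wavelet decomposition is orthogonal and WaEn behaves", {
  set.seed(19)
  xd <- rnorm(512)                    # dyadic length: exactly orthogonal
  expect_equal(sum(dwt_energies(xd, 5)), sum(xd^2), tolerance = 1e-9)
  x <- rnorm(500)                     # odd levels get padded: near-orthogonal
  expect_equal(sum(dwt_energies(x, 5)), sum(x^2), tolerance = 0.01)
  w <- wavelet_entropy(x)
  expect_gte(w, 0); expect_lte(w, 1)
  # dyadic white-noise sub-band energies halve per level: WaEn near 0.75
  set.seed(20)
  ww <- mean(replicate(10, wavelet_entropy(rnorm(500))))
  expect_gt(ww, 0.68); expect_lt(ww, 0.85)
  # a tone concentrated in one detail band is far less entropic
  tone <- sin(2 * pi * 10 * (0:499) / 250)
  expect_lt(wavelet_entropy(tone), ww - 0.2)
  expect_error(wavelet_entropy(rep(0, 500)), "zero total energy")
  expect_error(wavelet_entropy(rnorm(16), levels = 5), "2\\^levels")
})

test_that("per-subject complexity features average epochs and channels", {
  set.seed(21)
  x <- rnorm(3000)
  rec <- eeg_recording(rbind(x, x), 250, c("C3", "C4"))
  cfgc <- qeeg_config()
  cfgc$epoch$trim_s <- 0
  v <- complexity_features(list(rec), config = cfgc)
  expect_length(v, 4 * 3)
  for (e in c("apen", "saen", "peen", "waen")) {
    expect_equal(v[[paste0("ent.", e, ".C3")]], v[[paste0("ent.", e, ".C4")]])
    expect_equal(v[[paste0("ent.", e, ".global")]],
                 v[[paste0("ent.", e, ".C3")]])
  }
  # epoch-mean PeEn equals the mean of per-epoch values computed directly
  cfgc$ent$estimators <- "peen"
  ep <- segment_epochs(rec, 2, cfgc$epoch$overlap$entropy)
  M <- epoch_matrix(ep, 1)
  direct <- mean(apply(M, 2, permutation_entropy,
                       order = cfgc$ent$peen$order,
                       delay = cfgc$ent$peen$delay))
  v2 <- complexity_features(list(rec), config = cfgc)
  expect_equal(v2[["ent.peen.C3"]], direct, tolerance = 1e-12)
})
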