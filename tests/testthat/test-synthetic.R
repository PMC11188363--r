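test_that("cohort generation is a pure function of its configuration", {
  cfg <- tiny_cohort_config(seed = 5, segment_s = 10)
  a <- generate_subject(cfg, "WS", "w1", 3L)
  b <- generate_subject(cfg, "WS", "w1", 3L)
  expect_identical(a$segments[[1]]$samples, b$segments[[1]]$samples)
  # different subject seeds give different data
  c2 <- generate_subject(cfg, "WS", "w2", 4L)
  expect_false(identical(a$segments[[1]]$samples, c2$segments[[1]]$samples))
})

test_that("cohort layout, labels, and etiology flag prevalences are honored", {
  cfg <- generator_config(n_ws = 31, n_ctrl = 20, segment_s = 4,
                          ws_segments = 1, ctrl_segments = 1, seed = 2)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 51)
  expect_equal(sum(coh$meta$group == "WS"), 31)
  expect_equal(sum(coh$meta$structural_flag), 9)
  expect_equal(sum(coh$meta$genetic_flag), 17)
  expect_true(all(coh$meta$structural_flag[coh$meta$group == "control"] == 0))
  rec <- coh$subjects[[1]]$segments[[1]]
  expect_length(check_montage(rec), 0)
  expect_equal(rec$fs, 250)
})

test_that("raising the theta weight raises measured theta relative power", {
  base <- tiny_cohort_config(seed = 7, segment_s = 30)
  up <- base
  up$band_targets$ws["theta"] <- up$band_targets$ws["theta"] * 1.5
  up$band_targets$ws <- up$band_targets$ws / sum(up$band_targets$ws)
  co <- qeeg_config()
  rp <- function(cfg) {
    sub <- generate_subject(cfg, "WS", "w1", 1L)
    pre <- lapply(sub$segments, preprocess_segment, config = co)
    spectral_features(pre, config = co)[["rp.theta.global"]]
  }
  expect_gt(rp(up), rp(base))
})

test_that("with coupling strength zero the triplet bifrequency sits at the floor", {
  cfg0 <- tiny_cohort_config(seed = 9, segment_s = 40)
  cfg0$qpc_strength <- c(ws = 0, ctrl = 0)
  cfg1 <- tiny_cohort_config(seed = 9, segment_s = 40)
  cfg1$qpc_strength <- c(ws = 1, ctrl = 1)
  b_at <- function(cfg) {
    sub <- generate_subject(cfg, "WS", "w1", 1L)
    x <- preprocess_segment(sub$segments[[1]], qeeg_config())$samples[3, ]
    bicoherence_pair(x, 250, 6, 10)
  }
  b0 <- b_at(cfg0); b1 <- b_at(cfg1)
  expect_lt(b0, 0.15)
  expect_gt(b1, b0)
})

test_that("measured group contrasts follow the configured effect directions", {
  co <- qeeg_config(); co$ent$estimators <- "peen"
  cfg <- generator_config(n_ws = 3, n_ctrl = 3, segment_s = 60,
                          ws_segments = 1, ctrl_segments = 1, seed = 11)
  coh <- generate_cohort(cfg)
  ft <- extract_features(coh, config = co, families = c("rp", "ent"))
  grp <- coh$meta$group[match(ft$subject_id, coh$meta$subject_id)]
  mdiff <- function(f) mean(ft[[f]][grp == "WS"]) -
    mean(ft[[f]][grp == "control"])
  expect_gt(mdiff("rp.theta.global"), 0)
  expect_gt(mdiff("rp.alpha.global"), 0)
  expect_lt(mdiff("rp.delta.global"), 0)
  expect_lt(mdiff("rp.beta.global"), 0)
  expect_lt(mdiff("ent.peen.global"), 0)
})

test_that("generator self-calibration matches its configured targets", {
  # global RP within 0.05 of the configured band targets and PeEn near the
  # calibrated group levels (1.44 WS-like / 1.55 control-like)
  co <- qeeg_config(); co$ent$estimators <- "peen"
  cfg <- generator_config(n_ws = 4, n_ctrl = 4, segment_s = 60,
                          ws_segments = 1, ctrl_segments = 1, seed = 13)
  coh <- generate_cohort(cfg)
  ft <- extract_features(coh, config = co, families = c("rp", "ent"))
  grp <- coh$meta$group[match(ft$subject_id, coh$meta$subject_id)]
  for (g in c("WS", "control")) {
    tgt <- cfg$band_targets[[if (g == "WS") "ws" else "ctrl"]]
    for (b in c("delta", "theta", "alpha", "beta")) {
      m <- mean(ft[[paste0("rp.", b, ".global")]][grp == g])
      expect_lt(abs(m - tgt[[b]]), 0.05)
    }
  }
  expect_lt(abs(mean(ft[["ent.peen.global"]][grp == "WS"]) - 1.4411), 0.08)
  expect_lt(abs(mean(ft[["ent.peen.global"]][grp == "control"]) - 1.5544),
            0.08)
})

test_that("fixtures expose their designed spectral content", {
  sp <- welch_psd(make_fixture("sinusoid", list(f = 10, duration_s = 60),
                               seed = 1)$samples[1, ], fs = 250)
  expect_gt(relative_power(sp, c(8, 13)), 0.95)
  const <- make_fixture("constant", list(duration_s = 2), seed = 1)
  x <- const$samples[1, ]
  expect_equal(approximate_entropy(x), 0)
  expect_equal(sample_entropy(x), 0)
  expect_equal(permutation_entropy(x, 3), 0)
  pink <- make_fixture("pink_noise", list(duration_s = 120), seed = 3)
  spp <- welch_psd(pink$samples[1, ], fs = 250)
  expect_gt(relative_power(spp, c(1, 4)), relative_power(spp, c(13, 30)))
})

test_that("on-disk cohorts reload identically through the reader", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cohort_config(seed = 15, segment_s = 4)
  coh <- generate_cohort(cfg, dir = dir, format = "text")
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  reloaded <- wsqeeg:::.load_cohort_dir(dir, fs = 250)
  expect_equal(length(reloaded$subjects), 4)
  expect_equal(reloaded$subjects[[1]]$segments[[1]]$samples,
               coh$subjects[[1]]$segments[[1]]$samples,
               tolerance = 1e-12, ignore_attr = TRUE)
})
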