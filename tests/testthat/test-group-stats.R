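test_that("pooled t-test matches closed-form arithmetic and symmetry", {
  tt <- two_sample_ttest(1:5, 3:7)
  expect_equal(tt$t, -2)
  expect_equal(tt$df, 8)
  expect_equal(tt$p, 2 * stats::pt(-2, 8), tolerance = 1e-12)
  sw <- two_sample_ttest(3:7, 1:5)
  expect_equal(sw$t, 2)
  expect_equal(sw$p, tt$p)
  eq <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "degenerate")
  expect_error(two_sample_ttest(1, 1:3), "two non-missing")
})

test_that("BH adjustment equals the independent step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)               # single p passes through
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    # rejection at q <= alpha reproduces the step-up rule
    expect_identical(q <= 0.05, bh_reject_oracle(p, 0.05))
    # q is monotone along the sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group comparison finds nothing when groups are exchangeable", {
  set.seed(22)
  vals <- matrix(rnorm(12 * 6), 12,
                 dimnames = list(NULL, paste0("rp.theta.",
                                              c("C3", "C4", "F3", "F4",
                                                "O1", "global"))))
  ft <- feature_table(sprintf("s%02d", 1:12), vals)
  meta <- data.frame(subject_id = sprintf("s%02d", 1:12),
                     group = rep(c("WS", "control"), 6),
                     structural_flag = 0L, genetic_flag = 0L)
  cmp <- compare_groups(ft, meta)
  expect_equal(nrow(cmp), 6)
  expect_true(all(c("mean_ws", "sd_ws", "sem_ws", "t", "p", "q") %in%
                    names(cmp)))
  # mirrored groups: identical group values force t = 0 everywhere
  ft2 <- feature_table(sprintf("s%02d", 1:12), rbind(vals[1:6, ], vals[1:6, ]))
  meta2 <- data.frame(subject_id = sprintf("s%02d", 1:12),
                      group = rep(c("WS", "control"), each = 6),
                      structural_flag = 0L, genetic_flag = 0L)
  cmp2 <- compare_groups(ft2, meta2)
  expect_true(all(cmp2$t == 0) && all(cmp2$p == 1))
  expect_equal(sum(cmp2$significant), 0)
})

test_that("FDR strata isolate channel blocks and the t-map zeroes non-hits", {
  set.seed(23)
  n <- 30
  grp <- rep(c("WS", "control"), each = n / 2)
  shift <- ifelse(grp == "WS", 1.5, 0)
  vals <- cbind(matrix(rnorm(n * 19), n,
                       dimnames = list(NULL, paste0("rp.theta.",
                                                    canonical_montage()))),
                "rp.theta.global" = rnorm(n) + shift,
                "ent.peen.global" = rnorm(n))
  ft <- feature_table(sprintf("s%02d", 1:n), vals)
  meta <- data.frame(subject_id = sprintf("s%02d", 1:n), group = grp,
                     structural_flag = 0L, genetic_flag = 0L)
  cmp <- compare_groups(ft, meta)
  ch <- cmp[cmp$stratum == "rp.theta.channel", ]
  expect_equal(nrow(ch), 19)
  expect_equal(ch$q, bh_oracle(ch$p), tolerance = 1e-14)
  expect_true(cmp$significant[cmp$feature == "rp.theta.global"])
  tm <- channel_tmap(cmp, "rp", "theta")
  expect_equal(nrow(tm), 19)
  expect_true(all(tm$t[!cmp$significant[cmp$stratum == "rp.theta.channel"]] == 0))
  # global correction mode pools all features into one family
  cmpg <- compare_groups(ft, meta, fdr_scope = "global")
  expect_equal(cmpg$q, bh_oracle(cmpg$p), tolerance = 1e-14)
})

test_that("etiology regression recovers exact effects and flags collinearity", {
  n <- 20
  set.seed(24)
  s <- rep(c(0L, 1L), each = n / 2)
  g <- rep(c(0L, 1L), n / 2)
  y_exact <- 3 + 2 * g
  vals <- cbind("rp.theta.global" = y_exact,
                "rp.delta.global" = rnorm(n))
  ft <- feature_table(sprintf("w%02d", 1:n), vals)
  meta <- data.frame(subject_id = sprintf("w%02d", 1:n), group = "WS",
                     structural_flag = s, genetic_flag = g)
  et <- regress_etiology(ft, meta)
  expect_equal(et$beta_genetic[1], 2, tolerance = 1e-10)
  expect_lt(et$p_genetic[1], 1e-12)
  expect_true(all(et$valid))
  # identical flags: rank-deficient design is flagged invalid
  meta2 <- meta; meta2$structural_flag <- meta2$genetic_flag
  et2 <- regress_etiology(ft, meta2)
  expect_false(any(et2$valid))
  expect_true(all(is.na(et2$beta_genetic)))
})

test_that("regression p-values are uniform under the null", {
  set.seed(25)
  n <- 24
  s <- rep(c(0L, 1L), each = n / 2)
  g <- rep(c(0L, 1L), n / 2)
  meta <- data.frame(subject_id = sprintf("w%02d", 1:n), group = "WS",
                     structural_flag = s, genetic_flag = g)
  vals <- matrix(rnorm(n * 200), n,
                 dimnames = list(NULL, sprintf("rp.delta.ch%03d", 1:200)))
  ft <- feature_table(sprintf("w%02d", 1:n), vals)
  et <- regress_etiology(ft, meta)
  ks <- suppressWarnings(stats::ks.test(et$p_genetic, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("permutation of labels keeps the raw type-I rate near nominal", {
  set.seed(26)
  n <- 30
  vals <- matrix(rnorm(n * 40), n,
                 dimnames = list(NULL, sprintf("rp.alpha.f%02d", 1:40)))
  ft <- feature_table(sprintf("s%02d", 1:n), vals)
  meta <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     group = rep(c("WS", "control"), each = n / 2),
                     structural_flag = 0L, genetic_flag = 0L)
  set.seed(27)
  props <- permutation_type1(ft, meta, n_perm = 100, alpha = 0.05)
  expect_lt(mean(props), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})
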