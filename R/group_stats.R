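#' Pooled-variance two-sample t-test
#'
#' Student's two-sided t-test with pooled variance,
#' `df = n_a + n_b - 2`. Errors on degenerate (zero pooled variance) input.
#'
#' @param a,b numeric vectors with at least two non-missing values each.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return Named list with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two non-missing values per group")
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2L,
                                        p = 1))
    stop("degenerate groups: zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted q-values with enforced monotonicity, capped at 1;
#' rejecting at `q <= alpha` reproduces the BH step-up rule exactly.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# decompose feature names into family/stratum components.
# rp.theta.C3 -> measure rp.theta, scope channel; coh.alpha.F3-C3 -> pair.
parse_feature_names <- function(fn) {
  parts <- strsplit(fn, ".", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("unparseable feature name: ", fn[bad][1])
  fam <- vapply(parts, `[`, character(1), 1L)
  band <- vapply(parts, `[`, character(1), 2L)
  loc <- vapply(parts, `[`, character(1), 3L)
  scope <- ifelse(loc == "global", "global",
                  ifelse(grepl("-", loc, fixed = TRUE), "pair", "channel"))
  data.frame(feature = fn, family = fam, band = band, location = loc,
             scope = scope, stratum = paste(fam, band, scope, sep = "."),
             stringsAsFactors = FALSE)
}

#' Per-feature group comparison with FDR control
#'
#' Runs a two-sample t-test (WS minus control) for every feature and applies
#' Benjamini-Hochberg correction. By default the correction is stratified
#' within (measure x band x scope) blocks — e.g. the 19 channel-wise theta
#' relative-power tests form one block — mirroring how channel-wise maps are
#' screened per measure; `fdr_scope = "global"` corrects across everything
#' at once. Both SD and SEM are reported per group.
#'
#' @param ft a [feature_table()].
#' @param meta subject metadata with `subject_id`, `group`, flags.
#' @param alpha significance level on the q-value (default 0.05).
#' @param fdr_scope `"family"` (stratified, default) or `"global"`.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return Data frame with one row per feature: group means, SD, SEM, `t`,
#'   `p`, `q`, `significant` (q at or below `alpha`, the exact
#'   step-up rejection set), plus the parsed name columns. Features that are
#'   degenerate (missing groups or zero variance) are dropped with a warning.
#' @export
compare_groups <- function(ft, meta, alpha = 0.05,
                           fdr_scope = c("family", "global"),
                           var_equal = TRUE) {
  fdr_scope <- match.arg(fdr_scope)
  grp <- meta$group[match(ft$subject_id, meta$subject_id)]
  if (anyNA(grp)) stop("metadata missing for subject: ",
                       ft$subject_id[is.na(grp)][1])
  if (sum(grp == "WS") < 2L || sum(grp == "control") < 2L)
    stop("both groups need at least two subjects")
  fn <- feature_names(ft)
  info <- parse_feature_names(fn)
  rows <- lapply(fn, function(f) {
    a <- ft[[f]][grp == "WS"]; b <- ft[[f]][grp == "control"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    if (stats::var(a) + stats::var(b) == 0 && mean(a) != mean(b)) return(NULL)
    tt <- two_sample_ttest(a, b, var_equal = var_equal)
    data.frame(feature = f, mean_ws = mean(a), mean_ctrl = mean(b),
               sd_ws = stats::sd(a), sd_ctrl = stats::sd(b),
               sem_ws = stats::sd(a) / sqrt(length(a)),
               sem_ctrl = stats::sd(b) / sqrt(length(b)),
               n_ws = length(a), n_ctrl = length(b),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep))
    warning(sum(!keep), " degenerate feature(s) dropped from the comparison")
  res <- do.call(rbind, rows[keep])
  res <- merge(res, info, by = "feature", sort = FALSE)
  if (fdr_scope == "family") {
    res$q <- NA_real_
    for (s in unique(res$stratum)) {
      sel <- res$stratum == s
      res$q[sel] <- bh_fdr(res$p[sel])
    }
  } else {
    res$q <- bh_fdr(res$p)
  }
  res$significant <- res$q <= alpha
  res[order(match(res$feature, fn)), ]
}

#' Channel-wise t-map for one measure and band
#'
#' Extracts the 19 channel t-values of one (measure, band) block from a
#' [compare_groups()] result, zeroing non-significant channels, in the
#' format used for topographic reporting.
#'
#' @param comparison result of [compare_groups()].
#' @param family measure prefix, e.g. `"rp"`, `"ent"`.
#' @param band band or estimator name, e.g. `"theta"`, `"peen"`.
#' @return Data frame with `channel`, `t` (0 where non-significant), `q`.
#' @export
channel_tmap <- function(comparison, family, band) {
  sel <- comparison$family == family & comparison$band == band &
    comparison$scope == "channel"
  d <- comparison[sel, ]
  data.frame(channel = d$location,
             t = ifelse(d$significant, d$t, 0),
             q = d$q, stringsAsFactors = FALSE)
}

#' Regress features on structural and genetic etiology flags
#'
#' Within the WS group only, fits ordinary least squares of each feature on
#' `[intercept, structural_flag, genetic_flag]` and applies BH-FDR across
#' features separately per predictor. If a flag is constant or the design is
#' rank deficient, the affected results are flagged invalid (`NA` estimates).
#'
#' @param ft a [feature_table()].
#' @param meta subject metadata.
#' @param alpha significance level on q (default 0.05).
#' @return Data frame with one row per feature: `beta_structural`,
#'   `beta_genetic`, `p_*`, `q_*`, `significant_*`, `valid`.
#' @export
regress_etiology <- function(ft, meta, alpha = 0.05) {
  meta <- meta[match(ft$subject_id, meta$subject_id), ]
  ws <- meta$group == "WS"
  if (anyNA(ws)) stop("metadata missing for some subjects")
  s <- as.numeric(meta$structural_flag[ws])
  g <- as.numeric(meta$genetic_flag[ws])
  n <- sum(ws)
  if (n < 6L) stop("need at least 3 more WS subjects than predictors")
  X <- cbind(intercept = 1, structural = s, genetic = g)
  valid <- qr(X)$rank == 3L
  fn <- feature_names(ft)
  out <- data.frame(feature = fn,
                    beta_structural = NA_real_, beta_genetic = NA_real_,
                    p_structural = NA_real_, p_genetic = NA_real_,
                    q_structural = NA_real_, q_genetic = NA_real_,
                    valid = valid, stringsAsFactors = FALSE)
  if (valid) {
    Y <- as.matrix(ft[ws, fn, drop = FALSE])
    ok <- colSums(is.na(Y)) == 0
    qrx <- qr(X)
    coefs <- qr.coef(qrx, Y[, ok, drop = FALSE])
    res <- Y[, ok, drop = FALSE] - X %*% coefs
    df <- n - 3L
    sigma2 <- colSums(res^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    se_s <- sqrt(sigma2 * XtXinv[2, 2])
    se_g <- sqrt(sigma2 * XtXinv[3, 3])
    t_s <- coefs[2, ] / se_s
    t_g <- coefs[3, ] / se_g
    p_s <- 2 * stats::pt(abs(t_s), df, lower.tail = FALSE)
    p_g <- 2 * stats::pt(abs(t_g), df, lower.tail = FALSE)
    # exact fits: zero residual variance gives 0/0; call them machine-level
    exact <- sigma2 < .Machine$double.eps^0.9
    p_s[exact & abs(coefs[2, ]) > 1e-10] <- .Machine$double.xmin
    p_g[exact & abs(coefs[3, ]) > 1e-10] <- .Machine$double.xmin
    p_s[exact & abs(coefs[2, ]) <= 1e-10] <- 1
    p_g[exact & abs(coefs[3, ]) <= 1e-10] <- 1
    out$beta_structural[ok] <- coefs[2, ]
    out$beta_genetic[ok] <- coefs[3, ]
    out$p_structural[ok] <- p_s
    out$p_genetic[ok] <- p_g
    out$q_structural[ok] <- bh_fdr(p_s)
    out$q_genetic[ok] <- bh_fdr(p_g)
  }
  out$significant_structural <- out$q_structural <= alpha
  out$significant_genetic <- out$q_genetic <= alpha
  out
}

#' Empirical type-I calibration by label permutation
#'
#' Permutes group labels `n_perm` times and returns the proportion of raw
#' `p < alpha` feature tests per permutation, a calibration check that the
#' mass-univariate screen is at nominal level under the null.
#'
#' @param ft a [feature_table()].
#' @param meta subject metadata.
#' @param n_perm number of permutations.
#' @param alpha nominal level.
#' @return Numeric vector of length `n_perm` of per-permutation proportions.
#' @export
permutation_type1 <- function(ft, meta, n_perm = 200, alpha = 0.05) {
  meta <- meta[match(ft$subject_id, meta$subject_id), ]
  fn <- feature_names(ft)
  Y <- as.matrix(ft[, fn, drop = FALSE])
  is_ws <- meta$group == "WS"
  n <- nrow(Y)
  vapply(seq_len(n_perm), function(i) {
    lab <- sample(is_ws)
    a <- Y[lab, , drop = FALSE]; b <- Y[!lab, , drop = FALSE]
    na <- colSums(!is.na(a)); nb <- colSums(!is.na(b))
    ma <- colMeans(a, na.rm = TRUE); mb <- colMeans(b, na.rm = TRUE)
    va <- apply(a, 2, stats::var, na.rm = TRUE)
    vb <- apply(b, 2, stats::var, na.rm = TRUE)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(abs(tt), na + nb - 2, lower.tail = FALSE)
    mean(p < alpha, na.rm = TRUE)
  }, numeric(1))
}
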