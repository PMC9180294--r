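test_that("balanced LME equals the t-test on per-sample replicate means", {
  for (seed in 1:5) {
    d <- make_nested(n_samples_per_stage = 4, reps = 5, effect = 0.8,
                     seed = seed)
    r <- lme_stage_test(d$y, d$stage, d$sample_id)
    sm <- tapply(d$y, d$sample_id, mean)
    st <- tapply(as.character(d$stage), d$sample_id, `[`, 1)
    tt <- t.test(sm[st == "red"], sm[st == "half-red"], var.equal = TRUE)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    expect_equal(r$estimate, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
    expect_equal(r$df, 6)
  }
})

test_that("balanced closed form agrees with the numeric REML fit", {
  d <- make_nested(n_samples_per_stage = 5, reps = 4, effect = 0.5,
                   sigma_sample = 0.6, seed = 7)
  r <- lme_stage_test(d$y, d$stage, d$sample_id)
  d$sample_f <- factor(d$sample_id)
  fit <- lme4::lmer(y ~ stage + (1 | sample_f), data = d, REML = TRUE)
  co <- summary(fit)$coefficients
  expect_equal(r$estimate / r$se, co[2, "t value"], tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(r$sigma2_sample, vc$vcov[1], tolerance = 1e-5)
  expect_equal(r$sigma2_resid, vc$vcov[2], tolerance = 1e-5)
})

test_that("unbalanced designs fall back to the numeric fit", {
  d <- make_nested(n_samples_per_stage = 4, reps = 5, effect = 1, seed = 3)
  d <- d[-(1:3), ]  # break balance
  r <- lme_stage_test(d$y, d$stage, d$sample_id)
  expect_match(r$method, "lme4")
  expect_true(r$p > 0 && r$p < 1)
})

test_that("degenerate LME inputs are rejected", {
  d <- make_nested(seed = 4)
  expect_error(lme_stage_test(rep(1, nrow(d)), d$stage, d$sample_id),
               "zero total variance")
  one <- d[d$sample_id %in% c(1, 5), ]
  expect_error(lme_stage_test(one$y, one$stage, one$sample_id),
               "two biological samples")
})

test_that("LME type-I error is close to nominal under the null", {
  set.seed(42)
  rej <- 0L
  n_sim <- 1000L
  for (i in seq_len(n_sim)) {
    samp <- rep(1:12, each = 5)
    stage <- rep(c("half-red", "red"), each = 30)
    y <- rnorm(12, 0, sqrt(0.1))[samp] + rnorm(60, 0, sqrt(0.9))
    rej <- rej + (lme_stage_test(y, stage, samp)$p < 0.05)
  }
  expect_gte(rej / n_sim, 0.03)
  expect_lte(rej / n_sim, 0.07)
})

test_that("Benjamini-Hochberg matches the step-up thresholds and closed form", {
  r <- benjamini_hochberg(c(0.001, 0.02, 0.03, 0.04), delta = 0.05)
  expect_true(all(r$significant))   # thresholds i*delta/m all exceeded
  r2 <- benjamini_hochberg(rep(0.5, 6))
  expect_false(any(r2$significant))
  expect_equal(r2$adjusted, rep(0.5, 6))
  r3 <- benjamini_hochberg(0.04)
  expect_equal(r3$adjusted, 0.04)
  expect_true(r3$significant)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))
    got <- benjamini_hochberg(p)$adjusted
    expect_equal(got, bh_closed_form(p), tolerance = 1e-12)
    expect_true(all(diff(got[order(p)]) >= -1e-12))  # monotone in raw p
  }
})

test_that("fold change reproduces hand-computed median ratios", {
  expect_equal(round(fold_change(0.408, 0.439)$fc, 3), 0.929)
  expect_equal(round(fold_change(1.930, 1.322)$fc, 3), 1.460)
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3))$fc, 1)
  fc <- fold_change(c(2, 4), c(1, 3))  # even-n midpoint medians: 3 / 2
  expect_equal(fc$fc, 1.5)
  expect_equal(fc$fc_reciprocal, 2 / 3)
  expect_error(fold_change(1, 0), "zero")
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("rank AUC equals brute-force pair enumeration", {
  r <- roc_auc(c(3, 5, 1, 4), rep(c("red", "half-red"), each = 2),
               fold = FALSE)
  expect_equal(r$auc_raw, 0.75)  # 3 of 4 pairs concordant

  set.seed(12)
  for (i in 1:500) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    v <- sample(1:8, n1 + n0, replace = TRUE)  # ties likely
    lab <- c(rep("red", n1), rep("half-red", n0))
    expect_equal(roc_auc(v, lab, fold = FALSE)$auc_raw, brute_auc(v, lab))
  }
})

test_that("AUC saturates for separated groups and folds orientation", {
  lab <- rep(c("red", "half-red"), each = 5)
  expect_equal(roc_auc(c(6:10, 1:5), lab)$auc, 1)
  # feature lower in the positive class: folded AUC still 1, direction -1
  r <- roc_auc(c(1:5, 6:10), lab)
  expect_equal(r$auc, 1)
  expect_equal(r$direction, -1)
  expect_error(roc_auc(1:4, rep("red", 4)), "both classes")

  set.seed(13)
  null <- roc_auc(rnorm(2000), sample(rep(c("red", "half-red"), 1000)),
                  fold = FALSE)
  expect_lt(abs(null$auc_raw - 0.5), 0.05)
})

test_that("bootstrap AUC interval is deterministic, containing, degenerate", {
  set.seed(14)
  v <- c(rnorm(20, 1), rnorm(20))
  lab <- rep(c("red", "half-red"), each = 20)
  ci1 <- auc_ci(v, lab, B = 500, seed = 9)
  ci2 <- auc_ci(v, lab, B = 500, seed = 9)
  expect_identical(ci1, ci2)
  a <- roc_auc(v, lab)$auc
  expect_lte(ci1[1], a); expect_gte(ci1[2], a)

  # disjoint supports: every resample is perfectly separated
  ci <- auc_ci(c(10:15, 1:6), rep(c("red", "half-red"), each = 6), B = 200)
  expect_equal(unname(ci), c(1, 1))

  small <- auc_ci(c(3, 4, 5, 1, 2, 6), rep(c("red", "half-red"), each = 3),
                  B = 500, seed = 2)
  expect_gt(small[2] - small[1], 0)  # wide at n = 3 per class
})

test_that("table_summary has one complete row per feature", {
  d <- study_design(seed = 15)
  en <- gen_enose(d)
  ft <- assemble_feature_table(en$traces, en$manifest)
  tab <- table_summary(ft, B = 200)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$feature, paste0("S", 1:10))
  expect_false(anyNA(tab[, setdiff(names(tab), "FC_reciprocal")]))
  expect_true(all(tab$AUC >= 0.5 & tab$AUC <= 1))
  expect_true(all(tab$CI_low <= tab$AUC + 1e-9))
  expect_true(all(tab$CI_high >= tab$AUC - 1e-9))
  expect_true(all(tab$p5_half_red <= tab$median_half_red))
  expect_true(all(tab$median_red <= tab$p95_red))

  # empty feature set
  expect_equal(nrow(table_summary(ft, feature_cols = character(0))), 0L)
})

test_that("saturated and inert sensors mirror the published pattern", {
  d <- study_design(seed = 16)
  en <- gen_enose(d)
  ft <- assemble_feature_table(en$traces, en$manifest)
  tab <- table_summary(ft, B = 200)
  rownames(tab) <- tab$feature
  # disjoint printed ranges: S7 and S9 saturate and are FDR significant
  expect_equal(tab["S7", "AUC"], 1)
  expect_equal(tab["S9", "AUC"], 1)
  expect_true(tab["S7", "fdr_significant"])
  expect_true(tab["S9", "fdr_significant"])
  # near-identical stage specs: S4 and S10 are the weakest discriminators
  inert <- tab$feature %in% c("S4", "S10")
  expect_lt(max(tab$AUC[inert]), min(tab$AUC[!inert]))
  expect_lt(tab["S4", "AUC"], 0.75)
  expect_lt(tab["S10", "AUC"], 0.75)
})
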