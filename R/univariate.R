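#' Linear mixed-effect test of the maturity-stage effect
#'
#' Random-intercept model: maturity stage as the fixed factor, the
#' biological sample (whose technical replicates share an intercept) as the
#' random factor; fitted by REML, Wald t-test on the stage contrast with
#' between-sample degrees of freedom (`n_samples - 2`).
#'
#' For balanced designs (every sample has the same number of replicates) the
#' between-sample Wald test has an exact closed form: it equals the pooled
#' two-sample t-test on the per-sample replicate means, and the ANOVA
#' estimators of the variance components coincide with REML. Unbalanced
#' designs are fitted numerically with `lme4::lmer`.
#'
#' @param values numeric response vector (one feature).
#' @param stage factor/character of stage labels (exactly two levels).
#' @param sample_id biological sample identifier per observation.
#' @return List: `p` (p-value), `estimate` (stage contrast, second level
#'   minus first), `se`, `df`, `sigma2_sample`, `sigma2_resid`, `method`.
#' @export
#'
#' @examples
#' d <- data.frame(stage = rep(c("half-red", "red"), each = 6),
#'                 sample = rep(1:4, each = 3),
#'                 y = rnorm(12) + rep(c(0, 1), each = 6))
#' lme_stage_test(d$y, d$stage, d$sample)$p
lme_stage_test <- function(values, stage, sample_id) {
  stage <- factor(stage)
  if (nlevels(stage) != 2L)
    stop("exactly two stage levels required", call. = FALSE)
  sample_id <- factor(paste(stage, sample_id)) # samples are nested in stage
  if (var(values) == 0)
    stop("zero total variance: stage test undefined", call. = FALSE)
  per_stage <- table(unique(data.frame(stage, sample_id))$stage)
  if (any(per_stage < 2))
    stop("need at least two biological samples per stage", call. = FALSE)

  reps <- table(sample_id)
  n_samp <- length(reps)
  df <- n_samp - 2L
  balanced <- length(unique(reps)) == 1L

  if (balanced) {
    m <- as.integer(reps[1])
    sm <- tapply(values, sample_id, mean)
    st_of_samp <- tapply(as.character(stage), sample_id, `[`, 1)
    g <- split(sm, st_of_samp)[levels(stage)]
    n1 <- length(g[[1]]); n2 <- length(g[[2]])
    ss_b <- sum((g[[1]] - mean(g[[1]]))^2) + sum((g[[2]] - mean(g[[2]]))^2)
    ms_between <- ss_b / df * m                  # per-observation scale
    ms_within <- if (m > 1)
      sum((values - ave(values, sample_id))^2) / (length(values) - n_samp)
    else 0
    est <- mean(g[[2]]) - mean(g[[1]])
    se <- sqrt(ms_between / m * (1 / n1 + 1 / n2))
    if (se == 0) stop("zero between-sample variance and zero residual ",
                      "variance: test undefined", call. = FALSE)
    tval <- est / se
    p <- 2 * pt(-abs(tval), df)
    list(p = p, estimate = est, se = se, df = df,
         sigma2_sample = max((ms_between - ms_within) / m, 0),
         sigma2_resid = ms_within, method = "closed-form (balanced)")
  } else {
    dat <- data.frame(y = values, stage = stage, sample_id = sample_id)
    fit <- lme4::lmer(y ~ stage + (1 | sample_id), data = dat, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    "ignore"))
    co <- summary(fit)$coefficients
    est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    p <- 2 * pt(-abs(est / se), df)
    list(p = p, estimate = est, se = se, df = df,
         sigma2_sample = vc$vcov[vc$grp == "sample_id"],
         sigma2_resid = vc$vcov[vc$grp == "Residual"],
         method = "lme4 (unbalanced)")
  }
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `delta`: adjusted p-values are monotone
#' non-decreasing in the raw p-values and a feature is declared significant
#' iff its adjusted p-value is at most `delta`.
#'
#' @param pvalues raw p-values in `[0, 1]`.
#' @param delta FDR level (default 0.05).
#' @return List: `adjusted` (BH-adjusted p-values) and `significant`
#'   (logical flags).
#' @export
benjamini_hochberg <- function(pvalues, delta = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, significant = adj <= delta)
}

#' Fold change between maturity stages
#'
#' Ratio of the red-stage median to the half-red-stage median (standard
#' midpoint convention for even sample sizes). The reciprocal is returned
#' alongside because published summary tables sometimes print either
#' direction.
#'
#' @param red,half_red numeric feature values per stage.
#' @return List: `fc` (median(red)/median(half_red)) and `fc_reciprocal`.
#' @export
#'
#' @examples
#' fold_change(0.408, 0.439)$fc  # 0.929...
fold_change <- function(red, half_red) {
  if (!length(red) || !length(half_red))
    stop("both stage groups must be non-empty", call. = FALSE)
  mh <- median(half_red)
  if (mh == 0) stop("half-red median is zero: fold change undefined",
                    call. = FALSE)
  mr <- median(red)
  list(fc = mr / mh, fc_reciprocal = if (mr == 0) NA_real_ else mh / mr)
}

#' Rank-based ROC AUC for the stage contrast
#'
#' AUC = (concordant pairs + half ties) / (n_pos * n_neg), computed from the
#' midrank formula. The reported AUC is folded to be at least 0.5 (a feature
#' that is lower in the positive class discriminates just as well); the
#' original direction is retained.
#'
#' @param values numeric feature values.
#' @param labels class labels.
#' @param positive label of the positive class (default `"red"`).
#' @param fold fold the AUC to `>= 0.5`? (default TRUE).
#' @return List: `auc` (folded if requested), `auc_raw`, `direction` (+1 if
#'   the positive class tends higher, -1 otherwise).
#' @export
roc_auc <- function(values, labels, positive = "red", fold = TRUE) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(values)                       # midranks handle ties
  auc_raw <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  auc <- if (fold) max(auc_raw, 1 - auc_raw) else auc_raw
  list(auc = auc, auc_raw = auc_raw,
       direction = if (auc_raw >= 0.5) 1 else -1)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval from `B` stratified resamples (each class resampled
#' with replacement within itself). With perfectly separated stages every
#' resample has AUC 1 and the interval degenerates to [1, 1].
#'
#' @param values,labels,positive as in [roc_auc()].
#' @param B number of bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return Numeric vector `c(low, high)`.
#' @export
auc_ci <- function(values, labels, positive = "red", B = 2000,
                   level = 0.95, seed = 1L) {
  pos_idx <- which(labels == positive); neg_idx <- which(labels != positive)
  if (!length(pos_idx) || !length(neg_idx))
    stop("both classes must be present", call. = FALSE)
  set.seed(seed)
  stat <- numeric(B)
  lab <- c(rep(TRUE, length(pos_idx)), rep(FALSE, length(neg_idx)))
  for (b in seq_len(B)) {
    v <- c(values[sample(pos_idx, replace = TRUE)],
           values[sample(neg_idx, replace = TRUE)])
    r <- rank(v)
    n1 <- length(pos_idx); n0 <- length(neg_idx)
    a <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    stat[b] <- max(a, 1 - a)
  }
  unname(quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
}

#' Per-feature univariate discrimination summary
#'
#' For every feature column: stage-wise median and 5th/95th percentiles
#' (linear-interpolation, type-7, convention), LME stage p-value, BH-FDR
#' flag, fold change (red over half-red), ROC AUC and its bootstrap CI —
#' the structure of a published univariate discrimination table.
#'
#' @param features data frame containing `stage`, `sample_id` and the
#'   feature columns.
#' @param feature_cols character vector naming the feature columns; default
#'   every numeric column except metadata.
#' @param positive stage treated as the positive (red) class; default the
#'   second sorted unique stage.
#' @param delta FDR level.
#' @param B,ci_seed bootstrap parameters for [auc_ci()].
#' @return Data frame, one row per feature: `feature`, `median_half_red`,
#'   `p5_half_red`, `p95_half_red`, `median_red`, `p5_red`, `p95_red`, `p`,
#'   `p_adjusted`, `fdr_significant`, `FC`, `FC_reciprocal`, `AUC`,
#'   `CI_low`, `CI_high`.
#' @export
table_summary <- function(features, feature_cols = NULL, positive = NULL,
                          delta = 0.05, B = 2000, ci_seed = 1L) {
  meta <- c("obs_id", "stage", "harvest", "sample", "replicate", "sample_id",
            "true_red_fraction")
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))], meta)
  if (!length(feature_cols))
    return(data.frame(feature = character(0)))
  stages <- sort(unique(as.character(features$stage)))
  if (is.null(positive)) positive <- stages[2]
  negative <- setdiff(stages, positive)[1]

  rows <- lapply(feature_cols, function(fc) {
    v <- features[[fc]]
    red <- v[features$stage == positive]
    half <- v[features$stage == negative]
    qh <- quantile(half, c(0.05, 0.5, 0.95), type = 7)
    qr <- quantile(red, c(0.05, 0.5, 0.95), type = 7)
    lme <- lme_stage_test(v, features$stage, features$sample_id)
    fcv <- fold_change(red, half)
    auc <- roc_auc(v, features$stage, positive = positive)
    ci <- auc_ci(v, features$stage, positive = positive, B = B,
                 seed = ci_seed)
    data.frame(feature = fc,
               median_half_red = qh[2], p5_half_red = qh[1],
               p95_half_red = qh[3],
               median_red = qr[2], p5_red = qr[1], p95_red = qr[3],
               p = lme$p, FC = fcv$fc, FC_reciprocal = fcv$fc_reciprocal,
               AUC = auc$auc, CI_low = ci[1], CI_high = ci[2],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  bh <- benjamini_hochberg(out$p, delta)
  out$p_adjusted <- bh$adjusted
  out$fdr_significant <- bh$significant
  out[, c("feature", "median_half_red", "p5_half_red", "p95_half_red",
          "median_red", "p5_red", "p95_red", "p", "p_adjusted",
          "fdr_significant", "FC", "FC_reciprocal", "AUC",
          "CI_low", "CI_high")]
}
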