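#' Study design for synthetic ripening-stage data
#'
#' Encodes the nested sampling layout the generators emulate: two maturity
#' stages (half-red, red) harvested at several consecutive times, a number of
#' pooled biological samples per stage and harvest, and modality-specific
#' technical replication (11 e-nose runs, 5 FTIR spectra and 8 images per
#' sample in the default layout).
#'
#' @param n_harvests number of harvest times (default 3).
#' @param samples_per_stage_per_harvest biological samples per stage at each
#'   harvest (default 4).
#' @param stages character vector of exactly two stage labels.
#' @param reps_enose,reps_ftir,reps_image technical replicates per sample for
#'   each modality.
#' @param seed integer seed; together with the design it fully determines
#'   every generated dataset.
#'
#' @return An object of class `study_design` (a named list).
#' @export
#'
#' @examples
#' d <- study_design(seed = 1)
#' d$n_harvests * d$samples_per_stage_per_harvest * 2 * d$reps_enose # 264
study_design <- function(n_harvests = 3L,
                         samples_per_stage_per_harvest = 4L,
                         stages = c("half-red", "red"),
                         reps_enose = 11L,
                         reps_ftir = 5L,
                         reps_image = 8L,
                         seed = 1L) {
  counts <- c(n_harvests = n_harvests,
              samples_per_stage_per_harvest = samples_per_stage_per_harvest,
              reps_enose = reps_enose, reps_ftir = reps_ftir,
              reps_image = reps_image)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be integers >= 1", call. = FALSE)
  if (length(stages) != 2L || anyDuplicated(stages))
    stop("`stages` must be exactly two distinct labels", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  structure(list(n_harvests = as.integer(n_harvests),
                 samples_per_stage_per_harvest =
                   as.integer(samples_per_stage_per_harvest),
                 stages = as.character(stages),
                 reps_enose = as.integer(reps_enose),
                 reps_ftir = as.integer(reps_ftir),
                 reps_image = as.integer(reps_image),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  n_samp <- 2L * x$n_harvests * x$samples_per_stage_per_harvest
  cat("Study design:", paste(x$stages, collapse = " vs "),
      "| harvests:", x$n_harvests,
      "| samples:", n_samp, "\n")
  cat("  technical replicates: e-nose", x$reps_enose,
      "/ FTIR", x$reps_ftir, "/ image", x$reps_image,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Median and 5th/95th percentile specification for one feature
#'
#' The summary the study reports per sensor and stage (median with 5th-95th
#' percentile range); generators draw plateau levels compatible with it.
#'
#' @param median,p5,p95 the three quantiles; must satisfy `p5 <= median <= p95`.
#' @return An object of class `quantile_spec`.
#' @export
quantile_spec <- function(median, p5, p95) {
  if (!(is.finite(median) && is.finite(p5) && is.finite(p95)))
    stop("quantile_spec values must be finite", call. = FALSE)
  if (p5 > median || median > p95)
    stop("quantile_spec requires p5 <= median <= p95", call. = FALSE)
  structure(list(median = median, p5 = p5, p95 = p95),
            class = "quantile_spec")
}

#' Draw feature levels compatible with a quantile specification
#'
#' Samples from a normal with mean equal to the spec's median and sd
#' `(p95 - p5)/3.29` (the normal 5th-95th percentile spacing), clamped to
#' `[p5, p95]` so the support never leaves the reported range. For a
#' symmetric spec the clamped draw reproduces the median and both tail
#' percentiles exactly in distribution.
#'
#' @param n number of draws.
#' @param spec a [quantile_spec()].
#' @return Numeric vector of length `n`.
#' @export
#'
#' @examples
#' x <- sample_from_spec(1000, quantile_spec(1.93, 1.506, 2.198))
#' range(x)  # within [1.506, 2.198]
sample_from_spec <- function(n, spec) {
  stopifnot(inherits(spec, "quantile_spec"))
  rnorm_clamped(n, spec$median, sd_from_span(spec$p5, spec$p95),
                spec$p5, spec$p95)
}

# enumerate biological samples of a design for one modality
design_samples <- function(design) {
  g <- expand.grid(sample = seq_len(design$samples_per_stage_per_harvest),
                   harvest = seq_len(design$n_harvests),
                   stage = design$stages,
                   stringsAsFactors = FALSE)
  g$sample_id <- sample_id(g$stage, g$harvest, g$sample)
  g[order(g$stage, g$harvest, g$sample), c("stage", "harvest", "sample", "sample_id")]
}
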