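#' Default stage-wise quantile specifications for the 10 MOS sensors
#'
#' Median and 5th/95th percentiles of the G/G0 window response per sensor and
#' maturity stage, as observed for half-red and red strawberries. Sensors S7
#' and S9 have disjoint stage ranges (perfect discriminators); S4 and S10 are
#' nearly stage-invariant.
#'
#' @return Nested list: `specs[[sensor]][[stage]]` is a [quantile_spec()].
#' @export
enose_default_specs <- function() {
  tab <- list(
    S1  = list(`half-red` = c(0.439, 0.415, 0.456), red = c(0.408, 0.364, 0.429)),
    S2  = list(`half-red` = c(3.812, 3.416, 4.185), red = c(4.710, 3.924, 5.541)),
    S3  = list(`half-red` = c(0.430, 0.409, 0.443), red = c(0.389, 0.359, 0.414)),
    S4  = list(`half-red` = c(1.075, 1.061, 1.084), red = c(1.077, 1.067, 1.085)),
    S5  = list(`half-red` = c(0.421, 0.398, 0.443), red = c(0.380, 0.356, 0.406)),
    S6  = list(`half-red` = c(3.907, 3.691, 4.225), red = c(4.198, 3.845, 4.669)),
    S7  = list(`half-red` = c(1.322, 1.234, 1.445), red = c(1.930, 1.506, 2.198)),
    S8  = list(`half-red` = c(5.713, 5.349, 6.303), red = c(6.370, 5.671, 6.974)),
    S9  = list(`half-red` = c(1.800, 1.642, 1.950), red = c(2.283, 2.042, 2.555)),
    S10 = list(`half-red` = c(1.196, 1.160, 1.224), red = c(1.204, 1.172, 1.226))
  )
  lapply(tab, function(s) lapply(s, function(q) quantile_spec(q[1], q[2], q[3])))
}

enose_sensor_names <- function() paste0("S", 1:10)

# draw one plateau level: stage-level normal with a sample-level random
# intercept (10% of the stage-level variance), clamped to the printed range
draw_plateau <- function(n, spec, sample_offset_frac) {
  s <- sd_from_span(spec$p5, spec$p95)
  rnorm_clamped(n, spec$median + sample_offset_frac * s, sqrt(0.9) * s,
                spec$p5, spec$p95)
}

#' Generate synthetic e-nose measurements
#'
#' Simulates conductance-ratio (G/G0) traces for a 10-sensor MOS array over
#' an 80 s acquisition at 1 Hz. Each trace rises from 1 with exponential
#' saturation and holds a plateau well before 70 s; the plateau level is drawn
#' per sensor from a stage-specific normal with mean equal to the stage
#' median, sd `(p95 - p5)/3.29`, clamped to `[p5, p95]`. Replicates of one
#' biological sample share a random offset (variance 10% of the stage-level
#' variance) so the within-sample spread is smaller than the between-sample
#' spread.
#'
#' @param design a [study_design()].
#' @param sensor_specs nested list `specs[[sensor]][[stage]]` of
#'   [quantile_spec()] covering all 10 sensors for both stages; defaults to
#'   [enose_default_specs()].
#' @param trace_noise_sd additive measurement noise on the trace (G/G0 units).
#' @param tau_s time constant of the saturating rise, seconds.
#'
#' @return A list with `traces` (data frame: obs_id, sensor, time_s, value),
#'   `plateaus` (data frame of true plateau levels, one row per observation x
#'   sensor) and `manifest` (observation metadata: obs_id, stage, harvest,
#'   sample, replicate, sample_id).
#' @export
#'
#' @examples
#' en <- gen_enose(study_design(seed = 7))
#' nrow(en$manifest)  # 264 observations
gen_enose <- function(design, sensor_specs = enose_default_specs(),
                      trace_noise_sd = 5e-4, tau_s = 6) {
  sensors <- enose_sensor_names()
  for (sn in sensors) {
    sp <- sensor_specs[[sn]]
    if (is.null(sp)) stop("missing sensor spec: ", sn, call. = FALSE)
    for (st in design$stages) {
      if (is.null(sp[[st]]) || !inherits(sp[[st]], "quantile_spec"))
        stop("missing quantile_spec for sensor ", sn, ", stage ", st,
             call. = FALSE)
    }
  }
  set.seed(design$seed)
  samp <- design_samples(design)
  time_s <- 0:80
  rise <- 1 - exp(-time_s / tau_s)

  n_obs <- nrow(samp) * design$reps_enose
  manifest <- data.frame(
    obs_id = character(n_obs), stage = character(n_obs),
    harvest = integer(n_obs), sample = integer(n_obs),
    replicate = integer(n_obs), sample_id = character(n_obs),
    stringsAsFactors = FALSE)
  plateaus <- vector("list", n_obs)
  traces <- vector("list", n_obs)

  k <- 0L
  for (i in seq_len(nrow(samp))) {
    # one shared nesting offset per sample (in sd units, weight sqrt(0.1))
    offs <- setNames(rnorm(length(sensors), 0, sqrt(0.1)), sensors)
    for (r in seq_len(design$reps_enose)) {
      k <- k + 1L
      id <- obs_id(samp$stage[i], samp$harvest[i], samp$sample[i], r)
      manifest[k, ] <- list(id, samp$stage[i], samp$harvest[i],
                            samp$sample[i], r, samp$sample_id[i])
      pl <- vapply(sensors, function(sn)
        draw_plateau(1L, sensor_specs[[sn]][[samp$stage[i]]], offs[[sn]]),
        numeric(1))
      plateaus[[k]] <- data.frame(obs_id = id, sensor = sensors,
                                  plateau = unname(pl),
                                  stringsAsFactors = FALSE)
      vals <- outer(rise, pl - 1) + 1 +
        matrix(rnorm(length(time_s) * length(sensors), 0, trace_noise_sd),
               nrow = length(time_s))
      vals[vals <= 0] <- .Machine$double.eps
      traces[[k]] <- data.frame(
        obs_id = id,
        sensor = rep(sensors, each = length(time_s)),
        time_s = rep(time_s, times = length(sensors)),
        value = as.vector(vals), stringsAsFactors = FALSE)
    }
  }
  list(traces = do.call(rbind, traces),
       plateaus = do.call(rbind, plateaus),
       manifest = manifest)
}
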