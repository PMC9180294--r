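#' Relative conductance trace (G/G0)
#'
#' Converts a raw conductance series to the dimensionless sensor response
#' G/G0, the ratio of the conductance under sample gas to the conductance
#' under clean gas.
#'
#' @param raw numeric vector of raw conductance values.
#' @param baseline single positive clean-gas conductance G0.
#' @param time_s time grid (seconds) matching `raw`; strictly increasing.
#' @return Data frame with columns `time_s` and `value` (= raw / baseline).
#' @export
#'
#' @examples
#' relative_conductance(c(2, 4, 6), 2, 0:2)$value  # 1 2 3
relative_conductance <- function(raw, baseline, time_s = seq_along(raw) - 1) {
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline) ||
      baseline <= 0)
    stop("`baseline` must be a single positive conductance", call. = FALSE)
  if (any(!is.finite(raw)))
    stop("raw conductance contains non-finite values", call. = FALSE)
  if (length(time_s) != length(raw) || any(diff(time_s) <= 0))
    stop("`time_s` must be strictly increasing and match `raw`", call. = FALSE)
  data.frame(time_s = time_s, value = raw / baseline)
}

#' Sensor window feature: mean response over a time window
#'
#' The per-sensor feature entering the statistics is the average G/G0
#' response on the late, plateaued part of the acquisition (default
#' 70-75 s, both endpoints included). On the uniform 1 Hz grid the grid-point
#' mean and the trapezoidal integral divided by the window length agree to
#' within 0.1%; both are computed and their agreement is asserted.
#'
#' @param trace data frame with `time_s` and `value` (e.g. from
#'   [relative_conductance()] or one sensor of [gen_enose()] output).
#' @param window length-2 numeric, window start and end in seconds.
#' @return Single numeric feature value (the grid-point mean).
#' @export
#'
#' @examples
#' tr <- data.frame(time_s = 0:80, value = 0:80)
#' window_feature(tr)  # 72.5
window_feature <- function(trace, window = c(70, 75)) {
  t <- trace$time_s; v <- trace$value
  if (window[1] >= window[2]) stop("empty window", call. = FALSE)
  if (window[1] < min(t) || window[2] > max(t))
    stop("window outside trace support", call. = FALSE)
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 2L)
    stop("fewer than 2 grid points inside the window", call. = FALSE)
  m <- mean(v[sel])
  tw <- t[sel]; vw <- v[sel]
  trap <- sum(diff(tw) * (head(vw, -1) + vw[-1]) / 2) / (max(tw) - min(tw))
  if (abs(trap - m) > 1e-3 * max(abs(m), .Machine$double.eps))
    stop("grid-point mean and trapezoidal mean disagree by more than 0.1%; ",
         "is the grid uniform?", call. = FALSE)
  m
}

#' Assemble the e-nose feature table
#'
#' One row per observation (sample x technical replicate), one column per
#' sensor, each cell the [window_feature()] of that sensor's trace.
#'
#' @param traces long data frame with `obs_id`, `sensor`, `time_s`, `value`
#'   (the `traces` element of [gen_enose()] or read from CSV).
#' @param manifest observation metadata with `obs_id`, `stage`, `sample_id`
#'   (and any further columns, carried through).
#' @param window passed to [window_feature()].
#' @return Data frame: manifest columns followed by S1..S10 feature columns.
#' @export
assemble_feature_table <- function(traces, manifest, window = c(70, 75)) {
  sensors <- enose_sensor_names()
  key <- interaction(traces$obs_id, traces$sensor, drop = TRUE)
  split_tr <- split(traces[, c("time_s", "value")], key)
  # uniqueness: within one (obs, sensor) trace, time points must not repeat
  if (any(vapply(split_tr, function(d) anyDuplicated(d$time_s) > 0, logical(1))))
    stop("duplicate (observation, replicate, sensor) trace points", call. = FALSE)
  feats <- matrix(NA_real_, nrow(manifest), length(sensors),
                  dimnames = list(manifest$obs_id, sensors))
  for (id in manifest$obs_id) {
    for (sn in sensors) {
      k <- paste(id, sn, sep = ".")
      d <- split_tr[[k]]
      if (is.null(d))
        stop("missing sensor ", sn, " for observation ", id, call. = FALSE)
      feats[id, sn] <- window_feature(d[order(d$time_s), ], window)
    }
  }
  stopifnot(!anyNA(feats))
  cbind(manifest, as.data.frame(feats))
}
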