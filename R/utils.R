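#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif qnorm pnorm median quantile sd var cor
#'   pt hclust dist cutree setNames t.test aggregate ave p.adjust
#' @importFrom utils read.csv write.csv write.table read.delim head
#' @importFrom graphics hist
NULL

# Draw from a normal clamped (winsorized) to [lo, hi]. Clamping, rather than
# rejection, keeps the 5th/95th percentiles on the interval endpoints when
# lo/hi are the 5%/95% quantiles of the parent normal, and guarantees the
# support never leaves [lo, hi].
rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# sd implied by a 5th-95th percentile span of a normal
sd_from_span <- function(p5, p95) (p95 - p5) / 3.29

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
}

# stable observation id used across tables and the manifest
obs_id <- function(stage, harvest, sample, replicate) {
  sprintf("%s_H%d_s%02d_r%02d", stage, harvest, sample, replicate)
}

sample_id <- function(stage, harvest, sample) {
  sprintf("%s_H%d_s%02d", stage, harvest, sample)
}
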