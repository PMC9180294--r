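#' Default synthetic FTIR band table
#'
#' Gaussian band parameters used by [gen_ftir()]. Three bands carry the
#' ripening signal: the broad O-H stretch near 3295 cm-1 (stronger in
#' half-red fruit, tracking organic acids) and the C=O band at 1717 cm-1 and
#' sugar-fingerprint band at 1026 cm-1 (both stronger in red fruit). C-H
#' bands at 2928/2891 cm-1 and the CH2 band near 1400 cm-1 are
#' stage-invariant.
#'
#' @return Data frame with columns `center`, `width`, `amp_half_red`,
#'   `amp_red` (centers and widths in cm-1, amplitudes in absorbance units).
#' @export
ftir_default_bands <- function() {
  data.frame(
    center       = c(3295, 2928, 2891, 1717, 1400, 1026),
    width        = c(80,    18,   14,   22,   45,   35),
    amp_half_red = c(1.00, 0.30, 0.22, 0.22, 0.35, 0.55),
    amp_red      = c(0.65, 0.30, 0.22, 0.42, 0.35, 0.95)
  )
}

#' Wavenumber grid used throughout the package
#'
#' 600-4000 cm-1 inclusive at 1 cm-1 steps: 3401 points.
#' @return Numeric vector of wavenumbers.
#' @export
ftir_grid <- function() seq(600, 4000, by = 1)

#' Generate synthetic ATR-FTIR spectra
#'
#' One pooled sample per stage and harvest, `reps_ftir` technical replicates
#' each (default design: 2 x 3 x 5 = 30 spectra). A spectrum is the sum of
#' Gaussian bands plus a random linear baseline, a per-spectrum
#' multiplicative scatter factor and additive noise, so SNV preprocessing is
#' non-trivially exercised. Stage-dependent amplitudes get a sample-level
#' random effect (10% of the between-stage amplitude contrast) and smaller
#' replicate-level jitter.
#'
#' @param design a [study_design()].
#' @param band_table data frame as returned by [ftir_default_bands()].
#' @param noise_sd additive noise sd (absorbance units).
#' @param scatter_range range of the uniform multiplicative scatter factor.
#' @param baseline_max maximum absolute baseline offset/tilt.
#'
#' @return A list with `spectra` (matrix observations x 3401), `wavenumber`,
#'   and `manifest` (obs_id, stage, harvest, replicate, sample_id).
#' @export
gen_ftir <- function(design, band_table = ftir_default_bands(),
                     noise_sd = 0.002, scatter_range = c(0.75, 1.3),
                     baseline_max = 0.08) {
  if (any(band_table$width <= 0))
    stop("band widths must be positive", call. = FALSE)
  if (any(band_table$amp_half_red <= 0) || any(band_table$amp_red <= 0))
    stop("band amplitudes must be positive", call. = FALSE)
  set.seed(design$seed + 1L)
  wn <- ftir_grid()
  # unit-height Gaussian profiles, one column per band
  profiles <- sapply(seq_len(nrow(band_table)), function(b)
    exp(-0.5 * ((wn - band_table$center[b]) / band_table$width[b])^2))

  stages <- design$stages
  n_obs <- 2L * design$n_harvests * design$reps_ftir
  spectra <- matrix(0, n_obs, length(wn))
  manifest <- data.frame(obs_id = character(n_obs), stage = character(n_obs),
                         harvest = integer(n_obs), replicate = integer(n_obs),
                         sample_id = character(n_obs), stringsAsFactors = FALSE)
  contrast <- abs(band_table$amp_red - band_table$amp_half_red)
  k <- 0L
  for (st in stages) {
    amps_stage <- if (st == stages[1]) band_table$amp_half_red else
      band_table$amp_red
    for (h in seq_len(design$n_harvests)) {
      # pooled biological sample: shared band-amplitude offset, sd 10% of
      # the stage contrast (plus a floor so invariant bands vary a little)
      amp_sample <- amps_stage + rnorm(length(amps_stage), 0,
                                       0.1 * contrast + 0.01)
      amp_sample <- pmax(amp_sample, 0.01)
      for (r in seq_len(design$reps_ftir)) {
        k <- k + 1L
        amp <- pmax(amp_sample * (1 + rnorm(length(amp_sample), 0, 0.02)), 0.005)
        base <- runif(1, -baseline_max, baseline_max) +
          runif(1, -baseline_max, baseline_max) * (wn - 600) / 3400
        scatter <- runif(1, scatter_range[1], scatter_range[2])
        spectra[k, ] <- scatter * as.vector(profiles %*% amp) + base +
          rnorm(length(wn), 0, noise_sd)
        manifest[k, ] <- list(obs_id(st, h, 1L, r), st, h, r,
                              sample_id(st, h, 1L))
      }
    }
  }
  rownames(spectra) <- manifest$obs_id
  colnames(spectra) <- wn
  list(spectra = spectra, wavenumber = wn, manifest = manifest)
}
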