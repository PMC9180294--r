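#' Names of the 57 volatile compounds in the synthetic VOC panel
#'
#' Generic ester/aldehyde/terpene-style identifiers plus the two compounds
#' given distinct, weaker stage structure: 2-methylbutanoic acid (`Ac4`) and
#' mesifurane (`F1`).
#' @return Character vector of length 57.
#' @export
voc_names <- function() {
  c(sprintf("V%02d", 1:55), "Ac4", "F1")
}

#' Generate the synthetic chemistry panel and VOC table
#'
#' One row per biological sample (default design: 24 samples). The chemistry
#' panel follows the ripening chemistry of strawberries: titratable acidity
#' (TA, % citric acid), total phenols (TP, mg GAE/100 g) and antioxidant
#' activity (AA, umol TE/g) share a positively correlated latent "acidity"
#' block that is higher in half-red fruit, while total soluble solids (TSS,
#' degrees Brix) loads on it negatively and is higher in red fruit. The VOC
#' table has 57 non-negative relative-peak-area (RPA%%) columns; most VOCs
#' rise sharply in red fruit through a shared aroma latent, while `Ac4` and
#' `F1` get a weaker stage effect driven by an independent latent so cluster
#' analysis can isolate them.
#'
#' @param design a [study_design()].
#' @return List of data frames `chemistry` (sample_id, stage, harvest, TA,
#'   TP, AA, TSS) and `voc` (sample_id, stage, harvest + 57 compound
#'   columns).
#' @export
#'
#' @examples
#' cv <- gen_chemistry_voc(study_design(seed = 3))
#' cor(cv$chemistry$TA, cv$chemistry$TSS) < 0
gen_chemistry_voc <- function(design) {
  set.seed(design$seed + 3L)
  samp <- design_samples(design)
  n <- nrow(samp)
  red <- as.numeric(samp$stage == design$stages[2])

  # latent ripeness score: higher in red, with biological scatter
  ripeness <- red + rnorm(n, 0, 0.25)
  acid_lat <- -ripeness + rnorm(n, 0, 0.20)   # acidity block latent

  chemistry <- data.frame(
    sample_id = samp$sample_id, stage = samp$stage, harvest = samp$harvest,
    TA  = 0.80 + 0.10 * acid_lat + rnorm(n, 0, 0.02),
    TP  = 220 + 25 * acid_lat + rnorm(n, 0, 6),
    AA  = 18 + 2.5 * acid_lat + rnorm(n, 0, 0.6),
    TSS = 9.3 + 0.5 * ripeness + rnorm(n, 0, 0.15),
    stringsAsFactors = FALSE)

  nm <- voc_names()
  main <- setdiff(nm, c("Ac4", "F1"))
  voc <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  base <- runif(length(main), 0.2, 4)      # compound-specific abundance scale
  gain <- runif(length(main), 0.6, 1.6)    # stage-effect strength
  for (j in seq_along(main)) {
    voc[, main[j]] <- pmax(
      base[j] * (1 + gain[j] * ripeness) * exp(rnorm(n, 0, 0.15)), 0)
  }
  # Ac4 / F1: weak stage effect + shared independent latent
  side <- rnorm(n, 0, 1)
  for (cmp in c("Ac4", "F1")) {
    voc[, cmp] <- pmax(1.5 * (1 + 0.15 * ripeness + 0.45 * side) *
                         exp(rnorm(n, 0, 0.1)), 0)
  }
  voc <- data.frame(sample_id = samp$sample_id, stage = samp$stage,
                    harvest = samp$harvest, voc, check.names = FALSE,
                    stringsAsFactors = FALSE)
  list(chemistry = chemistry, voc = voc)
}
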