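# Independent oracles used across test files.

# brute-force AUC: enumerate all (positive, negative) pairs
brute_auc <- function(values, labels, positive = "red") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Benjamini-Hochberg adjusted p-values from the max-min closed form
bh_closed_form <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}

# small balanced nested dataset with a known stage effect
make_nested <- function(n_samples_per_stage = 4, reps = 5, effect = 1,
                        sigma_sample = 0.3, sigma_resid = 1, seed = 1) {
  set.seed(seed)
  n_samp <- 2 * n_samples_per_stage
  samp <- rep(seq_len(n_samp), each = reps)
  stage <- rep(c("half-red", "red"), each = n_samples_per_stage * reps)
  y <- rnorm(n_samp, 0, sigma_sample)[samp] +
    rnorm(n_samp * reps, 0, sigma_resid) + (stage == "red") * effect
  data.frame(y = y, stage = stage, sample_id = samp)
}

tiny_design <- function(seed = 1, ...) {
  study_design(n_harvests = 1L, samples_per_stage_per_harvest = 2L,
               reps_enose = 3L, reps_ftir = 2L, reps_image = 2L,
               seed = seed, ...)
}
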