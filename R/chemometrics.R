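preprocess_matrix <- function(X, preprocessing, center = NULL, scale = NULL) {
  if (preprocessing == "snv-mean-center") X <- snv(X)
  if (is.null(center)) center <- colMeans(X)
  X <- sweep(X, 2, center, "-")
  if (preprocessing == "autoscale") {
    if (is.null(scale)) {
      scale <- apply(X, 2, sd)
      if (any(scale == 0))
        stop("zero-variance column under autoscaling", call. = FALSE)
    }
    X <- sweep(X, 2, scale, "/")
  }
  attr(X, "center") <- center
  attr(X, "scale") <- scale
  X
}

#' Principal component analysis with explained variance per component
#'
#' Fits PCA by singular value decomposition after the chosen preprocessing:
#' `"mean-center"` (column centering), `"autoscale"` (centering and unit
#' column variance) or `"snv-mean-center"` (row-wise SNV, then column
#' centering — the standard choice for absorbance spectra). Explained
#' variance per component is the squared singular value over the total sum
#' of squares of the preprocessed matrix. Loading signs follow the
#' convention that each component's largest-magnitude loading element is
#' positive.
#'
#' @param X numeric matrix, observations in rows.
#' @param n_components number of components to retain.
#' @param preprocessing one of `"mean-center"`, `"autoscale"`,
#'   `"snv-mean-center"`.
#' @return Object of class `pca_model`: `loadings` (variables x components),
#'   `scores` (observations x components), `r2_per_component`, `r2_cum`,
#'   `singular_values`, `preprocessing`, `center`, `scale`.
#' @export
pca_fit <- function(X, n_components = 2,
                    preprocessing = c("mean-center", "autoscale",
                                      "snv-mean-center")) {
  preprocessing <- match.arg(preprocessing)
  X <- as.matrix(X)
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop("n_components exceeds min(rows - 1, cols)", call. = FALSE)
  Xp <- preprocess_matrix(X, preprocessing)
  sv <- svd(Xp, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  loadings <- sv$v
  scores <- sv$u %*% diag(d, n_components)
  for (a in seq_len(n_components)) { # reproducible sign convention
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  tss <- sum(Xp^2)
  r2 <- d^2 / tss
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  structure(list(loadings = loadings, scores = scores,
                 r2_per_component = r2, r2_cum = sum(r2),
                 singular_values = d, preprocessing = preprocessing,
                 center = attr(Xp, "center"), scale = attr(Xp, "scale")),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", length(x$r2_per_component), "components,",
      x$preprocessing, "\n")
  cat("  R2 per component:",
      paste(sprintf("%.3f", x$r2_per_component), collapse = " "),
      "| cumulative:", sprintf("%.3f", x$r2_cum), "\n")
  invisible(x)
}

#' Cross-validated Q2 of a PCA model
#'
#' Venetian-blind cross-validation of the explained variance: observations
#' (or whole biological samples, when `sample_id` is given, so technical
#' replicates never leak across folds) are assigned to folds in rotation;
#' each fold is predicted from a model fitted on the remainder, including
#' the preprocessing parameters. A held-out row is reconstructed variable by
#' variable with a leave-one-variable-out projection: variable j is
#' predicted from scores computed without variable j, which prevents the
#' trivial self-prediction leak of naive row projection. Q2 = 1 -
#' PRESS/TSS, with TSS the total sum of squares of the fully preprocessed
#' matrix.
#'
#' @param X numeric matrix, observations in rows.
#' @param n_components components of the cross-validated model.
#' @param preprocessing as in [pca_fit()].
#' @param folds number of venetian-blind folds (default 7).
#' @param sample_id optional per-row sample identifiers for grouped fold
#'   assignment.
#' @param seed integer; fixes the (deterministic) fold rotation origin.
#' @return Single numeric Q2 (can be negative for structureless data).
#' @export
pca_q2 <- function(X, n_components = 2,
                   preprocessing = c("mean-center", "autoscale",
                                     "snv-mean-center"),
                   folds = 7, sample_id = NULL, seed = 1L) {
  preprocessing <- match.arg(preprocessing)
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("need 2 <= folds <= rows", call. = FALSE)
  if (is.null(sample_id)) sample_id <- seq_len(n)
  units <- sort(unique(sample_id))
  if (folds > length(units))
    stop("more folds than distinct samples", call. = FALSE)
  offset <- seed %% folds
  unit_fold <- ((seq_along(units) - 1L + offset) %% folds) + 1L
  fold <- unit_fold[match(sample_id, units)]

  Xfull <- preprocess_matrix(X, preprocessing)
  tss <- sum(Xfull^2)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    Xtr <- preprocess_matrix(X[tr, , drop = FALSE], preprocessing)
    a <- min(n_components, nrow(Xtr) - 1L, ncol(Xtr))
    sv <- svd(Xtr, nu = 0, nv = a)
    P <- sv$v                                  # p x a, orthonormal columns
    Xte <- preprocess_matrix(X[te, , drop = FALSE], preprocessing,
                             center = attr(Xtr, "center"),
                             scale = attr(Xtr, "scale"))
    S <- Xte %*% P                             # rows x a
    for (i in seq_len(nrow(Xte))) {
      x <- Xte[i, ]; s <- S[i, ]
      # leave-one-variable-out projection via Sherman-Morrison:
      # (P_{-j}'P_{-j})^{-1} = I + p_j p_j' / (1 - |p_j|^2)
      pj2 <- rowSums(P^2)
      U <- -P * x + matrix(s, nrow(P), ncol(P), byrow = TRUE) # u_j = s - x_j p_j
      updj <- rowSums(U * P)
      denom <- pmax(1 - pj2, 1e-12)
      Tj <- U + P * (updj / denom)
      xhat <- rowSums(Tj * P)
      press <- press + sum((xhat - x)^2)
    }
  }
  1 - press / tss
}

#' Per-sample medians of PCA scores
#'
#' Component-wise median of the technical-replicate scores of each
#' biological sample — the summary overlaid on score scatter plots to show
#' that within-sample (technical) spread is smaller than the biological
#' spread.
#'
#' @param scores observations x components matrix.
#' @param sample_id per-observation sample identifiers.
#' @return List: `medians` (samples x components matrix, rownames =
#'   sample id) and `sample_id` order.
#' @export
replicate_medians <- function(scores, sample_id) {
  scores <- as.matrix(scores)
  if (length(sample_id) != nrow(scores))
    stop("every observation needs a sample id", call. = FALSE)
  ids <- unique(sample_id)
  med <- t(vapply(ids, function(s)
    apply(scores[sample_id == s, , drop = FALSE], 2, median),
    numeric(ncol(scores))))
  rownames(med) <- ids
  list(medians = med, sample_id = ids)
}
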