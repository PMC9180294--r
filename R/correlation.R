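#' Two-block Pearson correlation map with significance
#'
#' Pearson correlation of every feature of block A against every feature of
#' block B, over shared observations (rows), with a two-sided t-test
#' p-value per coefficient and a significance mask at level `alpha`.
#'
#' @param A,B numeric data frames/matrices with the same rows (observations)
#'   and features in columns.
#' @param alpha significance level for the mask (default 0.05).
#' @return Object of class `correlation_map`: `rho` (A-features x
#'   B-features), `pvals`, `significant`, `n`, `alpha`.
#' @export
#'
#' @examples
#' m <- two_block_pearson(data.frame(x = 1:4), data.frame(y = c(2, 1, 4, 3)))
#' m$rho  # 0.6
two_block_pearson <- function(A, B, alpha = 0.05) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B))
    stop("blocks must share the same observations", call. = FALSE)
  n <- nrow(A)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(apply(A, 2, sd) == 0) || any(apply(B, 2, sd) == 0))
    stop("zero-variance feature", call. = FALSE)
  rho <- cor(A, B)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pvals <- 2 * pt(-abs(tstat), n - 2)
  pvals[abs(rho) >= 1] <- 0
  structure(list(rho = rho, pvals = pvals, significant = pvals <= alpha,
                 n = n, alpha = alpha),
            class = "correlation_map")
}

#' Ward clustering of correlation profiles
#'
#' Agglomerative clustering of the rows or columns of a correlation matrix
#' (each feature represented by its profile of correlations with the other
#' block), using Euclidean distance and Ward's method (`ward.D2`, the
#' variant consistent with squared Euclidean Ward clustering on
#' untransformed distances).
#'
#' @param rho correlation matrix from [two_block_pearson()].
#' @param axis `"rows"` or `"cols"`: which block's features to cluster.
#' @param k number of clusters to cut the tree at.
#' @return List: `assignments` (named integer vector), `tree` (hclust
#'   object).
#' @export
cluster_features <- function(rho, axis = c("rows", "cols"), k = 2) {
  axis <- match.arg(axis)
  profiles <- if (axis == "rows") rho else t(rho)
  if (nrow(profiles) < 2)
    stop("need at least 2 features on the clustered axis", call. = FALSE)
  if (k > nrow(profiles))
    stop("k exceeds the number of features", call. = FALSE)
  tree <- hclust(dist(profiles, method = "euclidean"), method = "ward.D2")
  list(assignments = cutree(tree, k = k), tree = tree)
}

#' Silhouette-based selection of the number of clusters
#'
#' Computes the mean silhouette width of the Ward partition for each
#' candidate k and returns the k with the maximum mean width (ties go to
#' the smallest k).
#'
#' @param profiles numeric matrix, one feature (row) per clustered object —
#'   typically rows/columns of a correlation matrix.
#' @param k_range candidate cluster counts; default `2:min(8, n - 1)`.
#' @return List: `k` (selected), `widths` (named mean silhouette width per
#'   candidate k).
#' @export
silhouette_select_k <- function(profiles, k_range = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 3) stop("need at least 3 features", call. = FALSE)
  d <- dist(profiles, method = "euclidean")
  if (all(d < 1e-12))
    stop("all profiles identical: cluster count undefined", call. = FALSE)
  if (is.null(k_range)) k_range <- 2:min(8, n - 1)
  tree <- hclust(d, method = "ward.D2")
  widths <- vapply(k_range, function(k) {
    sil <- cluster::silhouette(cutree(tree, k = k), d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(widths) <- k_range
  list(k = k_range[which.max(widths)], widths = widths)
}

#' Cluster both axes of a correlation map
#'
#' Runs [silhouette_select_k()] and [cluster_features()] on each axis of a
#' [two_block_pearson()] result.
#'
#' @param map a `correlation_map`.
#' @param k_rows,k_cols fixed cluster counts; `NULL` (default) selects them
#'   by silhouette analysis.
#' @return The map with `row_clusters`, `col_clusters`, `k_rows`, `k_cols`,
#'   `row_tree`, `col_tree` added.
#' @export
cluster_correlation_map <- function(map, k_rows = NULL, k_cols = NULL) {
  stopifnot(inherits(map, "correlation_map"))
  if (is.null(k_rows)) k_rows <- silhouette_select_k(map$rho)$k
  if (is.null(k_cols)) k_cols <- silhouette_select_k(t(map$rho))$k
  cr <- cluster_features(map$rho, "rows", k_rows)
  cc <- cluster_features(map$rho, "cols", k_cols)
  map$row_clusters <- cr$assignments; map$row_tree <- cr$tree
  map$col_clusters <- cc$assignments; map$col_tree <- cc$tree
  map$k_rows <- k_rows; map$k_cols <- k_cols
  map
}

#' Export a clustered correlation map as heatmap and TSV
#'
#' Writes (1) a dendrogram-ordered heatmap with cluster colour bars
#' (non-significant coefficients can be blanked on the plot but are always
#' retained in the TSV) and (2) a long-format TSV of every coefficient with
#' its p-value, significance flag and cluster assignments. Reading the TSV
#' back reproduces `rho` to full precision.
#'
#' @param map a clustered `correlation_map` (see
#'   [cluster_correlation_map()]).
#' @param path output path stem; writes `<path>.png` and `<path>.tsv`.
#' @param blank_nonsignificant hide non-significant cells on the plot?
#' @return Invisibly, the TSV path.
#' @export
heatmap_export <- function(map, path, blank_nonsignificant = TRUE) {
  stopifnot(inherits(map, "correlation_map"),
            !is.null(map$row_clusters), !is.null(map$col_clusters))
  tsv <- paste0(path, ".tsv")
  long <- expand.grid(row_feature = rownames(map$rho),
                      col_feature = colnames(map$rho),
                      stringsAsFactors = FALSE)
  long$rho <- sprintf("%.17g", as.vector(map$rho))   # exact round-trip
  long$p <- sprintf("%.17g", as.vector(map$pvals))
  long$significant <- as.vector(map$significant)
  long$row_cluster <- map$row_clusters[long$row_feature]
  long$col_cluster <- map$col_clusters[long$col_feature]
  write.table(long, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  shown <- map$rho
  if (blank_nonsignificant) shown[!map$significant] <- NA
  ann_row <- data.frame(cluster = factor(map$row_clusters),
                        row.names = rownames(map$rho))
  ann_col <- data.frame(cluster = factor(map$col_clusters),
                        row.names = colnames(map$rho))
  grDevices::png(paste0(path, ".png"), width = 1200, height = 900, res = 120)
  ok <- try(pheatmap::pheatmap(
    shown,
    cluster_rows = map$row_tree, cluster_cols = map$col_tree,
    annotation_row = ann_row, annotation_col = ann_col,
    breaks = seq(-1, 1, length.out = 101), na_col = "white",
    main = "Pearson correlation (rho)"), silent = TRUE)
  grDevices::dev.off()
  if (inherits(ok, "try-error"))
    warning("heatmap rendering failed: ", attr(ok, "condition")$message)
  invisible(tsv)
}
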