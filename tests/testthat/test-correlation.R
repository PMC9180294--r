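test_that("two-block Pearson matches hand-computed values", {
  m <- two_block_pearson(data.frame(x = c(1, 2, 3, 4)),
                         data.frame(y = c(2, 1, 4, 3)))
  expect_equal(unname(m$rho[1, 1]), 0.6)   # cov 1 / (sd 1.291^2)
  x <- rnorm(10)
  self <- two_block_pearson(data.frame(x), data.frame(x))
  expect_equal(unname(self$rho[1, 1]), 1)
  expect_equal(unname(self$pvals[1, 1]), 0)
  neg <- two_block_pearson(data.frame(x), data.frame(y = -x))
  expect_equal(unname(neg$rho[1, 1]), -1)
  expect_error(two_block_pearson(data.frame(x = 1:2), data.frame(y = 2:1)),
               "3 observations")
  expect_error(two_block_pearson(data.frame(x = rep(1, 5)),
                                 data.frame(y = rnorm(5))), "zero-variance")
})

test_that("Pearson r is invariant to positive affine transforms", {
  set.seed(61)
  A <- data.frame(a = rnorm(20))
  B <- data.frame(b = rnorm(20))
  r0 <- two_block_pearson(A, B)$rho[1, 1]
  r1 <- two_block_pearson(A * 5 + 3, B)$rho[1, 1]
  r2 <- two_block_pearson(A, B * 0.1 - 7)$rho[1, 1]
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_equal(r0, r2, tolerance = 1e-12)
})

test_that("p-values agree with cor.test", {
  set.seed(62)
  A <- matrix(rnorm(45), 15, 3); colnames(A) <- c("a1", "a2", "a3")
  B <- matrix(rnorm(30), 15, 2); colnames(B) <- c("b1", "b2")
  m <- two_block_pearson(A, B)
  for (i in 1:3) for (j in 1:2) {
    ct <- cor.test(A[, i], B[, j])
    expect_equal(m$pvals[i, j], ct$p.value, tolerance = 1e-10)
  }
})

test_that("Ward clustering splits identical-profile groups perfectly", {
  rho <- rbind(matrix(0.8, 4, 6), matrix(-0.5, 3, 6))
  rho <- rho + matrix(rnorm(42, 0, 0.01), 7, 6)
  rownames(rho) <- paste0("f", 1:7)
  cl <- cluster_features(rho, "rows", k = 2)
  expect_equal(length(unique(cl$assignments[1:4])), 1L)
  expect_equal(length(unique(cl$assignments[5:7])), 1L)
  expect_false(cl$assignments[1] == cl$assignments[5])
  # Ward merge heights are monotone non-decreasing
  expect_true(all(diff(cl$tree$height) >= -1e-12))
  expect_error(cluster_features(rho, "rows", k = 10), "exceeds")
  expect_error(cluster_features(rho[1, , drop = FALSE], "rows", 1),
               "at least 2")
})

test_that("silhouette analysis recovers the true cluster count", {
  recovered <- 0L
  for (i in 1:100) {
    set.seed(i)
    centers <- matrix(rnorm(15, 0, 3), 3, 5)
    prof <- centers[rep(1:3, each = 4), ] +
      matrix(rnorm(60, 0, 0.3), 12, 5)
    recovered <- recovered + (silhouette_select_k(prof)$k == 3L)
  }
  expect_gte(recovered, 95L)

  set.seed(200)
  two <- rbind(matrix(rnorm(20, 5, 0.2), 4, 5),
               matrix(rnorm(20, -5, 0.2), 4, 5))
  expect_equal(silhouette_select_k(two)$k, 2L)
  expect_error(silhouette_select_k(matrix(1, 5, 3)), "identical")
  expect_error(silhouette_select_k(matrix(rnorm(4), 2, 2)), "at least 3")
})

test_that("sensor and VOC clusters mirror the published association", {
  d <- study_design(seed = 63)
  en <- gen_enose(d)
  ft <- assemble_feature_table(en$traces, en$manifest)
  cv <- gen_chemistry_voc(d)
  sensors <- paste0("S", 1:10)
  en_s <- aggregate(ft[, sensors], by = list(sample_id = ft$sample_id),
                    FUN = median)
  voc <- cv$voc[match(en_s$sample_id, cv$voc$sample_id), ]
  map <- two_block_pearson(en_s[, sensors], voc[, voc_names()])

  main_voc <- setdiff(voc_names(), c("Ac4", "F1"))
  mean_r <- rowMeans(map$rho[, main_voc])
  # red-responding sensors positively associated with the main VOC cluster
  expect_true(all(mean_r[c("S2", "S6", "S7", "S8", "S9")] > 0))
  # half-red-responding sensors inversely associated
  expect_true(all(mean_r[c("S1", "S3", "S5")] < 0))
  # hydrogen/methane sensors: negligible association
  expect_true(all(abs(mean_r[c("S4", "S10")]) <
                    min(abs(mean_r[c("S2", "S7", "S9")]))))

  # VOC axis at k = 2 isolates Ac4 and F1
  cl <- cluster_features(map$rho, "cols", k = 2)$assignments
  grp <- split(names(cl), cl)
  sizes <- vapply(grp, length, integer(1))
  expect_setequal(grp[[which.min(sizes)]], c("Ac4", "F1"))
})

test_that("chemistry blocks correlate with colour features as published", {
  d <- study_design(seed = 64, reps_image = 2)
  im <- gen_image_set(d, width = 160, height = 136)
  feats <- t(vapply(im$images, function(r)
    image_features(r$img, erode_radius = 1), numeric(7)))
  fm <- cbind(im$manifest, as.data.frame(feats))
  cols <- c("L", "a", "b", "Chroma", "Hue")
  im_s <- aggregate(fm[, cols], by = list(sample_id = fm$sample_id),
                    FUN = median)
  cv <- gen_chemistry_voc(d)
  chem <- cv$chemistry[match(im_s$sample_id, cv$chemistry$sample_id), ]
  map <- two_block_pearson(im_s[, cols], chem[, c("TA", "TP", "AA", "TSS")])
  expect_true(all(map$rho[, "TA"] > 0))
  expect_true(all(map$rho[, "TSS"] < 0))
})

test_that("heatmap export writes a TSV that round-trips and a figure", {
  set.seed(65)
  A <- matrix(rnorm(40), 10, 4); colnames(A) <- paste0("a", 1:4)
  B <- matrix(rnorm(30), 10, 3); colnames(B) <- paste0("b", 1:3)
  map <- cluster_correlation_map(two_block_pearson(A, B),
                                 k_rows = 2, k_cols = 2)
  stem <- file.path(withr::local_tempdir(), "map")
  heatmap_export(map, stem)
  expect_true(file.exists(paste0(stem, ".png")))
  tsv <- read.delim(paste0(stem, ".tsv"))
  expect_equal(nrow(tsv), 12L)
  back <- matrix(NA_real_, 4, 3,
                 dimnames = list(paste0("a", 1:4), paste0("b", 1:3)))
  back[cbind(tsv$row_feature, tsv$col_feature)] <- tsv$rho
  expect_identical(back, map$rho)   # full-precision round-trip
  expect_setequal(unique(tsv$row_cluster), c(1L, 2L))
})
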