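#' Run configuration for the end-to-end pipeline
#'
#' Bundles the study design with the module options so a stored config plus
#' seed reproduces a run bit-for-bit (rendered figures excepted). The
#' config serialises to JSON.
#'
#' @param seed master seed; the design seed is taken from it.
#' @param design a [study_design()]; default built from `seed`.
#' @param window e-nose feature window, seconds.
#' @param sg_window,sg_order Savitzky-Golay second-derivative settings.
#' @param q2_folds venetian-blind folds for [pca_q2()] (capped at the
#'   number of biological samples per modality at run time).
#' @param bootstrap_B resamples for [auc_ci()].
#' @param image_width,image_height synthetic image size in pixels.
#' @param alpha,delta significance levels (correlations, FDR).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = study_design(seed = seed),
                       window = c(70, 75), sg_window = 15, sg_order = 3,
                       q2_folds = 7, bootstrap_B = 2000,
                       image_width = 256, image_height = 216,
                       alpha = 0.05, delta = 0.05) {
  structure(list(seed = as.integer(seed), design = design, window = window,
                 sg_window = sg_window, sg_order = sg_order,
                 q2_folds = q2_folds, bootstrap_B = bootstrap_B,
                 image_width = image_width, image_height = image_height,
                 alpha = alpha, delta = delta),
            class = "run_config")
}

#' Generate the full synthetic dataset on disk
#'
#' Writes every modality with a JSON manifest mapping files to
#' stage/harvest/sample/replicate: e-nose traces and true plateaus (CSV),
#' FTIR spectra (wide CSV), berry images (PNG) with ground-truth red
#' fractions (CSV), and the chemistry + VOC tables (CSV).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("output directory not writable: ", out_dir, call. = FALSE)
  unlink(probe)
  design <- config$design

  en <- gen_enose(design)
  write.csv(en$traces, file.path(out_dir, "enose_traces.csv"),
            row.names = FALSE)
  write.csv(en$plateaus, file.path(out_dir, "enose_plateaus.csv"),
            row.names = FALSE)
  write.csv(en$manifest, file.path(out_dir, "enose_manifest.csv"),
            row.names = FALSE)

  ft <- gen_ftir(design)
  write_spectra_csv(ft$spectra, ft$wavenumber,
                    file.path(out_dir, "ftir_spectra.csv"))
  write.csv(ft$manifest, file.path(out_dir, "ftir_manifest.csv"),
            row.names = FALSE)

  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  writer <- function(rec, meta)
    write_image_png(rec$img, file.path(img_dir, paste0(meta$obs_id, ".png")))
  im <- gen_image_set(design, width = config$image_width,
                      height = config$image_height, writer = writer)
  im$manifest$file <- file.path("images", paste0(im$manifest$obs_id, ".png"))
  write.csv(im$manifest, file.path(out_dir, "image_manifest.csv"),
            row.names = FALSE)

  cv <- gen_chemistry_voc(design)
  write.csv(cv$chemistry, file.path(out_dir, "chemistry.csv"),
            row.names = FALSE)
  write.csv(cv$voc, file.path(out_dir, "voc.csv"), row.names = FALSE)

  manifest <- list(
    seed = design$seed, stages = design$stages,
    n_harvests = design$n_harvests,
    samples_per_stage_per_harvest = design$samples_per_stage_per_harvest,
    reps = list(enose = design$reps_enose, ftir = design$reps_ftir,
                image = design$reps_image),
    files = list(enose_traces = "enose_traces.csv",
                 enose_manifest = "enose_manifest.csv",
                 ftir_spectra = "ftir_spectra.csv",
                 ftir_manifest = "ftir_manifest.csv",
                 image_manifest = "image_manifest.csv",
                 chemistry = "chemistry.csv", voc = "voc.csv"),
    counts = list(enose_observations = nrow(en$manifest),
                  ftir_observations = nrow(ft$manifest),
                  image_observations = nrow(im$manifest)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

aggregate_by_sample <- function(features, cols) {
  agg <- aggregate(features[, cols, drop = FALSE],
                   by = list(sample_id = features$sample_id), FUN = median)
  agg[order(agg$sample_id), , drop = FALSE]
}

#' Run the full analysis on a generated dataset
#'
#' Reads a dataset written by [generate_dataset()] and runs every stage:
#' e-nose feature extraction, univariate discrimination tables (10 sensor
#' features; 5 colour features), PCA with cross-validated Q2 per modality,
#' the FTIR band report, and the two-block correlation maps
#' (sensors x VOCs; FTIR bands x chemistry; colour x chemistry), writing
#' CSV/TSV/JSON/PNG results plus a run log. Missing modalities are skipped
#' with a logged warning.
#'
#' @param config the [run_config()] used to generate the data.
#' @param data_dir dataset directory.
#' @param out_dir results directory (created if missing).
#' @return Invisibly, a list with the main in-memory results.
#' @export
analyze_dataset <- function(config, data_dir, out_dir) {
  if (!file.exists(file.path(data_dir, "manifest.json")))
    stop("dataset manifest not found in ", data_dir, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), "-", ...,
                            "\n", file = log_path, append = TRUE)
  cat("ripestage analysis run\n", file = log_path)
  logf("R", as.character(getRversion()), "| seed", config$seed)
  res <- list()

  have <- function(f) file.exists(file.path(data_dir, f))

  ## --- e-nose ---------------------------------------------------------
  if (have("enose_traces.csv")) {
    traces <- read.csv(file.path(data_dir, "enose_traces.csv"))
    man <- read.csv(file.path(data_dir, "enose_manifest.csv"))
    feats <- assemble_feature_table(traces, man, config$window)
    write.csv(feats, file.path(out_dir, "enose_features.csv"),
              row.names = FALSE)
    tab <- table_summary(feats, enose_sensor_names(), delta = config$delta,
                         B = config$bootstrap_B, ci_seed = config$seed)
    write.csv(tab, file.path(out_dir, "enose_univariate.csv"),
              row.names = FALSE)
    X <- as.matrix(feats[, enose_sensor_names()])
    pca <- pca_fit(X, 2, "mean-center")
    q2 <- pca_q2(X, 2, "mean-center",
                 folds = min(config$q2_folds,
                             length(unique(feats$sample_id))),
                 sample_id = feats$sample_id, seed = config$seed)
    med <- replicate_medians(pca$scores, feats$sample_id)
    write.csv(data.frame(obs_id = feats$obs_id, stage = feats$stage,
                         pca$scores),
              file.path(out_dir, "enose_scores.csv"), row.names = FALSE)
    jsonlite::write_json(list(modality = "enose", preprocessing =
                                "mean-center", n_components = 2,
                              r2 = pca$r2_cum, q2 = q2),
                         file.path(out_dir, "enose_pca.json"),
                         auto_unbox = TRUE, digits = NA)
    res$enose <- list(features = feats, univariate = tab, pca = pca,
                      q2 = q2, medians = med)
    logf("e-nose:", nrow(feats), "observations; R2",
         sprintf("%.3f", pca$r2_cum), "Q2", sprintf("%.3f", q2))
  } else {
    warning("e-nose traces missing; stage skipped"); logf("e-nose: skipped")
  }

  ## --- FTIR -----------------------------------------------------------
  if (have("ftir_spectra.csv")) {
    sp <- read_spectra_csv(file.path(data_dir, "ftir_spectra.csv"))
    man <- read.csv(file.path(data_dir, "ftir_manifest.csv"))
    stopifnot(length(sp$wavenumber) == 3401L)
    pca <- pca_fit(sp$spectra, 2, "snv-mean-center")
    q2 <- pca_q2(sp$spectra, 2, "snv-mean-center",
                 folds = min(config$q2_folds, length(unique(man$sample_id))),
                 sample_id = man$sample_id, seed = config$seed)
    bands <- band_report(pca$loadings[, 1], sp$wavenumber, top_k = 6)
    write.csv(bands, file.path(out_dir, "ftir_pc1_bands.csv"),
              row.names = FALSE)
    d2 <- second_derivative(sp$spectra, config$sg_window, config$sg_order)
    fp <- sp$wavenumber >= 800 & sp$wavenumber <= 1200
    write_spectra_csv(d2[, fp], sp$wavenumber[fp],
                      file.path(out_dir, "ftir_second_derivative_800_1200.csv"))
    jsonlite::write_json(list(modality = "ftir", preprocessing =
                                "snv-mean-center", n_components = 2,
                              r2 = pca$r2_cum, q2 = q2,
                              pc1_share = pca$r2_per_component[1]),
                         file.path(out_dir, "ftir_pca.json"),
                         auto_unbox = TRUE, digits = NA)
    res$ftir <- list(pca = pca, q2 = q2, bands = bands, manifest = man,
                     spectra = sp)
    logf("FTIR:", nrow(sp$spectra), "spectra; R2", sprintf("%.3f", pca$r2_cum),
         "Q2", sprintf("%.3f", q2))
  } else {
    warning("FTIR spectra missing; stage skipped"); logf("FTIR: skipped")
  }

  ## --- imaging --------------------------------------------------------
  if (have("image_manifest.csv")) {
    man <- read.csv(file.path(data_dir, "image_manifest.csv"))
    featm <- t(vapply(man$file, function(f)
      image_features(read_image_png(file.path(data_dir, f))),
      numeric(7)))
    feats <- cbind(man, as.data.frame(featm))
    write.csv(feats, file.path(out_dir, "image_features.csv"),
              row.names = FALSE)
    colour_cols <- c("L", "a", "b", "Chroma", "Hue")
    tab <- table_summary(feats, colour_cols, delta = config$delta,
                         B = config$bootstrap_B, ci_seed = config$seed)
    write.csv(tab, file.path(out_dir, "image_univariate.csv"),
              row.names = FALSE)
    X <- as.matrix(feats[, colour_cols])
    pca <- pca_fit(X, 2, "autoscale")
    q2 <- pca_q2(X, 2, "autoscale",
                 folds = min(config$q2_folds,
                             length(unique(feats$sample_id))),
                 sample_id = feats$sample_id, seed = config$seed)
    write.csv(data.frame(obs_id = feats$obs_id, stage = feats$stage,
                         pca$scores),
              file.path(out_dir, "image_scores.csv"), row.names = FALSE)
    jsonlite::write_json(list(modality = "image", preprocessing = "autoscale",
                              n_components = 2, r2 = pca$r2_cum, q2 = q2),
                         file.path(out_dir, "image_pca.json"),
                         auto_unbox = TRUE, digits = NA)
    res$image <- list(features = feats, univariate = tab, pca = pca, q2 = q2)
    logf("imaging:", nrow(feats), "observations; R2",
         sprintf("%.3f", pca$r2_cum))
  } else {
    warning("image manifest missing; stage skipped"); logf("imaging: skipped")
  }

  ## --- correlation maps ----------------------------------------------
  if (have("voc.csv") && !is.null(res$enose)) {
    voc <- read.csv(file.path(data_dir, "voc.csv"), check.names = FALSE)
    en_s <- aggregate_by_sample(res$enose$features, enose_sensor_names())
    voc <- voc[order(voc$sample_id), ]
    stopifnot(identical(en_s$sample_id, voc$sample_id))
    if (nrow(en_s) >= 3) {
      map <- two_block_pearson(en_s[, enose_sensor_names()],
                               voc[, voc_names()], alpha = config$alpha)
      map <- cluster_correlation_map(map)
      heatmap_export(map, file.path(out_dir, "cor_enose_voc"))
      res$cor_enose_voc <- map
      logf("correlation e-nose x VOC: k =", map$k_rows, "x", map$k_cols)
    } else {
      logf("correlation e-nose x VOC: skipped (<3 samples)")
    }
  }
  if (have("chemistry.csv") && !is.null(res$ftir)) {
    # FTIR vs chemistry: both aggregated to stage x harvest units
    chem <- read.csv(file.path(data_dir, "chemistry.csv"))
    chem$unit <- paste(chem$stage, chem$harvest, sep = "_H")
    chem_u <- aggregate(chem[, c("TA", "TP", "AA", "TSS")],
                        by = list(unit = chem$unit), FUN = median)
    man <- res$ftir$manifest
    sn <- snv(res$ftir$spectra$spectra)
    centers <- ftir_default_bands()$center
    bandX <- sn[, match(centers, res$ftir$spectra$wavenumber), drop = FALSE]
    colnames(bandX) <- paste0("band_", centers)
    unit <- paste(man$stage, man$harvest, sep = "_H")
    band_u <- aggregate(as.data.frame(bandX), by = list(unit = unit),
                        FUN = median)
    chem_u <- chem_u[order(chem_u$unit), ]; band_u <- band_u[order(band_u$unit), ]
    stopifnot(identical(chem_u$unit, band_u$unit))
    if (nrow(chem_u) >= 3) {
      map <- two_block_pearson(band_u[, -1], chem_u[, -1],
                               alpha = config$alpha)
      map <- cluster_correlation_map(map)
      heatmap_export(map, file.path(out_dir, "cor_ftir_chemistry"))
      res$cor_ftir_chemistry <- map
      logf("correlation FTIR bands x chemistry: k =", map$k_rows, "x",
           map$k_cols)
    } else {
      logf("correlation FTIR bands x chemistry: skipped (<3 units)")
    }
  }
  if (have("chemistry.csv") && !is.null(res$image)) {
    chem <- read.csv(file.path(data_dir, "chemistry.csv"))
    chem <- chem[order(chem$sample_id), ]
    im_s <- aggregate_by_sample(res$image$features,
                                c("L", "a", "b", "Chroma", "Hue"))
    stopifnot(identical(im_s$sample_id, chem$sample_id))
    if (nrow(im_s) >= 3) {
      map <- two_block_pearson(im_s[, -1],
                               chem[, c("TA", "TP", "AA", "TSS")],
                               alpha = config$alpha)
      map <- cluster_correlation_map(map)
      heatmap_export(map, file.path(out_dir, "cor_image_chemistry"))
      res$cor_image_chemistry <- map
      logf("correlation colour x chemistry: k =", map$k_rows, "x",
           map$k_cols)
    } else {
      logf("correlation colour x chemistry: skipped (<3 samples)")
    }
  }
  logf("done")
  invisible(res)
}
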