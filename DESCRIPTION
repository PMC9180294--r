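Package: ripestage
Title: Non-Destructive Ripening-Stage Discrimination for Strawberries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric toolkit for discriminating fruit ripening stages
    (half-red vs red strawberries) from non-destructive instrument
    fingerprints: electronic-nose conductance traces, ATR-FTIR absorbance
    spectra and RGB berry images. Provides feature extraction for each
    modality (sensor window means, SNV and Savitzky-Golay second-derivative
    spectral preprocessing, berry segmentation with CIELAB colour features),
    a per-feature discrimination battery (linear mixed-effect stage test,
    Benjamini-Hochberg FDR, fold change, ROC AUC with bootstrap confidence
    intervals), principal component analysis with cross-validated Q2, and
    two-block Pearson correlation maps with Ward clustering and
    silhouette-based cluster-count selection. A synthetic-data module
    emulates the nested study design (stages x harvests x samples x
    technical replicates) so the full pipeline can be exercised and tested
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    lme4,
    cluster,
    EBImage,
    png,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
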