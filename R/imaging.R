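#' Coarse berry segmentation from the red channel
#'
#' Segments fruit from a dark background: Otsu threshold on the R channel
#' (the channel with the highest contrast against a black background),
#' erosion of the berry edge with a disk structuring element, then hole
#' closure by flood filling (any region not reachable from the image border
#' through background becomes foreground).
#'
#' @param img height x width x 3 array, channels R, G, B in 0-255.
#' @param erode_radius disk radius in pixels (default 2; scale with image
#'   size for high-resolution frames).
#' @return Logical matrix (the primary berry mask).
#' @export
segment_primary <- function(img, erode_radius = 2) {
  r <- img[, , 1] / 255
  thr <- EBImage::otsu(EBImage::Image(t(r)), range = c(0, 1))
  mask <- r > thr
  if (!any(mask))
    stop("empty segmentation: no foreground above the Otsu threshold",
         call. = FALSE)
  em <- EBImage::Image(t(mask * 1))
  if (erode_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(erode_radius) + 1L,
                                shape = "disc")
    em <- EBImage::erode(em, brush)
  }
  em <- EBImage::fillHull(em)
  out <- t(EBImage::imageData(em)) > 0
  if (!any(out))
    stop("empty segmentation after erosion", call. = FALSE)
  out
}

#' Partition the berry surface into red and green areas
#'
#' Enhances red over green by the channel difference `clip(R - G, 0, 255)`,
#' Otsu-thresholds the enhanced image restricted to the primary mask to get
#' the red area, and takes the green area as the set difference. Percentages
#' are pixel counts relative to the berry area.
#'
#' @param img height x width x 3 array (0-255).
#' @param primary_mask logical matrix from [segment_primary()].
#' @return List of class `segmentation_result`: `primary_mask`, `red_mask`,
#'   `green_mask`, `red_pct`, `green_pct`.
#' @export
partition_red_green <- function(img, primary_mask) {
  if (!any(primary_mask)) stop("primary mask is empty", call. = FALSE)
  enhanced <- pmin(pmax(img[, , 1] - img[, , 2], 0), 255) / 255
  vals <- enhanced[primary_mask]
  single_class <- diff(range(vals)) < 1e-12
  if (!single_class) {
    h <- graphics::hist(vals, breaks = seq(0, 1, length.out = 257),
                        plot = FALSE)
    thr <- otsu_from_counts(h$counts, h$mids)
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    # Otsu always splits; accept the split only if the classes are genuinely
    # separated (bimodal), else the whole berry is one colour class
    pooled_sd <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                        max(length(vals) - 2, 1))
    single_class <- length(lo) == 0 || length(hi) == 0 ||
      (mean(hi) - mean(lo)) < 4 * max(pooled_sd, 1e-6) ||
      mean(hi) < 0.08   # even the upper class is below red-level enhancement
  }
  red_mask <- if (single_class) {
    # one colour class: red if the enhancement is clearly above the clipped
    # near-zero level of green flesh (R - G <= 0), even for dark ripe tones
    primary_mask & (mean(vals) > 0.08)
  } else {
    primary_mask & (enhanced > thr)
  }
  green_mask <- primary_mask & !red_mask
  n <- sum(primary_mask)
  structure(list(primary_mask = primary_mask, red_mask = red_mask,
                 green_mask = green_mask,
                 red_pct = 100 * sum(red_mask) / n,
                 green_pct = 100 * sum(green_mask) / n),
            class = "segmentation_result")
}

# Otsu threshold from a histogram (maximises between-class variance)
otsu_from_counts <- function(counts, mids) {
  p <- counts / sum(counts)
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  bcv <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Affine colour calibration against a 24-patch chart
#'
#' Fits the least-squares affine map (3x3 matrix plus offset) taking the
#' measured mean patch colours to their reference values, applies it to all
#' pixels and clips to 0-255. The root-mean-square residual over the patches
#' is attached as an attribute.
#'
#' @param img height x width x 3 array (0-255).
#' @param measured_patches 24 x 3 matrix of measured patch means (0-255).
#' @param reference_patches 24 x 3 matrix of reference colours, e.g.
#'   [colour_checker_reference()].
#' @return Calibrated image array with attributes `rms_residual` and
#'   `calibration` (the fitted 4 x 3 coefficient matrix).
#' @export
colour_calibrate <- function(img, measured_patches,
                             reference_patches = colour_checker_reference()) {
  measured_patches <- as.matrix(measured_patches)
  reference_patches <- as.matrix(reference_patches)
  if (nrow(measured_patches) != 24L || nrow(reference_patches) != 24L)
    stop("exactly 24 measured/reference patch pairs are required",
         call. = FALSE)
  X <- cbind(1, measured_patches)
  if (qr(X)$rank < 4L)
    stop("rank-deficient patch set: cannot identify an affine map",
         call. = FALSE)
  coef <- qr.solve(X, reference_patches)       # 4 x 3: offset + 3x3 matrix
  fitted <- X %*% coef
  rms <- sqrt(mean((fitted - reference_patches)^2))
  px <- cbind(1, matrix(img, ncol = 3))
  out <- array(pmin(pmax(px %*% coef, 0), 255), dim = dim(img))
  attr(out, "rms_residual") <- rms
  attr(out, "calibration") <- coef
  out
}

#' sRGB to CIELAB conversion (D65, 2 degree observer)
#'
#' Standard pipeline: inverse sRGB companding, the IEC 61966-2-1 sRGB-to-XYZ
#' matrix, then CIE L*a*b* against the D65 white point. Pure red
#' (255, 0, 0) maps to approximately (53.24, 80.09, 67.20).
#'
#' @param rgb numeric vector of length 3 or an n x 3 matrix, channels 0-255.
#' @return Matrix n x 3 with columns `L`, `a`, `b` (a length-3 named vector
#'   for single-triple input).
#' @export
rgb_to_lab <- function(rgb) {
  single <- is.null(dim(rgb))
  m <- if (single) matrix(rgb, ncol = 3) else as.matrix(rgb)
  if (any(m < 0 | m > 255) || anyNA(m))
    stop("RGB channels must be in [0, 255]", call. = FALSE)
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1.0, 1.08883)
  t3 <- sweep(xyz, 2, white, "/")
  f <- ifelse(t3 > (6 / 29)^3, t3^(1 / 3), t3 / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  if (single) lab[1, ] else lab
}

#' CIELAB colour features of a masked region
#'
#' Converts the masked pixels to CIELAB (after optional calibration),
#' averages L*, a*, b* over the region and derives Chroma =
#' sqrt(a*^2 + b*^2) and the hue angle atan(b*/a*) in radians (first
#' quadrant for the red-orange tones of ripening fruit).
#'
#' @param img height x width x 3 array (0-255).
#' @param mask logical matrix selecting the pixels to summarise.
#' @param calibration optional 4 x 3 affine coefficient matrix (from
#'   [colour_calibrate()]'s `calibration` attribute) applied before
#'   conversion.
#' @return Named numeric vector: `L`, `a`, `b`, `Chroma`, `Hue`.
#' @export
colour_features <- function(img, mask, calibration = NULL) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  px <- cbind(img[, , 1][mask], img[, , 2][mask], img[, , 3][mask])
  if (!is.null(calibration))
    px <- pmin(pmax(cbind(1, px) %*% calibration, 0), 255)
  lab <- rgb_to_lab(px)
  m <- colMeans(lab)
  c(L = unname(m["L"]), a = unname(m["a"]), b = unname(m["b"]),
    Chroma = unname(sqrt(m["a"]^2 + m["b"]^2)),
    Hue = unname(atan(m["b"] / m["a"])))
}

#' Full image-analysis feature extraction for one berry image
#'
#' Runs [segment_primary()], [partition_red_green()] and [colour_features()]
#' (over the whole berry mask) and returns one observation row.
#'
#' @param img height x width x 3 array (0-255).
#' @param calibration optional affine calibration matrix.
#' @param erode_radius passed to [segment_primary()].
#' @return Named numeric vector: `L`, `a`, `b`, `Chroma`, `Hue`, `red_pct`,
#'   `green_pct`.
#' @export
image_features <- function(img, calibration = NULL, erode_radius = 2) {
  pm <- segment_primary(img, erode_radius)
  seg <- partition_red_green(img, pm)
  cf <- colour_features(img, pm, calibration)
  c(cf, red_pct = seg$red_pct, green_pct = seg$green_pct)
}
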