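#' Reference colours of the 24-patch colour chart
#'
#' Published sRGB coordinates of the classic 24-patch ColorChecker chart,
#' used both to render the synthetic chart and as the reference block for
#' [colour_calibrate()].
#'
#' @return 24 x 3 numeric matrix (R, G, B in 0-255), rownames = patch names.
#' @export
colour_checker_reference <- function() {
  m <- rbind(
    dark_skin = c(115, 82, 68),  light_skin = c(194, 150, 130),
    blue_sky = c(98, 122, 157),  foliage = c(87, 108, 67),
    blue_flower = c(133, 128, 177), bluish_green = c(103, 189, 170),
    orange = c(214, 126, 44),    purplish_blue = c(80, 91, 166),
    moderate_red = c(193, 90, 99), purple = c(94, 60, 108),
    yellow_green = c(157, 188, 64), orange_yellow = c(224, 163, 46),
    blue = c(56, 61, 150),       green = c(70, 148, 73),
    red = c(175, 54, 60),        yellow = c(231, 199, 31),
    magenta = c(187, 86, 149),   cyan = c(8, 133, 161),
    white = c(243, 243, 242),    neutral_8 = c(200, 200, 200),
    neutral_65 = c(160, 160, 160), neutral_5 = c(122, 122, 121),
    neutral_35 = c(85, 85, 85),  black = c(52, 52, 52))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Generate one synthetic berry image with ground truth
#'
#' Renders `berries` non-overlapping ellipses on a near-black background.
#' Each berry surface is partitioned into a red-toned and a green-toned
#' region; the red surface fraction per berry is `red_fraction` plus uniform
#' jitter, realised exactly at pixel level (the lowest rows of the berry are
#' red). Optionally a 24-patch colour chart is rendered at a fixed position
#' in the top-left corner.
#'
#' @param width,height image size in pixels.
#' @param berries number of berries (default 12, a lot).
#' @param red_fraction target red surface fraction in `[0, 1]`.
#' @param jitter half-width of the per-berry uniform jitter on the fraction.
#' @param with_checker render the colour chart?
#' @param red_tone,green_tone,background mean RGB (0-255) of each region.
#'
#' @return List: `img` (height x width x 3 array, 0-255), `berry_mask`,
#'   `red_mask`, `green_mask` (logical matrices; red and green partition the
#'   berry mask exactly), `berry_red_fraction` (per berry), and, when
#'   `with_checker`, `checker` with patch bounding boxes, reference and
#'   rendered mean colours.
#' @export
gen_berry_image <- function(width = 1024, height = 864, berries = 12,
                            red_fraction = 0.5, jitter = 0.05,
                            with_checker = FALSE,
                            red_tone = c(205, 42, 47),
                            green_tone = c(150, 172, 78),
                            background = c(12, 12, 12)) {
  stop_if_not_scalar_prob(red_fraction, "red_fraction")
  ncol_grid <- ceiling(sqrt(berries * width / height))
  nrow_grid <- ceiling(berries / ncol_grid)
  cw <- width / ncol_grid; ch <- height / nrow_grid
  if (min(cw, ch) < 16)
    stop("image too small for ", berries, " non-overlapping berries",
         call. = FALSE)

  img <- array(0, dim = c(height, width, 3))
  for (c in 1:3) img[, , c] <- background[c] +
    matrix(rnorm(height * width, 0, 2.5), height, width)
  berry_mask <- red_mask <- matrix(FALSE, height, width)
  frac_true <- numeric(berries)

  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  for (b in seq_len(berries)) {
    gi <- (b - 1) %% ncol_grid; gj <- (b - 1) %/% ncol_grid
    cx <- (gi + 0.5) * cw + runif(1, -0.05, 0.05) * cw
    cy <- (gj + 0.5) * ch + runif(1, -0.05, 0.05) * ch
    rx <- runif(1, 0.28, 0.38) * cw; ry <- runif(1, 0.28, 0.38) * ch
    inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
    berry_mask <- berry_mask | inside
    # fully-red / fully-green lots are exact; jitter applies in between
    f <- if (red_fraction %in% c(0, 1)) red_fraction else
      min(max(red_fraction + runif(1, -jitter, jitter), 0), 1)
    idx <- which(inside)
    ord <- idx[order(ys[idx], xs[idx], decreasing = TRUE)] # bottom rows first
    n_red <- round(f * length(idx))
    red_px <- ord[seq_len(n_red)]
    frac_true[b] <- n_red / length(idx)
    red_mask[red_px] <- TRUE
  }
  green_mask <- berry_mask & !red_mask

  paint <- function(mask, tone, sd = 6) {
    n <- sum(mask)
    for (c in 1:3) {
      ch_mat <- img[, , c]
      ch_mat[mask] <- tone[c] + rnorm(n, 0, sd)
      img[, , c] <<- ch_mat
    }
  }
  paint(red_mask, red_tone)
  paint(green_mask, green_tone)

  checker <- NULL
  if (isTRUE(with_checker)) {
    ref <- colour_checker_reference()
    pw <- max(4L, floor(width / 40)); ph <- pw
    gap <- max(2L, floor(pw / 3))
    boxes <- data.frame(patch = rownames(ref), x0 = NA, y0 = NA,
                        x1 = NA, y1 = NA)
    measured <- matrix(NA_real_, 24, 3, dimnames = dimnames(ref))
    for (p in 1:24) {
      r <- (p - 1) %/% 6; cl <- (p - 1) %% 6
      x0 <- 4 + cl * (pw + gap); y0 <- 4 + r * (ph + gap)
      sel_y <- y0:(y0 + ph - 1); sel_x <- x0:(x0 + pw - 1)
      for (c in 1:3) img[sel_y, sel_x, c] <- ref[p, c]
      boxes[p, 2:5] <- c(x0, y0, x0 + pw - 1, y0 + ph - 1)
      measured[p, ] <- ref[p, ]
    }
    checker <- list(boxes = boxes, reference = ref, measured = measured)
  }
  img <- pmin(pmax(img, 0), 255)
  list(img = img, berry_mask = berry_mask, red_mask = red_mask,
       green_mask = green_mask, berry_red_fraction = frac_true,
       checker = checker)
}

#' Generate the full set of synthetic berry images for a design
#'
#' One image (a lot of `berries` fruit) per sample and technical replicate:
#' the default design yields 2 stages x 3 harvests x 4 samples x 8 replicates
#' = 192 image observations. The red surface fraction is stage-dependent
#' (half-red lots around 50% red, red lots fully red) with a sample-level
#' offset so replicates of one sample resemble each other.
#'
#' @param design a [study_design()].
#' @param width,height image size in pixels (the study camera delivered 3.2
#'   MPixel frames; a reduced default keeps in-memory sets manageable).
#' @param berries berries per image.
#' @param red_fraction_by_stage named vector of target red fractions, one per
#'   stage (names must match `design$stages`).
#' @param red_tone_by_stage named list of mean RGB for the red surface per
#'   stage: half-red fruit carry bright red patches while fully ripe fruit
#'   darken and desaturate, which is why every whole-berry colour feature
#'   (L*, a*, b*, Chroma, hue) comes out lower for red lots.
#' @param with_checker render the colour chart on every image?
#' @param writer optional `function(image_record, meta_row)` called per image
#'   instead of accumulating images in memory (used when writing PNGs).
#'
#' @return List with `manifest` (192-row metadata incl. true mean red
#'   fraction per image) and `images` (list of [gen_berry_image()] records;
#'   `NULL` when a `writer` is supplied).
#' @export
gen_image_set <- function(design, width = 256, height = 216, berries = 12,
                          red_fraction_by_stage =
                            c("half-red" = 0.5, "red" = 1.0),
                          red_tone_by_stage =
                            list("half-red" = c(205, 42, 47),
                                 "red" = c(80, 46, 42)),
                          with_checker = FALSE, writer = NULL) {
  if (!all(design$stages %in% names(red_fraction_by_stage)))
    stop("red_fraction_by_stage must name every stage", call. = FALSE)
  if (!all(design$stages %in% names(red_tone_by_stage)))
    stop("red_tone_by_stage must name every stage", call. = FALSE)
  set.seed(design$seed + 2L)
  samp <- design_samples(design)
  n_obs <- nrow(samp) * design$reps_image
  manifest <- data.frame(obs_id = character(n_obs), stage = character(n_obs),
                         harvest = integer(n_obs), sample = integer(n_obs),
                         replicate = integer(n_obs), sample_id = character(n_obs),
                         true_red_fraction = numeric(n_obs),
                         stringsAsFactors = FALSE)
  images <- if (is.null(writer)) vector("list", n_obs) else NULL
  k <- 0L
  for (i in seq_len(nrow(samp))) {
    f_target <- red_fraction_by_stage[[samp$stage[i]]]
    f_sample <- if (f_target %in% c(0, 1)) f_target else
      min(max(f_target + runif(1, -0.03, 0.03), 0), 1)
    tone_shift <- rnorm(3, 0, 4) # sample-level colour offset
    for (r in seq_len(design$reps_image)) {
      k <- k + 1L
      rec <- gen_berry_image(width, height, berries, f_sample,
                             jitter = 0.04, with_checker = with_checker,
                             red_tone = red_tone_by_stage[[samp$stage[i]]] +
                               tone_shift,
                             green_tone = c(150, 172, 78) + tone_shift)
      id <- obs_id(samp$stage[i], samp$harvest[i], samp$sample[i], r)
      manifest[k, ] <- list(id, samp$stage[i], samp$harvest[i], samp$sample[i],
                            r, samp$sample_id[i], mean(rec$berry_red_fraction))
      if (is.null(writer)) images[[k]] <- rec else writer(rec, manifest[k, ])
    }
  }
  list(manifest = manifest, images = images)
}
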