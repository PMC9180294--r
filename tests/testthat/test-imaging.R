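test_that("primary segmentation recovers the berry area at camera scale", {
  set.seed(31)
  rec <- gen_berry_image(width = 2064, height = 1744, berries = 12,
                         red_fraction = 0.5)
  mask <- segment_primary(rec$img, erode_radius = 2)
  truth <- sum(rec$berry_mask)
  expect_lt(abs(sum(mask) - truth) / truth, 0.03)
})

test_that("segmentation fails cleanly on an all-dark image", {
  dark <- array(3, dim = c(40, 40, 3))
  expect_error(segment_primary(dark), "empty segmentation")
})

test_that("flood filling closes interior dark specks", {
  set.seed(32)
  rec <- gen_berry_image(width = 400, height = 340, berries = 1,
                         red_fraction = 1)
  img <- rec$img
  ctr <- round(colMeans(which(rec$berry_mask, arr.ind = TRUE)))
  img[(ctr[1] - 3):(ctr[1] + 3), (ctr[2] - 3):(ctr[2] + 3), ] <- 2 # dark hole
  mask <- segment_primary(img, erode_radius = 1)
  expect_true(all(mask[(ctr[1] - 2):(ctr[1] + 2),
                       (ctr[2] - 2):(ctr[2] + 2)]))
})

test_that("red/green partition conserves pixels and recovers ground truth", {
  set.seed(33)
  for (f in c(0.3, 0.5, 0.8)) {
    rec <- gen_berry_image(width = 320, height = 280, berries = 12,
                           red_fraction = f)
    seg <- partition_red_green(rec$img, segment_primary(rec$img,
                                                        erode_radius = 1))
    expect_equal(seg$red_pct + seg$green_pct, 100, tolerance = 1e-9)
    expect_equal(sum(seg$red_mask) + sum(seg$green_mask),
                 sum(seg$primary_mask))
    expect_lt(abs(seg$red_pct - 100 * mean(rec$berry_red_fraction)), 5)
  }
})

test_that("single-class berries are not split by the threshold", {
  set.seed(34)
  rec <- gen_berry_image(width = 240, height = 200, berries = 6,
                         red_fraction = 1)
  seg <- partition_red_green(rec$img, segment_primary(rec$img,
                                                      erode_radius = 1))
  expect_equal(seg$red_pct, 100)
  # dark desaturated ripe tone is still recognised as red
  rec2 <- gen_berry_image(width = 240, height = 200, berries = 6,
                          red_fraction = 1, red_tone = c(80, 46, 42))
  seg2 <- partition_red_green(rec2$img, segment_primary(rec2$img,
                                                        erode_radius = 1))
  expect_equal(seg2$red_pct, 100)
  # fully green lot
  rec0 <- gen_berry_image(width = 240, height = 200, berries = 6,
                          red_fraction = 0)
  seg0 <- partition_red_green(rec0$img, segment_primary(rec0$img,
                                                        erode_radius = 1))
  expect_equal(seg0$red_pct, 0)
  expect_error(partition_red_green(rec$img, matrix(FALSE, 200, 240)),
               "empty")
})

test_that("colour calibration recovers affine casts exactly", {
  ref <- colour_checker_reference()
  img <- array(runif(30 * 30 * 3, 0, 255), dim = c(30, 30, 3))

  out <- colour_calibrate(img, ref, ref)      # identity
  expect_equal(attr(out, "rms_residual"), 0, tolerance = 1e-9)
  expect_equal(as.vector(out), as.vector(img), tolerance = 1e-9)

  cast <- ref * 0.8                           # global gain cast
  out2 <- colour_calibrate(img * 0.8, cast, ref)
  expect_equal(attr(out2, "rms_residual"), 0, tolerance = 1e-6)
  expect_equal(attr(out2, "calibration")[2, 1], 1 / 0.8, tolerance = 1e-8)
  expect_equal(as.vector(out2), as.vector(img), tolerance = 1e-6)

  expect_error(colour_calibrate(img, ref[1:23, ], ref), "24")
  grey <- matrix(rep(seq(10, 240, length.out = 24), 3), ncol = 3)
  expect_error(colour_calibrate(img, cbind(grey[, 1], grey[, 1],
                                           grey[, 1]), ref),
               "rank-deficient")
})

test_that("sRGB to CIELAB matches the standard reference values", {
  w <- rgb_to_lab(c(255, 255, 255))
  expect_equal(unname(w["L"]), 100, tolerance = 1e-3)
  expect_lt(abs(w["a"]), 0.01)
  expect_lt(abs(w["b"]), 0.01)
  expect_equal(unname(rgb_to_lab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-8)
  r <- rgb_to_lab(c(255, 0, 0))
  expect_equal(unname(r), c(53.2406, 80.0923, 67.2028), tolerance = 0.1 / 53)
  m <- rgb_to_lab(c(128, 64, 200))
  expect_equal(unname(m), c(41.8848, 53.5213, -60.3550), tolerance = 1e-3)
  expect_error(rgb_to_lab(c(-1, 0, 0)), "0, 255")
})

test_that("colour feature identities hold (Chroma, hue angle)", {
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 200; img[, , 2] <- 40; img[, , 3] <- 45
  mask <- matrix(TRUE, 4, 4)
  cf <- colour_features(img, mask)
  expect_equal(cf[["Chroma"]], sqrt(cf[["a"]]^2 + cf[["b"]]^2),
               tolerance = 1e-9)
  expect_equal(cf[["Hue"]], atan(cf[["b"]] / cf[["a"]]), tolerance = 1e-9)
  expect_error(colour_features(img, matrix(FALSE, 4, 4)), "empty")

  # worked example on the published half-red means: a* 25.78, b* 16.40
  expect_equal(round(sqrt(25.78^2 + 16.40^2), 2), 30.55)
  expect_equal(round(atan(16.40 / 25.78), 3), 0.567)
})

test_that("hue is reported in radians in the first quadrant", {
  set.seed(35)
  rec <- gen_berry_image(width = 200, height = 170, berries = 6,
                         red_fraction = 0.5)
  cf <- colour_features(rec$img, rec$berry_mask)
  expect_gt(cf[["Hue"]], 0)
  expect_lt(cf[["Hue"]], pi / 2)
})

test_that("PNG io round-trips the 8-bit image", {
  set.seed(36)
  rec <- gen_berry_image(width = 64, height = 56, berries = 1,
                         red_fraction = 0.5)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(rec$img, path)
  back <- read_image_png(path)
  expect_equal(dim(back), dim(rec$img))
  expect_lt(max(abs(back - rec$img)), 0.51)   # 8-bit quantisation only
})
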