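# ER segmentation: preprocessing contracts, hysteresis thresholding against
# the flood-fill oracle, cisterna identification, and the tubule-radius
# estimate.

test_that("preprocess enforces shape, positivity and background removal", {
  p <- segmentation_params(upsample_factor = 2L, background_radius_px = 10L,
                           denoise_sigma_px = 0)
  img <- matrix(runif(100 * 100), 100, 100)
  out <- preprocess(img, p)
  expect_equal(dim(out), c(200, 200))
  expect_true(all(out >= 0) && max(out) <= 1)

  const <- matrix(5, 40, 40)
  flat <- preprocess(const, segmentation_params(background_radius_px = 5L,
                                                denoise_sigma_px = 0))
  expect_true(all(flat == 0))   # opening removes a constant exactly

  expect_error(preprocess(matrix(0, 10, 10)), class = "empty_image")
})

test_that("preprocess preserves the location of an isolated peak", {
  spec <- phantom_spec(image_shape = c(64, 64), photon_scale = Inf,
                       read_noise_sd = 0, background_level = 0, seed = 1)
  ps <- spec$pixel_size_nm
  lay <- structure(list(
    segments = matrix(c(20 * ps, 30 * ps, 45 * ps, 30 * ps), nrow = 1),
    junctions = matrix(numeric(0), ncol = 2),
    tubule_diameter_nm = 40, cisternae = list(), spec_seed = 1
  ), class = "er_layout")
  img <- render_er_image(lay, spec)$image$channels$lumen
  p <- segmentation_params(upsample_factor = 2L, denoise_sigma_px = 0,
                           background_radius_px = 30L)
  out <- preprocess(img, p)
  # the ridge is a plateau of tied maxima: every upsampled peak pixel must
  # sit within ~1 upsampled pixel of a scaled original peak pixel
  before <- which(img == max(img), arr.ind = TRUE)
  after <- which(out == max(out), arr.ind = TRUE)
  for (i in seq_len(nrow(after))) {
    d <- sqrt((2 * before[, 1] - after[i, 1])^2 +
                (2 * before[, 2] - after[i, 2])^2)
    expect_lte(min(d), 2)
  }
})

test_that("hysteresis keeps the halo connected to cores and drops background", {
  img <- matrix(0.05, 10, 10)
  img[4:6, 4:6] <- 0.3          # halo
  img[5, 5] <- 0.9              # core
  img[1, 9:10] <- 0.3           # stray halo with no core
  p <- segmentation_params(hysteresis_low = 0.2, hysteresis_high = 0.8,
                           min_object_px = 1L)
  mask <- segment_er(img, p)
  expect_true(all(mask[4:6, 4:6]))
  expect_false(any(mask[1, 9:10]))
  expect_equal(sum(mask), 9)

  # low == high degenerates to plain thresholding
  p2 <- segmentation_params(hysteresis_low = 0.3, hysteresis_high = 0.3,
                            min_object_px = 1L)
  expect_equal(segment_er(img, p2), img >= 0.3)

  # unattainable high threshold: empty mask with a warning
  p3 <- segmentation_params(hysteresis_low = 0.1, hysteresis_high = 0.99)
  expect_warning(m3 <- segment_er(img, p3), class = "empty_mask")
  expect_false(any(m3))
})

test_that("hysteresis equals the flood-fill oracle on random images", {
  set.seed(101)
  for (i in 1:8) {
    img <- matrix(runif(32 * 32), 32, 32)
    img <- as.matrix(EBImage::gblur(img, sigma = 1.2))
    img <- img / max(img)
    lo <- runif(1, 0.3, 0.5); hi <- runif(1, 0.6, 0.85)
    p <- segmentation_params(hysteresis_low = lo, hysteresis_high = hi,
                             min_object_px = 1L)
    expect_identical(segment_er(img, p), oracle_hysteresis(img, lo, hi))
  }
})

test_that("opening isolates wide regions as cisternae", {
  # a thin line alone: no cisternae
  mask <- matrix(FALSE, 50, 50)
  mask[10:40, 24:26] <- TRUE
  p <- segmentation_params(opening_radius_px = 5L, min_object_px = 5L)
  seg <- identify_cisternae(mask, params = p)
  expect_length(seg$cisterna_ids, 0)
  expect_equal(sum(seg$label_map == 1L), sum(mask))

  # a 40x40 square plus the line: exactly one cisterna
  mask2 <- matrix(FALSE, 60, 60)
  mask2[10:49, 10:49] <- TRUE
  mask2[30:32, 50:59] <- TRUE
  seg2 <- identify_cisternae(mask2, params = p)
  expect_length(seg2$cisterna_ids, 1)
  # the opened square survives; the protruding line is tubule
  expect_true(all(seg2$label_map[15:45, 15:45] == 2L))
  expect_true(all(seg2$label_map[30:32, 52:59] == 1L))
})

test_that("labels partition the image and opening is monotone", {
  spec <- phantom_spec(image_shape = c(128, 128), seed = 21)
  cfg <- pipeline_config()
  ph <- phantom_for_condition(list(substructure = "sac"), cfg, seed = 21)
  p <- segmentation_params()
  pre <- preprocess(ph$image$channels$lumen, p)
  mask <- segment_er(pre, p)

  areas <- c()
  for (r in c(2L, 4L, 7L, 10L)) {
    seg <- identify_cisternae(mask, pre,
                              segmentation_params(opening_radius_px = r))
    counts <- table(factor(seg$label_map >= 2L, levels = c(FALSE, TRUE)))
    expect_equal(sum(seg$label_map == 0L) + sum(seg$label_map == 1L) +
                   sum(seg$label_map >= 2L), length(seg$label_map))
    areas <- c(areas, sum(seg$label_map >= 2L))
  }
  expect_true(all(diff(areas) <= 0))
})

test_that("phantom ER masks overlap ground truth and recover cisterna count", {
  cfg <- pipeline_config()
  ph <- phantom_for_condition(list(substructure = "sac"), cfg, seed = 31)
  res <- analyse_er_image(ph$image$channels$lumen, cfg, "i", "sac")
  truth <- ph$ground_truth$label_map > 0
  mask <- res$segmentation$label_map > 0
  jaccard <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jaccard, 0.8)
  expect_equal(length(res$segmentation$cisterna_ids),
               max(ph$ground_truth$label_map) - 1L)
})

test_that("upsampled segmentation scales cisterna areas by four", {
  cfg <- pipeline_config()
  ph <- phantom_for_condition(list(substructure = "sac"), cfg, seed = 41)
  img <- ph$image$channels$lumen
  p1 <- segmentation_params(upsample_factor = 1L, opening_radius_px = 4L)
  p2 <- segmentation_params(upsample_factor = 2L, opening_radius_px = 8L,
                            min_object_px = 80L)
  s1 <- identify_cisternae(segment_er(preprocess(img, p1), p1), params = p1)
  s2 <- identify_cisternae(segment_er(preprocess(img, p2), p2), params = p2)
  a1 <- sum(s1$label_map >= 2L); a2 <- sum(s2$label_map >= 2L)
  expect_lt(abs(a2 / a1 - 4), 0.2)
})

test_that("tubule radius estimate follows the intensity-ratio formula", {
  seg <- toy_segmentation(1, dim = c(30, 30))
  seg$label_map[1:5, 1:5] <- 1L   # give it tubule pixels
  img <- matrix(0, 30, 30)
  img[seg$label_map == 1L] <- 0.5
  img[seg$label_map == 2L] <- 0.5
  est <- estimate_tubule_radius(img, seg, psf_fwhm_nm = 140,
                                pixel_size_nm = 46)
  expect_equal(est$radius_nm, 70)   # equal intensities: half the PSF

  img[seg$label_map == 1L] <- 0.29
  img[seg$label_map == 2L] <- 1
  est2 <- estimate_tubule_radius(img, seg, 140, 46)
  expect_equal(est2$radius_nm, 46)  # 20.3 nm clipped up to the pixel size
  est3 <- estimate_tubule_radius(img, seg, 140, 10)
  expect_equal(est3$radius_nm, 0.5 * 140 * 0.29, tolerance = 1e-12)

  # no cisterna pixels: fall back to half the PSF with a warning
  seg$label_map[seg$label_map == 2L] <- 1L
  seg$cisterna_ids <- integer(0)
  expect_warning(est4 <- estimate_tubule_radius(img, seg, 140, 46),
                 class = "radius_fallback")
  expect_true(est4$fallback)
  expect_equal(est4$radius_nm, 70)
})

test_that("sub-resolution tubule width is recovered from matched phantoms", {
  cfg <- pipeline_config(
    segmentation = list(opening_radius_px = 8L, min_object_px = 60L,
                        hysteresis_low = 0.1, hysteresis_high = 0.3,
                        background_radius_px = 80L, upsample_factor = 2L))
  ph <- phantom_for_condition(list(substructure = "sac"), cfg, seed = 4)
  p <- do.call(segmentation_params, cfg$segmentation)
  pre <- preprocess(ph$image$channels$lumen, p)
  seg <- identify_cisternae(segment_er(pre, p), pre, p)
  est <- estimate_tubule_radius(pre, seg, psf_fwhm_nm = 140,
                                pixel_size_nm = 46 / 2)
  # true radius 20 nm (40 nm diameter); sub-resolution estimate within 50%
  expect_gt(est$radius_nm, 10)
  expect_lt(est$radius_nm, 30)
})
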