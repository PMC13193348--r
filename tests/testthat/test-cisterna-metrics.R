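# Radial binning/profiles and GLCM texture statistics.

test_that("radial bins are concentric, exhaustive and oracle-consistent", {
  # disc: bin index increases monotonically toward the centre
  mask <- matrix(FALSE, 25, 25)
  for (r in 1:25) for (c in 1:25)
    if ((r - 13)^2 + (c - 13)^2 <= 10^2) mask[r, c] <- TRUE
  bins <- radial_bin_map(mask, n_bins = 10)
  expect_equal(sum(!is.na(bins)), sum(mask))          # partition
  d <- sqrt((row(mask) - 13)^2 + (col(mask) - 13)^2)
  ring_means <- tapply(bins[mask], round(d[mask]), mean)
  expect_true(all(diff(as.numeric(ring_means)) <= 0)) # deeper = higher bin

  # square mask: bins equal level sets of the brute-force distance oracle
  sq <- matrix(FALSE, 20, 20)
  sq[4:17, 3:18] <- TRUE
  b <- radial_bin_map(sq, n_bins = 6)
  dor <- oracle_distance_to_background(sq)
  dmax <- max(dor)
  expected <- pmin(floor(6 * dor[sq] / dmax), 5)
  expect_equal(as.integer(b[sq]), as.integer(expected))

  # single-pixel cisterna flagged degenerate
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  bb <- radial_bin_map(px, n_bins = 4)
  expect_true(attr(bb, "degenerate"))
})

test_that("radial profiles enforce the five-cisternae rule", {
  img <- matrix(1, 60, 60)
  seg4 <- toy_segmentation(4)
  err <- expect_error(radial_intensity_profile(img, seg4),
                      class = "insufficient_cisternae")
  expect_equal(err$n_cisternae, 4L)
  seg5 <- toy_segmentation(5)
  prof <- radial_intensity_profile(img, seg5, n_bins = 4)
  expect_equal(prof$n_cisternae, 5L)
  expect_true(all(is.finite(prof$mean_intensity)))
})

test_that("sac profiles are flat and tubular-matrix profiles edge-peaked", {
  # noiseless, unblurred sac: profile exactly flat
  spec <- phantom_spec(image_shape = c(160, 160), psf_fwhm_nm = 0,
                       photon_scale = Inf, read_noise_sd = 0,
                       background_level = 0, seed = 3)
  cfg <- pipeline_config(spec = list(image_shape = c(160L, 160L),
                                     pixel_size_nm = 46, psf_fwhm_nm = 0,
                                     photon_scale = Inf, read_noise_sd = 0,
                                     background_level = 0),
                         segmentation = list(opening_radius_px = 4L,
                                             min_object_px = 20L,
                                             denoise_sigma_px = 0))
  lay <- make_tubule_network(spec, 0)
  for (reg in erquant:::place_cisterna_regions(spec, 6, 77))
    lay <- add_cisterna(lay, reg, "sac")
  out <- render_er_image(lay, spec)
  res <- analyse_er_image(out$image$channels$lumen, cfg, "s", "sac")
  prof <- radial_intensity_profile(out$image$channels$lumen,
                                   res$segmentation, n_bins = 10)
  expect_lt(max(prof$mean_intensity) / min(prof$mean_intensity), 1.1)

  # realistic matrix phantom: edge half of the profile peaks above centre
  cfgm <- pipeline_config()
  phm <- phantom_for_condition(list(substructure = "tubular_matrix"),
                               cfgm, seed = 5)
  resm <- analyse_er_image(phm$image$channels$lumen, cfgm, "m", "matrix")
  pm <- radial_intensity_profile(phm$image$channels$lumen,
                                 resm$segmentation, n_bins = 10)
  expect_gt(max(pm$mean_intensity[1:5]), 1.15 * mean(pm$mean_intensity[6:10]))
})

test_that("GLCM matches hand-enumerated small cases", {
  # 2 x 2 image [[0,1],[0,1]]: eight ordered pairs at radius 1
  img <- matrix(c(0, 0, 1, 1), 2, 2)      # columns: (0,0), (1,1)
  g <- glcm_of_cisterna(img, matrix(TRUE, 2, 2),
                        glcm_spec(neighbourhood_radius_px = 1, n_levels = 2))
  expect_equal(unclass(g)[1:2, 1:2], matrix(0.25, 2, 2), ignore_attr = TRUE)
  expect_equal(sum(g), 1)

  # checkerboard at radius 1 (4-neighbour offsets only)
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2)
  gcb <- glcm_of_cisterna(cb, matrix(TRUE, 6, 6),
                          glcm_spec(neighbourhood_radius_px = 1, n_levels = 2))
  p <- glcm_properties(gcb)
  expect_equal(p[["contrast"]], 1)
  expect_equal(p[["homogeneity"]], 0.5)
  expect_equal(p[["correlation"]], -1)

  # constant region: single diagonal entry
  gc <- glcm_of_cisterna(matrix(7, 4, 4), matrix(TRUE, 4, 4), glcm_spec())
  expect_equal(sum(unclass(gc) != 0), 1)
  expect_equal(unclass(gc)[1, 1], 1)
})

test_that("GLCM accumulator equals exhaustive pair enumeration", {
  set.seed(7)
  for (i in 1:12) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    img <- matrix(sample(0:31, nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.75, nr, nc)
    if (sum(mask) < 2) next
    radius <- sample(c(1, 1.5, 2, 3), 1)
    nlev <- sample(2:6, 1)
    sym <- i %% 2 == 0
    spec <- glcm_spec(radius, nlev, symmetric = sym)
    got <- tryCatch(glcm_of_cisterna(img, mask, spec), error = function(e) e)
    want <- oracle_glcm(img, mask, radius, nlev, symmetric = sym)
    if (inherits(got, "error")) {
      expect_true(all(is.nan(want)))     # no pairs in range for either
    } else {
      expect_equal(unclass(got), want, ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("texture properties satisfy their analytic identities and bounds", {
  gc <- glcm_of_cisterna(matrix(3, 8, 8), matrix(TRUE, 8, 8), glcm_spec())
  p <- glcm_properties(gc)
  expect_identical(p[["energy"]], 1)
  expect_identical(p[["contrast"]], 0)
  expect_identical(p[["homogeneity"]], 1)
  expect_identical(p[["correlation"]], 0)   # degenerate, flagged
  expect_true(attr(p, "degenerate_correlation"))

  # any diagonal GLCM has homogeneity 1
  dg <- diag(c(0.2, 0.3, 0.5))
  expect_equal(glcm_properties(dg)[["homogeneity"]], 1)

  # bounds on random inputs
  set.seed(11)
  for (i in 1:10) {
    img <- matrix(runif(64), 8, 8)
    pr <- glcm_properties(glcm_of_cisterna(img, matrix(TRUE, 8, 8),
                                           glcm_spec(2, 8)))
    expect_true(pr[["energy"]] > 0 && pr[["energy"]] <= 1)
    expect_true(pr[["homogeneity"]] > 0 && pr[["homogeneity"]] <= 1)
    expect_gte(pr[["contrast"]], 0)
    expect_true(abs(pr[["correlation"]]) <= 1 + 1e-12)
  }

  expect_error(glcm_properties(matrix(1, 2, 2)), class = "unnormalized_glcm")
})

test_that("pooling is the pixel-weighted mean and respects the 5-rule", {
  rows <- data.frame(image_id = "i", condition = "c",
                     cisterna_id = 2:7, area_px = c(100, 300, 50, 50, 50, 50),
                     contrast = 0.5, correlation = 0.1,
                     energy = c(0.2, 0.6, 0.4, 0.4, 0.4, 0.4),
                     homogeneity = 0.9)
  pooled <- pool_properties(rows)
  w <- rows$area_px
  expect_equal(pooled$energy, sum(w * rows$energy) / sum(w))
  expect_equal(pooled$contrast, 0.5)
  expect_true(pooled$energy >= min(rows$energy) &&
                pooled$energy <= max(rows$energy))

  # two cisternae, areas 100/300, energies 0.2/0.6: weighted mean 0.5
  two <- rows[1:2, ]
  expect_equal(sum(two$area_px * two$energy) / sum(two$area_px), 0.5)
  expect_error(pool_properties(two), class = "insufficient_cisternae")
  expect_error(pool_properties(rows[1:4, ]), class = "insufficient_cisternae")
  expect_s3_class(pool_properties(rows[1:5, ]), "data.frame")
})

test_that("sac and nanohole phantom sets separate in the expected direction", {
  cfg <- pipeline_config(n_images = 5L)
  pooled <- list()
  for (cond in names(cfg$conditions)) {
    for (k in 1:5) {
      ph <- phantom_for_condition(cfg$conditions[[cond]], cfg,
                                  seed = 100L * match(cond, names(cfg$conditions)) + k)
      res <- analyse_er_image(ph$image$channels$lumen, cfg,
                              sprintf("%s%d", cond, k), cond)
      pooled <- c(pooled, list(res$pooled))
    }
  }
  pooled <- do.call(rbind, pooled)
  sac <- pooled[pooled$condition == "sac", ]
  holes <- pooled[pooled$condition == "nanoholes", ]
  expect_gt(mean(sac$energy), mean(holes$energy))
  expect_gt(mean(sac$homogeneity), mean(holes$homogeneity))
  expect_lt(mean(sac$contrast), mean(holes$contrast))
})
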