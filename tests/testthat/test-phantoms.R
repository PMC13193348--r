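# Synthetic phantom generators: skeleton geometry, cisterna substructures,
# rendering model and detector statistics.

test_that("tubule networks have the requested three-way junction count", {
  spec <- phantom_spec(seed = 1)

  lay0 <- make_tubule_network(spec, n_junctions = 0)
  expect_equal(nrow(lay0$segments), 1)
  census0 <- segment_degree_census(lay0$segments)
  expect_false(any(census0 == 3))

  for (seed in c(1, 7)) {
    lay <- make_tubule_network(phantom_spec(seed = seed), n_junctions = 4)
    census <- segment_degree_census(lay$segments)
    expect_equal(sum(census == 3), 4)
    expect_true(all(census %in% c(1, 3)))   # open tips or 3-way junctions
  }
  expect_equal(lay0$tubule_diameter_nm, 40)
})

test_that("tubule network generation is reproducible and fails cleanly", {
  spec <- phantom_spec(seed = 42)
  a <- make_tubule_network(spec, n_junctions = 3)
  b <- make_tubule_network(spec, n_junctions = 3)
  expect_identical(a$segments, b$segments)

  tiny <- cbind(x = c(0, 300, 300, 0), y = c(0, 0, 300, 300))
  expect_error(make_tubule_network(spec, n_junctions = 5, region = tiny),
               class = "placement_failure")
})

test_that("sac cisternae have unit occupancy across their region", {
  spec <- phantom_spec(image_shape = c(96, 96), seed = 2)
  lay <- make_tubule_network(spec, 0)
  reg <- ellipse_polygon(2200, 2200, 1200, 900, n = 40)
  lay <- add_cisterna(lay, reg, "sac")
  geo <- layout_occupancy(lay, spec)
  expect_true(all(geo$occupancy[geo$label_map == 2L] == 1))
})

test_that("nanohole occupancy deficit matches the analytic hole area", {
  spec <- phantom_spec(image_shape = c(128, 128), seed = 3)
  lay <- make_tubule_network(spec, 0)
  reg <- ellipse_polygon(2900, 2900, 2000, 1700, n = 48)
  lay <- add_cisterna(lay, reg, "sac_nanoholes",
                      params = list(hole_radius_nm = 100,
                                    hole_density_um2 = 1.5, seed = 9))
  cis <- lay$cisternae[[1]]
  expect_gt(nrow(cis$hole_centres), 0)
  geo <- layout_occupancy(lay, spec)
  occ <- geo$occupancy[geo$label_map == 2L]
  analytic <- 1 - nrow(cis$hole_centres) * pi * 100^2 /
    (pi * 2000 * 1700)
  expect_lt(abs(mean(occ) - analytic), 0.03)
})

test_that("over-dense nanoholes record a warning in the layout", {
  spec <- phantom_spec(seed = 4)
  lay <- make_tubule_network(spec, 0)
  reg <- ellipse_polygon(3000, 3000, 1500, 1500, n = 40)
  lay <- add_cisterna(lay, reg, "sac_nanoholes",
                      params = list(hole_radius_nm = 300,
                                    hole_density_um2 = 12, seed = 5))
  expect_match(lay$cisternae[[1]]$warning, "fraction")
  out <- render_er_image(lay, spec)
  expect_gt(length(out$ground_truth$warnings), 0)
})

test_that("tubular-matrix cisternae exclude lumen from their centre", {
  spec <- phantom_spec(image_shape = c(128, 128), seed = 5)
  lay <- make_tubule_network(spec, 0)
  cx <- 2900; cy <- 2900; rx <- 2000; ry <- 1700
  lay <- add_cisterna(lay, ellipse_polygon(cx, cy, rx, ry, n = 48),
                      "tubular_matrix")
  geo <- layout_occupancy(lay, spec)
  p <- lay$cisternae[[1]]$params

  ps <- spec$pixel_size_nm
  px <- rep((seq_len(128) - 1) * ps, each = 128)
  py <- rep((seq_len(128) - 1) * ps, times = 128)
  central <- geo$label_map == 2L &
    matrix(((px - cx) / rx)^2 + ((py - cy) / ry)^2 < 0.5^2, 128, 128)
  edge_band <- geo$label_map == 2L & !central &
    matrix(((px - cx) / rx)^2 + ((py - cy) / ry)^2 > 0.9^2, 128, 128)
  expect_gt(mean(geo$occupancy[edge_band]), mean(geo$occupancy[central]))
  # interior occupancy between stripes is capped at the configured ceiling
  expect_true(all(geo$occupancy[central] %in%
                    c(p$interior_ceiling, 1)))
})

test_that("noiseless rendering reproduces the occupancy map exactly", {
  spec <- phantom_spec(image_shape = c(64, 64), psf_fwhm_nm = 0,
                       photon_scale = Inf, read_noise_sd = 0,
                       background_level = 0, seed = 6)
  lay <- make_tubule_network(spec, 1)
  lay <- add_cisterna(lay, ellipse_polygon(1500, 1500, 700, 500), "sac")
  out <- render_er_image(lay, spec)
  expect_equal(out$image$channels$lumen, out$ground_truth$lumen_occupancy)
})

test_that("rendering is deterministic and never alters ground truth", {
  spec <- phantom_spec(image_shape = c(64, 64), seed = 11)
  lay <- make_tubule_network(spec, 2)
  lay <- add_cisterna(lay, ellipse_polygon(1500, 1500, 700, 500), "sac")
  a <- render_er_image(lay, spec)
  b <- render_er_image(lay, spec)
  expect_identical(a$image$channels$lumen, b$image$channels$lumen)
  expect_identical(a$ground_truth, b$ground_truth)
  geo <- layout_occupancy(lay, spec)
  expect_identical(geo$occupancy, a$ground_truth$lumen_occupancy)
})

test_that("rendered line-spread FWHM matches the 1-D convolution oracle", {
  # single horizontal tubule, noiseless; profile across it should have the
  # FWHM of a 40 nm box convolved with the Gaussian PSF
  spec <- phantom_spec(image_shape = c(64, 64), psf_fwhm_nm = 140,
                       photon_scale = Inf, read_noise_sd = 0,
                       background_level = 0, seed = 1)
  ps <- spec$pixel_size_nm
  lay <- structure(list(
    segments = matrix(c(5 * ps, 32 * ps, 59 * ps, 32 * ps), nrow = 1),
    junctions = matrix(numeric(0), ncol = 2),
    tubule_diameter_nm = 40, cisternae = list(), spec_seed = 1
  ), class = "er_layout")
  img <- render_er_image(lay, spec)$image$channels$lumen

  prof <- img[, 33]                 # column across the tubule (0-based y = 32)
  y_nm <- ((seq_len(64) - 1) - 32) * ps
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # linear interpolation at the half-max crossings
  interp <- function(i1, i2) {
    y_nm[i1] + (half - prof[i1]) * (y_nm[i2] - y_nm[i1]) /
      (prof[i2] - prof[i1])
  }
  measured_fwhm <- interp(above[2], above[2] + 1) -
    interp(above[1], above[1] - 1)

  # oracle: box(40) * Gaussian(sigma) in 1 nm steps
  sigma <- 140 / (2 * sqrt(2 * log(2)))
  yy <- seq(-400, 400, by = 1)
  f <- pnorm((yy + 20) / sigma) - pnorm((yy - 20) / sigma)
  expected_fwhm <- 2 * approx(f[yy >= 0], yy[yy >= 0],
                              xout = max(f) / 2)$y
  expect_lt(abs(measured_fwhm - abs(expected_fwhm)), 8)   # < 1 pixel
})

test_that("detector noise follows Poisson plus read-noise statistics", {
  spec <- phantom_spec(image_shape = c(8, 8), psf_fwhm_nm = 0,
                       photon_scale = 50, read_noise_sd = 2,
                       background_level = 5, seed = 1)
  ims <- sapply(1:250, function(s) {
    sp <- spec; sp$seed <- s
    erquant:::render_counts(matrix(1, 8, 8), sp)
  })
  v <- apply(ims, 1, var)
  m <- apply(ims, 1, mean) - spec$background_level
  ratio <- mean(v) / (mean(m) + spec$read_noise_sd^2)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("golgi phantoms encode curvature and width by construction", {
  straight <- make_golgi_phantom(arc_radius_nm = Inf,
                                 swelling_amplitude_nm = 0)
  expect_equal(straight$true_curvature, 0)
  e <- straight$cisternae[[1]]
  expect_true(all(abs(e$edge_a[, 2] - 27.2 / 2) < 1e-12))
  expect_true(all(abs(e$edge_b[, 2] + 27.2 / 2) < 1e-12))

  arc <- make_golgi_phantom(arc_radius_nm = 500, swelling_amplitude_nm = 0)
  expect_equal(arc$true_curvature, 0.002)
  # edge points lie at radius R +/- w/2 from the arc centre (0, -R)
  ra <- sqrt(arc$cisternae[[1]]$edge_a[, 1]^2 +
               (arc$cisternae[[1]]$edge_a[, 2] + 500)^2)
  expect_true(all(abs(ra - (500 + 27.2 / 2)) < 1e-9))

  expect_error(make_golgi_phantom(base_width_nm = 27,
                                  swelling_amplitude_nm = 30),
               class = "invalid_params")
})

test_that("ratio pair phantoms satisfy the stated forward model", {
  spec <- phantom_spec(image_shape = c(32, 32), photon_scale = Inf,
                       read_noise_sd = 0, background_level = 10, seed = 8)
  out <- make_ratio_pair(1, spec, bleed_coeff = 0, autofluor_level = 0)
  expect_equal(out$image$channels$ex405, out$image$channels$ex488)

  out2 <- make_ratio_pair(0.7, spec, bleed_coeff = 0.2)
  gt <- out2$ground_truth
  expect_equal(out2$image$channels$ex405,
               0.7 * gt$latent_signal + 0.2 * gt$autofluorescence + 10)
  expect_equal(out2$image$channels$ex488, gt$latent_signal + 10)
  expect_error(make_ratio_pair(-1, spec), class = "invalid_params")
})

test_that("cell scenes reproduce their golgi fraction and secretion ratio", {
  spec <- phantom_spec(image_shape = c(192, 192), psf_fwhm_nm = 0,
                       photon_scale = Inf, read_noise_sd = 0,
                       background_level = 10, seed = 9)
  sc <- make_cell_scene(golgi_fraction = 50, secretion_ratio = 1,
                        spec = spec)
  tr <- golgi_transport_fraction(sc$image$channels$marker, sc$rois)
  expect_equal(tr$golgi_percent, 50, tolerance = 1e-6)

  sc0 <- make_cell_scene(golgi_fraction = 0, n_golgi = 4, spec = spec)
  tr0 <- golgi_transport_fraction(sc0$image$channels$marker, sc0$rois)
  expect_equal(tr0$golgi_percent, 0, tolerance = 1e-6)

  expect_error(make_cell_scene(golgi_fraction = 30, n_golgi = 0,
                               spec = spec),
               class = "invalid_params")
})
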