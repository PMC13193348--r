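# Whole-cell scenes with known Golgi-intensity fraction and apoplast/interior
# secretion ratio, for validating the trafficking quantification.

#' Generate a cell scene with known Golgi fraction and secretion ratio
#'
#' Renders a single-channel scene containing: a cell interior filled with an
#' ER-level signal, `n_golgi` Golgi puncta (flat discs whose
#' background-corrected intensity is set so the measured Golgi share of
#' total ER+Golgi fluorescence equals `golgi_fraction`), and an apoplast
#' ring just outside the cell whose raw mean intensity is
#' `secretion_ratio` times the cell-interior mean. Matching ground-truth
#' ROIs (3 Golgi, 3 ER, 1 background, plus the cell boundary) are emitted
#' for the measurement functions.
#'
#' @param golgi_fraction target Golgi percentage of background-corrected
#'   ER+Golgi intensity, in \[0, 100)
#' @param n_golgi number of Golgi puncta (>= 3 so three ROIs can be drawn;
#'   may only be 0 when `golgi_fraction` is 0)
#' @param secretion_ratio target apoplast/interior raw intensity ratio (>= 0)
#' @param spec a [phantom_spec()]
#' @param er_emission ER emission density (fraction of `photon_scale`)
#' @param ring_width_um apoplast ring width in microns
#' @param punctum_radius_px Golgi punctum radius in pixels
#' @param roi_halfwidth_px half-width of the square measurement ROIs
#' @return list with `image` (channel `marker`), `rois` (an [roi_set()]),
#'   and `ground_truth` (`golgi_fraction`, `secretion_ratio`, `emission`,
#'   `cell_polygon` in 0-based pixel coordinates)
#' @export
make_cell_scene <- function(golgi_fraction, n_golgi = 8L,
                            secretion_ratio = 1,
                            spec = phantom_spec(),
                            er_emission = 0.3,
                            ring_width_um = 1.5,
                            punctum_radius_px = 5L,
                            roi_halfwidth_px = 2L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (golgi_fraction < 0 || golgi_fraction >= 100)
    erq_stop("golgi_fraction must lie in [0, 100)", "invalid_params")
  if (secretion_ratio < 0)
    erq_stop("secretion_ratio must be >= 0", "invalid_params")
  if (n_golgi == 0 && golgi_fraction > 0)
    erq_stop("n_golgi = 0 with golgi_fraction > 0 is inconsistent",
             "invalid_params")
  if (n_golgi > 0 && n_golgi < 3)
    erq_stop("need n_golgi >= 3 to draw three Golgi ROIs", "invalid_params")

  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ps <- spec$pixel_size_nm
  ring_px <- max(1L, as.integer(round(ring_width_um * 1000 / ps)))

  # cell outline leaves room for the ring and a background ROI
  cell_poly <- ellipse_polygon(
    cx = (nc - 1) / 2, cy = (nr - 1) / 2,
    rx = 0.5 * nc - ring_px - 12, ry = 0.5 * nr - ring_px - 12, n = 72)
  interior <- rasterize_polygon(cell_poly, c(nr, nc))

  P <- if (is.infinite(spec$photon_scale)) 1 else spec$photon_scale
  g_emission <- if (golgi_fraction == 0) 0 else
    er_emission * golgi_fraction / (100 - golgi_fraction)

  # place puncta inside the cell, clear of the boundary and of each other
  centres <- if (n_golgi > 0) with_seed(spec$seed + 17L, {
    pts <- matrix(numeric(0), ncol = 2)
    xr <- range(cell_poly[, 1]); yr <- range(cell_poly[, 2])
    margin <- punctum_radius_px + 6
    guard <- 0L
    while (nrow(pts) < n_golgi && guard < 4000L) {
      guard <- guard + 1L
      p <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
      if (!points_in_polygon(p[1], p[2], cell_poly)) next
      if (dist_to_polygon_boundary(p[1], p[2], cell_poly) < margin) next
      if (nrow(pts) > 0 &&
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) <
            2.5 * punctum_radius_px + 2 * roi_halfwidth_px) next
      pts <- rbind(pts, p)
    }
    if (nrow(pts) < n_golgi)
      erq_stop("could not place the requested Golgi puncta", "placement_failure")
    pts
  }) else matrix(numeric(0), ncol = 2)

  cols <- rep(seq_len(nc) - 1, each = nr)
  rows <- rep(seq_len(nr) - 1, times = nc)
  emission <- matrix(0, nr, nc)
  emission[interior] <- er_emission
  for (i in seq_len(nrow(centres))) {
    d2 <- (cols - centres[i, 1])^2 + (rows - centres[i, 2])^2
    emission[d2 <= punctum_radius_px^2] <- g_emission   # puncta replace ER
  }

  # apoplast ring: raw-mean ratio target includes the detector background
  interior_expected <- mean(emission[interior]) * P + spec$background_level
  ap_emission <- max(0, (secretion_ratio * interior_expected -
                           spec$background_level) / P)
  ring <- (EBImage::dilate(interior + 0, disc_brush(ring_px)) > 0) & !interior
  emission[ring] <- ap_emission

  blurred <- blur_fwhm(emission, spec$psf_fwhm_nm, ps)
  img <- render_counts(blurred, spec, channel_index = 1L)

  square <- function(cx, cy, h) {
    cbind(x = c(cx - h, cx + h, cx + h, cx - h),
          y = c(cy - h, cy - h, cy + h, cy + h))
  }
  golgi_rois <- lapply(seq_len(min(3L, nrow(centres))), function(i)
    square(centres[i, 1], centres[i, 2], roi_halfwidth_px))
  if (length(golgi_rois) < 3)   # golgi_fraction 0, n_golgi 0: dark ROIs
    golgi_rois <- lapply(1:3, function(i)
      square((nc - 1) / 2 + (i - 2) * 8, (nr - 1) / 2, roi_halfwidth_px))

  # ER ROIs: interior positions away from every punctum
  er_rois <- with_seed(spec$seed + 31L, {
    out <- list(); guard <- 0L
    while (length(out) < 3 && guard < 4000L) {
      guard <- guard + 1L
      p <- c(stats::runif(1, 0, nc - 1), stats::runif(1, 0, nr - 1))
      if (!points_in_polygon(p[1], p[2], cell_poly)) next
      if (dist_to_polygon_boundary(p[1], p[2], cell_poly) < 10) next
      if (nrow(centres) > 0 &&
          min(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2)) <
            punctum_radius_px + roi_halfwidth_px + 5) next
      out <- c(out, list(square(p[1], p[2], roi_halfwidth_px)))
    }
    if (length(out) < 3)
      erq_stop("could not place ER ROIs", "placement_failure")
    out
  })

  bg_roi <- square(4 + roi_halfwidth_px, 4 + roi_halfwidth_px,
                   roi_halfwidth_px)

  rois <- roi_set(golgi = golgi_rois, er = er_rois, background = bg_roi,
                  cell_boundary = cell_poly)
  list(
    image = multichannel_image(list(marker = img), ps,
                               meta = list(seed = spec$seed, spec = spec)),
    rois = rois,
    ground_truth = list(golgi_fraction = golgi_fraction,
                        secretion_ratio = secretion_ratio,
                        emission = emission,
                        cell_polygon = cell_poly,
                        punctum_centres = centres)
  )
}
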