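# ER-to-Golgi transport fraction, apoplast secretion index, and the
# ROI-mean protein-amount proxy.

#' ROI set for transport/secretion quantification
#'
#' Polygons are in 0-based pixel coordinates (pixel centres at integer
#' coordinates); interiors follow the even-odd rule and include the
#' boundary.
#'
#' @param golgi list of exactly 3 polygons over Golgi bodies
#' @param er list of exactly 3 polygons over the ER
#' @param background single polygon just outside the cell
#' @param cell_boundary optional cell-outline polygon (secretion mode)
#' @return object of class `roi_set`
#' @export
roi_set <- function(golgi, er, background, cell_boundary = NULL) {
  if (length(golgi) != 3) erq_stop("need exactly 3 Golgi ROIs", "invalid_rois")
  if (length(er) != 3) erq_stop("need exactly 3 ER ROIs", "invalid_rois")
  chk <- function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3)
    if (polygon_self_intersects(p))
      erq_stop("ROI polygon is self-intersecting", "invalid_rois")
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  }
  structure(list(
    golgi = lapply(golgi, chk),
    er = lapply(er, chk),
    background = chk(background),
    cell_boundary = if (is.null(cell_boundary)) NULL else chk(cell_boundary)
  ), class = "roi_set")
}

#' Mean intensity over the pixels inside a polygon
#'
#' A pixel contributes when its centre lies inside the polygon (even-odd
#' rule, boundary-inclusive).
#'
#' @param image numeric matrix
#' @param polygon 2-column vertex matrix, 0-based pixel coordinates
#' @return scalar mean
#' @export
mean_roi_intensity <- function(image, polygon) {
  stopifnot(is.matrix(image))
  m <- rasterize_polygon(polygon, dim(image))
  if (!any(m)) erq_stop("polygon encloses no pixel centres", "empty_roi")
  mean(image[m])
}

#' Golgi share of background-corrected ER + Golgi fluorescence
#'
#' Averages the three Golgi ROI means and the three ER ROI means
#' (mean-of-ROI-means, not pixel-pooled), subtracts the background ROI mean
#' from both, and reports the Golgi percentage
#' \eqn{100\, G / (G + E)}. Negative corrected means are clipped to 0 and
#' flagged. High percentages indicate normal anterograde ER-to-Golgi
#' transport of the marker; low percentages indicate ER retention.
#'
#' @param image numeric matrix (marker channel)
#' @param rois an [roi_set()]
#' @return object of class `transport_result`: `golgi_mean`, `er_mean`,
#'   `background_mean` (raw), `golgi_corrected`, `er_corrected`,
#'   `golgi_percent`, `clipped`
#' @export
golgi_transport_fraction <- function(image, rois) {
  stopifnot(inherits(rois, "roi_set"))
  gm <- mean(vapply(rois$golgi, function(p) mean_roi_intensity(image, p), 0))
  em <- mean(vapply(rois$er, function(p) mean_roi_intensity(image, p), 0))
  bm <- mean_roi_intensity(image, rois$background)
  g <- gm - bm; e <- em - bm
  clipped <- g < 0 || e < 0
  g <- max(g, 0); e <- max(e, 0)
  if (g + e == 0)
    erq_stop("corrected ER and Golgi intensities are both zero: fraction undefined",
             "undefined_fraction")
  structure(list(
    golgi_mean = gm, er_mean = em, background_mean = bm,
    golgi_corrected = g, er_corrected = e,
    golgi_percent = 100 * g / (g + e),
    clipped = clipped
  ), class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("transport_result: Golgi %.1f%% of corrected ER+Golgi intensity%s\n",
              x$golgi_percent, if (x$clipped) " (clipped)" else ""))
  invisible(x)
}

#' Apoplast/interior secretion index
#'
#' The cell interior mean is measured inside the cell-boundary polygon; the
#' apoplast mean over a ring obtained by dilating the interior by
#' `ring_width_um` (rounded to the nearest pixel) and removing the
#' interior. The index is `apoplast_mean / interior_mean`: near 0 when the
#' marker is retained intracellularly, high when it is secreted.
#'
#' @param image numeric matrix (secretion marker channel)
#' @param cell_boundary cell-outline polygon, 0-based pixel coordinates
#' @param ring_width_um ring width in microns (default 1.5)
#' @param pixel_size_nm pixel size in nm
#' @return object of class `secretion_result`: `interior_mean`,
#'   `apoplast_mean`, `secretion_index`, `ring_width_px`
#' @export
secretion_index <- function(image, cell_boundary, ring_width_um = 1.5,
                            pixel_size_nm = 46) {
  stopifnot(is.matrix(image))
  if (ring_width_um <= 0) erq_stop("ring_width_um must be > 0",
                                   "invalid_params")
  ring_px <- max(1L, as.integer(round(ring_width_um * 1000 / pixel_size_nm)))
  interior <- rasterize_polygon(cell_boundary, dim(image))
  if (!any(interior)) erq_stop("cell polygon encloses no pixels", "empty_roi")
  # estimate border clipping on a padded grid
  pad <- ring_px + 1L
  padded <- matrix(FALSE, nrow(image) + 2L * pad, ncol(image) + 2L * pad)
  padded[pad + seq_len(nrow(image)), pad + seq_len(ncol(image))] <- interior
  ring_full <- (EBImage::dilate(padded + 0, disc_brush(ring_px)) > 0) & !padded
  ring <- ring_full[pad + seq_len(nrow(image)), pad + seq_len(ncol(image))]
  clipped_frac <- 1 - sum(ring) / sum(ring_full)
  if (clipped_frac > 0.5)
    erq_warn(sprintf("%.0f%% of the apoplast ring falls outside the image",
                     100 * clipped_frac), "ring_clipped")
  im <- mean(image[interior])
  if (im == 0) erq_stop("interior mean is zero: index undefined",
                        "undefined_index")
  am <- mean(image[ring])
  structure(list(
    interior_mean = im, apoplast_mean = am,
    secretion_index = am / im,
    ring_width_px = ring_px,
    ring_clipped_fraction = clipped_frac
  ), class = "secretion_result")
}

#' @export
print.secretion_result <- function(x, ...) {
  cat(sprintf("secretion_result: apoplast/interior = %.3f (ring %d px)\n",
              x$secretion_index, x$ring_width_px))
  invisible(x)
}

#' Whole-ER mean intensity as a protein-amount proxy
#'
#' Background-corrected mean intensity over a whole-ER ROI. Only comparable
#' across images acquired with identical settings (laser power, gain,
#' averaging): the value scales linearly with detector gain.
#'
#' @param image numeric matrix
#' @param whole_er_roi polygon covering the ER
#' @param background_roi optional background polygon (or numeric background
#'   level)
#' @return background-corrected mean intensity
#' @export
er_intensity_proxy <- function(image, whole_er_roi, background_roi = NULL) {
  m <- mean_roi_intensity(image, whole_er_roi)
  bg <- 0
  if (is.numeric(background_roi) && length(background_roi) == 1) {
    bg <- background_roi
  } else if (!is.null(background_roi)) {
    bg <- mean_roi_intensity(image, background_roi)
  }
  max(m - bg, 0)
}
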