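# ER network segmentation: preprocessing, hysteresis thresholding, cisterna
# identification by morphological opening, and the apparent-tubule-radius
# estimate that sets the texture neighbourhood scale.

#' Segmentation parameters
#'
#' @param fwhm_min_nm,fwhm_max_nm expected minimum/maximum tubule full width
#'   at half maximum in nm (bookkeeping for provenance; constrain what the
#'   radius estimate may return)
#' @param upsample_factor integer >= 1; images are interpolated by this
#'   factor before segmentation to limit pixelation artefacts
#' @param background_radius_px structuring-element radius of the grayscale
#'   (rolling-ball style) background opening
#' @param denoise_sigma_px Gaussian denoise sigma applied before contrast
#'   normalisation (0 disables)
#' @param hysteresis_low,hysteresis_high hysteresis thresholds on normalised
#'   intensity in \[0, 1\] with `low <= high`
#' @param opening_radius_px disc radius of the binary opening that isolates
#'   cisternae (regions wider than about twice this radius survive)
#' @param min_object_px minimum connected-object area kept in the foreground
#' @return object of class `segmentation_params`
#' @export
segmentation_params <- function(fwhm_min_nm = 100,
                                fwhm_max_nm = 300,
                                upsample_factor = 1L,
                                background_radius_px = 50L,
                                denoise_sigma_px = 1,
                                hysteresis_low = 0.2,
                                hysteresis_high = 0.5,
                                opening_radius_px = 5L,
                                min_object_px = 20L) {
  if (fwhm_min_nm > fwhm_max_nm)
    erq_stop("fwhm_min_nm must be <= fwhm_max_nm", "invalid_params")
  if (hysteresis_low > hysteresis_high)
    erq_stop("hysteresis_low must be <= hysteresis_high", "invalid_params")
  if (opening_radius_px < 1) erq_stop("opening_radius_px must be >= 1",
                                      "invalid_params")
  if (upsample_factor < 1) erq_stop("upsample_factor must be >= 1",
                                    "invalid_params")
  structure(list(
    fwhm_min_nm = fwhm_min_nm, fwhm_max_nm = fwhm_max_nm,
    upsample_factor = as.integer(upsample_factor),
    background_radius_px = as.integer(background_radius_px),
    denoise_sigma_px = denoise_sigma_px,
    hysteresis_low = hysteresis_low, hysteresis_high = hysteresis_high,
    opening_radius_px = as.integer(opening_radius_px),
    min_object_px = as.integer(min_object_px)
  ), class = "segmentation_params")
}

#' Preprocess a single-channel image for ER segmentation
#'
#' Upsamples by bilinear interpolation, subtracts a grayscale-opening
#' background estimate (preserving cisterna plateaus), applies a light
#' Gaussian denoise, and rescales the result to \[0, 1\].
#'
#' @param image numeric matrix (single channel)
#' @param params a [segmentation_params()]
#' @return preprocessed matrix in \[0, 1\] with attribute `upsample_factor`
#' @export
preprocess <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) erq_stop("image has non-finite values",
                                       "invalid_image")
  if (all(image == 0)) erq_stop("empty image (all zero)", "empty_image")

  f <- params$upsample_factor
  if (f > 1) {
    image <- as.matrix(EBImage::resize(image, w = nrow(image) * f,
                                       h = ncol(image) * f))
  }
  bg <- gray_opening_replicate(image, params$background_radius_px)
  out <- pmax(image - bg, 0)
  if (params$denoise_sigma_px > 0) {
    out <- as.matrix(EBImage::gblur(out, sigma = params$denoise_sigma_px))
    out <- pmax(out, 0)
  }
  m <- max(out)
  if (m > 0) out <- out / m
  attr(out, "upsample_factor") <- f
  out
}

#' Hysteresis-threshold segmentation of the ER foreground
#'
#' A pixel belongs to the foreground if it is connected (8-connectivity)
#' to any pixel at or above `hysteresis_high` through pixels at or above
#' `hysteresis_low`. Objects smaller than `min_object_px` are removed.
#'
#' @param image preprocessed image in \[0, 1\]
#' @param params a [segmentation_params()]
#' @return logical foreground mask
#' @export
segment_er <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  low <- image >= params$hysteresis_low
  high <- image >= params$hysteresis_high
  if (!any(high)) {
    erq_warn("hysteresis_high exceeds the image maximum: empty mask",
             "empty_mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  lab <- .cc_label(low, 8L)
  keep <- sort(unique(lab[high]))
  keep <- keep[keep > 0]
  mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  drop_small_objects(mask, params$min_object_px)
}

drop_small_objects <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- .cc_label(mask, 8L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Identify cisternae within a segmented ER mask
#'
#' Cisternae are the parts of the foreground that survive a binary opening
#' with a disc of `opening_radius_px` (regions wider than roughly twice the
#' radius); the remaining foreground is classed as tubule. Connected
#' cisterna components receive unique ids (>= 2) in the label map.
#'
#' @param mask logical foreground mask from [segment_er()]
#' @param image the intensity image the mask was derived from (stored sizes
#'   are used downstream; may be `NULL`)
#' @param params a [segmentation_params()]
#' @return object of class `er_segmentation`: `label_map` (0 background,
#'   1 tubule, ids >= 2 one per cisterna), `cisterna_ids`, `cisterna_areas`
#'   (pixels), `params`
#' @export
identify_cisternae <- function(mask, image = NULL,
                               params = segmentation_params()) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  opened <- EBImage::opening(mask + 0,
                             disc_brush(params$opening_radius_px)) > 0
  opened <- opened & mask
  lab <- .cc_label(opened, 8L)
  # small opened fragments revert to tubule class
  if (any(lab > 0)) {
    sizes <- tabulate(lab)
    small <- which(sizes < params$min_object_px)
    if (length(small)) lab[lab %in% small] <- 0L
    ids_old <- sort(unique(lab[lab > 0]))
    lab <- matrix(match(lab, ids_old, nomatch = 0L), nrow(lab))
  }
  label_map <- matrix(0L, nrow(mask), ncol(mask))
  label_map[mask] <- 1L
  label_map[lab > 0] <- lab[lab > 0] + 1L
  ids <- sort(unique(label_map[label_map >= 2L]))
  areas <- if (length(ids)) tabulate(label_map)[ids] else integer(0)
  structure(list(
    label_map = label_map,
    cisterna_ids = ids,
    cisterna_areas = areas,
    params = params,
    image = image
  ), class = "er_segmentation")
}

#' @export
print.er_segmentation <- function(x, ...) {
  cat(sprintf(
    "er_segmentation: %d x %d px, %d cisternae (%d cisterna px, %d tubule px)\n",
    nrow(x$label_map), ncol(x$label_map), length(x$cisterna_ids),
    sum(x$label_map >= 2L), sum(x$label_map == 1L)))
  invisible(x)
}

#' Logical mask of one cisterna
#' @param segmentation an `er_segmentation`
#' @param id cisterna id (>= 2)
#' @return logical matrix
#' @export
cisterna_mask <- function(segmentation, id) {
  stopifnot(inherits(segmentation, "er_segmentation"))
  segmentation$label_map == id
}

#' Estimate the apparent tubule radius from PSF width and intensity ratio
#'
#' Sub-resolution tubules appear dimmer than extended cisternae in
#' proportion to how much of the PSF they fill. The apparent radius is
#' operationalised as half the PSF full width scaled by the
#' tubule/cisterna median-intensity ratio,
#' \deqn{r = 0.5\, \mathrm{FWHM}_{psf} \cdot
#'   \mathrm{med}(I_{tub}) / \mathrm{med}(I_{cis}),}
#' clipped to \[pixel size, PSF FWHM\]. The pixel-unit radius is the default
#' GLCM neighbourhood scale.
#'
#' @param image intensity image matching the segmentation grid
#' @param segmentation an `er_segmentation`
#' @param psf_fwhm_nm microscope PSF full width at half maximum (nm)
#' @param pixel_size_nm effective pixel size of `image` in nm (after any
#'   upsampling)
#' @return object of class `tubule_width_estimate`: `radius_nm`,
#'   `radius_px`, `tubule_intensity`, `cisterna_intensity`, `psf_fwhm_nm`,
#'   `fallback` (TRUE when no cisterna pixels were available)
#' @export
estimate_tubule_radius <- function(image, segmentation,
                                   psf_fwhm_nm = 140,
                                   pixel_size_nm = 46) {
  stopifnot(is.matrix(image), inherits(segmentation, "er_segmentation"),
            identical(dim(image), dim(segmentation$label_map)))
  tub <- image[segmentation$label_map == 1L]
  cis <- image[segmentation$label_map >= 2L]
  if (!length(tub)) erq_stop("segmentation has no tubule pixels",
                             "no_tubule_pixels")
  fallback <- length(cis) == 0
  if (fallback) {
    erq_warn("no cisterna pixels: falling back to radius = PSF/2",
             "radius_fallback")
    radius_nm <- 0.5 * psf_fwhm_nm
    ti <- stats::median(tub); ci <- NA_real_
  } else {
    ti <- stats::median(tub); ci <- stats::median(cis)
    radius_nm <- 0.5 * psf_fwhm_nm * ti / ci
  }
  radius_nm <- min(max(radius_nm, pixel_size_nm), psf_fwhm_nm)
  structure(list(
    radius_nm = radius_nm,
    radius_px = radius_nm / pixel_size_nm,
    tubule_intensity = ti,
    cisterna_intensity = ci,
    psf_fwhm_nm = psf_fwhm_nm,
    pixel_size_nm = pixel_size_nm,
    fallback = fallback
  ), class = "tubule_width_estimate")
}
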