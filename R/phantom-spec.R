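#' Imaging specification for synthetic phantoms
#'
#' Bundles the optical and detector parameters shared by all phantom
#' renderers: image geometry, lateral pixel size, point-spread-function (PSF)
#' width, photon budget and detector noise. The defaults emulate the
#' high-resolution confocal regime used for cortical-ER imaging: 46 nm
#' lateral pixels and a PSF of roughly 140 nm full width at half maximum,
#' modelled as an isotropic 2D Gaussian.
#'
#' @param image_shape integer vector `(rows, cols)` in pixels
#' @param pixel_size_nm lateral pixel size in nm/pixel. The default of 46 nm
#'   treats the published "0.046 micron" scaling as a lateral pitch; if your
#'   metadata records pixel *area* instead, pass `sqrt(area)` here.
#' @param psf_fwhm_nm PSF full width at half maximum in nm (>= 0; 0 disables
#'   blurring)
#' @param photon_scale expected photon count at unit emission density.
#'   `Inf` disables Poisson sampling (noiseless rendering).
#' @param read_noise_sd Gaussian read-noise standard deviation in counts
#' @param background_level constant detector background in counts
#' @param seed integer seed; identical spec + seed gives bit-identical output
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(image_shape = c(256L, 256L),
                         pixel_size_nm = 46,
                         psf_fwhm_nm = 140,
                         photon_scale = 500,
                         read_noise_sd = 2,
                         background_level = 10,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape > 0))
  if (pixel_size_nm <= 0) erq_stop("pixel_size_nm must be > 0", "invalid_spec")
  if (psf_fwhm_nm < 0) erq_stop("psf_fwhm_nm must be >= 0", "invalid_spec")
  if (read_noise_sd < 0) erq_stop("read_noise_sd must be >= 0", "invalid_spec")
  structure(list(
    image_shape = as.integer(image_shape),
    pixel_size_nm = pixel_size_nm,
    psf_fwhm_nm = psf_fwhm_nm,
    photon_scale = photon_scale,
    read_noise_sd = read_noise_sd,
    background_level = background_level,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %d x %d px @ %.1f nm/px, PSF %.0f nm FWHM,\n  photons %s, read noise %.2f, background %.1f, seed %d\n",
    x$image_shape[1], x$image_shape[2], x$pixel_size_nm, x$psf_fwhm_nm,
    format(x$photon_scale), x$read_noise_sd, x$background_level, x$seed
  ))
  invisible(x)
}

# physical field-of-view (nm) of a spec: c(height, width)
spec_extent_nm <- function(spec) spec$image_shape * spec$pixel_size_nm

#' Construct a multi-channel image container
#'
#' @param channels named list of numeric matrices with identical dimensions
#' @param pixel_size_nm lateral pixel size in nm
#' @param meta optional list of metadata (seed, spec, provenance)
#' @return object of class `multichannel_image`
#' @export
multichannel_image <- function(channels, pixel_size_nm, meta = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d))
  structure(list(
    channels = channels,
    pixel_size_nm = pixel_size_nm,
    meta = meta
  ), class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("multichannel_image: %d x %d px @ %.1f nm/px, channels: %s\n",
              d[1], d[2], x$pixel_size_nm,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
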