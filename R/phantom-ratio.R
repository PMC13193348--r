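# Ratio-pair phantoms for the roGFP2 405/488 excitation-ratio workflow.

#' Generate a 405/488/autofluorescence image triplet with a known ratio
#'
#' Forward model for ratiometric excitation imaging of a redox probe:
#' a latent fluorophore signal `S` (smooth seeded random field scaled by the
#' photon budget) is observed in two excitation channels,
#' \deqn{I_{405} = r \cdot S + b \cdot A + bg + noise, \quad
#'       I_{488} = S + bg + noise,}
#' where `r` is the true 405/488 ratio (scalar or per-pixel map), `A` an
#' autofluorescence field with bleed-through coefficient `b`, and `bg` the
#' detector background. An autofluorescence reference channel
#' `A + bg + noise` is returned alongside for bleed-through correction.
#'
#' Useful presets for `true_ratio`: ~0.45 for a cytosolic (reducing)
#' environment and ~1.34 for the ER lumen (oxidising).
#'
#' @param true_ratio positive scalar or matrix matching the image shape
#' @param spec a [phantom_spec()]; `photon_scale = Inf` gives noiseless output
#' @param bleed_coeff autofluorescence bleed-through into the 405 channel
#'   (0 <= b < 1)
#' @param autofluor_level autofluorescence amplitude relative to the photon
#'   scale (0 disables autofluorescence)
#' @param signal_range range of the latent signal field as a fraction of
#'   `photon_scale`
#' @return list with `image` (channels `ex405`, `ex488`, `auto`) and
#'   `ground_truth` (`true_ratio`, `latent_signal`, `autofluorescence`,
#'   `bleed_coeff`, `background`)
#' @export
make_ratio_pair <- function(true_ratio, spec,
                            bleed_coeff = 0,
                            autofluor_level = 0.1,
                            signal_range = c(0.4, 1)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(true_ratio <= 0)) erq_stop("true_ratio must be > 0", "invalid_params")
  if (bleed_coeff < 0 || bleed_coeff >= 1)
    erq_stop("bleed_coeff must be in [0, 1)", "invalid_params")
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  if (is.matrix(true_ratio)) stopifnot(identical(dim(true_ratio), c(nr, nc)))

  scale <- if (is.infinite(spec$photon_scale)) 1000 else spec$photon_scale
  fields <- with_seed(spec$seed, {
    smooth_field <- function(lo, hi) {
      f <- matrix(stats::runif(nr * nc), nr, nc)
      f <- blur_fwhm(f, fwhm_nm = 8 * spec$pixel_size_nm,
                     pixel_size_nm = spec$pixel_size_nm)
      f <- (f - min(f)) / max(max(f) - min(f), 1e-12)
      lo + f * (hi - lo)
    }
    list(S = scale * smooth_field(signal_range[1], signal_range[2]),
         A = scale * autofluor_level *
           (if (autofluor_level > 0) smooth_field(0.2, 1) else matrix(0, nr, nc)))
  })
  S <- fields$S; A <- fields$A
  bg <- spec$background_level

  sample_channel <- function(lam, idx) {
    if (is.infinite(spec$photon_scale)) return(lam + bg)
    with_seed(spec$seed + 2000L + idx, {
      counts <- stats::rpois(length(lam), pmax(lam, 0))
      if (spec$read_noise_sd > 0)
        counts <- counts + stats::rnorm(length(lam), 0, spec$read_noise_sd)
      matrix(counts + bg, nrow = nr)
    })
  }

  image <- multichannel_image(
    list(ex405 = sample_channel(true_ratio * S + bleed_coeff * A, 1L),
         ex488 = sample_channel(S, 2L),
         auto = sample_channel(A, 3L)),
    spec$pixel_size_nm,
    meta = list(seed = spec$seed, spec = spec)
  )
  list(image = image,
       ground_truth = list(true_ratio = true_ratio, latent_signal = S,
                           autofluorescence = A, bleed_coeff = bleed_coeff,
                           background = bg))
}
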