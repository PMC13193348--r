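# Corrected 405/488 excitation ratios for roGFP2 membrane-topology assays.

#' Background and bleed-through correction of a 405/488 channel pair
#'
#' \deqn{C_{405} = \max(I_{405} - bg_{405} - b (I_{auto} - bg_{auto}), 0)}
#' \deqn{C_{488} = \max(I_{488} - bg_{488}, 0)}
#' Pixels saturated at `saturation` (e.g. the dtype maximum) in either
#' channel are marked in the returned `saturated` mask and excluded from
#' downstream ratios.
#'
#' @param i405,i488 numeric matrices (405-excited and 488-excited channels)
#' @param iauto autofluorescence reference channel (or `NULL` when
#'   `bleed_coeff = 0`)
#' @param bg405,bg488,bg_auto non-negative channel backgrounds
#' @param bleed_coeff autofluorescence bleed-through coefficient (>= 0)
#' @param saturation optional saturation level
#' @return list with `c405`, `c488` corrected matrices and `saturated`
#'   logical matrix
#' @export
correct_channels <- function(i405, i488, iauto = NULL,
                             bg405 = 0, bg488 = 0, bg_auto = 0,
                             bleed_coeff = 0, saturation = NULL) {
  stopifnot(is.matrix(i405), identical(dim(i405), dim(i488)))
  if (bg405 < 0 || bg488 < 0 || bg_auto < 0)
    erq_stop("backgrounds must be non-negative", "invalid_params")
  if (bleed_coeff < 0) erq_stop("bleed_coeff must be >= 0", "invalid_params")
  bleed <- 0
  if (bleed_coeff > 0) {
    if (is.null(iauto))
      erq_stop("bleed correction requires the autofluorescence channel",
               "invalid_params")
    stopifnot(identical(dim(iauto), dim(i405)))
    bleed <- bleed_coeff * pmax(iauto - bg_auto, 0)
  }
  saturated <- matrix(FALSE, nrow(i405), ncol(i405))
  if (!is.null(saturation)) {
    saturated <- i405 >= saturation | i488 >= saturation
    if (!is.null(iauto)) saturated <- saturated | iauto >= saturation
  }
  list(c405 = pmax(i405 - bg405 - bleed, 0),
       c488 = pmax(i488 - bg488, 0),
       saturated = saturated)
}

#' Estimate the bleed-through coefficient from an autofluorescence-only ROI
#'
#' Linear fit through the origin of background-corrected 405 signal against
#' background-corrected autofluorescence, over pixels where no probe signal
#' is expected.
#'
#' @param i405,iauto channel matrices
#' @param roi logical matrix selecting autofluorescence-only pixels
#' @param bg405,bg_auto channel backgrounds
#' @return scalar coefficient
#' @export
estimate_bleed_coeff <- function(i405, iauto, roi, bg405 = 0, bg_auto = 0) {
  stopifnot(identical(dim(i405), dim(iauto)), any(roi))
  x <- pmax(iauto[roi] - bg_auto, 0)
  y <- pmax(i405[roi] - bg405, 0)
  if (sum(x^2) == 0) return(0)
  sum(x * y) / sum(x^2)
}

#' Pixel-wise 405/488 ratio map and per-cell summary
#'
#' The ratio is computed where the corrected 488 channel is at or above
#' `signal_floor` (and unsaturated); other pixels are masked `NA`. A
#' sensible floor is `background mean + 3 * background SD`.
#'
#' @param c405,c488 corrected channels from [correct_channels()]
#' @param signal_floor minimum corrected 488 intensity for a valid ratio
#' @param saturated optional logical matrix of pixels to exclude
#' @return object of class `ratio_result`: `ratio_map` (NA-masked),
#'   `cell_mean`, `cell_sd`, `n_pixels`
#' @export
ratio_map <- function(c405, c488, signal_floor = 0, saturated = NULL) {
  stopifnot(is.matrix(c405), identical(dim(c405), dim(c488)))
  ok <- c488 >= max(signal_floor, .Machine$double.eps)
  if (!is.null(saturated)) ok <- ok & !saturated
  if (!any(ok)) erq_stop("no signal pixels above the floor", "no_signal")
  r <- matrix(NA_real_, nrow(c405), ncol(c405))
  r[ok] <- c405[ok] / c488[ok]
  structure(list(
    ratio_map = r,
    cell_mean = mean(r[ok]),
    cell_sd = stats::sd(r[ok]),
    n_pixels = sum(ok)
  ), class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("ratio_result: mean %.3f +/- %.3f over %d pixels\n",
              x$cell_mean, x$cell_sd, x$n_pixels))
  invisible(x)
}

#' Classify the probe environment from a cell-mean excitation ratio
#'
#' The 405/488 ratio of roGFP2 is low in a reducing compartment (cytosol)
#' and high in an oxidising one (ER lumen). Classification splits at the
#' geometric midpoint of the two reference means with a configurable
#' exclusion margin: below `midpoint * (1 - margin)` is `reducing`, above
#' `midpoint * (1 + margin)` is `oxidising`, in between is `ambiguous`.
#' Defaults use the cytosolic (0.45) and ER-lumen (1.34) control means.
#'
#' @param cell_mean mean corrected ratio of one cell
#' @param reducing_ref,oxidising_ref reference ratios (positive,
#'   `reducing_ref < oxidising_ref`)
#' @param margin relative ambiguity margin around the midpoint
#' @return one of `"reducing"`, `"oxidising"`, `"ambiguous"`
#' @export
classify_environment <- function(cell_mean, reducing_ref = 0.45,
                                 oxidising_ref = 1.34, margin = 0.1) {
  if (reducing_ref <= 0 || oxidising_ref <= 0 || reducing_ref >= oxidising_ref)
    erq_stop("need 0 < reducing_ref < oxidising_ref", "invalid_params")
  mid <- sqrt(reducing_ref * oxidising_ref)
  if (cell_mean < mid * (1 - margin)) "reducing"
  else if (cell_mean > mid * (1 + margin)) "oxidising"
  else "ambiguous"
}
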