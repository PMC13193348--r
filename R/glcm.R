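# Per-cisterna grey-level co-occurrence texture statistics.

#' GLCM specification
#'
#' @param neighbourhood_radius_px maximum pair offset length in pixels
#'   (>= 1); typically the apparent tubule radius from
#'   [estimate_tubule_radius()]
#' @param n_levels grey quantisation levels (>= 2); intensities are
#'   quantised over each cisterna's own min-max range
#' @param symmetric count each unordered pixel pair in both directions,
#'   producing a symmetric matrix (default TRUE)
#' @return object of class `glcm_spec`
#' @export
glcm_spec <- function(neighbourhood_radius_px = 2,
                      n_levels = 8L,
                      symmetric = TRUE) {
  if (neighbourhood_radius_px < 1)
    erq_stop("neighbourhood_radius_px must be >= 1", "invalid_params")
  if (n_levels < 2) erq_stop("n_levels must be >= 2", "invalid_params")
  structure(list(
    neighbourhood_radius_px = neighbourhood_radius_px,
    n_levels = as.integer(n_levels),
    symmetric = isTRUE(symmetric)
  ), class = "glcm_spec")
}

# all integer offsets with 0 < |(dr, dc)| <= radius; half-disc if !symmetric
glcm_offsets <- function(radius, symmetric) {
  R <- as.integer(floor(radius))
  g <- expand.grid(dr = -R:R, dc = -R:R)
  g <- g[g$dr^2 + g$dc^2 > 0 & g$dr^2 + g$dc^2 <= radius^2 + 1e-9, ]
  if (!symmetric) g <- g[g$dc > 0 | (g$dc == 0 & g$dr > 0), ]
  as.matrix(g)
}

# quantise intensities within the mask to 0..n_levels-1 over min-max
quantize_levels <- function(image, mask, n_levels) {
  q <- matrix(0L, nrow(image), ncol(image))
  v <- image[mask]
  rng <- range(v)
  if (diff(rng) > 0) {
    lv <- pmin(as.integer(floor(n_levels * (v - rng[1]) / diff(rng))),
               n_levels - 1L)
    q[mask] <- lv
  }
  q
}

#' Normalised grey-level co-occurrence matrix of one cisterna
#'
#' Accumulates counts over all ordered pixel pairs `(p, q)` with both pixels
#' inside the mask and `0 < |q - p| <= radius` (a disc-shaped accumulator:
#' all offsets within the neighbourhood pooled into one matrix). Intensities
#' are quantised to `n_levels` over the cisterna's own min-max range;
#' a constant-intensity cisterna yields a single-cell GLCM. The matrix is
#' normalised to sum 1.
#'
#' @param image intensity matrix
#' @param mask logical matrix selecting the cisterna (area >= 2)
#' @param spec a [glcm_spec()]
#' @return normalised `n_levels x n_levels` matrix of class `glcm`, with
#'   attributes `n_pixels` (mask area) and `spec`
#' @export
glcm_of_cisterna <- function(image, mask, spec = glcm_spec()) {
  stopifnot(is.matrix(image), identical(dim(image), dim(mask)))
  mask <- mask > 0
  if (sum(mask) < 2) erq_stop("mask area must be >= 2", "mask_too_small")
  q <- quantize_levels(image, mask, spec$n_levels)
  off <- glcm_offsets(spec$neighbourhood_radius_px, spec$symmetric)
  acc <- .glcm_accumulate(q, mask, off, spec$n_levels)
  total <- sum(acc)
  if (total == 0)
    erq_stop("no pixel pairs within the neighbourhood radius", "no_pairs")
  g <- acc / total
  attr(g, "n_pixels") <- sum(mask)
  attr(g, "spec") <- spec
  class(g) <- c("glcm", class(g))
  g
}

#' Scalar texture properties of a normalised GLCM
#'
#' With `p(i, j)` the normalised co-occurrence probabilities:
#' \deqn{contrast = \sum (i-j)^2 p(i,j)}
#' \deqn{correlation = \sum (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)}
#' \deqn{energy = \sum p(i,j)^2}
#' \deqn{homogeneity = \sum p(i,j) / (1 + |i-j|)}
#' A perfectly constant region gives energy 1 and contrast 0; any GLCM with
#' all mass on the diagonal gives homogeneity 1. Correlation is returned as
#' 0 (flagged via the `degenerate_correlation` attribute) when either
#' marginal standard deviation vanishes, so pooling stays defined.
#'
#' @param glcm normalised co-occurrence matrix (entries sum to 1)
#' @return named numeric vector `(contrast, correlation, energy,
#'   homogeneity)`
#' @export
glcm_properties <- function(glcm) {
  g <- unclass(glcm)
  if (!is.matrix(g) || nrow(g) != ncol(g))
    erq_stop("glcm must be a square matrix", "invalid_glcm")
  if (abs(sum(g) - 1) > 1e-8)
    erq_stop("glcm is not normalised (entries must sum to 1)",
             "unnormalized_glcm")
  n <- nrow(g)
  i <- matrix(0:(n - 1), n, n)        # row level index
  j <- t(i)
  contrast <- sum((i - j)^2 * g)
  energy <- sum(g^2)
  homogeneity <- sum(g / (1 + abs(i - j)))
  pi_ <- rowSums(g); pj_ <- colSums(g)
  mi <- sum((0:(n - 1)) * pi_); mj <- sum((0:(n - 1)) * pj_)
  si <- sqrt(sum(((0:(n - 1)) - mi)^2 * pi_))
  sj <- sqrt(sum(((0:(n - 1)) - mj)^2 * pj_))
  degenerate <- si * sj < 1e-12
  correlation <- if (degenerate) 0 else
    sum((i - mi) * (j - mj) * g) / (si * sj)
  out <- c(contrast = contrast, correlation = correlation,
           energy = energy, homogeneity = homogeneity)
  attr(out, "degenerate_correlation") <- degenerate
  out
}

#' Per-cisterna texture properties for every cisterna in a segmentation
#'
#' @param image intensity matrix (lumenal channel)
#' @param segmentation an `er_segmentation`
#' @param spec a [glcm_spec()]
#' @param image_id,condition labels carried into the output
#' @return data frame with one row per cisterna: `image_id`, `condition`,
#'   `cisterna_id`, `area_px`, `contrast`, `correlation`, `energy`,
#'   `homogeneity`
#' @export
cisterna_texture_table <- function(image, segmentation, spec = glcm_spec(),
                                   image_id = "image", condition = NA) {
  ids <- segmentation$cisterna_ids
  rows <- lapply(ids, function(id) {
    m <- segmentation$label_map == id
    if (sum(m) < 2) return(NULL)
    p <- glcm_properties(glcm_of_cisterna(image, m, spec))
    data.frame(image_id = image_id, condition = condition,
               cisterna_id = id, area_px = sum(m),
               contrast = p[["contrast"]], correlation = p[["correlation"]],
               energy = p[["energy"]], homogeneity = p[["homogeneity"]])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pixel-weighted pooling of per-cisterna texture properties
#'
#' Pools each property as the area-weighted mean
#' \eqn{\sum_i a_i x_i / \sum_i a_i} over all cisternae of an image, so
#' results are not dominated by many small cisternae. Requires at least
#' `min_cisternae` rows (default 5, the same representativeness rule as the
#' radial profiles).
#'
#' @param per_cisterna data frame from [cisterna_texture_table()]
#' @param min_cisternae minimum cisterna count
#' @return one-row data frame of pooled `contrast`, `correlation`,
#'   `energy`, `homogeneity` plus `n_cisternae` and `total_px`
#' @export
pool_properties <- function(per_cisterna, min_cisternae = 5L) {
  if (is.null(per_cisterna) || nrow(per_cisterna) < min_cisternae)
    erq_stop(sprintf("only %d cisternae; %d required for pooling",
                     if (is.null(per_cisterna)) 0L else nrow(per_cisterna),
                     min_cisternae),
             "insufficient_cisternae",
             n_cisternae = if (is.null(per_cisterna)) 0L
                           else nrow(per_cisterna))
  w <- per_cisterna$area_px
  pool <- function(x) sum(w * x) / sum(w)
  data.frame(
    image_id = per_cisterna$image_id[1],
    condition = per_cisterna$condition[1],
    contrast = pool(per_cisterna$contrast),
    correlation = pool(per_cisterna$correlation),
    energy = pool(per_cisterna$energy),
    homogeneity = pool(per_cisterna$homogeneity),
    n_cisternae = nrow(per_cisterna),
    total_px = sum(w)
  )
}
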