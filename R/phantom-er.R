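# ER network phantoms: tubule skeletons with three-way junctions plus
# cisternae of three substructure classes (sac, nanohole-punctured sac,
# dense tubular matrix with a lumen-filled edge band).

#' Generate a random ER tubule skeleton with three-way junctions
#'
#' Builds a connected planar skeleton of straight tubule segments in
#' physical (nm) coordinates. Growth starts from a single chord across the
#' region; each junction is created by attaching a new branch to a random
#' interior point of an existing segment, which yields a degree-3 node.
#' Branch endpoints are rejection-sampled so segments do not cross, keeping
#' the skeleton planar.
#'
#' @param spec a [phantom_spec()]
#' @param n_junctions number of three-way junctions to place (>= 0)
#' @param region optional polygon (nm coordinates, 2-column matrix) that the
#'   skeleton must stay inside; defaults to the image rectangle inset by 5%
#' @param min_branch_nm minimum branch length
#' @param max_attempts rejection-sampling budget per junction
#' @return an object of class `er_layout` with fields `segments`
#'   (n x 4 matrix: x1, y1, x2, y2 nm), `junctions` (J x 2 matrix),
#'   `tubule_diameter_nm` (40 nm default, the physical tubule calibre),
#'   `cisternae` (empty list), `region`
#' @export
make_tubule_network <- function(spec, n_junctions, region = NULL,
                                min_branch_nm = 10 * spec$pixel_size_nm,
                                max_attempts = 400L) {
  stopifnot(inherits(spec, "phantom_spec"), n_junctions >= 0)
  ext <- spec_extent_nm(spec)
  if (is.null(region)) {
    mx <- 0.05 * ext[2]; my <- 0.05 * ext[1]
    region <- cbind(x = c(mx, ext[2] - mx, ext[2] - mx, mx),
                    y = c(my, my, ext[1] - my, ext[1] - my))
  }
  region <- as.matrix(region)
  rx <- range(region[, 1]); ry <- range(region[, 2])
  if (diff(rx) < 2 * min_branch_nm || diff(ry) < 2 * min_branch_nm)
    erq_stop("region too small to place the requested skeleton",
             "placement_failure")

  rand_pt <- function() {
    for (i in 1:200) {
      p <- c(stats::runif(1, rx[1], rx[2]), stats::runif(1, ry[1], ry[2]))
      if (points_in_polygon(p[1], p[2], region)) return(p)
    }
    erq_stop("could not sample a point inside the region", "placement_failure")
  }

  with_seed(spec$seed, {
    # initial open tubule: a long chord
    repeat {
      p1 <- rand_pt(); p2 <- rand_pt()
      if (sqrt(sum((p1 - p2)^2)) > 0.5 * min(diff(rx), diff(ry))) break
    }
    segs <- matrix(c(p1, p2), nrow = 1)
    junctions <- matrix(numeric(0), ncol = 2)

    placed <- 0L
    attempts <- 0L
    while (placed < n_junctions) {
      attempts <- attempts + 1L
      if (attempts > max_attempts * (n_junctions + 1L))
        erq_stop(sprintf(
          "placed only %d of %d junctions within the attempt budget",
          placed, n_junctions), "placement_failure")
      i <- sample.int(nrow(segs), 1)
      t <- stats::runif(1, 0.2, 0.8)
      a <- segs[i, 1:2]; b <- segs[i, 3:4]
      at <- a + t * (b - a)                      # attachment point
      tip <- rand_pt()
      v <- tip - at
      len <- sqrt(sum(v^2))
      if (len < min_branch_nm) next
      # reject branches crossing existing segments (planarity)
      ok <- TRUE
      for (j in seq_len(nrow(segs))) {
        if (j == i) next
        if (segments_intersect(at, tip, segs[j, 1:2], segs[j, 3:4])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      # split segment i at the attachment point, add the branch
      segs <- rbind(segs[-i, , drop = FALSE],
                    c(a, at), c(at, b), c(at, tip))
      junctions <- rbind(junctions, at)
      placed <- placed + 1L
    }

    structure(list(
      segments = unname(segs),
      junctions = unname(junctions),
      tubule_diameter_nm = 40,
      cisternae = list(),
      region = region,
      spec_seed = spec$seed
    ), class = "er_layout")
  })
}

#' @export
print.er_layout <- function(x, ...) {
  cat(sprintf(
    "er_layout: %d tubule segments, %d three-way junctions, %d cisternae (diameter %.0f nm)\n",
    nrow(x$segments), nrow(x$junctions), length(x$cisternae),
    x$tubule_diameter_nm))
  invisible(x)
}

#' Add a cisterna of a given substructure class to an ER layout
#'
#' Three substructure classes are supported, mirroring the structural models
#' distinguishable by lumenal-marker texture:
#' \describe{
#'   \item{`sac`}{uniform lumen: occupancy 1 across the region.}
#'   \item{`sac_nanoholes`}{uniform lumen punctured by circular nanoholes
#'     (occupancy 0 inside holes) at a given radius and areal density.}
#'   \item{`tubular_matrix`}{a dense tubular matrix: a continuous
#'     lumen-filled edge band plus packed internal tubule stripes at full
#'     occupancy; the compressed lumen elsewhere sits at a low ceiling,
#'     so the cisterna centre largely excludes the soluble marker.}
#' }
#'
#' @param layout an `er_layout`
#' @param region cisterna outline polygon (nm coordinates, 2-column matrix);
#'   must be simple (non-self-intersecting)
#' @param substructure one of `"sac"`, `"sac_nanoholes"`, `"tubular_matrix"`
#' @param params substructure parameters: for `sac_nanoholes`,
#'   `hole_radius_nm` and `hole_density_um2` (holes per square micron) plus
#'   optional `seed`; for `tubular_matrix`, `tubule_spacing_nm` (default 2x
#'   tubule diameter), `edge_band_nm` (default 150), `interior_ceiling`
#'   (default 0.1) and optional `orientation` (radians)
#' @return the layout with the cisterna appended
#' @export
add_cisterna <- function(layout, region,
                         substructure = c("sac", "sac_nanoholes",
                                          "tubular_matrix"),
                         params = list()) {
  stopifnot(inherits(layout, "er_layout"))
  substructure <- match.arg(substructure)
  region <- as.matrix(region)
  if (nrow(region) < 3) erq_stop("region polygon needs >= 3 vertices",
                                 "invalid_region")
  if (polygon_self_intersects(region))
    erq_stop("cisterna region polygon is self-intersecting", "invalid_region")

  cis <- list(region = region, substructure = substructure,
              params = params, warning = NULL)

  if (substructure == "sac_nanoholes") {
    if (is.null(params$hole_radius_nm) || is.null(params$hole_density_um2))
      erq_stop("sac_nanoholes needs hole_radius_nm and hole_density_um2",
               "invalid_params")
    area_um2 <- polygon_area(region) / 1e6
    seed <- if (!is.null(params$seed)) params$seed else layout$spec_seed + 101L
    centres <- with_seed(seed, {
      n_holes <- stats::rpois(1, params$hole_density_um2 * area_um2)
      if (n_holes == 0) matrix(numeric(0), ncol = 2) else {
        xr <- range(region[, 1]); yr <- range(region[, 2])
        pts <- matrix(numeric(0), ncol = 2)
        guard <- 0L
        while (nrow(pts) < n_holes && guard < 50L * n_holes + 200L) {
          guard <- guard + 1L
          p <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
          if (points_in_polygon(p[1], p[2], region)) pts <- rbind(pts, p)
        }
        pts
      }
    })
    cis$hole_centres <- centres
    hole_frac <- nrow(centres) * pi * params$hole_radius_nm^2 /
      polygon_area(region)
    if (hole_frac > 0.5) {
      cis$warning <- sprintf(
        "nanohole area fraction %.2f exceeds 0.5; holes likely merged",
        hole_frac)
    }
  }
  if (substructure == "tubular_matrix") {
    p <- params
    if (is.null(p$tubule_spacing_nm))
      p$tubule_spacing_nm <- 2 * layout$tubule_diameter_nm
    if (is.null(p$edge_band_nm)) p$edge_band_nm <- 150
    if (is.null(p$interior_ceiling)) p$interior_ceiling <- 0.1
    if (is.null(p$orientation)) p$orientation <- 0
    cis$params <- p
  }
  layout$cisternae <- c(layout$cisternae, list(cis))
  layout
}

# shoelace area (absolute)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  closed <- rbind(poly, poly[1, , drop = FALSE])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (segments_intersect(closed[i, ], closed[i + 1, ],
                             closed[j, ], closed[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Rasterise the lumen occupancy and true label map of an ER layout
#'
#' Pure geometry: no optics or noise. Occupancy is the per-pixel fraction of
#' lumen present in \[0, 1\]; the label map assigns 0 = background,
#' 1 = tubule, and ids 2, 3, ... to cisternae in the order they were added.
#'
#' @param layout an `er_layout`
#' @param spec a [phantom_spec()] fixing the pixel grid
#' @return list with `occupancy` and `label_map` matrices
#' @export
layout_occupancy <- function(layout, spec) {
  stopifnot(inherits(layout, "er_layout"), inherits(spec, "phantom_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ps <- spec$pixel_size_nm
  occ <- matrix(0, nr, nc)
  lab <- matrix(0L, nr, nc)

  px <- rep((seq_len(nc) - 1) * ps, each = nr)   # x for every pixel (col-major)
  py <- rep((seq_len(nr) - 1) * ps, times = nc)  # y

  # tubules: occupancy 1 within diameter/2 of the skeleton
  if (nrow(layout$segments) > 0) {
    half <- layout$tubule_diameter_nm / 2
    d <- rep(Inf, nr * nc)
    for (i in seq_len(nrow(layout$segments))) {
      s <- layout$segments[i, ]
      # restrict to bounding box for speed
      bb <- c(min(s[1], s[3]) - half - ps, max(s[1], s[3]) + half + ps,
              min(s[2], s[4]) - half - ps, max(s[2], s[4]) + half + ps)
      sel <- which(px >= bb[1] & px <= bb[2] & py >= bb[3] & py <= bb[4])
      if (!length(sel)) next
      d[sel] <- pmin(d[sel],
                     dist_to_polyline(px[sel], py[sel],
                                      rbind(s[1:2], s[3:4])))
    }
    tub <- d <= half
    occ[tub] <- 1
    lab[tub] <- 1L
  }

  for (k in seq_along(layout$cisternae)) {
    cis <- layout$cisternae[[k]]
    inside <- rasterize_polygon(cis$region, c(nr, nc), pixel_size = ps)
    idx <- which(inside)
    if (!length(idx)) next
    o <- switch(
      cis$substructure,
      sac = rep(1, length(idx)),
      sac_nanoholes = {
        v <- rep(1, length(idx))
        if (nrow(cis$hole_centres) > 0) {
          for (h in seq_len(nrow(cis$hole_centres))) {
            hc <- cis$hole_centres[h, ]
            d2 <- (px[idx] - hc[1])^2 + (py[idx] - hc[2])^2
            v[d2 <= cis$params$hole_radius_nm^2] <- 0
          }
        }
        v
      },
      tubular_matrix = {
        p <- cis$params
        db <- dist_to_polygon_boundary(px[idx], py[idx], cis$region)
        u <- px[idx] * cos(p$orientation) + py[idx] * sin(p$orientation)
        phase <- u %% p$tubule_spacing_nm
        on_stripe <- phase < layout$tubule_diameter_nm
        v <- ifelse(on_stripe, 1, p$interior_ceiling)
        v[db <= p$edge_band_nm] <- 1
        v
      }
    )
    occ[idx] <- o
    lab[idx] <- k + 1L
  }
  list(occupancy = occ, label_map = lab)
}

#' Render an ER phantom to a noisy multi-channel image with ground truth
#'
#' Forward imaging model: per-channel emission maps are convolved with an
#' isotropic Gaussian PSF of the spec's FWHM, scaled by the photon budget,
#' Poisson-sampled, and corrupted by Gaussian read noise on top of a constant
#' background. Rendering never alters the ground truth geometry.
#'
#' Channels: `lumen` emits the lumen occupancy (a soluble lumenal marker);
#' `membrane` emits along structure outlines (a membrane marker);
#' `morphogen` emits either along cisterna edges (`morphogen_mode =
#' "edges"`, junction/edge-localised morphogen) or across the whole network
#' (`"whole"`).
#'
#' @param layout an `er_layout`
#' @param spec a [phantom_spec()]
#' @param channels subset of `c("lumen", "membrane", "morphogen")`
#' @param morphogen_mode `"edges"` or `"whole"`
#' @return list with `image` (a [multichannel_image()]) and `ground_truth`
#'   (fields `label_map`, `lumen_occupancy`, `true_params`, `warnings`)
#' @export
render_er_image <- function(layout, spec,
                            channels = c("lumen"),
                            morphogen_mode = c("edges", "whole")) {
  stopifnot(inherits(layout, "er_layout"), inherits(spec, "phantom_spec"))
  channels <- match.arg(channels, c("lumen", "membrane", "morphogen"),
                        several.ok = TRUE)
  morphogen_mode <- match.arg(morphogen_mode)
  if (spec$psf_fwhm_nm > 0 && spec$psf_fwhm_nm < spec$pixel_size_nm)
    erq_warn("PSF FWHM below the pixel size: the PSF is undersampled",
             "undersampled_psf")

  geo <- layout_occupancy(layout, spec)
  fg <- geo$occupancy > 0
  outline <- fg & !(EBImage::erode(fg + 0, disc_brush(1)) > 0)

  emission_for <- function(ch) {
    switch(ch,
      lumen = geo$occupancy,
      membrane = outline + 0,
      morphogen = {
        if (morphogen_mode == "whole") (fg + 0) else {
          m <- matrix(0, spec$image_shape[1], spec$image_shape[2])
          band <- max(spec$psf_fwhm_nm / 2, spec$pixel_size_nm)
          nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
          px <- rep((seq_len(nc) - 1) * spec$pixel_size_nm, each = nr)
          py <- rep((seq_len(nr) - 1) * spec$pixel_size_nm, times = nc)
          for (cis in layout$cisternae) {
            db <- dist_to_polygon_boundary(px, py, cis$region)
            m[db <= band] <- 1
          }
          m[geo$label_map == 1L] <- 1   # morphogen also decorates tubules
          m
        }
      })
  }

  imgs <- list()
  for (i in seq_along(channels)) {
    em <- emission_for(channels[i])
    blurred <- blur_fwhm(em, spec$psf_fwhm_nm, spec$pixel_size_nm)
    imgs[[channels[i]]] <- render_counts(blurred, spec, channel_index = i)
  }

  warnings <- Filter(Negate(is.null),
                     lapply(layout$cisternae, function(c) c$warning))
  list(
    image = multichannel_image(imgs, spec$pixel_size_nm,
                               meta = list(seed = spec$seed, spec = spec)),
    ground_truth = list(
      label_map = geo$label_map,
      lumen_occupancy = geo$occupancy,
      true_params = list(
        tubule_diameter_nm = layout$tubule_diameter_nm,
        n_junctions = nrow(layout$junctions),
        substructures = vapply(layout$cisternae, `[[`, "", "substructure")
      ),
      warnings = warnings
    )
  )
}

# detector model shared by all phantom renderers: expectation -> counts
render_counts <- function(expectation, spec, channel_index = 1L) {
  lam <- expectation * spec$photon_scale
  if (is.infinite(spec$photon_scale)) {
    # noiseless limit: report expected emission plus background
    return(expectation + spec$background_level)
  }
  with_seed(spec$seed + 1000L * channel_index, {
    n <- length(lam)
    counts <- stats::rpois(n, pmax(lam, 0))
    if (spec$read_noise_sd > 0)
      counts <- counts + stats::rnorm(n, 0, spec$read_noise_sd)
    matrix(counts + spec$background_level, nrow = nrow(lam))
  })
}
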