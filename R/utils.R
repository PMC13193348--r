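# Shared internal helpers: seeded evaluation, geometry primitives, conditions.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Signal a classed erquant error
#' @noRd
erq_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "erquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Signal a classed erquant warning
#' @noRd
erq_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "erquant_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Vectorised even-odd point-in-polygon test, boundary-inclusive.
#'
#' @param px,py point coordinates
#' @param poly two-column matrix of polygon vertices (closed implicitly)
#' @return logical vector
#' @noRd
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    # boundary test: point within eps of the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    } else {
      d2 <- (px - x1)^2 + (py - y1)^2
    }
    on_edge <- on_edge | d2 <= eps
    # even-odd ray crossing (ray towards +x)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1 + (y2 == y1)) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Rasterise a polygon onto a pixel grid (pixel-centre sampling)
#'
#' Pixel (r, c), 1-based in R, has its centre at 0-based coordinates
#' (x = c - 1, y = r - 1) in pixel units, or scaled by `pixel_size` for
#' physical coordinates. Returns a logical matrix.
#' @noRd
rasterize_polygon <- function(poly, dim, pixel_size = 1) {
  nr <- dim[1]; nc <- dim[2]
  poly <- as.matrix(poly)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  c0 <- max(1L, floor(xr[1] / pixel_size) + 1L)
  c1 <- min(nc, ceiling(xr[2] / pixel_size) + 1L)
  r0 <- max(1L, floor(yr[1] / pixel_size) + 1L)
  r1 <- min(nr, ceiling(yr[2] / pixel_size) + 1L)
  out <- matrix(FALSE, nr, nc)
  if (c0 > c1 || r0 > r1) return(out)
  cols <- c0:c1; rows <- r0:r1
  px <- rep((cols - 1) * pixel_size, each = length(rows))
  py <- rep((rows - 1) * pixel_size, times = length(cols))
  hit <- points_in_polygon(px, py, poly)
  out[rows, cols] <- hit
  out
}

#' Minimum distance from points to a polyline (set of joined segments)
#' @param px,py point coordinates; `line` a two-column matrix of vertices
#' @noRd
dist_to_polyline <- function(px, py, line) {
  line <- as.matrix(line)
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1)) {
    x1 <- line[i, 1]; y1 <- line[i, 2]
    x2 <- line[i + 1, 1]; y2 <- line[i + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Distance from points to a polygon boundary (closed)
#' @noRd
dist_to_polygon_boundary <- function(px, py, poly) {
  poly <- as.matrix(poly)
  dist_to_polyline(px, py, rbind(poly, poly[1, , drop = FALSE]))
}

#' Do two segments properly intersect (excluding shared endpoints)?
#' @noRd
segments_intersect <- function(a1, a2, b1, b2, eps = 1e-9) {
  orient <- function(p, q, r) {
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  }
  # treat near-touching endpoints as non-intersections
  for (p in list(a1, a2)) for (q in list(b1, b2)) {
    if (sum((p - q)^2) < eps) return(FALSE)
  }
  d1 <- orient(b1, b2, a1); d2 <- orient(b1, b2, a2)
  d3 <- orient(a1, a2, b1); d4 <- orient(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Regular polygon approximation of an ellipse
#'
#' Convenience for building cisterna regions and cell outlines.
#'
#' @param cx,cy centre coordinates
#' @param rx,ry semi-axes
#' @param n number of vertices
#' @param rotation rotation angle in radians
#' @return an `n` x 2 matrix of vertices
#' @export
ellipse_polygon <- function(cx, cy, rx, ry = rx, n = 64, rotation = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- rx * cos(th); y0 <- ry * sin(th)
  cbind(
    x = cx + x0 * cos(rotation) - y0 * sin(rotation),
    y = cy + x0 * sin(rotation) + y0 * cos(rotation)
  )
}

#' Gaussian blur with FWHM given in physical units
#' @noRd
blur_fwhm <- function(img, fwhm_nm, pixel_size_nm) {
  if (fwhm_nm <= 0) return(img)
  sigma_px <- fwhm_to_sigma(fwhm_nm) / pixel_size_nm
  ksize <- max(3L, 2L * as.integer(ceiling(4 * sigma_px)) + 1L)
  ax <- seq_len(ksize) - (ksize + 1) / 2
  g <- exp(-ax^2 / (2 * sigma_px^2))
  k <- outer(g, g); k <- k / sum(k)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

#' Grayscale opening with edge-replicated padding
#'
#' EBImage's grayscale morphology treats pixels beyond the border as zero,
#' which would drag the background estimate down near edges; replicating
#' the edge rows/columns before opening keeps a constant image exactly
#' constant.
#' @noRd
gray_opening_replicate <- function(img, radius_px) {
  r <- max(1L, as.integer(round(radius_px)))
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  padded <- img[ri, ci]
  # EBImage grayscale morphology clamps to [0, 1]: rescale around it
  m <- max(padded)
  if (m <= 0) return(matrix(0, nr, nc))
  opened <- m * as.matrix(EBImage::opening(padded / m, disc_brush(r)))
  opened[r + seq_len(nr), r + seq_len(nc)]
}

#' Flat disc structuring element of a given pixel radius
#' @noRd
disc_brush <- function(radius_px) {
  radius_px <- max(1L, as.integer(round(radius_px)))
  sz <- 2L * radius_px + 1L
  ax <- seq_len(sz) - radius_px - 1L
  k <- outer(ax, ax, function(a, b) sqrt(a^2 + b^2)) <= radius_px + 1e-9
  storage.mode(k) <- "integer"
  k
}

#' Map an adjusted p-value to the significance-star convention
#'
#' `***` for p <= 0.001, `**` for 0.001 < p <= 0.01, `*` for 0.01 < p <= 0.05,
#' `ns` otherwise.
#'
#' @param p numeric vector of p-values
#' @return character vector of stars
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
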