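# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no shared geometry helpers, plain loops) so that agreement is
# evidence, not tautology.

# Flood-fill hysteresis oracle: keep every low-threshold pixel reachable
# (8-connectivity) from a high-threshold pixel.
oracle_hysteresis <- function(image, low, high) {
  nr <- nrow(image); nc <- ncol(image)
  lowm <- image >= low
  visited <- matrix(FALSE, nr, nc)
  queue <- which(image >= high & lowm)
  visited[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (lowm[r2, c2] && !visited[r2, c2]) {
        visited[r2, c2] <- TRUE
        queue <- c(queue, (c2 - 1) * nr + r2)
      }
    }
  }
  visited
}

# Exhaustive ordered-pair GLCM census over a mask.
oracle_glcm <- function(image, mask, radius, n_levels, symmetric = TRUE) {
  idx <- which(mask, arr.ind = TRUE)
  v <- image[mask]
  rng <- range(v)
  lev <- if (diff(rng) > 0)
    pmin(floor(n_levels * (v - rng[1]) / diff(rng)), n_levels - 1)
  else rep(0, length(v))
  acc <- matrix(0, n_levels, n_levels)
  n <- nrow(idx)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    dr <- idx[b, 1] - idx[a, 1]; dc <- idx[b, 2] - idx[a, 2]
    d <- sqrt(dr^2 + dc^2)
    if (d > radius + 1e-9) next
    if (!symmetric && !(dc > 0 || (dc == 0 && dr > 0))) next
    acc[lev[a] + 1, lev[b] + 1] <- acc[lev[a] + 1, lev[b] + 1] + 1
  }
  acc / sum(acc)
}

# Per-pixel nearest-background Euclidean distance (radial-bin oracle).
oracle_distance_to_background <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    out[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  }
  out
}

# Scalar even-odd point-in-polygon (winding loop, boundary-inclusive).
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment check
    d <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi))
    len <- sqrt((xj - xi)^2 + (yj - yi)^2)
    if (len > 0 && d / len < 1e-9 &&
        x >= min(xi, xj) - 1e-9 && x <= max(xi, xj) + 1e-9 &&
        y >= min(yi, yj) - 1e-9 && y <= max(yi, yj) + 1e-9) return(TRUE)
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# Node-degree census of a segment set: endpoints matched by rounding.
segment_degree_census <- function(segments, digits = 6) {
  pts <- rbind(round(segments[, 1:2], digits), round(segments[, 3:4], digits))
  key <- paste(pts[, 1], pts[, 2])
  table(key)
}

# Small labelled segmentation built from disc masks, for threshold tests.
toy_segmentation <- function(n_cisternae, dim = c(60, 60), radius = 4) {
  lab <- matrix(0L, dim[1], dim[2])
  centres <- cbind(seq(10, dim[1] - 10, length.out = n_cisternae),
                   seq(10, dim[2] - 10, length.out = n_cisternae))
  for (i in seq_len(n_cisternae)) {
    for (r in 1:dim[1]) for (c in 1:dim[2]) {
      if ((r - centres[i, 1])^2 + (c - centres[i, 2])^2 <= radius^2)
        lab[r, c] <- i + 1L
    }
  }
  structure(list(label_map = lab,
                 cisterna_ids = seq_len(n_cisternae) + 1L,
                 cisterna_areas = tabulate(lab)[seq_len(n_cisternae) + 1L],
                 params = segmentation_params()),
            class = "er_segmentation")
}

# rotation helper for rigid-motion tests
rotate_points <- function(points, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(as.matrix(points) %*% t(R), 2, -shift)
}
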