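# Golgi cisterna morphometry from traced polylines: B-spline curvature and
# integrated shortest-distance width.

#' Fit a parametric spline curve through an ordered point trace
#'
#' Coordinates are fitted as cubic splines in a chord-length parameter.
#' With `smoothing = 0` (the default; traces are usually already
#' human-smoothed) the curve interpolates the points; positive `smoothing`
#' is passed as the penalty of [stats::smooth.spline()]. The returned curve
#' is evaluable with first and second derivatives.
#'
#' @param points n x 2 matrix of coordinates (nm); >= 4 distinct points
#' @param smoothing penalty (0 = interpolation)
#' @return object of class `spline_curve` with `eval(t, deriv)` over
#'   `t` in \[0, 1\]
#' @export
fit_bspline <- function(points, smoothing = 0) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 4)
    erq_stop("need at least 4 distinct points for a cubic spline fit",
             "too_few_points")
  d <- sqrt(rowSums(diff(points)^2))
  t <- c(0, cumsum(d)); t <- t / t[length(t)]     # chord-length parameter
  if (smoothing <= 0) {
    fx <- stats::splinefun(t, points[, 1], method = "fmm")
    fy <- stats::splinefun(t, points[, 2], method = "fmm")
    evalf <- function(tt, deriv = 0) {
      cbind(x = fx(tt, deriv = deriv), y = fy(tt, deriv = deriv))
    }
  } else {
    sx <- stats::smooth.spline(t, points[, 1], lambda = smoothing,
                               all.knots = TRUE)
    sy <- stats::smooth.spline(t, points[, 2], lambda = smoothing,
                               all.knots = TRUE)
    evalf <- function(tt, deriv = 0) {
      cbind(x = stats::predict(sx, tt, deriv = deriv)$y,
            y = stats::predict(sy, tt, deriv = deriv)$y)
    }
  }
  structure(list(eval = evalf, knots = t, points = points,
                 smoothing = smoothing), class = "spline_curve")
}

#' Mean absolute curvature of a fitted curve
#'
#' Signed curvature of a plane parametric curve,
#' \deqn{\kappa(t) = \frac{x' y'' - y' x''}{(x'^2 + y'^2)^{3/2}},}
#' is sampled at points uniformly spaced in arc length (so the average is a
#' geometric, not parameter-weighted, mean) and the mean of its absolute
#' value returned. A straight trace gives 0; a circular arc of radius R
#' gives 1/R.
#'
#' @param curve a `spline_curve`
#' @param n_samples number of arc-length samples
#' @return list with `mean_abs_curvature` (nm^-1), `arc_length` (nm),
#'   `curvature` (per-sample values)
#' @export
mean_curvature <- function(curve, n_samples = 200L) {
  stopifnot(inherits(curve, "spline_curve"))
  # dense parameter grid -> arc length -> uniform arc-length resample
  tt <- seq(0, 1, length.out = max(20L * n_samples, 1000L))
  d1 <- curve$eval(tt, deriv = 1)
  speed <- sqrt(rowSums(d1^2))
  s <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(tt)))
  total <- s[length(s)]
  su <- seq(0, total, length.out = n_samples)
  tu <- stats::approx(s, tt, xout = su, ties = "ordered")$y
  d1 <- curve$eval(tu, deriv = 1)
  d2 <- curve$eval(tu, deriv = 2)
  sp2 <- rowSums(d1^2)
  zero <- sp2 < .Machine$double.eps
  if (any(zero)) {
    erq_warn("zero-speed parameter points skipped in curvature average",
             "zero_speed")
  }
  k <- abs(d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / sp2^1.5
  k <- k[!zero]
  list(mean_abs_curvature = mean(k), arc_length = total, curvature = k)
}

polyline_length <- function(points) sum(sqrt(rowSums(diff(as.matrix(points))^2)))

# n points uniformly spaced in arc length along a polyline
resample_polyline <- function(points, n) {
  points <- as.matrix(points)
  d <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(d))
  su <- seq(0, s[length(s)], length.out = n)
  cbind(x = stats::approx(s, points[, 1], xout = su, ties = "ordered")$y,
        y = stats::approx(s, points[, 2], xout = su, ties = "ordered")$y)
}

#' Integrated-distance width profile between two edge polylines
#'
#' Samples `n_samples` points uniformly along the shorter polyline (by arc
#' length; the arguments are reordered automatically) and records the
#' shortest point-to-segment distance from each to the longer polyline.
#' The mean of these distances is the cisterna width and their max - min
#' the width range.
#'
#' @param line_a,line_b two-column point matrices (>= 2 points each)
#' @param n_samples number of samples along the shorter line
#' @return object of class `width_profile`: `distances`, `mean_width`,
#'   `width_range`
#' @export
integrated_distance <- function(line_a, line_b, n_samples = 100L) {
  a <- as.matrix(line_a); b <- as.matrix(line_b)
  stopifnot(nrow(a) >= 2, nrow(b) >= 2)
  la <- polyline_length(a); lb <- polyline_length(b)
  if (la == 0 || lb == 0)
    erq_stop("degenerate (zero-length) polyline", "degenerate_polyline")
  shorter <- if (la <= lb) a else b
  longer <- if (la <= lb) b else a
  pts <- resample_polyline(shorter, n_samples)
  d <- dist_to_polyline(pts[, 1], pts[, 2], longer)
  structure(list(distances = d,
                 mean_width = mean(d),
                 width_range = max(d) - min(d),
                 n_samples = as.integer(n_samples)),
            class = "width_profile")
}

#' Per-stack summary of Golgi cisterna width and curvature
#'
#' Groups traces by stack, pairs `edge_a`/`edge_b` traces per cisterna to
#' measure widths ([integrated_distance()]), fits a spline to every edge
#' trace with >= 4 points for curvature ([mean_curvature()]), and averages
#' within each stack. The per-stack rows are the replication unit for the
#' group statistics.
#'
#' @param traces list of [golgi_trace()] objects
#' @param n_samples samples per width profile
#' @return data frame with one row per stack: `stack_id`, `condition`,
#'   `n_cisternae`, `mean_width`, `mean_width_range`, `mean_curvature`
#' @export
stack_summary <- function(traces, n_samples = 100L) {
  if (!length(traces)) erq_stop("empty trace set", "empty_traces")
  stopifnot(all(vapply(traces, inherits, TRUE, "golgi_trace")))
  stacks <- vapply(traces, `[[`, "", "stack_id")
  rows <- lapply(unique(stacks), function(sid) {
    tr <- traces[stacks == sid]
    cond <- tr[[1]]$condition
    cis_idx <- vapply(tr, `[[`, 1L, "cisterna")
    widths <- c(); ranges <- c(); curvs <- c()
    for (ci in unique(cis_idx)) {
      sub <- tr[cis_idx == ci]
      roles <- vapply(sub, `[[`, "", "role")
      ea <- sub[roles == "edge_a"]; eb <- sub[roles == "edge_b"]
      if (length(ea) && length(eb)) {
        wp <- integrated_distance(ea[[1]]$points, eb[[1]]$points, n_samples)
        widths <- c(widths, wp$mean_width)
        ranges <- c(ranges, wp$width_range)
      }
      for (t in sub) {
        if (nrow(t$points) >= 4) {
          mc <- mean_curvature(fit_bspline(t$points))
          curvs <- c(curvs, mc$mean_abs_curvature)
        }
      }
    }
    data.frame(stack_id = sid, condition = cond,
               n_cisternae = length(unique(cis_idx)),
               mean_width = if (length(widths)) mean(widths) else NA_real_,
               mean_width_range = if (length(ranges)) mean(ranges) else NA_real_,
               mean_curvature = if (length(curvs)) mean(curvs) else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
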