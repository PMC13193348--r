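# Golgi stack phantoms: paired edge polylines around circular arcs with
# known curvature and width profile, for validating the trace morphometry.

#' Generate a synthetic Golgi stack with known curvature and width
#'
#' Each cisterna is modelled as a pair of edge polylines offset around a
#' circular arc (or a straight line for `arc_radius_nm = Inf`). The local
#' width is `base_width_nm` plus optional smooth swelling bumps, emulating
#' the irregular swellings seen along perturbed Golgi cisternae. True mean
#' centreline curvature is `1 / arc_radius_nm` by construction.
#'
#' @param arc_radius_nm radius of the centreline arc in nm, or `Inf` for a
#'   straight cisterna
#' @param n_cisternae number of stacked cisternae (>= 1)
#' @param base_width_nm baseline cisternal width (lumen thickness) in nm;
#'   the 27.2 nm default is a typical unperturbed width, with ~37.5 nm
#'   representing the swollen phenotype
#' @param swelling_amplitude_nm amplitude of width bumps (must be smaller
#'   than `base_width_nm`; 0 for constant width)
#' @param n_swellings number of bumps per cisterna
#' @param arc_length_nm trace length along the centreline
#' @param n_points points per polyline
#' @param stack_spacing_nm radial distance between adjacent cisternae
#' @param seed integer seed for bump placement
#' @param stack_id,condition labels propagated to the traces
#' @return an object of class `golgi_phantom`: list with `cisternae` (each
#'   holding `edge_a`, `edge_b`, `centerline` point matrices and per-cisterna
#'   truth), `traces` (flat list consumable by [stack_summary()]),
#'   `true_curvature` (1/R), `true_mean_width`, `true_width_range`
#' @export
make_golgi_phantom <- function(arc_radius_nm = Inf,
                               n_cisternae = 1L,
                               base_width_nm = 27.2,
                               swelling_amplitude_nm = 0,
                               n_swellings = 3L,
                               arc_length_nm = 1000,
                               n_points = 60L,
                               stack_spacing_nm = 80,
                               seed = 1L,
                               stack_id = "stack1",
                               condition = "phantom") {
  if (!(is.infinite(arc_radius_nm) || arc_radius_nm > 0))
    erq_stop("arc_radius_nm must be > 0 or Inf", "invalid_params")
  stopifnot(n_cisternae >= 1)
  if (swelling_amplitude_nm >= base_width_nm)
    erq_stop("swelling amplitude >= base width gives a self-intersecting cisterna",
             "invalid_params")

  s <- seq(0, arc_length_nm, length.out = n_points)   # arc-length parameter
  bumps <- with_seed(seed, {
    lapply(seq_len(n_cisternae), function(i) {
      if (swelling_amplitude_nm == 0 || n_swellings == 0)
        return(list(pos = numeric(0), width = numeric(0)))
      list(pos = stats::runif(n_swellings, 0.15, 0.85) * arc_length_nm,
           width = stats::runif(n_swellings, 0.05, 0.12) * arc_length_nm)
    })
  })

  cisternae <- list()
  traces <- list()
  for (i in seq_len(n_cisternae)) {
    w <- rep(base_width_nm, n_points)
    b <- bumps[[i]]
    for (k in seq_along(b$pos))
      w <- w + swelling_amplitude_nm * exp(-(s - b$pos[k])^2 / (2 * b$width[k]^2))
    off <- (i - 1) * stack_spacing_nm
    if (is.infinite(arc_radius_nm)) {
      centre <- cbind(x = s, y = rep(off, n_points))
      edge_a <- cbind(x = s, y = off + w / 2)
      edge_b <- cbind(x = s, y = off - w / 2)
    } else {
      R <- arc_radius_nm + off
      phi <- s / R - (arc_length_nm / R) / 2   # centred arc
      centre <- cbind(x = R * sin(phi), y = R * cos(phi) - arc_radius_nm)
      ra <- R + w / 2; rb <- R - w / 2
      edge_a <- cbind(x = ra * sin(phi), y = ra * cos(phi) - arc_radius_nm)
      edge_b <- cbind(x = rb * sin(phi), y = rb * cos(phi) - arc_radius_nm)
    }
    cis <- list(
      edge_a = edge_a, edge_b = edge_b, centerline = centre,
      true_width_profile = w,
      true_mean_width = mean(w),
      true_width_range = max(w) - min(w),
      true_curvature = if (is.infinite(arc_radius_nm)) 0
                       else 1 / (arc_radius_nm + off)
    )
    cisternae[[i]] <- cis
    traces <- c(traces, list(
      golgi_trace(edge_a, role = "edge_a", stack_id = stack_id,
                  cisterna = i, condition = condition),
      golgi_trace(edge_b, role = "edge_b", stack_id = stack_id,
                  cisterna = i, condition = condition)
    ))
  }

  structure(list(
    cisternae = cisternae,
    traces = traces,
    true_curvature = if (is.infinite(arc_radius_nm)) 0 else 1 / arc_radius_nm,
    true_mean_width = mean(vapply(cisternae, `[[`, 0, "true_mean_width")),
    true_width_range = mean(vapply(cisternae, `[[`, 0, "true_width_range")),
    arc_radius_nm = arc_radius_nm,
    base_width_nm = base_width_nm
  ), class = "golgi_phantom")
}

#' Construct a Golgi trace (ordered point list in nm)
#'
#' @param points n x 2 matrix of coordinates in nm (>= 2 rows; >= 4 for
#'   spline fitting); consecutive duplicate points are dropped
#' @param role `"centerline"`, `"edge_a"` or `"edge_b"`
#' @param stack_id identifier of the Golgi stack the trace belongs to
#' @param cisterna cisterna index within the stack
#' @param condition condition/genotype label
#' @return object of class `golgi_trace`
#' @export
golgi_trace <- function(points, role = "centerline", stack_id = "stack1",
                        cisterna = 1L, condition = NA_character_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2)
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
  points <- points[keep, , drop = FALSE]
  structure(list(points = points, role = role, stack_id = stack_id,
                 cisterna = as.integer(cisterna), condition = condition),
            class = "golgi_trace")
}
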