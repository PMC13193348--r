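# End-to-end orchestration: phantom generation -> segmentation -> texture
# metrics -> group statistics -> tidy outputs and a provenance manifest.

#' Default pipeline configuration
#'
#' Describes a phantom study: per-condition cisterna substructures, the
#' number of images per condition, imaging spec arguments, segmentation
#' and GLCM parameters. Any element can be overridden via `...` or by
#' supplying a YAML/JSON file to [run_pipeline()].
#'
#' @param ... named overrides of the defaults
#' @return a named list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    conditions = list(
      sac = list(substructure = "sac"),
      nanoholes = list(substructure = "sac_nanoholes",
                       hole_radius_nm = 120, hole_density_um2 = 6)
    ),
    n_images = 8L,
    n_cisternae = 6L,
    n_junctions = 3L,
    seed = 1L,
    spec = list(image_shape = c(192L, 192L), pixel_size_nm = 46,
                psf_fwhm_nm = 140, photon_scale = 500,
                read_noise_sd = 2, background_level = 10),
    segmentation = list(opening_radius_px = 4L, min_object_px = 20L,
                        hysteresis_low = 0.2, hysteresis_high = 0.5,
                        background_radius_px = 50L),
    glcm = list(radius = "auto", n_levels = 8L),
    n_bins = 10L,
    min_cisternae = 5L
  )
  utils::modifyList(cfg, list(...))
}

# place n_cis elliptical cisterna regions on a grid inside the field
place_cisterna_regions <- function(spec, n_cis, seed) {
  ext <- spec_extent_nm(spec)
  with_seed(seed, {
    ncol_g <- ceiling(sqrt(n_cis))
    nrow_g <- ceiling(n_cis / ncol_g)
    cellw <- ext[2] / ncol_g; cellh <- ext[1] / nrow_g
    regions <- list()
    for (i in seq_len(n_cis)) {
      gc <- (i - 1) %% ncol_g; gr <- (i - 1) %/% ncol_g
      cx <- (gc + 0.5) * cellw + stats::runif(1, -0.05, 0.05) * cellw
      cy <- (gr + 0.5) * cellh + stats::runif(1, -0.05, 0.05) * cellh
      rx <- stats::runif(1, 0.24, 0.32) * cellw
      ry <- stats::runif(1, 0.24, 0.32) * cellh
      regions[[i]] <- ellipse_polygon(cx, cy, rx, ry, n = 40,
                                      rotation = stats::runif(1, 0, pi))
    }
    regions
  })
}

#' Build one phantom image for a study condition
#'
#' @param condition_params list with `substructure` and its parameters
#' @param cfg a [pipeline_config()]
#' @param seed image-specific seed
#' @return the [render_er_image()] result
#' @export
phantom_for_condition <- function(condition_params, cfg = pipeline_config(),
                                  seed = 1L) {
  spec <- do.call(phantom_spec, c(cfg$spec, list(seed = seed)))
  layout <- make_tubule_network(spec, n_junctions = cfg$n_junctions)
  regions <- place_cisterna_regions(spec, cfg$n_cisternae, seed + 7L)
  sub <- condition_params$substructure
  params <- condition_params[setdiff(names(condition_params), "substructure")]
  for (k in seq_along(regions)) {
    params$seed <- seed + 1000L + k
    layout <- add_cisterna(layout, regions[[k]], substructure = sub,
                           params = params)
  }
  render_er_image(layout, spec, channels = "lumen")
}

#' Segment a phantom image and compute pooled texture properties
#'
#' Runs [preprocess()], [segment_er()], [identify_cisternae()],
#' [estimate_tubule_radius()] (when `radius = "auto"`), the per-cisterna
#' GLCM, and [pool_properties()].
#'
#' @param image single-channel matrix (lumenal marker)
#' @param cfg a [pipeline_config()]
#' @param image_id,condition labels for the output rows
#' @return list with `segmentation`, `per_cisterna`, `pooled` (or an
#'   `insufficient_cisternae` condition propagated)
#' @export
analyse_er_image <- function(image, cfg = pipeline_config(),
                             image_id = "image", condition = NA) {
  params <- do.call(segmentation_params, cfg$segmentation)
  pre <- preprocess(image, params)
  mask <- segment_er(pre, params)
  seg <- identify_cisternae(mask, pre, params)
  ps_eff <- cfg$spec$pixel_size_nm / params$upsample_factor
  radius_px <- if (identical(cfg$glcm$radius, "auto")) {
    if (length(seg$cisterna_ids) > 0 && any(seg$label_map == 1L)) {
      est <- estimate_tubule_radius(pre, seg,
                                    psf_fwhm_nm = cfg$spec$psf_fwhm_nm,
                                    pixel_size_nm = ps_eff)
      max(1, est$radius_px)
    } else 2
  } else cfg$glcm$radius
  gspec <- glcm_spec(neighbourhood_radius_px = radius_px,
                     n_levels = cfg$glcm$n_levels)
  per <- cisterna_texture_table(pre, seg, gspec,
                                image_id = image_id, condition = condition)
  pooled <- pool_properties(per, min_cisternae = cfg$min_cisternae)
  list(segmentation = seg, per_cisterna = per, pooled = pooled,
       glcm_radius_px = radius_px)
}

#' Run the full phantom study pipeline
#'
#' Generates `n_images` phantoms per condition, analyses each
#' (segmentation, per-cisterna GLCM, pixel-weighted pooling), assembles the
#' pooled properties into a [group_table()], applies [compare_texture()],
#' and writes tidy CSVs plus a JSON provenance manifest to `out_dir`.
#' Deterministic for a fixed config: image seeds are derived from
#' `cfg$seed`.
#'
#' @param cfg a [pipeline_config()], or a path to a YAML/JSON file of
#'   overrides
#' @param out_dir output directory (created; `NULL` skips file output)
#' @return object of class `pipeline_result`: `pooled` (per-image rows),
#'   `per_cisterna`, `report` (the texture [compare_texture()] output),
#'   `manifest`
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  if (is.character(cfg)) {
    ov <- if (grepl("\\.ya?ml$", cfg)) yaml::read_yaml(cfg)
          else jsonlite::read_json(cfg, simplifyVector = TRUE)
    cfg <- utils::modifyList(pipeline_config(), ov)
  }
  validate_pipeline_config(cfg)

  pooled_rows <- list(); per_rows <- list()
  for (ci in seq_along(cfg$conditions)) {
    cname <- names(cfg$conditions)[ci]
    for (k in seq_len(cfg$n_images)) {
      seed <- cfg$seed + 10000L * ci + k
      ph <- phantom_for_condition(cfg$conditions[[ci]], cfg, seed = seed)
      res <- analyse_er_image(ph$image$channels$lumen, cfg,
                              image_id = sprintf("%s_%02d", cname, k),
                              condition = cname)
      pooled_rows <- c(pooled_rows, list(res$pooled))
      per_rows <- c(per_rows, list(res$per_cisterna))
    }
  }
  pooled <- do.call(rbind, pooled_rows)
  per_cisterna <- do.call(rbind, per_rows)

  metrics <- c("contrast", "correlation", "energy", "homogeneity")
  long <- do.call(rbind, lapply(metrics, function(m) {
    group_table(condition = pooled$condition, value = pooled[[m]],
                metric_name = m, technical_replicate = pooled$image_id)
  }))
  class(long) <- c("group_table", "data.frame")
  report <- compare_texture(long, metrics)

  manifest <- list(
    package_version = as.character(utils::packageVersion("erquant")),
    seed = cfg$seed,
    n_images = cfg$n_images,
    conditions = names(cfg$conditions),
    spec = cfg$spec,
    segmentation = cfg$segmentation,
    glcm = cfg$glcm,
    manova_tests = c("Pillai", "Roy"),
    posthoc = "Tukey HSD",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pooled, file.path(out_dir, "pooled_properties.csv"),
                     row.names = FALSE)
    utils::write.csv(per_cisterna,
                     file.path(out_dir, "per_cisterna_properties.csv"),
                     row.names = FALSE)
    utils::write.csv(report$posthoc, file.path(out_dir, "posthoc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    summary_lines <- c(
      "# Phantom study summary", "",
      sprintf("Conditions: %s", paste(names(cfg$conditions), collapse = ", ")),
      sprintf("Images per condition: %d", cfg$n_images), "",
      "MANOVA omnibus:",
      utils::capture.output(print(report$manova, row.names = FALSE)), "",
      "Per-metric ANOVA (Bonferroni):",
      utils::capture.output(print(report$anova, row.names = FALSE)), "",
      "Tukey HSD post-hoc:",
      utils::capture.output(print(report$posthoc, row.names = FALSE))
    )
    writeLines(summary_lines, file.path(out_dir, "summary.md"))
  }

  structure(list(pooled = pooled, per_cisterna = per_cisterna,
                 report = report, manifest = manifest),
            class = "pipeline_result")
}

validate_pipeline_config <- function(cfg) {
  required <- c("conditions", "n_images", "n_cisternae", "n_junctions",
                "seed", "spec", "segmentation", "glcm", "min_cisternae")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    erq_stop(paste("config is missing fields:",
                   paste(missing, collapse = ", ")), "invalid_config")
  if (length(cfg$conditions) < 2)
    erq_stop("config needs >= 2 conditions", "invalid_config")
  for (cn in names(cfg$conditions)) {
    if (is.null(cfg$conditions[[cn]]$substructure))
      erq_stop(sprintf("condition '%s' lacks a substructure", cn),
               "invalid_config")
  }
  invisible(TRUE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d images, conditions: %s\n",
              nrow(x$pooled), paste(unique(x$pooled$condition),
                                    collapse = ", ")))
  print(x$report)
  invisible(x)
}
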