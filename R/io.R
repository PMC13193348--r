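# Readers and writers for the package's external interfaces: multi-page
# TIFF images with JSON sidecars, label maps, ROI/polyline JSON, tidy CSVs.

#' Write a multi-channel image as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per channel (32-bit float); the sidecar records pixel
#' size, channel names and any metadata (seed, spec).
#'
#' @param img a [multichannel_image()]
#' @param path output TIFF path (`.json` sidecar written alongside)
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "multichannel_image"))
  pages <- lapply(img$channels, function(ch) {
    m <- as.matrix(ch)
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    pixel_size_nm = img$pixel_size_nm,
    channels = names(img$channels),
    meta = img$meta[setdiff(names(img$meta), "spec")],
    spec = if (!is.null(img$meta$spec)) unclass(img$meta$spec) else NULL
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-channel image written by [write_image()]
#'
#' @param path TIFF path with a `.json` sidecar alongside
#' @return a [multichannel_image()]
#' @export
read_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  names(pages) <- side$channels
  multichannel_image(pages, side$pixel_size_nm, meta = as.list(side$meta))
}

#' Write a segmentation label map as 16-bit TIFF plus per-cisterna CSV
#'
#' @param segmentation an `er_segmentation`
#' @param path base path (writes `<path>.tif`, `<path>_cisternae.csv`,
#'   `<path>_provenance.json`)
#' @param pixel_size_nm pixel size recorded with the areas
#' @return `path`, invisibly
#' @export
write_segmentation <- function(segmentation, path, pixel_size_nm = 46) {
  stopifnot(inherits(segmentation, "er_segmentation"))
  lab <- segmentation$label_map / 65535
  tiff::writeTIFF(lab, paste0(path, ".tif"), bits.per.sample = 16L)
  ids <- segmentation$cisterna_ids
  df <- data.frame(
    cisterna_id = ids,
    area_px = segmentation$cisterna_areas,
    area_um2 = segmentation$cisterna_areas * (pixel_size_nm / 1000)^2
  )
  cents <- lapply(ids, function(id) {
    w <- which(segmentation$label_map == id, arr.ind = TRUE)
    colMeans(w) - 1      # 0-based pixel coordinates
  })
  df$centroid_row <- vapply(cents, `[`, 0, 1)
  df$centroid_col <- vapply(cents, `[`, 0, 2)
  utils::write.csv(df, paste0(path, "_cisternae.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(segmentation$params),
                       paste0(path, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write/read ROI polygon sets as JSON
#'
#' Polygons are stored as named lists of vertex arrays in pixel
#' coordinates, with the pixel size so nm coordinates can be recovered.
#'
#' @param rois an [roi_set()]
#' @param path output JSON path
#' @param pixel_size_nm pixel size recorded in the file
#' @return `path`, invisibly
#' @export
write_rois <- function(rois, path, pixel_size_nm = 46) {
  stopifnot(inherits(rois, "roi_set"))
  ser <- function(p) list(x = p[, 1], y = p[, 2])
  obj <- list(
    pixel_size_nm = pixel_size_nm,
    golgi = lapply(rois$golgi, ser),
    er = lapply(rois$er, ser),
    background = ser(rois$background),
    cell_boundary = if (is.null(rois$cell_boundary)) NULL
                    else ser(rois$cell_boundary)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(p) cbind(x = as.numeric(unlist(p$x)),
                          y = as.numeric(unlist(p$y)))
  roi_set(golgi = lapply(obj$golgi, de),
          er = lapply(obj$er, de),
          background = de(obj$background),
          cell_boundary = if (is.null(obj$cell_boundary)) NULL
                          else de(obj$cell_boundary))
}

#' Write/read Golgi traces as JSON point lists
#'
#' @param traces list of [golgi_trace()] objects
#' @param path output JSON path
#' @return `path` (write) or list of traces (read)
#' @export
write_traces <- function(traces, path) {
  obj <- lapply(traces, function(t) list(
    x = t$points[, 1], y = t$points[, 2], role = t$role,
    stack_id = t$stack_id, cisterna = t$cisterna, condition = t$condition))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(t) {
    golgi_trace(cbind(as.numeric(unlist(t$x)), as.numeric(unlist(t$y))),
                role = t$role, stack_id = t$stack_id,
                cisterna = t$cisterna, condition = t$condition)
  })
}
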