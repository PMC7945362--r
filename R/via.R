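## VGG Image Annotator (VIA) 2.x polygon JSON import/export, measurement CSV
## and overlay rendering.
##
## Both VIA dialects are accepted: the exported annotation JSON (a dict keyed
## by "<filename><filesize>") and the full project file (the same dict under
## "_via_img_metadata"). Only polygon regions are converted; regions with
## fewer than three vertices are skipped with a warning.

#' Read VIA polygon annotations
#'
#' @param path Path to a VIA 2.x JSON file (exported annotations or project
#'   file).
#' @param grid_size Integer `(h, w)` of the annotated images, either a single
#'   vector applied to all images or a named list keyed by filename. When
#'   `NULL`, each image's grid is inferred as the smallest grid containing
#'   all its vertices (VIA files do not store image dimensions).
#' @return Named list: for each image filename, a list of [instance_mask]
#'   objects.
#' @export
read_via <- function(path, grid_size = NULL) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("cannot parse VIA JSON '", path, "': ", conditionMessage(e)))
  )
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  out <- list()
  for (entry in doc) {
    if (is.null(entry$filename)) next
    fname <- entry$filename
    regions <- entry$regions %||% list()
    polys <- list()
    for (reg in regions) {
      sa <- reg$shape_attributes
      if (is.null(sa) || !identical(sa$name, "polygon")) {
        warn(paste0("skipping non-polygon region in '", fname, "'"))
        next
      }
      xs <- unlist(sa$all_points_x); ys <- unlist(sa$all_points_y)
      if (length(xs) != length(ys) || length(xs) < 3L) {
        warn(paste0("skipping degenerate region (<3 vertices) in '", fname, "'"))
        next
      }
      polys[[length(polys) + 1L]] <- cbind(x = xs, y = ys)
    }
    gs <- via_grid_for(fname, grid_size, polys)
    out[[fname]] <- lapply(polys, mask_from_polygon, grid_size = gs)
  }
  out
}

via_grid_for <- function(fname, grid_size, polys) {
  if (is.list(grid_size)) {
    gs <- grid_size[[fname]]
    if (is.null(gs)) abort(paste0("no grid_size given for image '", fname, "'"))
    return(as.integer(gs))
  }
  if (!is.null(grid_size)) return(as.integer(grid_size))
  if (!length(polys)) return(c(1L, 1L))
  all_v <- do.call(rbind, polys)
  c(as.integer(ceiling(max(all_v[, 2])) + 2L), as.integer(ceiling(max(all_v[, 1])) + 2L))
}

#' Write VIA polygon annotations
#'
#' Emits the VIA 2.x exported-annotation dialect. Vertex sequences of the
#' masks' polygons are preserved exactly (rounded to the nearest integer
#' only if `integer_vertices = TRUE`, the convention of hand-made VIA
#' annotations).
#'
#' @param annotations Named list: filename -> list of [instance_mask].
#' @param path Output JSON path.
#' @param integer_vertices Round vertices to integers.
#' @return `path`, invisibly.
#' @export
write_via <- function(annotations, path, integer_vertices = FALSE) {
  doc <- list()
  for (fname in names(annotations)) {
    regions <- lapply(annotations[[fname]], function(m) {
      xs <- m$polygon[, 1]; ys <- m$polygon[, 2]
      if (integer_vertices) {
        xs <- round(xs); ys <- round(ys)
      }
      list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = as.list(xs),
          all_points_y = as.list(ys)
        ),
        region_attributes = setNames(list(), character())
      )
    })
    doc[[paste0(fname, "-1")]] <- list(
      filename = fname, size = -1,
      regions = regions,
      file_attributes = setNames(list(), character())
    )
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write a measurement CSV
#'
#' One row per stoma with the schema of [measure_detections()]. A zero-row
#' input yields a valid header-only CSV.
#'
#' @param records Measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  cols <- c(
    "image_id", "instance_id", "confidence", "area_px", "centroid_x",
    "centroid_y", "orientation_deg", "major_axis_px", "minor_axis_px",
    "eccentricity", "perimeter_px", "kept_by_filter"
  )
  if (nrow(records) == 0 && !all(cols %in% names(records))) {
    records <- as_tibble(setNames(
      lapply(cols, function(x) logical(0)), cols
    ))
  }
  keep <- c(intersect(cols, names(records)), setdiff(names(records), cols))
  write.csv(records[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Render a prediction / ground-truth overlay
#'
#' Draws instance boundaries (never boxes) onto the image: predictions in
#' yellow, ground truth (when given) in cyan.
#'
#' @param img A [stoma_image].
#' @param detections A [detection_set] with masks.
#' @param gt Optional list of ground-truth [instance_mask] objects.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, detections, gt = NULL, path) {
  stopifnot(is_stoma_image(img))
  ebi <- to_ebimage(img)
  pred_masks <- Filter(Negate(is.null), detections$mask)
  if (length(pred_masks)) {
    ebi <- EBImage::paintObjects(label_image(pred_masks), ebi, col = c("yellow", NA))
  }
  if (!is.null(gt) && length(gt)) {
    ebi <- EBImage::paintObjects(label_image(gt), ebi, col = c("cyan", NA))
  }
  EBImage::writeImage(ebi, path)
  invisible(path)
}

label_image <- function(masks) {
  d <- dim(masks[[1]]$raster)
  lab <- matrix(0L, d[1], d[2])
  for (i in seq_along(masks)) lab[masks[[i]]$raster] <- i
  EBImage::Image(t(lab))
}
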