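## Per-stoma morphometry from boundary masks.
##
## Shape descriptors come from the raster's second central moments: the
## moment-equivalent ellipse (the ellipse with the same second moments as the
## pixel set) yields major/minor axis lengths, orientation and eccentricity.
## Orientation is the angle of the major axis in image coordinates
## (x rightwards, y downwards), measured from +x towards +y, reported in
## degrees in [-90, 90).

#' Measure one stoma instance
#'
#' @param mask An [instance_mask] with at least one pixel.
#' @param pixel_size Optional physical pixel size in micrometres per pixel;
#'   when given, `area_units` (square micrometres) and physical axis lengths
#'   are added.
#' @return A one-row tibble: `area_px`, `centroid_x`, `centroid_y`,
#'   `orientation_deg`, `major_axis_px`, `minor_axis_px`, `eccentricity`,
#'   `perimeter_px`, bbox columns, and `area_um2`, `major_axis_um`,
#'   `minor_axis_um` when `pixel_size` is supplied.
#' @export
measure_instance <- function(mask, pixel_size = NULL) {
  stopifnot(is_instance_mask(mask))
  idx <- which(mask$raster, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) abort("cannot measure an empty mask")
  x <- idx[, "col"] - 1; y <- idx[, "row"] - 1
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2); mu11 <- mean((x - cx) * (y - cy))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l_max <- (mu20 + mu02) / 2 + common
  l_min <- (mu20 + mu02) / 2 - common
  major <- 4 * sqrt(max(l_max, 0))
  minor <- 4 * sqrt(max(l_min, 0))
  theta <- if (common < 1e-12) 0 else 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  theta <- ((theta + 90) %% 180) - 90
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
  out <- tibble(
    area_px = n,
    centroid_x = cx, centroid_y = cy,
    orientation_deg = theta,
    major_axis_px = major, minor_axis_px = minor,
    eccentricity = ecc,
    perimeter_px = polygon_perimeter(mask$polygon),
    bbox_xmin = mask$bbox[["xmin"]], bbox_ymin = mask$bbox[["ymin"]],
    bbox_xmax = mask$bbox[["xmax"]], bbox_ymax = mask$bbox[["ymax"]]
  )
  if (!is.null(pixel_size)) {
    out$area_um2 <- n * pixel_size^2
    out$major_axis_um <- major * pixel_size
    out$minor_axis_um <- minor * pixel_size
  }
  out
}

#' Measure every detection in a set
#'
#' @param ds A [detection_set] whose `mask` column holds instance masks.
#' @param pixel_size Optional micrometres per pixel.
#' @param kept Logical vector marking detections retained by the statistical
#'   filter. Defaults to the set's own filter trace when one is attached
#'   (useful when measuring the unfiltered set for audit), else all `TRUE`.
#' @return A tibble with one row per detection: `image_id`, `instance_id`,
#'   `confidence`, the [measure_instance()] columns, and `kept_by_filter`.
#' @export
measure_detections <- function(ds, pixel_size = NULL, kept = NULL) {
  stopifnot(is_detection_set(ds))
  if (is.null(kept)) {
    trace <- filter_trace(ds)
    kept <- if (!is.null(trace) && nrow(ds) == trace$n_input) {
      seq_len(nrow(ds)) %in% trace$accepted
    } else {
      rep(TRUE, nrow(ds))
    }
  }
  rows <- purrr::map(ds$mask, function(m) {
    if (is.null(m)) abort("detection has no mask; morphometry needs instance masks")
    measure_instance(m, pixel_size)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(
    tibble(
      image_id = image_ref(ds),
      instance_id = ds$instance_id,
      confidence = ds$confidence,
      kept_by_filter = kept
    ),
    out
  )
}

#' Summarise the stomata of one image
#'
#' @param records Measurement tibble from [measure_detections()] (or
#'   [measure_instance()] rows bound together).
#' @param image_dims Integer `(h, w)` of the measured image.
#' @param pixel_size Optional micrometres per pixel for density per mm2.
#' @return One-row tibble: `stomata_count`, `mean_area_px`, `area_sd_px`,
#'   `density_per_px2` and, when `pixel_size` is given, `density_per_mm2`.
#'   Means are `NA` for empty input.
#' @export
summarize_image <- function(records, image_dims, pixel_size = NULL) {
  n <- if (is.null(records)) 0L else nrow(records)
  px_area <- prod(as.numeric(image_dims))
  out <- tibble(
    stomata_count = n,
    mean_area_px = if (n > 0) mean(records$area_px) else NA_real_,
    area_sd_px = if (n > 1) stats::sd(records$area_px) else NA_real_,
    density_per_px2 = n / px_area
  )
  if (!is.null(pixel_size)) {
    ## one mm2 covers (1000 / pixel_size)^2 pixels
    out$density_per_mm2 <- n / (px_area * pixel_size^2 / 1e6)
  }
  out
}
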