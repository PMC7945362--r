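## Detection sets.
##
## A detection set is a tibble with one row per predicted stoma:
##   instance_id  stable integer id (1..n in detector output order)
##   confidence   detector confidence in [0, 1]
##   area_px      pixel count of the instance mask at working scale
##   mask         list-column of instance_mask (may be NULL for abstract
##                detection samples used to exercise the statistical filter)
## plus attributes `image_ref` (identifier) and `working_scale` (ratio of the
## working grid to the original image). Extra columns (e.g. the `is_true`
## labels attached by the synthetic generators) ride along untouched.

#' Build a detection set
#'
#' @param masks List of [instance_mask] objects on a common grid, or `NULL`
#'   for abstract detections (then `area_px` must be given).
#' @param confidence Numeric vector of per-detection confidences in \[0, 1\].
#' @param area_px Pixel areas; defaults to the mask raster counts.
#' @param image_ref Identifier of the source image.
#' @param working_scale Ratio working-size / original-size.
#' @param ... Extra per-detection columns (recycled by [tibble::tibble()]).
#' @return A tibble of class `detection_set`.
#' @export
detection_set <- function(masks = NULL, confidence = numeric(), area_px = NULL,
                          image_ref = NA_character_, working_scale = 1, ...) {
  if (!is.null(masks)) {
    stopifnot(all(vapply(masks, is_instance_mask, logical(1))))
    if (length(masks) > 1L) {
      dims <- vapply(masks, function(m) dim(m$raster), integer(2))
      if (any(dims != dims[, 1])) abort("all masks in a detection set must share one grid")
    }
    if (is.null(area_px)) area_px <- vapply(masks, mask_area, numeric(1))
  } else {
    masks <- rep(list(NULL), length(confidence))
    if (is.null(area_px)) abort("`area_px` is required when no masks are given")
  }
  if (any(confidence < 0 | confidence > 1)) abort("confidences must lie in [0, 1]")
  if (length(area_px) && any(area_px < 1)) abort("detection areas must be >= 1 px")
  out <- tibble(
    instance_id = seq_along(confidence),
    confidence = as.numeric(confidence),
    area_px = as.numeric(area_px),
    mask = masks,
    ...
  )
  as_detection_set(out, image_ref = image_ref, working_scale = working_scale)
}

as_detection_set <- function(df, image_ref = NA_character_, working_scale = 1) {
  structure(
    df,
    image_ref = image_ref,
    working_scale = working_scale,
    class = unique(c("detection_set", class(as_tibble(df))))
  )
}

#' @rdname detection_set
#' @export
is_detection_set <- function(x) inherits(x, "detection_set")

#' @rdname detection_set
#' @export
image_ref <- function(x) attr(x, "image_ref") %||% NA_character_

## Canonical detector output order: descending confidence, ties broken by
## descending area, then raster-scan order of the mask centroid.
sort_detections <- function(ds) {
  if (nrow(ds) < 2L) return(ds)
  cent <- vapply(ds$mask, function(m) {
    if (is.null(m)) return(0)
    idx <- which(m$raster, arr.ind = TRUE)
    mean(idx[, "row"] - 1) * ncol(m$raster) + mean(idx[, "col"] - 1)
  }, numeric(1))
  ord <- order(-ds$confidence, -ds$area_px, cent)
  out <- ds[ord, ]
  out$instance_id <- seq_len(nrow(out))
  as_detection_set(out, image_ref(ds), attr(ds, "working_scale") %||% 1)
}
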