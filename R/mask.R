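## Instance masks and mask arithmetic.
##
## Coordinate convention: 0-based pixel coordinates, pixel (row r, col c)
## centred at (x, y) = (c, r) and occupying the unit square
## [c - 0.5, c + 0.5] x [r - 0.5, r + 0.5]. Polygons are matrices with columns
## (x, y), matching the VGG Image Annotator vertex order. Rasterisation uses
## centre-of-pixel inclusion with a half-open tie rule (a centre exactly on a
## left band edge is inside, on a right band edge outside), which makes the
## even-odd fill deterministic for axis-aligned polygon edges.

normalise_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L) abort("polygon must have two columns (x, y)")
  n <- nrow(polygon)
  if (n >= 2L && all(polygon[1, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3L) abort("polygon must have at least 3 distinct vertices")
  colnames(polygon) <- c("x", "y")
  polygon
}

## Signed area via the shoelace formula (positive for counter-clockwise in
## (x, y) with y increasing downwards).
polygon_area_signed <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname polygon_to_raster
#' @export
polygon_area <- function(polygon) abs(polygon_area_signed(normalise_polygon(polygon)))

polygon_perimeter <- function(polygon) {
  p2 <- rbind(polygon, polygon[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(p2)^2)))
}

## O(n^2) proper-crossing test; shared endpoints are not intersections.
polygon_self_intersects <- function(polygon) {
  n <- nrow(polygon)
  if (n < 4L) return(FALSE)
  p <- polygon
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)] # adjacent via wrap-around
    if (!length(js)) next
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    d3 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], rep(p[i, 1], length(js)), rep(p[i, 2], length(js)))
    d4 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], rep(q[i, 1], length(js)), rep(q[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Convert between polygon and raster mask representations
#'
#' `polygon_to_raster()` fills a simple polygon onto a pixel grid using
#' even-odd centre-of-pixel inclusion. `raster_to_polygon()` traces the
#' boundary of a single connected pixel region; the returned polygon
#' rasterises back to the identical raster (the trace runs between inside and
#' outside pixel centres). A single-pixel mask is exported as that pixel's
#' unit square.
#'
#' @param polygon Matrix with columns (x, y) of polygon vertices in 0-based
#'   pixel coordinates (closed or open ring).
#' @param grid_size Integer `(h, w)` raster dimensions.
#' @param raster Logical matrix; must contain one connected true region.
#' @return `polygon_to_raster()`: a logical `h x w` matrix.
#'   `raster_to_polygon()`: a vertex matrix with columns (x, y).
#'   `polygon_area()`: the shoelace area of the ring.
#' @export
polygon_to_raster <- function(polygon, grid_size) {
  polygon <- normalise_polygon(polygon)
  if (polygon_self_intersects(polygon)) abort("polygon is self-intersecting")
  h <- as.integer(grid_size[1]); w <- as.integer(grid_size[2])
  out <- matrix(FALSE, h, w)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  r0 <- max(0L, ceiling(min(y1))); r1 <- min(h - 1L, floor(max(y1)))
  if (r0 > r1) return(out)
  for (r in r0:r1) {
    crosses <- (y1 <= r) != (y2 <= r)
    if (!any(crosses)) next
    xs <- sort(x1[crosses] + (r - y1[crosses]) * (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      lo <- ceiling(xs[k]); hi <- ceiling(xs[k + 1L]) - 1L
      lo <- max(lo, 0L); hi <- min(hi, w - 1L)
      if (lo <= hi) out[r + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  out
}

#' @rdname polygon_to_raster
#' @export
raster_to_polygon <- function(raster) {
  stopifnot(is.logical(raster), is.matrix(raster))
  n_on <- sum(raster)
  if (n_on == 0L) abort("empty raster has no boundary polygon")
  if (n_on == 1L) {
    idx <- which(raster, arr.ind = TRUE)[1, ]
    x <- idx[["col"]] - 1; y <- idx[["row"]] - 1
    return(cbind(
      x = c(x - 0.5, x + 0.5, x + 0.5, x - 0.5),
      y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
    ))
  }
  ## Fill interior holes first: masks here are simply connected by contract.
  filled <- fill_holes(raster)
  h <- nrow(filled); w <- ncol(filled)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- filled
  cl <- grDevices::contourLines(x = seq(-1, w) , y = seq(-1, h), z = t(pad), levels = 0.5)
  if (!length(cl)) abort("contour tracing failed")
  areas <- vapply(cl, function(co) abs(polygon_area_signed(cbind(co$x, co$y))), numeric(1))
  co <- cl[[which.max(areas)]]
  poly <- cbind(x = co$x, y = co$y)
  normalise_polygon(poly)
}

fill_holes <- function(raster) {
  ebi <- EBImage::fillHull(EBImage::Image(t(raster * 1)))
  t(EBImage::imageData(ebi)) > 0.5
}

raster_bbox <- function(raster) {
  idx <- which(raster, arr.ind = TRUE)
  c(
    xmin = min(idx[, "col"]) - 1L, ymin = min(idx[, "row"]) - 1L,
    xmax = max(idx[, "col"]) - 1L, ymax = max(idx[, "row"]) - 1L
  )
}

#' Instance masks
#'
#' An `instance_mask` holds the three linked representations of one stoma
#' boundary: the vertex polygon, the boolean raster aligned to its image, and
#' the tight axis-aligned bounding box of the raster.
#'
#' `mask_from_polygon()` rasterises a VIA-style polygon onto the image grid;
#' `mask_from_raster()` traces the boundary polygon of a pixel region.
#'
#' @param polygon Vertex matrix with columns (x, y), 0-based pixel coords.
#' @param grid_size Integer `(h, w)` of the owning image.
#' @param raster Logical matrix with a single connected true region.
#' @return An object of class `instance_mask` with elements `polygon`,
#'   `raster` and `bbox` (`xmin`, `ymin`, `xmax`, `ymax`, 0-based inclusive).
#' @export
mask_from_polygon <- function(polygon, grid_size) {
  polygon <- normalise_polygon(polygon)
  raster <- polygon_to_raster(polygon, grid_size)
  if (!any(raster)) abort("polygon rasterises to an empty mask on this grid")
  new_instance_mask(polygon, raster)
}

#' @rdname mask_from_polygon
#' @export
mask_from_raster <- function(raster) {
  new_instance_mask(raster_to_polygon(raster), raster)
}

new_instance_mask <- function(polygon, raster) {
  structure(
    list(polygon = polygon, raster = raster, bbox = raster_bbox(raster)),
    class = "instance_mask"
  )
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf(
    "<instance_mask> %d px on %d x %d grid, bbox [%d, %d] - [%d, %d]\n",
    mask_area(x), ncol(x$raster), nrow(x$raster),
    x$bbox["xmin"], x$bbox["ymin"], x$bbox["xmax"], x$bbox["ymax"]
  ))
  invisible(x)
}

#' @rdname mask_from_polygon
#' @export
is_instance_mask <- function(x) inherits(x, "instance_mask")

#' @rdname mask_from_polygon
#' @export
mask_area <- function(mask) sum(mask$raster)

check_same_grid <- function(a, b) {
  if (!identical(dim(a$raster), dim(b$raster))) {
    abort("masks lie on different grids; align them to one image before comparing")
  }
}

#' Intersection-over-union of two instance masks
#'
#' `mask_iou()` compares the pixel sets; `bbox_iou()` compares the tight
#' axis-aligned bounding rectangles (each pixel counted as a unit square).
#' Disjoint masks score 0, identical masks 1.
#'
#' @param a,b [instance_mask] objects on the same grid.
#' @return A number in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  check_same_grid(a, b)
  ## bbox prefilter: disjoint boxes cannot overlap
  if (a$bbox["xmin"] > b$bbox["xmax"] || b$bbox["xmin"] > a$bbox["xmax"] ||
      a$bbox["ymin"] > b$bbox["ymax"] || b$bbox["ymin"] > a$bbox["ymax"]) {
    return(0)
  }
  inter <- sum(a$raster & b$raster)
  if (inter == 0L) return(0)
  inter / (sum(a$raster) + sum(b$raster) - inter)
}

#' @rdname mask_iou
#' @export
bbox_iou <- function(a, b) {
  check_same_grid(a, b)
  rect_iou(a$bbox, b$bbox)
}

rect_iou <- function(ra, rb) {
  ix <- min(ra["xmax"], rb["xmax"]) - max(ra["xmin"], rb["xmin"]) + 1
  iy <- min(ra["ymax"], rb["ymax"]) - max(ra["ymin"], rb["ymin"]) + 1
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  area_a <- (ra["xmax"] - ra["xmin"] + 1) * (ra["ymax"] - ra["ymin"] + 1)
  area_b <- (rb["xmax"] - rb["xmin"] + 1) * (rb["ymax"] - rb["ymin"] + 1)
  unname(inter / (area_a + area_b - inter))
}

## Mask whose raster is the filled bounding box of `mask` (used by the
## bounding-box variant of the segmentation score).
bbox_as_mask <- function(mask) {
  r <- matrix(FALSE, nrow(mask$raster), ncol(mask$raster))
  bb <- mask$bbox
  r[(bb["ymin"]:bb["ymax"]) + 1L, (bb["xmin"]:bb["xmax"]) + 1L] <- TRUE
  new_instance_mask(cbind(
    x = c(bb["xmin"], bb["xmax"], bb["xmax"], bb["xmin"]) + c(-0.5, 0.5, 0.5, -0.5),
    y = c(bb["ymin"], bb["ymin"], bb["ymax"], bb["ymax"]) + c(-0.5, -0.5, 0.5, 0.5)
  ), r)
}
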