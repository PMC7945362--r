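# Shared fixtures and independent oracles used across the suite.

# Polygon tracing the outline of the pixel block cols x0..x1, rows y0..y1
# (unit-square convention): rasterises to exactly that block.
pixel_block_polygon <- function(x0, x1, y0, y1) {
  cbind(
    x = c(x0 - 0.5, x1 + 0.5, x1 + 0.5, x0 - 0.5),
    y = c(y0 - 0.5, y0 - 0.5, y1 + 0.5, y1 + 0.5)
  )
}

square_mask <- function(x0, y0, side, grid = c(40L, 40L)) {
  mask_from_polygon(pixel_block_polygon(x0, x0 + side - 1, y0, y0 + side - 1), grid)
}

# Independent point-in-polygon rasteriser: classifies every pixel centre with
# mgcv's in/out test (even-odd rule). Boundary-centre ties may legitimately
# differ from the half-open production convention, so comparisons exclude
# centres that lie within eps of any polygon edge.
brute_force_raster <- function(polygon, grid_size) {
  h <- grid_size[1]; w <- grid_size[2]
  centres <- as.matrix(expand.grid(x = seq_len(w) - 1, y = seq_len(h) - 1))
  bnd <- rbind(polygon, polygon[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, centres)
  matrix(inside[order(centres[, "y"], centres[, "x"])], h, w, byrow = TRUE)
}

point_edge_distance <- function(px, py, polygon) {
  p2 <- rbind(polygon, polygon[1, , drop = FALSE])
  dmin <- Inf
  for (i in seq_len(nrow(polygon))) {
    ax <- p2[i, 1]; ay <- p2[i, 2]; bx <- p2[i + 1, 1]; by <- p2[i + 1, 2]
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / max((bx - ax)^2 + (by - ay)^2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    dmin <- pmin(dmin, sqrt((px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2))
  }
  dmin
}

# Step-by-step brute-force reimplementation of the statistical filter, written
# with explicit loops and independent of the production code path.
brute_force_filter <- function(conf, area, q = 0.90, coeff_low = 0.65, coeff_high = 1.5) {
  n <- length(conf)
  if (n == 0L) return(integer())
  # step 1: {A} = detections at/above the nearest-rank q-th percentile
  sorted <- sort(conf)
  rank <- ceiling(q * n)
  if (rank < 1) rank <- 1
  thr <- sorted[rank]
  A <- integer()
  for (i in seq_len(n)) if (conf[i] >= thr) A <- c(A, i)
  # step 2: mean area of {A}
  mean_area <- sum(area[A]) / length(A)
  # steps 3-4: split at the mean (equality to the large side)
  As <- integer(); Al <- integer()
  for (i in A) {
    if (area[i] < mean_area) As <- c(As, i) else Al <- c(Al, i)
  }
  # steps 5-6: choose the side that represents the true scale
  if (length(Al) > length(As)) {
    ao <- mean(area[Al])
  } else if (length(As) > length(Al)) {
    conf_s <- mean(conf[As])
    conf_l <- if (length(Al) > 0) mean(conf[Al]) else -Inf
    ao <- if (conf_s > conf_l) mean(area[As]) else mean(area[Al])
  } else {
    ao <- mean(area[A])
  }
  # step 7: band acceptance over the original detections
  keep <- integer()
  for (i in seq_len(n)) {
    if (area[i] > coeff_low * ao && area[i] <= coeff_high * ao) keep <- c(keep, i)
  }
  keep
}

# Random detection sets for the filter equivalence sweep: mixed area and
# confidence distributions, deliberately including ties.
random_detection_tibble <- function(n) {
  if (n == 0L) {
    return(detection_set(masks = NULL, confidence = numeric(), area_px = numeric()))
  }
  areas <- switch(sample.int(4, 1),
    exp(rnorm(n, log(300), 0.6)),
    runif(n, 10, 2000),
    rep(sample(c(50, 200, 400), 1), n),
    c(rnorm(ceiling(n / 2), 400, 40), runif(floor(n / 2), 10, 100))
  )
  areas <- pmax(1, areas[seq_len(n)])
  confs <- switch(sample.int(3, 1),
    runif(n, 0.5, 1),
    round(runif(n, 0.5, 1), 2), # coarse grid -> ties
    rbeta(n, 8, 2)
  )
  detection_set(masks = NULL, confidence = confs, area_px = areas)
}

# 90-degree clockwise rotation of a stoma image (h x w x 3 array).
rotate_image_90 <- function(img) {
  a <- unclass(img)
  rot <- array(0, dim = c(dim(a)[2], dim(a)[1], 3))
  for (ch in 1:3) rot[, , ch] <- t(a[nrow(a):1, , ch])
  stoma_image(rot)
}
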