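## Stage 2: the instance-detector contract and two desk-scale detectors.
##
## The pipeline is detector-agnostic: anything that maps a pre-processed
## 3-channel image to a set of instance masks with confidences satisfies the
## contract. A Mask R-CNN (or any CNN segmenter) plugs in through
## `detector_adapter()`; its published operating point is captured in
## `detector_config()` (anchor scales 12/24/48/96/192 px, confidence
## threshold 0.5, 1024 px input). Bundled here:
##   * `baseline_detector()` - classical local-contrast thresholding,
##     connected components and elliptical-shape scoring; deterministic and
##     training-free, for running the full pipeline at desk scale.
##   * `oracle_detect()` - perturbs known ground truth (drops, boundary
##     jitter, injected false positives) to exercise the statistical filter
##     and the evaluation harness with controlled error structure.

#' Detector operating configuration
#'
#' @param confidence_threshold Detections below this confidence are discarded
#'   by [detect_stomata()] (default 0.5).
#' @param anchor_scales Anchor box scales in pixels per feature-pyramid
#'   level, strictly increasing (metadata consumed by CNN adapters).
#' @param input_long_side Expected working-image long side in pixels.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(confidence_threshold = 0.5,
                            anchor_scales = c(12, 24, 48, 96, 192),
                            input_long_side = 1024) {
  stopifnot(
    confidence_threshold > 0, confidence_threshold < 1,
    all(diff(anchor_scales) > 0)
  )
  structure(
    list(
      confidence_threshold = confidence_threshold,
      anchor_scales = anchor_scales,
      input_long_side = input_long_side
    ),
    class = "detector_config"
  )
}

#' Run a detector under the pipeline contract
#'
#' Applies the detector, drops detections below the configured confidence
#' threshold and returns them in canonical order (descending confidence,
#' ties by descending area then centroid raster-scan position).
#'
#' @param img A pre-processed [stoma_image].
#' @param detector A detector object ([baseline_detector()] or
#'   [detector_adapter()]).
#' @param cfg A [detector_config].
#' @return A [detection_set].
#' @export
detect_stomata <- function(img, detector, cfg = detector_config()) {
  ds <- tryCatch(
    run_detector(detector, img),
    error = function(e) {
      abort(paste0("detector failed on image '", image_ref_of(img), "': ", conditionMessage(e)))
    }
  )
  keep <- ds$confidence >= cfg$confidence_threshold
  out <- as_detection_set(ds[keep, ], image_ref(ds), attr(ds, "working_scale") %||% 1)
  sort_detections(out)
}

image_ref_of <- function(img) attr(img, "image_ref") %||% "<unnamed>"

#' @rdname detect_stomata
#' @export
run_detector <- function(detector, img) UseMethod("run_detector")

#' Wrap an external instance segmenter as a pipeline detector
#'
#' @param fun Function `img -> detection_set` (or a plain tibble with
#'   `confidence`, `area_px` and `mask` columns).
#' @param name Identifier used in logs.
#' @return A detector usable with [detect_stomata()].
#' @export
detector_adapter <- function(fun, name = "adapter") {
  structure(list(fun = fun, name = name), class = c("detector_adapter", "stoma_detector"))
}

#' @export
run_detector.detector_adapter <- function(detector, img) {
  out <- detector$fun(img)
  if (!is_detection_set(out)) out <- as_detection_set(as_tibble(out))
  out
}

#' Classical baseline detector
#'
#' Training-free stand-in detector: inverts the grayscale image (stomata
#' image darker than the epidermis background), applies local adaptive
#' thresholding, cleans up with a morphological opening, labels connected
#' components, and scores each component by how closely its boundary follows
#' its own moment-equivalent ellipse. The shape score, clipped to \[0, 1\],
#' is the detection confidence, so blob-like noise scores low and is
#' removable downstream by the statistical filter.
#'
#' @param window_px Side of the local-threshold window in pixels.
#' @param offset Threshold offset on the \[0, 1\] intensity scale.
#' @param min_area Minimum component area in pixels.
#' @param max_area_frac Maximum component area as a fraction of the image.
#' @return A detector for [detect_stomata()]; or call
#'   `baseline_detect(img, ...)` directly.
#' @export
baseline_detector <- function(window_px = 31, offset = 0.03,
                              min_area = 40, max_area_frac = 0.2) {
  structure(
    list(
      window_px = window_px, offset = offset,
      min_area = min_area, max_area_frac = max_area_frac,
      name = "baseline"
    ),
    class = c("baseline_detector", "stoma_detector")
  )
}

#' @export
run_detector.baseline_detector <- function(detector, img) {
  baseline_detect(img, detector)
}

#' @rdname baseline_detector
#' @param img A grayscale-normalised [stoma_image].
#' @param params A `baseline_detector` parameter object.
#' @export
baseline_detect <- function(img, params = baseline_detector()) {
  if (!is_stoma_image(img)) img <- stoma_image(img)
  gray <- unclass(img)[, , 1] / 255
  neg <- EBImage::Image(t(1 - gray))
  w <- min(params$window_px, dim(neg) - 1)
  bin <- EBImage::thresh(neg, w = w, h = w, offset = params$offset)
  bin <- EBImage::opening(bin, EBImage::makeBrush(5, shape = "disc"))
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  labels <- t(EBImage::imageData(lab))
  n_comp <- max(labels)
  if (n_comp == 0) {
    return(detection_set(masks = NULL, confidence = numeric(), area_px = numeric()))
  }
  h <- nrow(labels); wpx <- ncol(labels)
  max_area <- params$max_area_frac * h * wpx
  masks <- list(); confs <- numeric()
  for (k in seq_len(n_comp)) {
    raster <- labels == k
    area <- sum(raster)
    if (area < params$min_area || area > max_area) next
    m <- tryCatch(mask_from_raster(raster), error = function(e) NULL)
    if (is.null(m)) next
    confs <- c(confs, ellipse_shape_score(m))
    masks <- c(masks, list(m))
  }
  if (!length(masks)) {
    return(detection_set(masks = NULL, confidence = numeric(), area_px = numeric()))
  }
  ds <- detection_set(masks = masks, confidence = confs)
  sort_detections(nms_dedupe(ds))
}

## Shape score: 1 minus the mean absolute deviation of boundary vertices from
## the component's moment-equivalent ellipse, in normalised elliptical radius
## (a perfect ellipse boundary sits at radius 1). Clipped to [0, 1].
ellipse_shape_score <- function(mask) {
  rec <- measure_instance(mask)
  a <- rec$major_axis_px / 2; b <- rec$minor_axis_px / 2
  if (b <= 0.5) return(0)
  th <- rec$orientation_deg * pi / 180
  dx <- mask$polygon[, 1] - rec$centroid_x
  dy <- mask$polygon[, 2] - rec$centroid_y
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  resid <- mean(abs(sqrt(u^2 + v^2) - 1))
  max(0, min(1, 1 - resid))
}

## Suppress duplicate detections (mask IoU > 0.9), keeping the higher
## confidence of each pair: detectors own non-max suppression under the
## contract.
nms_dedupe <- function(ds, iou_limit = 0.9) {
  n <- nrow(ds)
  if (n < 2L) return(ds)
  ord <- order(-ds$confidence)
  keep <- logical(n)
  for (i in ord) {
    dup <- FALSE
    for (j in which(keep)) {
      if (mask_iou(ds$mask[[i]], ds$mask[[j]]) > iou_limit) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep[i] <- TRUE
  }
  as_detection_set(ds[keep, ], image_ref(ds), attr(ds, "working_scale") %||% 1)
}

#' Perturbation specification for the oracle detector
#'
#' @param drop_rate Fraction of ground-truth instances omitted (simulated
#'   false negatives).
#' @param jitter_px Boundary displacement scale in pixels: each kept
#'   instance's polygon is translated and radially perturbed by smooth
#'   low-order harmonics of this amplitude.
#' @param confidence Beta shape parameters `(a, b)` for true-detection
#'   confidences (see [confidence_params_for_tier()]).
#' @param fp_count Number of injected false-positive detections.
#' @param fp_area_factors Range of false-positive areas as multiples of the
#'   mean ground-truth area.
#' @param fp_confidence Beta shape parameters for false-positive confidences.
#' @param seed Integer seed; every random draw in [oracle_detect()] comes
#'   from this seed (global RNG state is left untouched).
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(drop_rate = 0, jitter_px = 0,
                              confidence = c(18, 2),
                              fp_count = 0, fp_area_factors = c(0.05, 0.3),
                              fp_confidence = c(3, 3), seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate <= 1, jitter_px >= 0, fp_count >= 0)
  structure(
    list(
      drop_rate = drop_rate, jitter_px = jitter_px, confidence = confidence,
      fp_count = as.integer(fp_count), fp_area_factors = fp_area_factors,
      fp_confidence = fp_confidence, seed = as.integer(seed)
    ),
    class = "perturbation_spec"
  )
}

#' Confidence distribution parameters by image-quality tier
#'
#' Beta shape parameters used by the synthetic generators: sharp images give
#' confident detections, blurry ones diffuse confidence.
#'
#' @param tier `"high"`, `"medium"` or `"low"`.
#' @return Numeric `(shape1, shape2)`.
#' @export
confidence_params_for_tier <- function(tier = c("high", "medium", "low")) {
  switch(match.arg(tier), high = c(18, 2), medium = c(8, 3), low = c(4, 3))
}

#' Oracle detector: perturbed ground truth
#'
#' Produces a detection set from known ground truth, with controlled error
#' structure: a fraction of instances dropped without replacement, smooth
#' boundary jitter, Beta-distributed confidences, and `fp_count` injected
#' false-positive ellipses whose areas are drawn from
#' `fp_area_factors` times the mean ground-truth area. With no perturbation
#' the output masks equal the ground truth exactly. Fully reproducible from
#' `spec$seed`.
#'
#' @param gt List of ground-truth [instance_mask] objects (one image).
#' @param spec A [perturbation_spec].
#' @param image_ref Identifier passed through to the detection set.
#' @return A [detection_set] sorted in canonical order.
#' @export
oracle_detect <- function(gt, spec = perturbation_spec(), image_ref = NA_character_) {
  n <- length(gt)
  grid_size <- if (n > 0) dim(gt[[1]]$raster) else c(256L, 256L)
  withr::with_seed(spec$seed, {
    n_drop <- round(spec$drop_rate * n)
    keep_idx <- if (n > 0) sort(sample.int(n, n - n_drop)) else integer()
    masks <- list(); confs <- numeric(); is_true <- logical(); matches_gt <- integer()
    for (i in keep_idx) {
      m <- gt[[i]]
      if (spec$jitter_px > 0) {
        jm <- jitter_mask(m, spec$jitter_px, grid_size)
        if (is.null(jm)) next
        m <- jm
      }
      masks <- c(masks, list(m))
      confs <- c(confs, rbeta(1, spec$confidence[1], spec$confidence[2]))
      is_true <- c(is_true, TRUE)
      matches_gt <- c(matches_gt, i)
    }
    if (spec$fp_count > 0) {
      mean_area <- if (n > 0) mean(vapply(gt, mask_area, numeric(1))) else 400
      for (k in seq_len(spec$fp_count)) {
        fp <- random_fp_mask(mean_area, spec$fp_area_factors, grid_size)
        masks <- c(masks, list(fp))
        confs <- c(confs, rbeta(1, spec$fp_confidence[1], spec$fp_confidence[2]))
        is_true <- c(is_true, FALSE)
        matches_gt <- c(matches_gt, NA_integer_)
      }
    }
    if (!length(masks)) {
      detection_set(masks = NULL, confidence = numeric(), area_px = numeric(),
                    image_ref = image_ref)
    } else {
      ds <- detection_set(
        masks = masks, confidence = confs, image_ref = image_ref,
        is_true = is_true, gt_index = matches_gt
      )
      sort_detections(ds)
    }
  })
}

## Smooth star-shaped boundary perturbation: translate the polygon and scale
## each vertex radius by 1 + (low-order sinusoid of amplitude ~ jitter_px).
jitter_mask <- function(mask, jitter_px, grid_size) {
  poly <- mask$polygon
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  dx <- poly[, 1] - cx; dy <- poly[, 2] - cy
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  amp <- jitter_px * abs(rnorm(2, 0, 0.7))
  phase <- runif(2, 0, 2 * pi)
  wobble <- amp[1] * sin(ang + phase[1]) + amp[2] * sin(2 * ang + phase[2])
  scale <- pmax(0.2, 1 + wobble / pmax(r, 1))
  shift <- rnorm(2, 0, jitter_px)
  jittered <- cbind(
    x = cx + dx * scale + shift[1],
    y = cy + dy * scale + shift[2]
  )
  tryCatch(mask_from_polygon(jittered, grid_size), error = function(e) NULL)
}

## Random elliptical false positive with area ~ factor * mean true area.
random_fp_mask <- function(mean_area, area_factors, grid_size) {
  repeat {
    area <- mean_area * runif(1, area_factors[1], area_factors[2])
    ratio <- runif(1, 1.2, 2.5)
    b <- sqrt(area / (pi * ratio)); a <- ratio * b
    cx <- runif(1, a, grid_size[2] - 1 - a)
    cy <- runif(1, a, grid_size[1] - 1 - a)
    poly <- ellipse_polygon(cx, cy, a, b, runif(1, -90, 90))
    m <- tryCatch(mask_from_polygon(poly, grid_size), error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
}

#' Polygon approximation of an ellipse
#'
#' @param cx,cy Centre in 0-based pixel coordinates.
#' @param a,b Semi-major and semi-minor axis lengths in pixels.
#' @param orientation_deg Major-axis angle in degrees, measured from +x
#'   towards +y (image coordinates).
#' @param n_vertices Number of polygon vertices.
#' @return A vertex matrix with columns (x, y).
#' @export
ellipse_polygon <- function(cx, cy, a, b, orientation_deg = 0, n_vertices = 64L) {
  th <- orientation_deg * pi / 180
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(
    x = cx + a * cos(t) * cos(th) - b * sin(t) * sin(th),
    y = cy + a * cos(t) * sin(th) + b * sin(t) * cos(th)
  )
}
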