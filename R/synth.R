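## Synthetic epidermis scenes with exact ground truth.
##
## Scenes emulate the statistical structure the pipeline assumes rather than
## photorealism: elliptical stomata of near-uniform per-image scale (darker
## guard-cell ring around a lighter pore) scattered without overlap on a
## textured background; a quality tier controlling blur, noise, contrast and
## artifact counts (air bubbles, vein lines); and an optional per-channel
## colour cast emulating staining / illumination bias. Ground-truth masks are
## the rasterised ellipse supports, fixed before blur and noise are applied.

#' Scene specification
#'
#' @param image_size Integer `(w, h)` in pixels.
#' @param n_stomata Number of stomata to place (generation fails loudly if
#'   they cannot be packed).
#' @param major_axis_range Range (px) from which the image-level mean major
#'   axis is drawn; individual stomata vary by at most 10% around it,
#'   matching the within-image size uniformity of real micrographs.
#' @param axis_ratio_range Range of major/minor axis ratios.
#' @param orientation `"uniform"` or a list `list(mu, kappa)` for von Mises
#'   orientations (degrees; kappa 0 = uniform).
#' @param quality_tier `"high"`, `"medium"` or `"low"` (sharp ... blurry with
#'   bubbles and veins).
#' @param colour_cast Per-channel RGB gains (e.g. `c(1.3, 1, 0.8)` for a
#'   red shift).
#' @param artifact_counts Named counts `c(bubbles = , veins = )`; defaults
#'   depend on the quality tier.
#' @param min_separation Minimum gap between stoma supports, px.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(512, 512), n_stomata = 12,
                       major_axis_range = c(50, 90), axis_ratio_range = c(1.5, 3),
                       orientation = "uniform",
                       quality_tier = c("high", "medium", "low"),
                       colour_cast = c(1, 1, 1), artifact_counts = NULL,
                       min_separation = 8, seed = 1L) {
  quality_tier <- match.arg(quality_tier)
  if (is.null(artifact_counts)) {
    artifact_counts <- switch(quality_tier,
      high = c(bubbles = 0, veins = 0),
      medium = c(bubbles = 1, veins = 1),
      low = c(bubbles = 3, veins = 2)
    )
  }
  spec <- structure(
    list(
      image_size = as.integer(image_size), n_stomata = as.integer(n_stomata),
      major_axis_range = major_axis_range, axis_ratio_range = axis_ratio_range,
      orientation = orientation, quality_tier = quality_tier,
      colour_cast = colour_cast, artifact_counts = artifact_counts,
      min_separation = min_separation, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
  ## feasibility: requested instances must fit in ~30% of the image
  mean_area <- pi * mean(major_axis_range)^2 / (4 * mean(axis_ratio_range))
  if (spec$n_stomata * mean_area > 0.30 * prod(spec$image_size)) {
    abort("infeasible packing: requested stomata would exceed 30% of the image area")
  }
  spec
}

tier_params <- function(tier) {
  switch(tier,
    high = list(blur_sigma = 0.5, noise_sd = 0.01, contrast = 1.0),
    medium = list(blur_sigma = 1.5, noise_sd = 0.03, contrast = 0.7),
    low = list(blur_sigma = 3.0, noise_sd = 0.06, contrast = 0.45)
  )
}

## Geometry only: sample non-overlapping ellipse parameters and build masks.
## Separated from rendering so statistical tests can skip the raster work.
sample_scene_geometry <- function(spec) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  ## one scale and one shape per image: magnification is fixed within a
  ## micrograph, so per-stoma variation is a small jitter around image-level
  ## draws
  mean_major <- runif(1, spec$major_axis_range[1], spec$major_axis_range[2])
  mean_ratio <- runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
  placed <- list()
  tries <- 0L
  max_tries <- 400L * spec$n_stomata
  while (length(placed) < spec$n_stomata) {
    if (tries >= max_tries) {
      abort(sprintf(
        "failed to pack %d stomata after %d attempts; reduce n_stomata or sizes",
        spec$n_stomata, max_tries
      ))
    }
    tries <- tries + 1L
    major <- mean_major * runif(1, 0.9, 1.1)
    ratio <- mean_ratio * runif(1, 0.95, 1.05)
    a <- major / 2; b <- a / ratio
    ori <- sample_orientation(spec$orientation)
    margin <- a + 2
    if (2 * margin >= min(w, h)) abort("stomata too large for the image")
    cx <- runif(1, margin, w - 1 - margin)
    cy <- runif(1, margin, h - 1 - margin)
    ok <- TRUE
    for (p in placed) {
      ## separation along the centre-connecting direction, using each
      ## ellipse's radius in that direction (tighter than a circle test)
      d <- sqrt((cx - p$cx)^2 + (cy - p$cy)^2)
      phi <- atan2(cy - p$cy, cx - p$cx)
      if (d < ellipse_radius_at(a, b, ori, phi) +
            ellipse_radius_at(p$a, p$b, p$ori, phi) + spec$min_separation) {
        ok <- FALSE
        break
      }
    }
    if (ok) placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, a = a, b = b, ori = ori)
  }
  placed
}

## Radius of an ellipse (semi-axes a >= b, orientation ori in degrees) in
## absolute direction phi (radians).
ellipse_radius_at <- function(a, b, ori, phi) {
  psi <- phi - ori * pi / 180
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

sample_orientation <- function(orientation) {
  if (identical(orientation, "uniform")) return(runif(1, -90, 90))
  ## von Mises on the doubled angle (axial data)
  mu <- orientation$mu %||% 0
  kappa <- orientation$kappa %||% 0
  if (kappa <= 0) return(runif(1, -90, 90))
  ## simple rejection sampler; adequate for scene generation
  repeat {
    cand <- runif(1, -pi, pi)
    if (runif(1) < exp(kappa * (cos(cand) - 1))) {
      return(((mu + cand * 90 / pi + 90) %% 180) - 90)
    }
  }
}

#' Generate one synthetic epidermis scene
#'
#' @param spec A [scene_spec].
#' @param render When `FALSE`, skip image rendering and return only the
#'   ground-truth masks (`image` is `NULL`); useful for statistical tests
#'   that never look at pixels.
#' @return List with `image` (a [stoma_image] or `NULL`), `gt` (list of
#'   [instance_mask]), and `params` (per-stoma ellipse parameter tibble).
#' @export
generate_scene <- function(spec = scene_spec(), render = TRUE) {
  withr::with_seed(spec$seed, {
    w <- spec$image_size[1]; h <- spec$image_size[2]
    geom <- sample_scene_geometry(spec)
    gt <- lapply(geom, function(g) {
      mask_from_polygon(ellipse_polygon(g$cx, g$cy, g$a, g$b, g$ori), c(h, w))
    })
    params <- dplyr::bind_rows(lapply(geom, as_tibble))
    image <- if (render) render_scene(spec, geom, gt) else NULL
    list(image = image, gt = gt, params = params)
  })
}

render_scene <- function(spec, geom, gt) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  tp <- tier_params(spec$quality_tier)
  ## textured background: base tone plus a low-frequency field
  field <- matrix(rnorm(h * w, 0, 1), h, w)
  field <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(field)), sigma = 18)))
  field <- field / max(abs(field), 1e-9)
  canvas <- 0.72 + 0.06 * field
  ## stomata: darker guard-cell ring with a lighter central pore
  for (i in seq_along(geom)) {
    g <- geom[[i]]
    support <- gt[[i]]$raster
    pore <- polygon_to_raster(
      ellipse_polygon(g$cx, g$cy, 0.45 * g$a, 0.45 * g$b, g$ori), c(h, w)
    )
    depth <- 0.32 * tp$contrast
    canvas[support] <- canvas[support] - depth
    canvas[pore] <- canvas[pore] + 0.55 * depth
  }
  canvas <- add_artifacts(canvas, spec, tp)
  ## quality degradation: grain noise, then defocus blur over everything
  canvas <- canvas + matrix(rnorm(h * w, 0, tp$noise_sd), h, w)
  if (tp$blur_sigma > 0) {
    canvas <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(canvas)), sigma = tp$blur_sigma)))
  }
  canvas <- pmin(pmax(canvas, 0), 1)
  rgb <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) rgb[, , ch] <- pmin(pmax(canvas * spec$colour_cast[ch], 0), 1)
  stoma_image(rgb * 255)
}

add_artifacts <- function(canvas, spec, tp) {
  h <- nrow(canvas); w <- ncol(canvas)
  n_bub <- spec$artifact_counts[["bubbles"]]
  n_vein <- spec$artifact_counts[["veins"]]
  if (n_bub > 0) {
    for (k in seq_len(n_bub)) {
      r <- runif(1, 8, 25)
      cx <- runif(1, r, w - 1 - r); cy <- runif(1, r, h - 1 - r)
      ring <- polygon_to_raster(ellipse_polygon(cx, cy, r, r), c(h, w))
      inner <- polygon_to_raster(ellipse_polygon(cx, cy, 0.8 * r, 0.8 * r), c(h, w))
      canvas[ring & !inner] <- canvas[ring & !inner] - 0.25 * tp$contrast
      canvas[inner] <- pmin(canvas[inner] + 0.18, 1)
    }
  }
  if (n_vein > 0) {
    xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
    for (k in seq_len(n_vein)) {
      ang <- runif(1, 0, pi)
      offs <- runif(1, 0.2, 0.8) * (cos(ang) * w + sin(ang) * h)
      d <- abs(xs * cos(ang) + ys * sin(ang) - offs)
      width <- runif(1, 3, 7)
      canvas[d < width] <- canvas[d < width] - 0.18 * tp$contrast
    }
  }
  canvas
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG scenes, one VIA 2.x polygon JSON with the ground
#' truth of every image, and a manifest CSV (`image_id`, `tier`,
#' `n_instances`, `seed`).
#'
#' @param spec Base [scene_spec]; image `i` uses `spec$seed + i`.
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest, invisibly; files under `out_dir`.
#' @export
generate_dataset <- function(spec = scene_spec(), n_images = 5, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  annotations <- list()
  manifest <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i
    scene <- generate_scene(spec_i)
    fname <- sprintf("scene_%03d.png", i)
    write_image(scene$image, file.path(out_dir, fname))
    annotations[[fname]] <- scene$gt
    manifest[[i]] <- tibble(
      image_id = fname, tier = spec$quality_tier,
      n_instances = length(scene$gt), seed = spec_i$seed
    )
  }
  manifest <- dplyr::bind_rows(manifest)
  write_via(annotations, file.path(out_dir, "ground_truth_via.json"))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Detection sample specification
#'
#' Direct inputs for exercising the statistical filter without any imagery:
#' abstract detections with controlled area and confidence distributions.
#'
#' @param n_true Number of true-scale detections.
#' @param true_area_mean Mean true area in pixels.
#' @param true_area_cv Coefficient of variation of true areas.
#' @param true_confidence Beta shape parameters for true confidences.
#' @param n_fp Number of off-scale false positives.
#' @param fp_area_factor_range False-positive areas as multiples of
#'   `true_area_mean`.
#' @param fp_confidence Beta shape parameters for false-positive confidences.
#' @param seed Integer seed.
#' @return A list of class `detection_sample_spec`.
#' @export
detection_sample_spec <- function(n_true = 15, true_area_mean = 400,
                                  true_area_cv = 0.1, true_confidence = c(18, 2),
                                  n_fp = 5, fp_area_factor_range = c(0.05, 0.2),
                                  fp_confidence = c(3, 3), seed = 1L) {
  stopifnot(n_true >= 0, n_fp >= 0, true_area_cv >= 0)
  structure(
    list(
      n_true = as.integer(n_true), true_area_mean = true_area_mean,
      true_area_cv = true_area_cv, true_confidence = true_confidence,
      n_fp = as.integer(n_fp), fp_area_factor_range = fp_area_factor_range,
      fp_confidence = fp_confidence, seed = as.integer(seed)
    ),
    class = "detection_sample_spec"
  )
}

#' Generate an abstract detection sample
#'
#' Draws `n_true + n_fp` detections with areas and confidences per the spec.
#' The `is_true` column records which rows are genuine, for test assertions.
#' With `with_masks = TRUE` a synthetic circular mask of matching area is
#' attached to each detection so the full detection-set invariants hold;
#' without, the `mask` column is `NULL` (the statistical filter only reads
#' areas and confidences).
#'
#' @param spec A [detection_sample_spec].
#' @param with_masks Attach synthetic circular masks (slower).
#' @return A [detection_set] with an `is_true` column.
#' @export
generate_detections <- function(spec = detection_sample_spec(), with_masks = FALSE) {
  withr::with_seed(spec$seed, {
    true_areas <- pmax(
      10,
      rnorm(spec$n_true, spec$true_area_mean, spec$true_area_cv * spec$true_area_mean)
    )
    fp_areas <- spec$true_area_mean *
      runif(spec$n_fp, spec$fp_area_factor_range[1], spec$fp_area_factor_range[2])
    fp_areas <- pmax(1, fp_areas)
    areas <- c(true_areas, fp_areas)
    confs <- c(
      rbeta(spec$n_true, spec$true_confidence[1], spec$true_confidence[2]),
      rbeta(spec$n_fp, spec$fp_confidence[1], spec$fp_confidence[2])
    )
    is_true <- rep(c(TRUE, FALSE), c(spec$n_true, spec$n_fp))
    if (!length(areas)) {
      detection_set(masks = NULL, confidence = numeric(), area_px = numeric())
    } else if (with_masks) {
      masks_and_areas <- circle_masks_for_areas(areas)
      detection_set(
        masks = masks_and_areas, confidence = confs, is_true = is_true
      )
    } else {
      detection_set(
        masks = NULL, confidence = confs, area_px = areas, is_true = is_true
      )
    }
  })
}

## Circular masks approximating the requested areas, all on one grid sized to
## the largest circle; detection areas become the exact raster counts.
circle_masks_for_areas <- function(areas) {
  radii <- sqrt(areas / pi)
  side <- as.integer(ceiling(2 * max(radii) + 6))
  centre <- (side - 1) / 2
  lapply(radii, function(r) {
    mask_from_polygon(ellipse_polygon(centre, centre, r, r), c(side, side))
  })
}
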