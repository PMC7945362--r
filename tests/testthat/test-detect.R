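test_that("a blank image yields an empty detection set", {
  img <- stoma_image(array(200, dim = c(128, 128, 3)))
  ds <- detect_stomata(img, baseline_detector())
  expect_s3_class(ds, "detection_set")
  expect_equal(nrow(ds), 0)
})

test_that("the contract drops detections below the confidence threshold", {
  fake <- detector_adapter(function(img) {
    detection_set(
      masks = list(
        square_mask(2, 2, 5, grid = c(64L, 64L)),
        square_mask(20, 20, 5, grid = c(64L, 64L)),
        square_mask(40, 40, 5, grid = c(64L, 64L))
      ),
      confidence = c(0.9, 0.5, 0.3)
    )
  })
  img <- stoma_image(array(128, dim = c(64, 64, 3)))
  ds <- detect_stomata(img, fake)
  expect_equal(nrow(ds), 2)
  expect_true(all(ds$confidence >= 0.5))
  # detections arrive sorted by descending confidence
  expect_equal(ds$confidence, sort(ds$confidence, decreasing = TRUE))
})

test_that("detector failures propagate with context", {
  broken <- detector_adapter(function(img) stop("weights missing"))
  img <- stoma_image(array(128, dim = c(32, 32, 3)))
  expect_error(detect_stomata(img, broken), "detector failed")
})

test_that("the unperturbed oracle reproduces ground truth exactly", {
  sc <- generate_scene(scene_spec(n_stomata = 8, image_size = c(320, 320), seed = 41), render = FALSE)
  ds <- oracle_detect(sc$gt, perturbation_spec(drop_rate = 0, jitter_px = 0, fp_count = 0, seed = 4))
  expect_equal(nrow(ds), 8)
  expect_true(all(ds$is_true))
  ious <- vapply(seq_len(nrow(ds)), function(i) {
    mask_iou(ds$mask[[i]], sc$gt[[ds$gt_index[i]]])
  }, numeric(1))
  expect_equal(ious, rep(1, 8))
})

test_that("the oracle honours drop and false-positive counts", {
  sc <- generate_scene(scene_spec(n_stomata = 10, image_size = c(384, 384), seed = 42), render = FALSE)
  ds <- oracle_detect(sc$gt, perturbation_spec(drop_rate = 0.2, fp_count = 5, seed = 6))
  expect_equal(nrow(ds), 10 - round(0.2 * 10) + 5)
  expect_equal(sum(!ds$is_true), 5)
  # full drop with no injections gives a valid empty set
  ds_empty <- oracle_detect(sc$gt, perturbation_spec(drop_rate = 1, fp_count = 0, seed = 6))
  expect_equal(nrow(ds_empty), 0)
})

test_that("oracle output is reproducible from its seed", {
  sc <- generate_scene(scene_spec(n_stomata = 6, image_size = c(320, 320), seed = 43), render = FALSE)
  spec <- perturbation_spec(drop_rate = 0.3, jitter_px = 2, fp_count = 3, seed = 77)
  a <- oracle_detect(sc$gt, spec)
  b <- oracle_detect(sc$gt, spec)
  expect_equal(a$confidence, b$confidence)
  expect_equal(a$area_px, b$area_px)
  expect_identical(lapply(a$mask, `[[`, "raster"), lapply(b$mask, `[[`, "raster"))
})

test_that("the baseline detector finds well-separated stomata on an easy scene", {
  sc <- generate_scene(scene_spec(n_stomata = 10, image_size = c(512, 512), quality_tier = "high", seed = 11))
  img <- colour_normalise(sc$image)
  ds <- detect_stomata(img, baseline_detector())
  hits <- vapply(sc$gt, function(g) {
    any(vapply(ds$mask, function(m) mask_iou(m, g) >= 0.5, logical(1)))
  }, logical(1))
  expect_gte(sum(hits), 9)
  # determinism: identical output on a second run
  ds2 <- detect_stomata(img, baseline_detector())
  expect_equal(ds$confidence, ds2$confidence)
  expect_equal(ds$area_px, ds2$area_px)
})

test_that("baseline detections carry no near-duplicate masks", {
  sc <- generate_scene(scene_spec(n_stomata = 8, image_size = c(448, 448), seed = 12))
  ds <- detect_stomata(colour_normalise(sc$image), baseline_detector())
  n <- nrow(ds)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        expect_lte(mask_iou(ds$mask[[i]], ds$mask[[j]]), 0.9)
      }
    }
  }
  expect_gte(n, 1)
})

test_that("the baseline detector is robust to a 90-degree rotation", {
  sc <- generate_scene(scene_spec(n_stomata = 8, image_size = c(448, 448), quality_tier = "high", seed = 19))
  img <- colour_normalise(sc$image)
  n0 <- nrow(detect_stomata(img, baseline_detector()))
  n90 <- nrow(detect_stomata(rotate_image_90(img), baseline_detector()))
  expect_lte(abs(n0 - n90), 1)
})

test_that("pure noise produces only low-shape-score detections", {
  withr::with_seed(99, {
    img <- stoma_image(array(runif(256 * 256 * 3) * 255, dim = c(256, 256, 3)))
  })
  ds <- run_detector(baseline_detector(), colour_normalise(img))
  if (nrow(ds) > 0) expect_lt(stats::median(ds$confidence), 0.9)
  expect_lte(nrow(ds), 40)
})

test_that("detector configuration validates anchor scales and threshold", {
  cfg <- detector_config()
  expect_equal(cfg$anchor_scales, c(12, 24, 48, 96, 192))
  expect_equal(cfg$confidence_threshold, 0.5)
  expect_error(detector_config(anchor_scales = c(24, 12)))
  expect_error(detector_config(confidence_threshold = 0))
})
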