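make_pred <- function(masks, conf) detection_set(masks = masks, confidence = conf)

test_that("perfect predictions match one-to-one with no errors", {
  gt <- list(square_mask(2, 2, 8), square_mask(20, 20, 8), square_mask(2, 25, 8))
  pred <- make_pred(gt, c(0.9, 0.8, 0.95))
  m <- match_instances(pred, gt)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$unmatched_pred, 0)
  expect_length(m$unmatched_gt, 0)
  expect_equal(m$pairs$iou, rep(1, 3))
})

test_that("missing predictions become false negatives", {
  gt <- replicate(5, square_mask(2, 2, 5), simplify = FALSE)
  for (i in 1:5) gt[[i]] <- square_mask(2 + 7 * (i - 1), 2, 5)
  empty <- detection_set(masks = NULL, confidence = numeric(), area_px = numeric())
  m <- match_instances(empty, gt)
  expect_equal(nrow(m$pairs), 0)
  expect_length(m$unmatched_gt, 5)
  prf <- precision_recall_f(m)
  expect_equal(prf$recall, 0)
  expect_equal(prf$precision, 100) # vacuous precision convention
})

test_that("competing predictions over one ground truth: confidence wins", {
  gt <- list(square_mask(10, 10, 10))
  close1 <- square_mask(10, 10, 9) # IoU 81/100
  close2 <- square_mask(11, 11, 9) # IoU 64/117
  pred <- make_pred(list(close1, close2), c(0.7, 0.95))
  m <- match_instances(pred, gt)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$pred, 2) # higher confidence claimed the gt
  expect_equal(m$unmatched_pred, 1L)
})

test_that("matching is one-to-one and respects the IoU threshold", {
  gt <- list(square_mask(0, 0, 10), square_mask(25, 25, 10))
  pred <- make_pred(list(square_mask(2, 2, 10), square_mask(12, 25, 10)), c(0.9, 0.8))
  m <- match_instances(pred, gt, iou_threshold = 0.5)
  # first prediction overlaps gt1 with IoU 64/136 < 0.5; second is disjoint-ish
  expect_true(all(m$pairs$iou >= 0.5))
  expect_equal(length(unique(m$pairs$gt)), nrow(m$pairs))
})

test_that("F-score is the harmonic mean matching published detection rows", {
  expect_equal(round(f_score_from_pr(95.87, 98.41), 2), 97.12)
  expect_equal(round(f_score_from_pr(93.22, 83.46), 2), 88.07)
  expect_equal(round(f_score_from_pr(87.98, 81.13), 2), 84.42)
  # conventions
  expect_equal(precision_recall_f(tp = 0, fp = 0, fn = 0)$f_score, 100)
  prf <- precision_recall_f(tp = 0, fp = 0, fn = 3)
  expect_equal(prf$precision, 100)
  expect_equal(prf$recall, 0)
  expect_equal(prf$f_score, 0)
})

test_that("F is symmetric, bounded by max(P, R), equal when P == R", {
  withr::with_seed(4, {
    for (k in 1:20) {
      p <- runif(1, 0, 100); r <- runif(1, 0, 100)
      expect_equal(f_score_from_pr(p, r), f_score_from_pr(r, p))
      expect_lte(f_score_from_pr(p, r), max(p, r) + 1e-9)
    }
  })
  expect_equal(f_score_from_pr(73, 73), 73)
})

test_that("segmentation IoU scores unions and charges FPs and FNs", {
  gt <- list(square_mask(0, 0, 10), square_mask(20, 20, 10))
  perfect <- make_pred(gt, c(0.9, 0.9))
  expect_equal(segmentation_iou(perfect, gt)$mask_iou, 1)
  # one of two equal-area disjoint instances missed, the other perfect
  partial <- make_pred(gt[1], 0.9)
  expect_equal(segmentation_iou(partial, gt)$mask_iou, 0.5)
  # ellipse instances: mask union perfect, bbox variant ~ pi/4
  egt <- list(mask_from_polygon(ellipse_polygon(95, 50, 90, 45, 0, 256), c(100, 200)))
  eperf <- make_pred(egt, 0.9)
  seg <- segmentation_iou(eperf, egt)
  expect_equal(seg$mask_iou, 1)
  expect_equal(seg$bbox_iou, 1) # identical boxes on both sides
  # bbox-as-prediction against elliptical ground truth shows the box penalty
  boxes <- make_pred(lapply(egt, stomapipe:::bbox_as_mask), 0.9)
  seg_box <- segmentation_iou(boxes, egt)
  expect_lt(abs(seg_box$mask_iou - pi / 4), 0.02)
})

test_that("adding a false positive never improves precision or segmentation IoU", {
  gt <- list(square_mask(0, 0, 10), square_mask(20, 20, 10))
  pred <- make_pred(gt, c(0.9, 0.9))
  with_fp <- make_pred(c(gt, list(square_mask(32, 2, 6))), c(0.9, 0.9, 0.7))
  p0 <- precision_recall_f(match_instances(pred, gt))
  p1 <- precision_recall_f(match_instances(with_fp, gt))
  expect_lte(p1$precision, p0$precision)
  expect_lte(segmentation_iou(with_fp, gt)$mask_iou, segmentation_iou(pred, gt)$mask_iou)
  expect_equal(p1$recall, p0$recall)
})

test_that("grid mismatches between prediction and ground truth are errors", {
  gt <- list(square_mask(0, 0, 5, grid = c(30L, 30L)))
  pred <- make_pred(list(square_mask(0, 0, 5, grid = c(40L, 40L))), 0.9)
  expect_error(match_instances(pred, gt), "grid")
})

test_that("dataset evaluation pools counts and reports per-image metrics", {
  sc1 <- generate_scene(scene_spec(n_stomata = 6, image_size = c(320, 320), seed = 61), render = FALSE)
  sc2 <- generate_scene(scene_spec(n_stomata = 6, image_size = c(320, 320), seed = 62), render = FALSE)
  d1 <- oracle_detect(sc1$gt, perturbation_spec(seed = 1), image_ref = "a")
  d2 <- oracle_detect(sc2$gt, perturbation_spec(drop_rate = 0.5, seed = 2), image_ref = "b")
  rep <- evaluate_detections(list(d1, d2), list(sc1$gt, sc2$gt))
  expect_equal(nrow(rep$per_image), 2)
  expect_equal(rep$summary$tp, sum(rep$per_image$tp))
  expect_equal(rep$summary$recall, 100 * 9 / 12)
  expect_equal(rep$per_image$image_id, c("a", "b"))
  g <- glance(rep)
  expect_equal(g$macro_precision, mean(rep$per_image$precision))
  expect_s3_class(tidy(rep), "tbl_df")
})
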