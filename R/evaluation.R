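## Detection and segmentation scoring.
##
## Matching protocol: greedy one-to-one matching in descending prediction
## confidence; each prediction claims the free ground-truth instance with the
## highest mask IoU, provided that IoU reaches the threshold (default 0.5).
## Unclaimed predictions are false positives, unclaimed ground truths false
## negatives. Segmentation quality is scored per image on pixel unions
## (|U pred n U gt| / |U pred u U gt|), so false positives and false
## negatives both depress the score; the bounding-box variant replaces every
## instance by its filled bounding rectangle.

#' Match predicted instances to ground truth
#'
#' @param pred A [detection_set] with masks.
#' @param gt List of ground-truth [instance_mask] objects on the same grid.
#' @param iou_threshold Minimum mask IoU for a valid match.
#' @return A `match_result`: list with `pairs`
#'   (tibble `pred`, `gt`, `iou`), `unmatched_pred` and `unmatched_gt`
#'   index vectors.
#' @export
match_instances <- function(pred, gt, iou_threshold = 0.5) {
  np <- nrow(pred); ng <- length(gt)
  if (np > 0L && ng > 0L) {
    g1 <- dim(pred$mask[[1]]$raster); g2 <- dim(gt[[1]]$raster)
    if (!identical(g1, g2)) abort("prediction and ground-truth masks lie on different grids")
  }
  order_pred <- order(-pred$confidence)
  free <- rep(TRUE, ng)
  pairs <- list()
  matched_pred <- logical(np)
  for (i in order_pred) {
    ious <- vapply(seq_len(ng), function(j) {
      if (!free[j]) return(-1)
      mask_iou(pred$mask[[i]], gt[[j]])
    }, numeric(1))
    if (ng == 0L) next
    j_best <- which.max(ious)
    if (length(j_best) && ious[j_best] >= iou_threshold) {
      free[j_best] <- FALSE
      matched_pred[i] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble(pred = i, gt = j_best, iou = ious[j_best])
    }
  }
  structure(
    list(
      pairs = if (length(pairs)) dplyr::bind_rows(pairs) else tibble(pred = integer(), gt = integer(), iou = numeric()),
      unmatched_pred = which(!matched_pred),
      unmatched_gt = which(free),
      iou_threshold = iou_threshold
    ),
    class = "match_result"
  )
}

#' Precision, recall and F-score from matched counts
#'
#' `P = 100 tp / (tp + fp)`, `R = 100 tp / (tp + fn)`,
#' `F = 2PR / (P + R)`, all in percent. Vacuous conventions: with no
#' predictions and no ground truth all three are 100; with no predictions
#' but ground truth present, precision is 100 and recall 0.
#'
#' @param m A `match_result` from [match_instances()], or `NULL` when
#'   passing counts directly.
#' @param tp,fp,fn Counts (ignored when `m` is given).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score` (percent).
#' @export
precision_recall_f <- function(m = NULL, tp = 0, fp = 0, fn = 0) {
  if (!is.null(m)) {
    stopifnot(inherits(m, "match_result"))
    tp <- nrow(m$pairs); fp <- length(m$unmatched_pred); fn <- length(m$unmatched_gt)
  }
  p <- if (tp + fp == 0) 100 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0) 100 else 100 * tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f_score = f)
}

#' @rdname precision_recall_f
#' @param precision,recall Percentages, for computing the harmonic-mean
#'   F-score directly from reported precision/recall figures.
#' @export
f_score_from_pr <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Per-image segmentation IoU
#'
#' Pixel IoU between the union of predicted masks and the union of
#' ground-truth masks; the bounding-box variant replaces each instance by
#' its filled bounding rectangle before taking unions. Both scores charge
#' false positives and false negatives. An image with neither predictions
#' nor ground truth scores 1.
#'
#' @inheritParams match_instances
#' @return One-row tibble: `mask_iou`, `bbox_iou`.
#' @export
segmentation_iou <- function(pred, gt) {
  pred_masks <- Filter(Negate(is.null), pred$mask)
  tibble(
    mask_iou = union_iou(pred_masks, gt),
    bbox_iou = union_iou(lapply(pred_masks, bbox_as_mask), lapply(gt, bbox_as_mask))
  )
}

union_iou <- function(masks_a, masks_b) {
  if (!length(masks_a) && !length(masks_b)) return(1)
  if (!length(masks_a) || !length(masks_b)) return(0)
  ua <- Reduce(`|`, lapply(masks_a, function(m) m$raster))
  ub <- Reduce(`|`, lapply(masks_b, function(m) m$raster))
  inter <- sum(ua & ub)
  if (inter == 0L) return(0)
  inter / (sum(ua) + sum(ub) - inter)
}

#' Evaluate detections over a set of images
#'
#' Runs [match_instances()] on every image and aggregates. Dataset-level
#' precision/recall/F come from the pooled true/false positive and false
#' negative counts; per-image macro averages are also reported since both
#' aggregations are common.
#'
#' @param preds List of [detection_set] objects, one per image.
#' @param gts List (same length) of ground-truth mask lists.
#' @param iou_threshold Minimum mask IoU for a match.
#' @param image_ids Optional image identifiers (defaults to each set's
#'   `image_ref`, then to sequence numbers).
#' @return An `eval_report`: list with `summary` (one-row pooled tibble with
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`, `mean_mask_iou`,
#'   `mean_bbox_iou`, `mean_matched_iou`), `per_image` (tibble), and
#'   `macro` (means of the per-image metrics).
#' @export
evaluate_detections <- function(preds, gts, iou_threshold = 0.5, image_ids = NULL) {
  stopifnot(length(preds) == length(gts))
  if (is.null(image_ids)) {
    image_ids <- purrr::imap_chr(preds, function(p, i) {
      id <- image_ref(p)
      if (is.na(id)) paste0("image_", i) else id
    })
  }
  per_image <- purrr::pmap(list(preds, gts, image_ids), function(p, g, id) {
    m <- match_instances(p, g, iou_threshold)
    prf <- precision_recall_f(m)
    seg <- segmentation_iou(p, g)
    dplyr::bind_cols(
      tibble(image_id = id),
      prf, seg,
      tibble(mean_matched_iou = if (nrow(m$pairs)) mean(m$pairs$iou) else NA_real_)
    )
  })
  per_image <- dplyr::bind_rows(per_image)
  pooled <- precision_recall_f(
    tp = sum(per_image$tp), fp = sum(per_image$fp), fn = sum(per_image$fn)
  )
  pooled$mean_mask_iou <- mean(per_image$mask_iou)
  pooled$mean_bbox_iou <- mean(per_image$bbox_iou)
  pooled$mean_matched_iou <- mean(per_image$mean_matched_iou, na.rm = TRUE)
  macro <- tibble(
    precision = mean(per_image$precision),
    recall = mean(per_image$recall),
    f_score = mean(per_image$f_score)
  )
  structure(
    list(
      summary = pooled, per_image = per_image, macro = macro,
      iou_threshold = iou_threshold
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<eval_report> %d images, IoU threshold %.2f\n",
      "  pooled: P %.2f%%  R %.2f%%  F %.2f%%  (tp %d, fp %d, fn %d)\n",
      "  segmentation: mask IoU %.3f, bbox IoU %.3f\n"
    ),
    nrow(x$per_image), x$iou_threshold,
    s$precision, s$recall, s$f_score, s$tp, s$fp, s$fn,
    s$mean_mask_iou, s$mean_bbox_iou
  ))
  invisible(x)
}

#' Write an evaluation report
#'
#' @param report An `eval_report`.
#' @param json_path Optional path for the JSON report.
#' @param csv_path Optional path for the per-image CSV.
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(json_path)) {
    payload <- list(
      iou_threshold = report$iou_threshold,
      pooled = as.list(report$summary),
      macro = as.list(report$macro),
      per_image = report$per_image
    )
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null"), json_path)
  }
  if (!is.null(csv_path)) write.csv(report$per_image, csv_path, row.names = FALSE)
  invisible(report)
}
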