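## Full pipeline: pre-process -> detect -> statistical filter -> measure.

#' Run the stomata pipeline on one image
#'
#' Chains colour normalisation, working-scale resizing, detection, the
#' statistical false-positive filter (optional) and per-stoma morphometry.
#'
#' @param img A [stoma_image] (raw, un-normalised).
#' @param detector A detector for [detect_stomata()] (default the classical
#'   baseline).
#' @param pre_cfg A [preprocess_config].
#' @param det_cfg A [detector_config].
#' @param flt_cfg A [filter_config], or `NULL` to bypass the statistical
#'   filter (trading precision for recall).
#' @param pixel_size Optional micrometres per pixel for physical units.
#' @return List: `image` (pre-processed working image), `raw` (unfiltered
#'   [detection_set]), `detections` (post-filter set with its trace),
#'   `measurements` (tibble over all raw detections, `kept_by_filter`
#'   flagging survivors), `summary` (one-row [summarize_image()] tibble of
#'   the kept stomata).
#' @export
run_pipeline <- function(img, detector = baseline_detector(),
                         pre_cfg = preprocess_config(),
                         det_cfg = detector_config(),
                         flt_cfg = filter_config(),
                         pixel_size = NULL) {
  work <- resize_for_inference(colour_normalise(img, pre_cfg), pre_cfg)
  raw <- detect_stomata(work, detector, det_cfg)
  if (is.null(flt_cfg)) {
    kept <- raw
    kept_flags <- rep(TRUE, nrow(raw))
  } else {
    kept <- apply_statistical_filter(raw, flt_cfg)
    kept_flags <- seq_len(nrow(raw)) %in% filter_trace(kept)$accepted
  }
  measurements <- if (nrow(raw)) {
    measure_detections(raw, pixel_size, kept = kept_flags)
  } else {
    measure_detections(raw, pixel_size, kept = logical())
  }
  list(
    image = work,
    raw = raw,
    detections = kept,
    measurements = measurements,
    summary = summarize_image(
      measurements[measurements$kept_by_filter, , drop = FALSE],
      image_dim(work), pixel_size
    )
  )
}
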