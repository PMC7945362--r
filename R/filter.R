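## Stage 3: the statistical false-positive filter.
##
## Multi-scale detectors propose stomata at several spurious scales in one
## image, although within a single micrograph true stomata are nearly uniform
## in size. The filter estimates the image's true stomatal area from the most
## confident detections and rejects every detection outside a fixed
## multiplicative band around that estimate:
##
##   1. {A}   = detections with confidence at or above the q-th percentile
##              (nearest-rank; default q = 0.90).
##   2. Split {A} at its mean area into {A_s} (area < mean) and
##      {A_l} (area >= mean).
##   3. If |A_l| > |A_s|                      -> area_optimal = mean area of {A_l}   ["large" image]
##      If |A_s| > |A_l| and {A_s} is the more confident half
##                                            -> area_optimal = mean area of {A_s}   ["small" image]
##      If |A_s| > |A_l| otherwise            -> area_optimal = mean area of {A_l}   [small side is noise]
##      If |A_s| == |A_l|                     -> area_optimal = mean area of {A}
##   4. Keep every original detection with
##        coeff_low * area_optimal < area <= coeff_high * area_optimal
##      regardless of its confidence (strict lower bound, inclusive upper).
##
## The default coefficients 0.65 and 1.5 bracket a ~50% variation around the
## size estimate (0.65 * 1.5 ~= 1, 1 * 1.5 = 1.5).

#' Statistical filter configuration
#'
#' @param confidence_quantile Quantile (0-1) defining the high-confidence
#'   seed set `{A}`; nearest-rank convention, membership by `>=` so the seed
#'   set is never empty for non-empty input.
#' @param coeff_low,coeff_high Multiplicative band around the inferred
#'   optimal area; a detection is kept when
#'   `coeff_low * area_optimal < area <= coeff_high * area_optimal`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(confidence_quantile = 0.90, coeff_low = 0.65, coeff_high = 1.5) {
  stopifnot(
    confidence_quantile > 0, confidence_quantile < 1,
    coeff_low > 0, coeff_low < 1, coeff_high > 1
  )
  structure(
    list(
      confidence_quantile = confidence_quantile,
      coeff_low = coeff_low,
      coeff_high = coeff_high
    ),
    class = "filter_config"
  )
}

#' Select the high-confidence seed detections
#'
#' Returns the indices of detections whose confidence is at or above the
#' nearest-rank `q`-quantile of all confidences in the set.
#'
#' @param ds A [detection_set] (any tibble with a `confidence` column works).
#' @param q Quantile in (0, 1).
#' @return Integer vector of row indices (empty for empty input).
#' @export
select_top_confidence <- function(ds, q = 0.90) {
  conf <- ds$confidence
  n <- length(conf)
  if (n == 0L) return(integer())
  threshold <- sort(conf)[max(1L, ceiling(q * n))]
  which(conf >= threshold)
}

#' Partition detections at their mean area
#'
#' Splits a detection subset into a below-mean and an at-or-above-mean part.
#' Equality goes to the "large" side, which keeps the partition exhaustive
#' and makes the single-detection case well defined.
#'
#' @param areas Numeric vector of pixel areas of the seed set `{A}`.
#' @return List with `small` and `large` index vectors (into `areas`) and
#'   `mean_area`.
#' @export
partition_by_mean_area <- function(areas) {
  m <- mean(areas)
  list(small = which(areas < m), large = which(areas >= m), mean_area = m)
}

#' Infer the optimal stomatal area for an image
#'
#' Chooses which side of the mean-area split represents the true stomatal
#' scale, preferring the large side unless the small side is both more
#' numerous and more confident.
#'
#' @param areas,confidences Vectors over the seed set `{A}`.
#' @param part Partition from [partition_by_mean_area()].
#' @return List with `area_optimal` and `branch`
#'   (`"large"`, `"small"`, `"fallback"` or `"tie"`).
#' @export
infer_area_optimal <- function(areas, confidences, part = partition_by_mean_area(areas)) {
  ns <- length(part$small); nl <- length(part$large)
  if (nl > ns) {
    list(area_optimal = mean(areas[part$large]), branch = "large")
  } else if (ns > nl) {
    conf_s <- mean(confidences[part$small])
    conf_l <- if (nl > 0L) mean(confidences[part$large]) else -Inf
    if (conf_s > conf_l) {
      list(area_optimal = mean(areas[part$small]), branch = "small")
    } else {
      ## more small detections, but the large ones are the confident ones:
      ## treat the small surplus as noise
      list(area_optimal = mean(areas[part$large]), branch = "fallback")
    }
  } else {
    list(area_optimal = mean(areas), branch = "tie")
  }
}

#' Apply the statistical false-positive filter
#'
#' Runs the full size-consistency filter on a detection set and returns the
#' accepted subset. The complete audit trail (seed set, partition, branch,
#' inferred optimal area, acceptance band) is attached as the
#' `"filter_trace"` attribute, retrievable with [filter_trace()].
#'
#' @param ds A [detection_set].
#' @param cfg A [filter_config].
#' @return The filtered [detection_set] (a subset of the input rows, order
#'   preserved) with a `filter_trace` attribute.
#' @export
apply_statistical_filter <- function(ds, cfg = filter_config()) {
  n <- nrow(ds)
  if (n == 0L) {
    trace <- new_filter_trace(
      ds, cfg, set_A = integer(), mean_area_A = NA_real_,
      set_As = integer(), set_Al = integer(),
      branch_taken = NA_character_, area_optimal = NA_real_,
      accepted = integer(), note = "empty input"
    )
    return(set_filter_trace(ds, trace))
  }
  idx_A <- select_top_confidence(ds, cfg$confidence_quantile)
  areas_A <- ds$area_px[idx_A]
  part <- partition_by_mean_area(areas_A)
  opt <- infer_area_optimal(areas_A, ds$confidence[idx_A], part)
  lo <- cfg$coeff_low * opt$area_optimal
  hi <- cfg$coeff_high * opt$area_optimal
  accepted <- which(ds$area_px > lo & ds$area_px <= hi)
  trace <- new_filter_trace(
    ds, cfg,
    set_A = idx_A, mean_area_A = part$mean_area,
    set_As = idx_A[part$small], set_Al = idx_A[part$large],
    branch_taken = opt$branch, area_optimal = opt$area_optimal,
    accepted = accepted, note = NA_character_
  )
  out <- ds[accepted, ]
  out <- as_detection_set(out, image_ref(ds), attr(ds, "working_scale") %||% 1)
  set_filter_trace(out, trace)
}

new_filter_trace <- function(ds, cfg, set_A, mean_area_A, set_As, set_Al,
                             branch_taken, area_optimal, accepted, note) {
  structure(
    list(
      n_input = nrow(ds),
      confidence = ds$confidence, area_px = ds$area_px,
      set_A = set_A, mean_area_A = mean_area_A,
      set_As = set_As, set_Al = set_Al,
      branch_taken = branch_taken, area_optimal = area_optimal,
      band = c(
        low = cfg$coeff_low * area_optimal,
        high = cfg$coeff_high * area_optimal
      ),
      accepted = accepted,
      config = unclass(cfg),
      note = note
    ),
    class = "filter_trace"
  )
}

set_filter_trace <- function(ds, trace) {
  attr(ds, "filter_trace") <- trace
  ds
}

#' @rdname apply_statistical_filter
#' @export
filter_trace <- function(ds) attr(ds, "filter_trace")

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf(
    "<filter_trace> %d detections; |A| = %d, branch = %s, area_optimal = %.1f px\n  band (%.1f, %.1f], accepted %d\n",
    x$n_input, length(x$set_A),
    x$branch_taken %||% NA, x$area_optimal,
    x$band["low"], x$band["high"], length(x$accepted)
  ))
  invisible(x)
}

#' Serialise a filter trace to JSON
#'
#' @param trace A `filter_trace`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly `path` when writing to file).
#' @export
filter_trace_json <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "filter_trace"))
  js <- jsonlite::toJSON(unclass(trace), auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
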