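## broom-style tidiers and autoplot methods for pipeline result objects.

#' Tidy a filter trace
#'
#' One row per input detection with its role in the statistical filter.
#'
#' @param x A `filter_trace` from [apply_statistical_filter()].
#' @param ... Unused.
#' @return Tibble: `instance`, `confidence`, `area_px`, `in_seed_set`,
#'   `seed_side` (`"small"`/`"large"`/`NA`), `accepted`.
#' @exportS3Method generics::tidy
tidy.filter_trace <- function(x, ...) {
  n <- x$n_input
  side <- rep(NA_character_, n)
  side[x$set_As] <- "small"
  side[x$set_Al] <- "large"
  tibble(
    instance = seq_len(n),
    confidence = x$confidence,
    area_px = x$area_px,
    in_seed_set = seq_len(n) %in% x$set_A,
    seed_side = side,
    accepted = seq_len(n) %in% x$accepted
  )
}

#' Summarise a filter trace
#'
#' @inheritParams tidy.filter_trace
#' @return One-row tibble: input/seed/accepted counts, branch, inferred
#'   optimal area and acceptance band.
#' @exportS3Method generics::glance
glance.filter_trace <- function(x, ...) {
  tibble(
    n_input = x$n_input,
    n_seed = length(x$set_A),
    n_small = length(x$set_As),
    n_large = length(x$set_Al),
    branch = x$branch_taken,
    area_optimal = x$area_optimal,
    band_low = unname(x$band["low"]),
    band_high = unname(x$band["high"]),
    n_accepted = length(x$accepted)
  )
}

#' Plot a filter trace
#'
#' Area-versus-confidence scatter of all detections with the acceptance band
#' of the statistical filter.
#'
#' @param object A `filter_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.filter_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area_px, y = .data$confidence)) +
    ggplot2::geom_rect(
      xmin = object$band["low"], xmax = object$band["high"], ymin = -Inf, ymax = Inf,
      fill = "seagreen", alpha = 0.04, inherit.aes = FALSE,
      data = tibble(.dummy = 1)
    ) +
    ggplot2::geom_vline(xintercept = object$area_optimal, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted, shape = .data$in_seed_set)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "seagreen", `FALSE` = "firebrick")) +
    ggplot2::labs(
      x = "detection area (px)", y = "confidence",
      colour = "accepted", shape = "seed set",
      title = sprintf(
        "statistical filter: area_optimal = %.0f px, band (%.0f, %.0f]",
        object$area_optimal, object$band["low"], object$band["high"]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` from [evaluate_detections()].
#' @param ... Unused.
#' @return The per-image metric tibble.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$per_image

#' Summarise an evaluation report
#'
#' @inheritParams tidy.eval_report
#' @return One-row tibble of pooled metrics plus macro-averaged P/R/F.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    dplyr::rename_with(x$macro, ~ paste0("macro_", .x))
  )
}

#' Plot an evaluation report
#'
#' Per-image precision versus recall, sized by ground-truth count.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  df <- object$per_image
  df$n_gt <- df$tp + df$fn
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision, size = .data$n_gt)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::labs(
      x = "recall (%)", y = "precision (%)", size = "ground-truth stomata",
      title = sprintf(
        "pooled P %.1f%%, R %.1f%%, F %.1f%%",
        object$summary$precision, object$summary$recall, object$summary$f_score
      )
    ) +
    ggplot2::theme_minimal()
}
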