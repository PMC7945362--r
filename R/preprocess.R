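## Stage 1: colour-bias removal and working-scale resizing.
##
## Microscope datasets differ wildly in colour balance (safranin staining,
## fluorescence, DIC, SEM, nail-polish imprints...). The normalisation used
## here equalises local contrast on the luma channel and then discards
## chroma entirely, so that downstream detectors see the same grayscale
## statistics regardless of the acquisition colour cast:
##   1. RGB -> YCbCr (full-range BT.601),
##   2. CLAHE on the Y channel,
##   3. YCbCr -> RGB,
##   4. RGB -> grayscale (BT.601 luma), replicated onto 3 channels.

#' Pre-processing configuration
#'
#' @param clahe_clip_limit CLAHE contrast clip limit (> 0; higher limits allow
#'   stronger local amplification).
#' @param clahe_tile_grid Integer `(rows, cols)` of CLAHE tiles.
#' @param target_long_side Target size in pixels for [resize_for_inference()].
#' @param resize_mode `"longest_side"` scales the larger dimension to the
#'   target; `"width"` scales the width (both conventions occur in practice
#'   for this pipeline, so both are provided).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 2, clahe_tile_grid = c(8, 8),
                              target_long_side = 1024,
                              resize_mode = c("longest_side", "width")) {
  stopifnot(clahe_clip_limit > 0, all(clahe_tile_grid >= 1), target_long_side >= 64)
  structure(
    list(
      clahe_clip_limit = clahe_clip_limit,
      clahe_tile_grid = as.integer(clahe_tile_grid),
      target_long_side = as.integer(target_long_side),
      resize_mode = match.arg(resize_mode)
    ),
    class = "preprocess_config"
  )
}

## Full-range (JPEG-style) BT.601 conversions on the [0, 255] scale.
rgb_to_ycbcr <- function(r, g, b) {
  list(
    y  =  0.299 * r + 0.587 * g + 0.114 * b,
    cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
    cr = 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  )
}

ycbcr_to_rgb <- function(y, cb, cr) {
  list(
    r = y + 1.402 * (cr - 128),
    g = y - 0.344136 * (cb - 128) - 0.714136 * (cr - 128),
    b = y + 1.772 * (cb - 128)
  )
}

#' Remove colour-space bias from a microscope image
#'
#' Applies CLAHE to the luma channel in YCbCr space, converts back, and
#' collapses to grayscale replicated on three channels, so images of one
#' scene under different colour casts converge to near-identical renderings.
#'
#' @param img A 3-channel [stoma_image].
#' @param cfg A [preprocess_config].
#' @return A [stoma_image] with `R == G == B` at every pixel.
#' @export
colour_normalise <- function(img, cfg = preprocess_config()) {
  if (!is_stoma_image(img)) img <- stoma_image(img)
  a <- unclass(img)
  yc <- rgb_to_ycbcr(a[, , 1], a[, , 2], a[, , 3])
  y_eq <- clahe_channel(yc$y, cfg)
  rgb <- ycbcr_to_rgb(y_eq, yc$cb, yc$cr)
  rgb <- lapply(rgb, function(ch) pmin(pmax(ch, 0), 255))
  gray <- 0.299 * rgb$r + 0.587 * rgb$g + 0.114 * rgb$b
  stoma_image(round(gray), scale_factor = scale_factor(img))
}

clahe_channel <- function(y, cfg) {
  if (max(y) - min(y) < .Machine$double.eps * 255) return(y) # flat field
  ebi <- EBImage::Image(t(y) / 255)
  eq <- EBImage::clahe(
    ebi,
    nx = cfg$clahe_tile_grid[2], ny = cfg$clahe_tile_grid[1],
    limit = cfg$clahe_clip_limit
  )
  t(EBImage::imageData(eq)) * 255
}

#' Bring an image to the pipeline working scale
#'
#' Scales the image so that the dimension selected by `cfg$resize_mode`
#' equals `cfg$target_long_side`, preserving aspect ratio within one pixel
#' and recording the applied scale in the result's `scale_factor` (upscaling
#' is permitted).
#'
#' @inheritParams colour_normalise
#' @return A resized [stoma_image] whose `scale_factor` is the ratio of
#'   working size to original size (composed with any pre-existing factor).
#' @export
resize_for_inference <- function(img, cfg = preprocess_config()) {
  if (!is_stoma_image(img)) img <- stoma_image(img)
  d <- image_dim(img) # (h, w)
  ref <- if (cfg$resize_mode == "width") d[2] else max(d)
  s <- cfg$target_long_side / ref
  if (abs(s - 1) < 1e-12) return(img)
  new_h <- max(1L, as.integer(round(d[1] * s)))
  new_w <- max(1L, as.integer(round(d[2] * s)))
  ebi <- EBImage::resize(to_ebimage(img), w = new_w, h = new_h)
  from_ebimage(ebi, scale_factor = scale_factor(img) * s)
}

#' Histogram distance between the luma channels of two images
#'
#' Earth-mover (Wasserstein-1) distance between the 256-bin intensity
#' histograms of the first channels, in intensity units. Used to verify that
#' colour-cast twins of one scene converge under [colour_normalise()].
#'
#' @param a,b [stoma_image] objects.
#' @return Non-negative distance in \[0, 255\].
#' @export
luma_histogram_distance <- function(a, b) {
  luma_hist <- function(img) {
    v <- unclass(img)
    y <- round(0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3])
    tabulate(y + 1, nbins = 256)
  }
  ha <- luma_hist(a); hb <- luma_hist(b)
  sum(abs(cumsum(ha / sum(ha)) - cumsum(hb / sum(hb))))
}
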