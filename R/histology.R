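#' Convert an RGB stained section to a single 256-level grey image
#'
#' Collapses a three-channel RGB image of a luxol-fast-blue stained section
#' to one 8-bit grey channel. The default conversion is the Rec. 709
#' luminance `0.2126 R + 0.7152 G + 0.0722 B`, rounded half-to-even; the
#' unweighted channel mean is available as an alternative.
#'
#' @param image numeric array `h x w x 3`. Values in `[0, 1]` are
#'   interpreted as normalized 8-bit (multiplied by 255); values in
#'   `[0, 255]` are used as-is.
#' @param weights `"rec709"` (default) or `"mean"`.
#' @return matrix of integers in 0..255 with attributes `conversion`
#'   (weights used) and `provenance`.
#' @export
rgb_to_grey <- function(image, weights = c("rec709", "mean")) {
  weights <- match.arg(weights)
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop_callomap("image must be an h x w x 3 RGB array", "callomap_format_error")
  img <- image[, , 1:3, drop = FALSE]
  if (!is.numeric(img) || any(!is.finite(img)))
    stop_callomap("image values must be finite numerics", "callomap_format_error")
  mx <- max(img)
  if (mx <= 1) img <- img * 255
  if (min(img) < 0 || max(img) > 255)
    stop_callomap("image values outside the 8-bit range", "callomap_format_error")
  w <- if (weights == "rec709") c(0.2126, 0.7152, 0.0722) else rep(1/3, 3)
  grey <- w[1] * img[, , 1] + w[2] * img[, , 2] + w[3] * img[, , 3]
  grey <- round(grey)   # round() is round-half-to-even in R
  structure(grey, conversion = weights)
}

#' Rescale a grey section to the 1-7 myelin-density scale
#'
#' Computes the optical-density proxy `d = 255 - grey` (darker stain means
#' more myelin) and rescales the full 0..255 intensity range linearly onto
#' `[1, 7]`: `density = 1 + 6 d / 255`. Grey 255 (unstained white) maps to
#' density 1 and grey 0 (saturated stain) to density 7, so both endpoints of
#' the scale are attainable. With consistent light calibration across
#' acquisitions the fixed global range is the appropriate default; supply
#' `calibration = c(min, max)` (bounds on `d`) to min-max normalize per
#' image instead. `mode = "log"` uses the logarithmic transmittance OD
#' `-log10((grey + 1)/256)`, min-max normalized over its own fixed range,
#' for workflows that quantify absorbance rather than intensity.
#'
#' @param grey matrix from [rgb_to_grey()] (values 0..255).
#' @param mask a [callosal_mask()] aligned with `grey`.
#' @param calibration optional `c(min, max)` bounds on the inverted
#'   intensity `d` used for min-max normalization before the 1-7 rescale.
#' @param mode `"linear"` (default) or `"log"`.
#' @return matrix of densities in `[1, 7]` over the mask, `NA` outside,
#'   with attribute `polarity = "higher_is_more_myelin"`.
#' @export
grey_to_density <- function(grey, mask, calibration = NULL,
                            mode = c("linear", "log")) {
  mode <- match.arg(mode)
  if (!inherits(mask, "callosal_mask"))
    stop_callomap("mask must be a callosal_mask", "callomap_input_error")
  if (!identical(dim(grey), dim(mask$pixels)))
    stop_callomap(sprintf("grey image (%s) and mask (%s) dimensions differ",
                          paste(dim(grey), collapse = "x"),
                          paste(dim(mask$pixels), collapse = "x")),
                  "callomap_alignment_error")
  if (mode == "linear") {
    d <- 255 - grey
    if (!is.null(calibration)) {
      if (length(calibration) != 2 || calibration[2] <= calibration[1])
        stop_callomap("calibration must be c(min, max) with max > min",
                      "callomap_config_error")
      d <- 255 * (d - calibration[1]) / (calibration[2] - calibration[1])
      d <- pmin(pmax(d, 0), 255)
    }
    density <- 1 + 6 * d / 255
  } else {
    d <- -log10((grey + 1) / 256)
    density <- 1 + 6 * d / (-log10(1 / 256))
  }
  density[!mask$pixels] <- NA_real_
  structure(density, polarity = "higher_is_more_myelin")
}

# The seven discrete colours of the myelin-density maps, lowest to highest.
density_palette <- function() {
  c(purple = "#7B2D8E", blue = "#2457C5", cyan = "#22B5C4",
    green = "#2CA02C", yellow = "#F2D324", orange = "#F28C22",
    dark_red = "#8B1A1A")
}

# Bin densities in [1,7] into the 7 colour classes; edges at 1 + 6k/7.
density_bins <- function(density) {
  bins <- floor((density - 1) * 7 / 6) + 1
  bins[bins > 7] <- 7   # density exactly 7 belongs to the top bin
  bins
}

#' Render a myelin-density map as a colour-coded RGB image
#'
#' Maps densities on the 1-7 scale into 7 discrete colour bins from purple
#' (lowest myelin density) through blue, cyan, green, yellow and orange to
#' dark red (highest); bin edges sit at `1 + 6k/7`. Background (`NA`) pixels
#' render white.
#'
#' @param density matrix from [grey_to_density()], values in `[1, 7]` or `NA`.
#' @param file optional PNG output path.
#' @return RGB array `h x w x 3` in `[0, 1]`, invisibly if `file` is given.
#' @export
render_density_colormap <- function(density, file = NULL) {
  vals <- density[!is.na(density)]
  if (length(vals) && (min(vals) < 1 || max(vals) > 7))
    stop_callomap("density values outside [1, 7]", "callomap_contract_error")
  pal <- t(col2rgb(density_palette())) / 255
  img <- array(1, dim = c(nrow(density), ncol(density), 3))
  idx <- which(!is.na(density))
  if (length(idx)) {
    bins <- density_bins(density[idx])
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- pal[bins, ch]
      img[, , ch] <- plane
    }
  }
  if (!is.null(file)) {
    png::writePNG(img, file)
    return(invisible(img))
  }
  img
}
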