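#' Construct a midsagittal callosal mask
#'
#' Wraps a binary 2D image of the midsagittal corpus callosum cross-section
#' together with its pixel spacing and orientation. The mask is the
#' geometric substrate for the Witelson parcellation and the 92-ROI
#' sampling template: all downstream coordinates refer to this grid.
#'
#' @param pixels logical or 0/1 matrix; rows run dorsal (row 1) to ventral,
#'   columns run anterior (column 1) to posterior.
#' @param spacing numeric length-2, millimetres per pixel along the
#'   antero-posterior and dorsoventral axes.
#' @param anterior which image side is anterior; only `"left"` (column 1
#'   anterior, the convention used by all generators in this package) is
#'   currently supported, `"right"` inputs are flipped on construction.
#' @param check validate connectivity (single 4-connected foreground
#'   component) via [EBImage::bwlabel()]. Set `FALSE` only for trusted
#'   generated masks.
#' @return an object of class `callosal_mask`.
#' @export
callosal_mask <- function(pixels, spacing = c(1, 1), anterior = c("left", "right"),
                          check = TRUE) {
  anterior <- match.arg(anterior)
  if (!is.matrix(pixels))
    stop_callomap("mask pixels must be a matrix", "callomap_input_error")
  px <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  px[is.na(px)] <- FALSE
  if (anterior == "right") px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  if (!any(px))
    stop_callomap("mask is empty", "callomap_input_error")
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_callomap("spacing must be two positive numbers (mm/px, AP and DV)",
                  "callomap_input_error")
  if (check) {
    ncomp <- max(EBImage::bwlabel(px * 1L))
    if (ncomp != 1L)
      stop_callomap(sprintf("mask must have exactly one connected component (found %d)",
                            ncomp), "callomap_input_error")
  }
  structure(list(pixels = px, spacing = as.numeric(spacing), anterior = "left"),
            class = "callosal_mask")
}

#' @export
print.callosal_mask <- function(x, ...) {
  bb <- mask_bbox(x)
  cat(sprintf("<callosal_mask> %d x %d px, %d foreground px, AP extent %d px (%.1f mm)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              bb$width, bb$width * x$spacing[1]))
  invisible(x)
}

# Bounding box of the foreground, 1-based column/row ranges plus extents.
mask_bbox <- function(mask) {
  px <- if (inherits(mask, "callosal_mask")) mask$pixels else mask
  cols <- which(colSums(px) > 0)
  rows <- which(rowSums(px) > 0)
  list(col_min = min(cols), col_max = max(cols),
       row_min = min(rows), row_max = max(rows),
       width = max(cols) - min(cols) + 1L,
       height = max(rows) - min(rows) + 1L)
}

#' Read / write a callosal mask as a PNG image
#'
#' Masks are stored as 8-bit greyscale PNG where foreground is any pixel
#' with intensity above `threshold`.
#'
#' @param path file path.
#' @param spacing,anterior passed to [callosal_mask()].
#' @param threshold foreground threshold on the 0-1 intensity scale.
#' @return [read_mask_png()] a `callosal_mask`; [write_mask_png()] the path,
#'   invisibly.
#' @export
read_mask_png <- function(path, spacing = c(1, 1), anterior = "left",
                          threshold = 0.5) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  callosal_mask(img > threshold, spacing = spacing, anterior = anterior)
}

#' @rdname read_mask_png
#' @param mask a `callosal_mask`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}
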