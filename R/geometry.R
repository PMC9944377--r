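#' Witelson macro-region names, anterior to posterior
#' @export
witelson_regions <- function() {
  c("rostrum_genu", "rostral_body", "anterior_midbody",
    "posterior_midbody", "isthmus", "splenium")
}

#' Default antero-posterior boundary fractions of the Witelson subdivision
#'
#' Witelson's geometric scheme places boundaries at 1/3, 1/2, 2/3 and 4/5 of
#' the antero-posterior callosal length; the split between rostrum/genu and
#' rostral body inside the anterior third is set at 1/6 by convention. All
#' five fractions are configurable in [parcellate_witelson()].
#' @export
witelson_fractions <- function() c(1/6, 1/3, 1/2, 2/3, 4/5)

#' Parcellate a callosal mask into the six Witelson macro-regions
#'
#' Assigns every foreground pixel to one of the six macro-regions
#' (rostrum/genu, rostral body, anterior midbody, posterior midbody,
#' isthmus, splenium) by its normalized antero-posterior position. The AP
#' extent is measured on the bounding box of the mask; the normalized
#' coordinate of a pixel is the position of its center within that extent,
#' `u = (col - col_min + 0.5) / width`, so the subdivision scales with the
#' individual callosal size. Intervals are half-open and anterior-closed: a
#' pixel whose center falls exactly on a boundary fraction belongs to the
#' posterior region.
#'
#' @param mask a [callosal_mask()].
#' @param fractions five strictly increasing AP boundary fractions in (0,1);
#'   default [witelson_fractions()].
#' @return an object of class `witelson_parcellation` with elements
#'   `labels` (integer matrix, 0 = background, 1..6 anterior to posterior),
#'   `region_names`, `fractions`, `mask`.
#' @export
parcellate_witelson <- function(mask, fractions = witelson_fractions()) {
  if (!inherits(mask, "callosal_mask"))
    stop_callomap("mask must be a callosal_mask", "callomap_input_error")
  fractions <- as.numeric(fractions)
  if (length(fractions) != 5 || any(diff(fractions) <= 0) ||
      fractions[1] <= 0 || fractions[5] >= 1)
    stop_callomap("fractions must be 5 strictly increasing values in (0,1)",
                  "callomap_config_error")
  bb <- mask_bbox(mask)
  if (bb$width < 6)
    stop_callomap("mask AP extent below 6 px: too degenerate to subdivide",
                  "callomap_degenerate_mask_error")
  u_col <- (seq_len(ncol(mask$pixels)) - bb$col_min + 0.5) / bb$width
  region_col <- findInterval(u_col, fractions) + 1L   # boundary -> posterior
  region_col[region_col < 1L] <- 1L
  region_col[region_col > 6L] <- 6L
  labels <- matrix(rep(region_col, each = nrow(mask$pixels)),
                   nrow(mask$pixels), ncol(mask$pixels))
  labels[!mask$pixels] <- 0L
  structure(list(labels = labels, region_names = witelson_regions(),
                 fractions = fractions, mask = mask),
            class = "witelson_parcellation")
}

#' @export
print.witelson_parcellation <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0], nbins = 6)
  cat("<witelson_parcellation>\n")
  for (k in 1:6)
    cat(sprintf("  %-18s %6d px\n", x$region_names[k], counts[k]))
  invisible(x)
}

#' Region pixel counts of a parcellation
#' @param parcellation a `witelson_parcellation`.
#' @return named integer vector of per-region foreground pixel counts.
#' @export
region_pixel_counts <- function(parcellation) {
  counts <- tabulate(parcellation$labels[parcellation$labels > 0], nbins = 6)
  names(counts) <- parcellation$region_names
  counts
}

#' Build the 92-circle callosal sampling template
#'
#' Constructs the ROI template used to sample intensity maps over the
#' corpus callosum: the AP extent of the mask is divided into `grid[1]`
#' columns of equal width, the local dorsoventral extent of the mask within
#' each column is split into `grid[2]` equal rows, and a circle is inscribed
#' in each resulting cell (radius = `circle_ratio` x half the shorter cell
#' side). The default 46 x 2 grid yields the 92 circular ROIs. Because all
#' cell bounds are fractions of the mask's own extents, the template adapts
#' to individual callosal size.
#'
#' ROIs are ordered anterior to posterior, dorsal row before ventral row
#' within a column. Each ROI is labeled with the Witelson macro-region of
#' its circle center.
#'
#' @param parcellation a `witelson_parcellation` from [parcellate_witelson()].
#' @param grid integer length-2 `(columns, rows)`; the product must be 92.
#' @param circle_ratio circle diameter as a fraction of the shorter cell
#'   side, in (0, 1].
#' @return an object of class `roi_template`: a data.frame with one row per
#'   ROI (`roi`, `column`, `row`, `cx`, `cy`, `radius`, `x0`, `x1`, `y0`,
#'   `y1`, `region`) ordered by ROI index, carrying the mask and the cached
#'   per-ROI pixel index lists as attributes.
#' @export
build_roi_template <- function(parcellation, grid = c(46L, 2L), circle_ratio = 0.8) {
  if (!inherits(parcellation, "witelson_parcellation"))
    stop_callomap("parcellation must come from parcellate_witelson()",
                  "callomap_input_error")
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 1) || prod(grid) != 92L)
    stop_callomap("grid must be (columns, rows) with columns * rows == 92",
                  "callomap_config_error")
  if (circle_ratio <= 0 || circle_ratio > 1)
    stop_callomap("circle_ratio must be in (0, 1]", "callomap_config_error")
  mask <- parcellation$mask
  px <- mask$pixels
  bb <- mask_bbox(mask)
  C <- grid[1]; R <- grid[2]
  x_origin <- bb$col_min - 1          # 0-based continuous AP origin
  col_w <- bb$width / C
  # grid column of each image column, by pixel-center position
  img_cols <- seq_len(ncol(px))
  gcol <- floor((img_cols - 0.5 - x_origin) / col_w) + 1L
  gcol[img_cols < bb$col_min | img_cols > bb$col_max] <- NA_integer_
  gcol[!is.na(gcol) & gcol > C] <- C   # posterior edge pixel-center rounding
  gcol[!is.na(gcol) & gcol < 1L] <- 1L

  rows_list <- vector("list", 92L)
  out <- data.frame(roi = integer(92), column = integer(92), row = integer(92),
                    cx = numeric(92), cy = numeric(92), radius = numeric(92),
                    x0 = numeric(92), x1 = numeric(92),
                    y0 = numeric(92), y1 = numeric(92),
                    region = character(92))
  k <- 0L
  for (i in seq_len(C)) {
    in_col <- which(!is.na(gcol) & gcol == i)
    rows_here <- which(rowSums(px[, in_col, drop = FALSE]) > 0)
    if (length(rows_here) == 0)
      stop_callomap(sprintf("grid column %d contains no mask pixels: mask is not a contiguous arch", i),
                    "callomap_template_error")
    y_top <- min(rows_here) - 1       # 0-based continuous
    y_bot <- max(rows_here)
    cell_h <- (y_bot - y_top) / R
    x0 <- x_origin + (i - 1) * col_w
    x1 <- x_origin + i * col_w
    for (r in seq_len(R)) {
      k <- k + 1L
      y0 <- y_top + (r - 1) * cell_h
      y1 <- y_top + r * cell_h
      cx <- (x0 + x1) / 2
      cy <- (y0 + y1) / 2
      radius <- circle_ratio * min(col_w, cell_h) / 2
      if (radius < 1)
        stop_callomap(sprintf("ROI %d circle radius %.2f px < 1 px: mask resolution too low",
                              k, radius), "callomap_resolution_error")
      cpx_row <- floor(cy) + 1L; cpx_col <- floor(cx) + 1L
      lab <- parcellation$labels[cpx_row, cpx_col]
      if (lab == 0L)
        stop_callomap(sprintf("ROI %d center (%.1f, %.1f) lies outside the mask", k, cx, cy),
                      "callomap_template_error")
      out[k, c("roi", "column", "row")] <- list(k, i, r)
      out[k, c("cx", "cy", "radius", "x0", "x1", "y0", "y1")] <-
        list(cx, cy, radius, x0, x1, y0, y1)
      out$region[k] <- parcellation$region_names[lab]
      rows_list[[k]] <- circle_pixel_index(px, cx, cy, radius)
      if (length(rows_list[[k]]) < 1)
        stop_callomap(sprintf("ROI %d contains no mask pixel centers", k),
                      "callomap_sampling_error")
    }
  }
  structure(out, class = c("roi_template", "data.frame"),
            mask = mask, grid = grid, circle_ratio = circle_ratio,
            fractions = parcellation$fractions, pixel_index = rows_list)
}

# Linear indices of mask pixels whose centers fall strictly inside a circle.
circle_pixel_index <- function(px, cx, cy, radius) {
  jr <- max(1L, floor(cx - radius) + 1L):min(ncol(px), ceiling(cx + radius))
  ir <- max(1L, floor(cy - radius) + 1L):min(nrow(px), ceiling(cy + radius))
  xs <- jr - 0.5; ys <- ir - 0.5
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  inside <- d2 < radius^2
  sub <- which(inside & px[ir, jr, drop = FALSE], arr.ind = TRUE)
  (jr[sub[, 2]] - 1L) * nrow(px) + ir[sub[, 1]]
}

#' Write / read an ROI template as CSV
#'
#' One row per ROI with index, circle center and radius, enclosing cell
#' bounds, macro-region label and grid position. Reading back restores the
#' data.frame but not the mask, so a template read from CSV samples all
#' in-circle pixels rather than in-circle mask pixels; rebuild from the mask
#' when exact mask-restricted sampling is required.
#'
#' @param template a `roi_template`.
#' @param path CSV file path.
#' @export
write_roi_template <- function(template, path) {
  write.csv(as.data.frame(template), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_template
#' @export
read_roi_template <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("roi", "column", "row", "cx", "cy", "radius",
              "x0", "x1", "y0", "y1", "region")
  if (!all(needed %in% names(df)))
    stop_callomap("not an ROI template CSV", "callomap_input_error")
  structure(df[order(df$roi), needed], class = c("roi_template", "data.frame"))
}
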