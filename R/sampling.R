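#' Construct a modality map
#'
#' A named intensity field, either 2D (an extracted slice or a histology
#' density map) or 3D (a sagittal volume whose first array dimension is the
#' sagittal axis).
#'
#' @param name modality name, e.g. `"T1wT2w"`, `"MWF"`, `"QSM"`, `"LFB"`.
#' @param data numeric matrix (2D) or 3D array `[sagittal, row, col]`.
#' @param spacing mm per voxel per axis: length 2 `(AP, DV)` for 2D, length
#'   3 `(sagittal, DV, AP)` for 3D.
#' @param midsagittal_index 1-based sagittal index of the midline slice (3D
#'   only); defaults to the middle slice.
#' @return object of class `modality_map`.
#' @export
modality_map <- function(name, data, spacing, midsagittal_index = NULL) {
  nd <- length(dim(data))
  if (!nd %in% 2:3)
    stop_callomap("data must be a 2D matrix or 3D array", "callomap_input_error")
  if (length(spacing) != nd || any(spacing <= 0))
    stop_callomap("spacing must be positive, one value per axis", "callomap_input_error")
  if (nd == 3 && is.null(midsagittal_index))
    midsagittal_index <- (dim(data)[1] + 1L) %/% 2L
  if (nd == 3 && (midsagittal_index < 1 || midsagittal_index > dim(data)[1]))
    stop_callomap("midsagittal_index outside the volume", "callomap_input_error")
  structure(list(name = name, data = data, spacing = as.numeric(spacing),
                 midsagittal_index = midsagittal_index),
            class = "modality_map")
}

#' @export
print.modality_map <- function(x, ...) {
  cat(sprintf("<modality_map> %s, %s, spacing %s mm\n", x$name,
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Read / write a sagittal volume as NIfTI-1
#'
#' The first array dimension is taken as the sagittal axis; voxel spacing
#' is read from (written to) `pixdim`.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param name modality name for the returned map.
#' @param midsagittal_index midline slice; default middle slice.
#' @return [read_modality_nifti()]: a `modality_map`.
#' @export
read_modality_nifti <- function(path, name = basename(path),
                                midsagittal_index = NULL) {
  img <- RNifti::readNifti(path)
  spc <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2) {
    modality_map(name, arr, spacing = spc[seq_len(2)])
  } else {
    modality_map(name, arr, spacing = spc[seq_len(3)],
                 midsagittal_index = midsagittal_index)
  }
}

#' @rdname read_modality_nifti
#' @param map a `modality_map`.
#' @export
write_modality_nifti <- function(map, path) {
  img <- RNifti::asNifti(map$data)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Average the two parasagittal slices of a volume
#'
#' Extracts the slices at `+offset_mm` and `-offset_mm` from the
#' midsagittal slice (indices `midsagittal_index +/- round(offset_mm /
#' sagittal_spacing)`) and returns their voxelwise mean as a 2D map. A
#' warning is emitted when the offset is more than 25% of a voxel away from
#' an exact slice position.
#'
#' @param map a 3D [modality_map()].
#' @param offset_mm lateral offset of each parasagittal slice, millimetres.
#' @return 2D `modality_map` named like the input.
#' @export
extract_parasagittal_average <- function(map, offset_mm = 4) {
  if (!inherits(map, "modality_map") || length(dim(map$data)) != 3)
    stop_callomap("map must be a 3D modality_map", "callomap_input_error")
  step <- offset_mm / map$spacing[1]
  k <- round(step)
  if (abs(step - k) > 0.25)
    warning(sprintf("offset %.1f mm is %.2f voxels; rounded to %d slices",
                    offset_mm, step, k))
  lo <- map$midsagittal_index - k
  hi <- map$midsagittal_index + k
  if (lo < 1 || hi > dim(map$data)[1])
    stop_callomap(sprintf("parasagittal slices %d/%d outside volume (1..%d)",
                          lo, hi, dim(map$data)[1]), "callomap_bounds_error")
  avg <- (map$data[lo, , ] + map$data[hi, , ]) / 2
  modality_map(map$name, avg, spacing = map$spacing[2:3])
}

#' Sample a 2D map over the 92-ROI template
#'
#' For each ROI, averages the pixels whose centers lie strictly inside the
#' circle (intersected with the mask when the template carries one). The
#' circle mean stands for the whole enclosing cell in rendered maps.
#'
#' @param map2d numeric matrix aligned with the template's mask, or a 2D
#'   `modality_map`.
#' @param template a [build_roi_template()] template.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return numeric length-92 vector of ROI values with attribute
#'   `n_pixels` (integer per-ROI pixel counts).
#' @export
sample_rois <- function(map2d, template, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (inherits(map2d, "modality_map")) map2d <- map2d$data
  if (!inherits(template, "roi_template"))
    stop_callomap("template must be a roi_template", "callomap_input_error")
  idx <- attr(template, "pixel_index")
  mask <- attr(template, "mask")
  if (!is.null(mask) && !identical(dim(map2d), dim(mask$pixels)))
    stop_callomap("map and template mask dimensions differ", "callomap_alignment_error")
  if (is.null(idx)) {
    px <- matrix(TRUE, nrow(map2d), ncol(map2d))
    idx <- lapply(seq_len(nrow(template)), function(k)
      circle_pixel_index(px, template$cx[k], template$cy[k], template$radius[k]))
  }
  stat_fun <- if (statistic == "mean") mean else stats::median
  vals <- numeric(length(idx))
  npix <- integer(length(idx))
  for (k in seq_along(idx)) {
    v <- map2d[idx[[k]]]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop_callomap(sprintf("ROI %d: no pixels inside circle", k),
                    "callomap_sampling_error")
    vals[k] <- stat_fun(v)
    npix[k] <- length(v)
  }
  structure(vals, n_pixels = npix)
}

#' Assemble an ROI sample table
#'
#' Long-format table holding one value per modality, sample and ROI,
#' flagged with its normalization state.
#'
#' @param df data.frame with columns `modality`, `sample`, `roi`, `region`,
#'   `value`, `n_pixels`.
#' @param units_state `"raw"` or `"rescaled_1_7"`.
#' @return object of class `roi_sample_table` (a data.frame).
#' @export
roi_sample_table <- function(df, units_state = c("raw", "rescaled_1_7")) {
  units_state <- match.arg(units_state)
  needed <- c("modality", "sample", "roi", "region", "value", "n_pixels")
  if (!all(needed %in% names(df)))
    stop_callomap(paste("roi_sample_table needs columns:",
                        paste(needed, collapse = ", ")), "callomap_input_error")
  if (any(is.na(df$value)))
    stop_callomap("roi_sample_table must not contain missing values",
                  "callomap_input_error")
  structure(as.data.frame(df[needed]), units_state = units_state,
            class = c("roi_sample_table", "data.frame"))
}

#' @export
print.roi_sample_table <- function(x, ...) {
  cat(sprintf("<roi_sample_table> %s units; %d modalities, %d rows\n",
              attr(x, "units_state"), length(unique(x$modality)), nrow(x)))
  NextMethod()
}

#' Units state of an ROI sample table
#' @param table a `roi_sample_table`.
#' @export
units_state <- function(table) attr(table, "units_state")

#' Rescale each modality's ROI values to the 1-7 arbitrary-unit scale
#'
#' Per modality, applies the min-max affine map of that modality's pooled
#' ROI values (all samples together) onto `[1, 7]`, the arbitrary-unit
#' scale on which all modalities are reported. Being affine per modality,
#' the rescale leaves every Pearson correlation between modalities
#' unchanged. Already-rescaled tables are returned unchanged.
#'
#' @param table a [roi_sample_table()] in raw units.
#' @return the table with `units_state = "rescaled_1_7"`.
#' @export
rescale_to_units <- function(table) {
  if (!inherits(table, "roi_sample_table"))
    stop_callomap("table must be a roi_sample_table", "callomap_input_error")
  if (identical(attr(table, "units_state"), "rescaled_1_7"))
    return(table)
  for (m in unique(table$modality)) {
    sel <- table$modality == m
    v <- table$value[sel]
    rng <- range(v)
    if (diff(rng) == 0)
      stop_callomap(sprintf("modality %s is constant: cannot rescale to 1-7", m),
                    "callomap_degenerate_scale_error")
    table$value[sel] <- 1 + 6 * (v - rng[1]) / (rng[2] - rng[1])
  }
  attr(table, "units_state") <- "rescaled_1_7"
  table
}

#' Write / read an ROI sample table as CSV
#' @param table a `roi_sample_table`.
#' @param path CSV file path.
#' @export
write_roi_table <- function(table, path) {
  df <- as.data.frame(table)
  df$units_state <- attr(table, "units_state")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  state <- unique(df$units_state) %||% "raw"
  df$units_state <- NULL
  roi_sample_table(df, units_state = state[1])
}
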