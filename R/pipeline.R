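#' Configure an end-to-end phantom pipeline run
#'
#' @param phantom a [phantom_spec()] describing the synthetic input; real
#'   histology/MRI data enter the workflow through the stage functions
#'   ([read_mask_png()], [read_modality_nifti()], [sample_rois()], ...) or
#'   the command-line subcommands instead.
#' @param fractions Witelson boundary fractions.
#' @param grid ROI grid `(columns, rows)`, product 92.
#' @param offset_mm parasagittal sampling offset.
#' @param pairs modality pairs to correlate.
#' @param out_dir output directory; `NULL` disables file output.
#' @param seed overrides the phantom spec's seed when given.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            fractions = witelson_fractions(),
                            grid = c(46L, 2L), offset_mm = 4,
                            pairs = list(c("T1wT2w", "LFB"), c("MWF", "LFB"),
                                         c("T1wT2w", "MWF")),
                            out_dir = NULL, seed = NULL) {
  if (!inherits(phantom, "phantom_spec"))
    stop_callomap("phantom must be a phantom_spec", "callomap_config_error")
  if (!is.null(seed)) phantom$seed <- as.integer(seed)
  structure(list(phantom = phantom, fractions = fractions, grid = grid,
                 offset_mm = offset_mm, pairs = pairs, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full phantom-to-statistics pipeline
#'
#' Generates the phantom (mask, sections, volumes), parcellates, builds the
#' 92-ROI template, runs optical-density conversion and parasagittal
#' sampling, rescales all modalities to the 1-7 arbitrary-unit scale, and
#' computes the pairwise Pearson correlations and (for multi-sample
#' modalities) the cross-region/cross-sample variance decomposition. With
#' an output directory set, writes the template and ROI tables (CSV),
#' correlation and variance results (JSON), colour-coded ROI maps and
#' scatter plots (PNG), a provenance sidecar naming the config hash and
#' seed, and a markdown report. Deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `dataset`, `table` (rescaled),
#'   `correlations`, `variance` (list per multi-sample modality), `config`,
#'   `files` (written paths, if any).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_callomap("config must be a pipeline_config", "callomap_config_error")
  stage <- function(name, expr) {
    tryCatch(expr, callomap_error = function(e) {
      stop_callomap(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                    class(e)[1])
    })
  }
  mask <- stage("phantom_mask", generate_mask(config$phantom))
  dataset <- stage("phantom_images",
                   generate_modality_images(mask, config$phantom,
                                            fractions = config$fractions,
                                            grid = config$grid))
  raw <- stage("sampling", sample_dataset(dataset, offset_mm = config$offset_mm))
  table <- stage("rescale", rescale_to_units(raw))
  correlations <- stage("correlate", correlate_all(table, config$pairs))
  multi <- names(which(tapply(table$sample, table$modality,
                              function(s) length(unique(s))) >= 2))
  variance <- lapply(multi, function(m) variance_decomposition(table, m))
  names(variance) <- multi

  files <- character(0)
  if (!is.null(config$out_dir)) {
    files <- write_pipeline_outputs(config, dataset, table, correlations, variance)
  }
  structure(list(dataset = dataset, table = table, correlations = correlations,
                 variance = variance, config = config, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$correlations, row.names = FALSE)
  for (v in x$variance) print(v)
  invisible(x)
}

write_pipeline_outputs <- function(config, dataset, table, correlations, variance) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(config = file.path(dir, "config.yaml"))
  yaml::write_yaml(serialize_config(config), files[["config"]])
  cfg_hash <- unname(tools::md5sum(files[["config"]]))

  files[["template"]] <- file.path(dir, "template.csv")
  write_roi_template(dataset$template, files[["template"]])
  files[["truth"]] <- file.path(dir, "truth_table.csv")
  write_roi_table(dataset$truth, files[["truth"]])
  files[["table"]] <- file.path(dir, "roi_table.csv")
  write_roi_table(table, files[["table"]])
  files[["correlations"]] <- file.path(dir, "correlations.json")
  jsonlite::write_json(correlations, files[["correlations"]],
                       dataframe = "rows", digits = NA, pretty = TRUE)
  files[["variance"]] <- file.path(dir, "variance.json")
  jsonlite::write_json(lapply(variance, unclass), files[["variance"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (m in unique(table$modality)) {
    vals <- modality_roi_means(table, m)
    p <- file.path(dir, sprintf("roi_map_%s.png", m))
    render_roi_map(dataset$template, vals, file = p)
    files[[paste0("roi_map_", m)]] <- p
  }
  for (pr in config$pairs) {
    p <- file.path(dir, sprintf("scatter_%s_vs_%s.png", pr[1], pr[2]))
    plot_correlation(table, pr, file = p)
    files[[paste0("scatter_", pr[1], "_", pr[2])]] <- p
  }
  files[["report"]] <- file.path(dir, "report.md")
  write_report(files[["report"]], config, dataset, correlations, variance, cfg_hash)
  files[["provenance"]] <- file.path(dir, "provenance.json")
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = config$phantom$seed,
         package = "callomap", version = as.character(packageVersion("callomap")),
         outputs = as.list(files)),
    files[["provenance"]], auto_unbox = TRUE, pretty = TRUE)
  files
}

serialize_config <- function(config) {
  ph <- config$phantom
  list(phantom = list(
         arch_length_px = ph$arch_length_px,
         base_thickness_px = ph$base_thickness_px,
         genu_factor = ph$genu_factor, splenium_factor = ph$splenium_factor,
         n_samples = ph$n_samples, sample_jitter_sd = ph$sample_jitter_sd,
         pixel_spacing_mm = ph$pixel_spacing_mm,
         sagittal_spacing_mm = ph$sagittal_spacing_mm, seed = ph$seed,
         modalities = lapply(ph$modalities, function(m)
           list(name = m$name, kind = m$kind, u = m$u, v = m$v,
                noise_sd = m$noise_sd, jitter_sd = m$jitter_sd,
                n_samples = m$n_samples))),
       fractions = config$fractions, grid = as.integer(config$grid),
       offset_mm = config$offset_mm,
       pairs = lapply(config$pairs, as.character))
}

#' Read a phantom pipeline configuration from YAML
#'
#' Inverse of the `config.yaml` written by [run_pipeline()]; also accepts a
#' hand-written file with the same layout (a `phantom:` block with an
#' optional `modalities:` list, plus `fractions`, `grid`, `offset_mm`,
#' `pairs`).
#'
#' @param path YAML file.
#' @param out_dir,seed forwarded to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom %||% list()
  mods <- if (is.null(ph$modalities)) default_modality_profiles() else
    lapply(ph$modalities, function(m)
      phantom_modality(m$name, m$kind, u = unlist(m$u), v = unlist(m$v),
                       noise_sd = m$noise_sd, jitter_sd = m$jitter_sd,
                       n_samples = m$n_samples))
  spec <- phantom_spec(
    arch_length_px = ph$arch_length_px %||% 460,
    base_thickness_px = ph$base_thickness_px %||% 42,
    genu_factor = ph$genu_factor %||% 1.4,
    splenium_factor = ph$splenium_factor %||% 1.7,
    modalities = mods,
    n_samples = ph$n_samples %||% 3,
    sample_jitter_sd = ph$sample_jitter_sd %||% 0.10,
    pixel_spacing_mm = ph$pixel_spacing_mm %||% 0.5,
    sagittal_spacing_mm = ph$sagittal_spacing_mm %||% 4,
    seed = ph$seed %||% 1L)
  pipeline_config(
    phantom = spec,
    fractions = unlist(y$fractions) %||% witelson_fractions(),
    grid = as.integer(unlist(y$grid) %||% c(46L, 2L)),
    offset_mm = y$offset_mm %||% 4,
    pairs = if (is.null(y$pairs)) list(c("T1wT2w", "LFB"), c("MWF", "LFB"),
                                       c("T1wT2w", "MWF"))
            else lapply(y$pairs, as.character),
    out_dir = out_dir, seed = seed)
}

#' Render a colour-coded 92-ROI map
#'
#' Paints each ROI's enclosing cell with the 7-bin colour of its value on
#' the 1-7 scale (the circle value extended to the surrounding cell),
#' draws cell outlines, thicker boundaries between Witelson macro-regions,
#' and a white background.
#'
#' @param template a [build_roi_template()] template.
#' @param values numeric length-92, on the `[1, 7]` scale, in ROI order.
#' @param file optional PNG path.
#' @return RGB array `h x w x 3`, invisibly when `file` is given.
#' @export
render_roi_map <- function(template, values, file = NULL) {
  if (length(values) != nrow(template))
    stop_callomap(sprintf("expected %d values, got %d", nrow(template),
                          length(values)), "callomap_contract_error")
  if (min(values) < 1 - 1e-9 || max(values) > 7 + 1e-9)
    stop_callomap("values must lie on the [1, 7] scale", "callomap_contract_error")
  mask <- attr(template, "mask")
  H <- if (!is.null(mask)) nrow(mask$pixels) else ceiling(max(template$y1)) + 8L
  W <- if (!is.null(mask)) ncol(mask$pixels) else ceiling(max(template$x1)) + 8L
  img <- array(1, dim = c(H, W, 3))
  pal <- t(col2rgb(density_palette())) / 255
  bins <- density_bins(pmin(pmax(values, 1), 7))
  for (k in seq_len(nrow(template))) {
    rr <- (floor(template$y0[k]) + 1L):min(H, ceiling(template$y1[k]))
    cc <- (floor(template$x0[k]) + 1L):min(W, ceiling(template$x1[k]))
    for (ch in 1:3) img[rr, cc, ch] <- pal[bins[k], ch]
    img[range(rr), cc, ] <- img[range(rr), cc, ] * 0.75   # cell outline
    img[rr, range(cc), ] <- img[rr, range(cc), ] * 0.75
  }
  # black boundary between macro-regions
  for (k in 2:nrow(template)) {
    if (template$column[k] != template$column[k - 1] &&
        template$region[k] != template$region[k - 1]) {
      cc <- floor(template$x0[k]) + 1L
      rr <- (floor(min(template$y0[template$column == template$column[k]])) + 1L):
            min(H, ceiling(max(template$y1[template$column == template$column[k]])))
      img[rr, cc, ] <- 0
    }
  }
  if (!is.null(file)) {
    png::writePNG(img, file)
    return(invisible(img))
  }
  img
}

write_report <- function(path, config, dataset, correlations, variance, cfg_hash) {
  lines <- c(
    "# Callosal cross-modal myelin mapping report", "",
    sprintf("- config hash: `%s`", cfg_hash),
    sprintf("- seed: %d", config$phantom$seed),
    sprintf("- ROIs: %d; grid %s; Witelson fractions %s",
            nrow(dataset$template), paste(config$grid, collapse = "x"),
            paste(format(config$fractions, digits = 3), collapse = ", ")),
    sprintf("- modalities: %s",
            paste(vapply(dataset$modalities, function(m)
              sprintf("%s (%s, %d sample(s))", m$name, m$kind,
                      length(m$samples)), ""), collapse = "; ")),
    "", "## Pairwise Pearson correlations (92 ROIs, 1-7 a.u.)", "",
    "| pair | r | r^2 | p (two-sided) | n |",
    "|---|---|---|---|---|",
    sprintf("| %s vs %s | %.3f | %.3f | %.3g | %d |",
            correlations$modality_a, correlations$modality_b,
            correlations$r, correlations$r_squared,
            correlations$p_two_sided, correlations$n))
  if (length(variance)) {
    lines <- c(lines, "", "## Variance decomposition", "",
               "| modality | SD across regions | SD across samples | samples |",
               "|---|---|---|---|",
               vapply(variance, function(v)
                 sprintf("| %s | %.3f | %.3f | %d |", v$modality,
                         v$sd_across_regions, v$sd_across_samples, v$n_samples),
                 ""))
  }
  writeLines(lines, path)
  invisible(path)
}
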