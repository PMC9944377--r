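#' Describe one phantom modality
#'
#' A modality is defined by a strictly positive piecewise-linear
#' antero-posterior intensity profile over the normalized AP coordinate
#' `u` in `[0, 1]` (0 = anterior tip, 1 = posterior tip) plus a noise
#' level and, for multi-sample modalities, a per-sample profile
#' perturbation.
#'
#' @param name modality name.
#' @param kind `"histology"` (rendered as an RGB stained section, higher
#'   profile = darker blue; profile values must lie in `[0, 1]` as myelin
#'   fractions), `"volume"` (3-slice sagittal volume at the midline and
#'   +/- one sagittal spacing), or `"map"` (single 2D intensity map).
#' @param u,v profile knots: positions in `[0, 1]` and strictly positive
#'   values; evaluated by linear interpolation, constant beyond the end
#'   knots.
#' @param noise_sd additive Gaussian noise SD per pixel, in profile units;
#'   `NULL` defaults to 5% of the profile range (or 5% of the profile mean
#'   for flat profiles).
#' @param jitter_sd SD of the smooth per-sample profile perturbation, in
#'   profile units; `NULL` defaults to 10% of the profile range for
#'   multi-sample modalities and 0 otherwise.
#' @param n_samples number of samples of this modality; `NULL` defers to
#'   the phantom-level `n_samples` for histology modalities and 1 for the
#'   others (mirroring multi-sample post-mortem sections vs single
#'   averaged MRI maps).
#' @return list of class `phantom_modality`.
#' @export
phantom_modality <- function(name, kind = c("histology", "volume", "map"),
                             u, v, noise_sd = NULL, jitter_sd = NULL,
                             n_samples = NULL) {
  kind <- match.arg(kind)
  if (length(u) != length(v) || length(u) < 2 || is.unsorted(u, strictly = TRUE))
    stop_callomap(sprintf("%s: profile knots must be strictly increasing, >= 2", name),
                  "callomap_config_error")
  if (any(v <= 0))
    stop_callomap(sprintf("%s: profile must be strictly positive", name),
                  "callomap_config_error")
  if (kind == "histology" && any(v > 1))
    stop_callomap(sprintf("%s: histology profiles are myelin fractions in (0, 1]", name),
                  "callomap_config_error")
  if (!is.null(noise_sd) && noise_sd < 0)
    stop_callomap(sprintf("%s: noise_sd must be >= 0", name), "callomap_config_error")
  structure(list(name = name, kind = kind, u = as.numeric(u), v = as.numeric(v),
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 n_samples = n_samples),
            class = "phantom_modality")
}

profile_eval <- function(mod, u) approx(mod$u, mod$v, xout = u, rule = 2)$y

profile_range <- function(mod) {
  rng <- diff(range(mod$v))
  if (rng == 0) rng <- abs(mean(mod$v))
  rng
}

modality_noise_sd <- function(mod) mod$noise_sd %||% (0.05 * profile_range(mod))

#' Default phantom modality profiles
#'
#' Piecewise-linear antero-posterior profiles qualitatively emulating the
#' reported regional patterns of the three myelin-sensitive modalities on
#' the midsagittal corpus callosum: LFB optical density low in the
#' rostrum/genu and high posteriorly (isthmus/splenium); the T1w/T2w ratio
#' highest in the rostrum/genu with a posterior-midbody trough and partial
#' splenial recovery; and myelin water fraction elevated at the genu,
#' dipping in the anterior body and rising through the posterior midbody
#' and splenium. These shapes give the negative T1w/T2w-vs-LFB and positive
#' MWF-vs-LFB correlation structure characteristic of the cross-modal
#' comparison.
#'
#' @return named list of [phantom_modality()] objects (`LFB`, `T1wT2w`,
#'   `MWF`).
#' @export
default_modality_profiles <- function() {
  list(
    LFB = phantom_modality("LFB", "histology",
                           u = c(0, 0.2, 0.5, 0.75, 1),
                           v = c(0.30, 0.35, 0.55, 0.72, 0.68)),
    T1wT2w = phantom_modality("T1wT2w", "volume",
                              u = c(0, 0.15, 0.5, 0.68, 0.88, 1),
                              v = c(1.60, 1.52, 1.15, 1.02, 1.28, 1.22)),
    MWF = phantom_modality("MWF", "volume",
                           u = c(0, 0.1, 0.3, 0.55, 0.8, 1),
                           v = c(0.125, 0.13, 0.085, 0.13, 0.155, 0.145))
  )
}

#' Specify a callosal phantom
#'
#' Parameters of the synthetic midsagittal phantom: an arch-shaped
#' (half-annulus) callosal mask with a parametric thickness profile
#' (thicker genu-like anterior and splenium-like posterior bulbs), a set of
#' modalities with antero-posterior intensity profiles, additive noise, and
#' per-sample profile perturbation for multi-sample modalities.
#'
#' @param arch_length_px antero-posterior extent of the arch in pixels
#'   (>= 200 so the default 46-column grid keeps >= 4 px per column).
#' @param base_thickness_px arch thickness at the mid-body, pixels.
#' @param genu_factor,splenium_factor thickness multipliers of the anterior
#'   and posterior bulbs relative to the mid-body.
#' @param modalities named list of [phantom_modality()]; default
#'   [default_modality_profiles()].
#' @param n_samples default number of samples for histology modalities.
#' @param sample_jitter_sd default per-sample perturbation SD as a fraction
#'   of each modality's profile range (used where a modality does not set
#'   its own `jitter_sd`).
#' @param pixel_spacing_mm in-plane spacing, mm per pixel (AP and DV).
#' @param sagittal_spacing_mm slice spacing of generated volumes, mm; the
#'   two outer slices of the 3-slice volumes sit at +/- this offset from
#'   the midline.
#' @param seed integer seed governing all phantom randomness.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(arch_length_px = 460, base_thickness_px = 42,
                         genu_factor = 1.4, splenium_factor = 1.7,
                         modalities = default_modality_profiles(),
                         n_samples = 3, sample_jitter_sd = 0.10,
                         pixel_spacing_mm = 0.5, sagittal_spacing_mm = 4,
                         seed = 1L) {
  if (arch_length_px < 200)
    stop_callomap("arch_length_px must be >= 200", "callomap_config_error")
  if (base_thickness_px < 8)
    stop_callomap("base_thickness_px must be >= 8", "callomap_config_error")
  if (genu_factor <= 0 || splenium_factor <= 0)
    stop_callomap("bulb factors must be positive", "callomap_config_error")
  if (n_samples < 1)
    stop_callomap("n_samples must be >= 1", "callomap_config_error")
  if (sample_jitter_sd < 0)
    stop_callomap("sample_jitter_sd must be >= 0", "callomap_config_error")
  if (!length(modalities) || !all(vapply(modalities, inherits, TRUE, "phantom_modality")))
    stop_callomap("modalities must be a list of phantom_modality objects",
                  "callomap_config_error")
  names(modalities) <- vapply(modalities, `[[`, "", "name")
  structure(list(arch_length_px = arch_length_px,
                 base_thickness_px = base_thickness_px,
                 genu_factor = genu_factor, splenium_factor = splenium_factor,
                 modalities = modalities, n_samples = n_samples,
                 sample_jitter_sd = sample_jitter_sd,
                 pixel_spacing_mm = pixel_spacing_mm,
                 sagittal_spacing_mm = sagittal_spacing_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Arch thickness (px) as a function of normalized AP position.
arch_thickness <- function(spec, u) {
  ku <- c(0, 0.12, 0.45, 0.70, 0.88, 1)
  kv <- c(spec$genu_factor, 1, 0.8, 0.85, spec$splenium_factor,
          0.9 * spec$splenium_factor)
  spec$base_thickness_px * approx(ku, kv, xout = u, rule = 2)$y
}

#' Generate the phantom callosal mask
#'
#' Rasterizes a concave-down half-annulus arch whose thickness follows the
#' spec's profile: a thicker anterior (genu-like) and posterior
#' (splenium-like) bulb around a thinner mid-body. Only the
#' antero-posterior topology matters for the sampling template, not
#' anatomical fidelity. Deterministic: the mask depends only on the shape
#' parameters.
#'
#' @param spec a [phantom_spec()].
#' @return a [callosal_mask()] with one 4-connected component.
#' @export
generate_mask <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop_callomap("spec must be a phantom_spec", "callomap_config_error")
  margin <- 8
  L <- spec$arch_length_px
  half <- L / 2
  # The annulus is slightly larger than the arch and truncated vertically at
  # +/- half, so the anterior/posterior ends are straight caps: every image
  # column then holds one solid vertical span and the AP extent is exact.
  R <- half + L / 23
  cx <- margin + half
  cy <- margin + R
  W <- ceiling(L + 2 * margin)
  H <- ceiling(R + 2 * margin)
  xs <- seq_len(W) - 0.5
  ys <- seq_len(H) - 0.5
  dx <- matrix(xs - cx, H, W, byrow = TRUE)
  dy <- matrix(cy - ys, H, W)             # >= 0 above the center row
  d <- sqrt(dx^2 + dy^2)
  u <- pmin(pmax((dx + half) / L, 0), 1)
  tt <- matrix(arch_thickness(spec, u), H, W)
  px <- dy >= 0 & abs(dx) <= half & d <= R & d >= (R - tt)
  callosal_mask(px, spacing = rep(spec$pixel_spacing_mm, 2))
}

# Normalized AP coordinate of each image column (pixel centers, mask bbox).
mask_ap_coord <- function(mask) {
  bb <- mask_bbox(mask)
  pmin(pmax((seq_len(ncol(mask$pixels)) - bb$col_min + 0.5) / bb$width, 0), 1)
}

# Smooth zero-mean random field over u with pointwise SD exactly `sd`:
# a 3-harmonic random Fourier series (stationary variance).
sample_jitter_fun <- function(sd) {
  K <- 3
  a <- rnorm(K); b <- rnorm(K)
  function(u) {
    out <- 0
    for (k in seq_len(K))
      out <- out + a[k] * cos(2 * pi * k * u) + b[k] * sin(2 * pi * k * u)
    sd * out / sqrt(K)
  }
}

hist_stain_rgb <- c(40, 40, 120) / 255  # blue-dominant full-stain colour

# Render a myelin-fraction matrix as an 8-bit-quantized RGB stain image.
render_stain <- function(frac, mask_px) {
  H <- nrow(frac); W <- ncol(frac)
  img <- array(1, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- (1 - frac) + frac * hist_stain_rgb[ch]
    plane[!mask_px] <- 1
    img[, , ch] <- round(plane * 255) / 255
  }
  img
}

#' Generate phantom modality images with known ground truth
#'
#' For every modality in the spec, renders its antero-posterior profile
#' over the mask and emits, per sample: an RGB stained-section image
#' (histology kind; higher myelin fraction = darker, blue-dominant pixels),
#' a 3-slice sagittal volume (volume kind; slices at the midline and +/-
#' one sagittal spacing, profile + independent noise per slice, background
#' 0), or a plain 2D map. Multi-sample modalities perturb the shared
#' profile per sample with a smooth random field of SD `jitter_sd`.
#' The returned dataset carries the noise-free, jitter-free per-ROI profile
#' means as ground truth, computed on the same 92-ROI template the pipeline
#' uses. Fully deterministic given the spec (which includes the seed).
#'
#' @param mask the mask from [generate_mask()] (or any [callosal_mask()]).
#' @param spec the [phantom_spec()].
#' @param fractions,grid forwarded to [parcellate_witelson()] and
#'   [build_roi_template()].
#' @return list of class `phantom_dataset`: `spec`, `mask`, `parcellation`,
#'   `template`, `truth` (a [roi_sample_table()] with `sample = "truth"`),
#'   and `modalities` (per modality: `kind`, `samples` = list of images,
#'   `noise_sd`, `jitter_sd`).
#' @export
generate_modality_images <- function(mask, spec,
                                     fractions = witelson_fractions(),
                                     grid = c(46L, 2L)) {
  if (!inherits(spec, "phantom_spec"))
    stop_callomap("spec must be a phantom_spec", "callomap_config_error")
  if (!inherits(mask, "callosal_mask"))
    stop_callomap("mask must be a callosal_mask", "callomap_input_error")
  parc <- parcellate_witelson(mask, fractions)
  template <- build_roi_template(parc, grid = grid)
  pix_idx <- attr(template, "pixel_index")
  u_col <- mask_ap_coord(mask)
  H <- nrow(mask$pixels); W <- ncol(mask$pixels)
  mask_px <- mask$pixels

  set.seed(spec$seed)
  truth_rows <- list()
  out_mods <- list()
  for (mod in spec$modalities) {
    prof_col <- profile_eval(mod, u_col)
    PM <- matrix(prof_col, H, W, byrow = TRUE)
    truth <- vapply(pix_idx, function(ix) mean(PM[ix]), 0)
    truth_rows[[mod$name]] <- data.frame(
      modality = mod$name, sample = "truth", roi = template$roi,
      region = template$region, value = truth,
      n_pixels = vapply(pix_idx, length, 0L), stringsAsFactors = FALSE)

    n_s <- mod$n_samples %||%
      (if (mod$kind == "histology") spec$n_samples else 1L)
    jit_sd <- mod$jitter_sd %||%
      (if (n_s > 1) spec$sample_jitter_sd * profile_range(mod) else 0)
    noise_sd <- modality_noise_sd(mod)
    n_mask <- sum(mask_px)

    samples <- vector("list", n_s)
    for (s in seq_len(n_s)) {
      jit <- if (jit_sd > 0) sample_jitter_fun(jit_sd) else function(u) 0
      SP <- PM + matrix(jit(u_col), H, W, byrow = TRUE)
      if (mod$kind == "histology") {
        frac <- SP
        if (noise_sd > 0)
          frac[mask_px] <- frac[mask_px] + rnorm(n_mask, 0, noise_sd)
        frac <- pmin(pmax(frac, 0), 1)
        samples[[s]] <- render_stain(frac, mask_px)
      } else if (mod$kind == "volume") {
        vol <- array(0, dim = c(3, H, W))
        for (sl in 1:3) {
          slice <- SP
          if (noise_sd > 0)
            slice[mask_px] <- slice[mask_px] + rnorm(n_mask, 0, noise_sd)
          slice[slice < 0] <- 0
          slice[!mask_px] <- 0
          vol[sl, , ] <- slice
        }
        samples[[s]] <- vol
      } else {
        m2 <- SP
        if (noise_sd > 0)
          m2[mask_px] <- m2[mask_px] + rnorm(n_mask, 0, noise_sd)
        m2[m2 < 0] <- 0
        m2[!mask_px] <- 0
        samples[[s]] <- m2
      }
    }
    out_mods[[mod$name]] <- list(name = mod$name, kind = mod$kind,
                                 samples = samples, noise_sd = noise_sd,
                                 jitter_sd = jit_sd)
  }
  truth <- roi_sample_table(do.call(rbind, truth_rows), units_state = "raw")
  structure(list(spec = spec, mask = mask, parcellation = parc,
                 template = template, truth = truth, modalities = out_mods),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d modalities over a %d-px-long arch, %d ROIs\n",
              length(x$modalities), x$spec$arch_length_px, nrow(x$template)))
  for (m in x$modalities)
    cat(sprintf("  %-8s %-9s %d sample(s), noise_sd %.4g, jitter_sd %.4g\n",
                m$name, m$kind, length(m$samples), m$noise_sd, m$jitter_sd))
  invisible(x)
}

#' Run the sampling pipeline over a phantom dataset
#'
#' Applies the measurement chain each modality would see on real data:
#' histology images go through grey conversion ([rgb_to_grey()]) and the
#' 1-7 optical-density rescale ([grey_to_density()]); volumes through
#' parasagittal extraction and averaging ([extract_parasagittal_average()]);
#' then every resulting 2D map is sampled over the 92-ROI template
#' ([sample_rois()]).
#'
#' @param dataset a [generate_modality_images()] result.
#' @param offset_mm parasagittal offset for volume modalities.
#' @return a raw-units [roi_sample_table()] (histology values are on the
#'   1-7 density scale at this stage; MRI values in native units — apply
#'   [rescale_to_units()] before cross-modal statistics).
#' @export
sample_dataset <- function(dataset, offset_mm = NULL) {
  if (!inherits(dataset, "phantom_dataset"))
    stop_callomap("dataset must be a phantom_dataset", "callomap_input_error")
  offset_mm <- offset_mm %||% dataset$spec$sagittal_spacing_mm
  template <- dataset$template
  mask <- dataset$mask
  spc <- dataset$spec
  rows <- list()
  for (m in dataset$modalities) {
    for (s in seq_along(m$samples)) {
      img <- m$samples[[s]]
      map2d <- switch(m$kind,
        histology = grey_to_density(rgb_to_grey(img), mask),
        volume = extract_parasagittal_average(
          modality_map(m$name, img,
                       spacing = c(spc$sagittal_spacing_mm,
                                   spc$pixel_spacing_mm, spc$pixel_spacing_mm),
                       midsagittal_index = 2L),
          offset_mm = offset_mm)$data,
        map = img)
      vals <- sample_rois(map2d, template)
      rows[[paste(m$name, s)]] <- data.frame(
        modality = m$name, sample = s, roi = template$roi,
        region = template$region, value = as.numeric(vals),
        n_pixels = attr(vals, "n_pixels"), stringsAsFactors = FALSE)
    }
  }
  roi_sample_table(do.call(rbind, rows), units_state = "raw")
}

#' Construct a modality pair with an exact ground-truth ROI correlation
#'
#' Builds two strictly positive piecewise-linear profiles whose noise-free
#' per-ROI truth vectors on the given template have Pearson correlation
#' exactly `rho`. Because per-ROI truth means are linear in the profile,
#' the target profile is obtained by Gram-Schmidt mixing of two basis
#' profiles (a linear ramp and one sine period) in ROI space, then shifted
#' and scaled into a positive range (an affine change that leaves the
#' correlation untouched). Used to validate correlation recovery through
#' the full pipeline.
#'
#' @param rho target correlation in (-1, 1).
#' @param template the [build_roi_template()] the phantom will be sampled
#'   on.
#' @param mask the template's mask.
#' @param kind modality kind for the returned pair.
#' @param noise_frac per-pixel noise SD as a fraction of each profile's
#'   range.
#' @return list with `modality_a`, `modality_b` ([phantom_modality()]
#'   objects named `"A"` and `"B"`) and `truth_r` (the achieved truth
#'   correlation, equal to `rho` up to floating point).
#' @export
make_correlated_pair <- function(rho, template, mask, kind = "map",
                                 noise_frac = 0.05) {
  if (abs(rho) >= 1)
    stop_callomap("rho must be strictly inside (-1, 1)", "callomap_config_error")
  knots <- seq(0, 1, length.out = 41)
  p1 <- 0.3 + 0.5 * knots
  p2 <- sin(2 * pi * knots)
  u_col <- mask_ap_coord(mask)
  pix_idx <- attr(template, "pixel_index")
  truth_of <- function(kv) {
    pm <- matrix(approx(knots, kv, xout = u_col, rule = 2)$y,
                 nrow(mask$pixels), ncol(mask$pixels), byrow = TRUE)
    vapply(pix_idx, function(ix) mean(pm[ix]), 0)
  }
  t1 <- truth_of(p1); t2 <- truth_of(p2)
  # standardized t1 and the standardized residual of t2 on t1, expressed as
  # profile mixtures (truth is linear in the profile)
  s1 <- sd(t1)
  a_prof <- p1 / s1                      # truth: (t1 - m1)/s1 + const
  beta <- cov(t2, t1) / stats::var(t1)
  resid <- t2 - beta * t1
  sc <- sd(resid)
  c_prof <- (p2 - beta * p1) / sc
  mix <- rho * a_prof + sqrt(1 - rho^2) * c_prof
  rngm <- range(mix)
  B <- if (diff(rngm) > 0) 0.5 / diff(rngm) else 1
  prof_b <- 0.2 + B * (mix - rngm[1])
  mod_a <- phantom_modality("A", kind, u = knots, v = p1)
  mod_b <- phantom_modality("B", kind, u = knots, v = prof_b)
  mod_a$noise_sd <- noise_frac * profile_range(mod_a)
  mod_b$noise_sd <- noise_frac * profile_range(mod_b)
  tb <- truth_of(prof_b)
  list(modality_a = mod_a, modality_b = mod_b, truth_r = cor(t1, tb))
}

#' Write a phantom dataset to disk
#'
#' Emits the mask (PNG), histology sections (PNG), volumes (NIfTI-1 with
#' voxel spacing in `pixdim`), 2D maps (NIfTI-1), the ground-truth ROI
#' table (CSV) and the template (CSV).
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_phantom <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mask = file.path(dir, "mask.png"))
  write_mask_png(dataset$mask, paths[["mask"]])
  spc <- dataset$spec
  for (m in dataset$modalities) {
    for (s in seq_along(m$samples)) {
      if (m$kind == "histology") {
        p <- file.path(dir, sprintf("%s_sample%d.png", m$name, s))
        png::writePNG(m$samples[[s]], p)
      } else {
        p <- file.path(dir, sprintf("%s_sample%d.nii.gz", m$name, s))
        spacing <- if (m$kind == "volume")
          c(spc$sagittal_spacing_mm, spc$pixel_spacing_mm, spc$pixel_spacing_mm)
        else rep(spc$pixel_spacing_mm, 2)
        mm <- modality_map(m$name, m$samples[[s]], spacing = spacing,
                           midsagittal_index = if (m$kind == "volume") 2L else NULL)
        write_modality_nifti(mm, p)
      }
      paths[[sprintf("%s_%d", m$name, s)]] <- p
    }
  }
  paths[["truth"]] <- file.path(dir, "truth_table.csv")
  write_roi_table(dataset$truth, paths[["truth"]])
  paths[["template"]] <- file.path(dir, "template.csv")
  write_roi_template(dataset$template, paths[["template"]])
  invisible(paths)
}
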