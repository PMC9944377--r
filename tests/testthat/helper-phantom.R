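# Shared fixtures built in code. The small arch (300 px) keeps the heavier
# simulation-based tests fast; geometry is identical in kind to the default.

.fixture_cache <- new.env(parent = emptyenv())

small_arch_spec <- function(seed = 1L, modalities = default_modality_profiles(),
                            ...) {
  phantom_spec(arch_length_px = 300, base_thickness_px = 30,
               modalities = modalities, seed = seed, ...)
}

small_arch_mask <- function() {
  if (is.null(.fixture_cache$mask))
    .fixture_cache$mask <- generate_mask(small_arch_spec())
  .fixture_cache$mask
}

small_arch_template <- function() {
  if (is.null(.fixture_cache$template)) {
    parc <- parcellate_witelson(small_arch_mask())
    .fixture_cache$template <- build_roi_template(parc)
  }
  .fixture_cache$template
}

rect_mask <- function(h = 60, w = 460) callosal_mask(matrix(TRUE, h, w))

# Foreground bounding box computed independently of package internals.
mask_bbox_public <- function(m) {
  cols <- which(colSums(m$pixels) > 0)
  rows <- which(rowSums(m$pixels) > 0)
  list(col_min = min(cols), col_max = max(cols),
       row_min = min(rows), row_max = max(rows),
       width = diff(range(cols)) + 1L, height = diff(range(rows)) + 1L)
}

# From-definition product-moment correlation, independent of stats::cor.
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Brute-force ROI mean: enumerate every image pixel, keep centers strictly
# inside the circle (and inside the mask), average.
brute_roi_mean <- function(map2d, mask_px, cx, cy, radius) {
  acc <- c()
  for (i in seq_len(nrow(map2d))) {
    for (j in seq_len(ncol(map2d))) {
      if (!mask_px[i, j]) next
      if ((j - 0.5 - cx)^2 + (i - 0.5 - cy)^2 < radius^2)
        acc <- c(acc, map2d[i, j])
    }
  }
  mean(acc)
}

roi_vector <- function(table, modality, sample = NULL) {
  sub <- table[table$modality == modality, ]
  if (!is.null(sample)) sub <- sub[sub$sample == sample, ]
  sub$value[order(sub$roi)]
}
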