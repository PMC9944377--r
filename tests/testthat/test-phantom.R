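test_that("generated masks are single-component arches of the requested extent", {
  spec <- small_arch_spec()
  m <- generate_mask(spec)
  expect_s3_class(m, "callosal_mask")
  expect_equal(max(EBImage::bwlabel(m$pixels * 1L)), 1)
  bb <- mask_bbox_public(m)
  expect_lte(abs(bb$width - 300), 2)

  m2 <- generate_mask(phantom_spec(arch_length_px = 300, base_thickness_px = 30,
                                   seed = 99L))
  expect_identical(m$pixels, m2$pixels)  # shape ignores the seed

  # concave-down with thicker ends: the mid-body column span is thinner than
  # the splenium-side span
  spans <- apply(m$pixels, 2, sum)
  mid <- spans[round(ncol(m$pixels) / 2)]
  expect_gt(max(spans), mid)
})

test_that("mask construction rejects invalid shape parameters", {
  expect_error(phantom_spec(arch_length_px = 150), class = "callomap_config_error")
  expect_error(phantom_spec(n_samples = 0), class = "callomap_config_error")
  expect_error(phantom_modality("x", "map", u = c(0, 1), v = c(0, 1)),
               class = "callomap_config_error")  # non-positive profile
  expect_error(phantom_modality("x", "map", u = c(0, 1), v = c(1, 2),
                                noise_sd = -1), class = "callomap_config_error")
})

test_that("phantom generation is byte-deterministic given the spec", {
  spec <- small_arch_spec(seed = 42L)
  m <- generate_mask(spec)
  d1 <- generate_modality_images(m, spec)
  d2 <- generate_modality_images(m, spec)
  expect_identical(d1$modalities, d2$modalities)
  expect_identical(d1$truth$value, d2$truth$value)
  d3 <- generate_modality_images(m, small_arch_spec(seed = 43L))
  expect_false(identical(d1$modalities$LFB$samples[[1]],
                         d3$modalities$LFB$samples[[1]]))
})

test_that("zero-noise constant profiles propagate exactly to voxels and truths", {
  mods <- list(
    phantom_modality("flatvol", "volume", u = c(0, 1), v = c(2.5, 2.5),
                     noise_sd = 0),
    phantom_modality("flatmap", "map", u = c(0, 1), v = c(2.5, 2.5),
                     noise_sd = 0))
  spec <- small_arch_spec(modalities = mods)
  m <- generate_mask(spec)
  ds <- generate_modality_images(m, spec)
  vol <- ds$modalities$flatvol$samples[[1]]
  for (sl in 1:3) expect_true(all(vol[sl, , ][m$pixels] == 2.5))
  expect_true(all(vol[1, , ][!m$pixels] == 0))
  expect_true(all(ds$truth$value == 2.5))
})

test_that("a strictly increasing AP profile yields strictly increasing ROI truths", {
  mods <- list(phantom_modality("ramp", "map", u = c(0, 1), v = c(1, 3),
                                noise_sd = 0))
  spec <- small_arch_spec(modalities = mods)
  m <- generate_mask(spec)
  ds <- generate_modality_images(m, spec)
  tr <- ds$truth
  for (r in 1:2) {
    v <- tr$value[ds$template$row == r][order(ds$template$column[ds$template$row == r])]
    expect_true(all(diff(v) > 0))
  }
})

test_that("identical zero-noise profiles give pipeline-end r = 1", {
  mods <- list(
    phantom_modality("a", "map", u = c(0, 0.5, 1), v = c(1, 2, 1.5), noise_sd = 0),
    phantom_modality("b", "map", u = c(0, 0.5, 1), v = c(1, 2, 1.5), noise_sd = 0))
  spec <- small_arch_spec(modalities = mods)
  ds <- generate_modality_images(generate_mask(spec), spec)
  tab <- rescale_to_units(sample_dataset(ds))
  res <- correlate_all(tab, list(c("a", "b")))
  expect_equal(res$r, 1)
})

test_that("stained sections are darker where the myelin fraction is higher", {
  mods <- list(phantom_modality("LFB", "histology", u = c(0, 1),
                                v = c(0.1, 0.9), noise_sd = 0, n_samples = 1))
  spec <- small_arch_spec(modalities = mods)
  m <- generate_mask(spec)
  ds <- generate_modality_images(m, spec)
  img <- ds$modalities$LFB$samples[[1]]
  grey <- rgb_to_grey(img)
  bb <- mask_bbox_public(m)
  left <- grey[, bb$col_min + 5][m$pixels[, bb$col_min + 5]]
  right <- grey[, bb$col_max - 5][m$pixels[, bb$col_max - 5]]
  expect_gt(mean(left), mean(right))      # anterior lighter (less myelin)
  expect_true(all(img[, , 3] >= img[, , 1]))  # blue-dominant stain
})

test_that("correlated profile pairs hit their target truth correlation exactly", {
  tpl <- small_arch_template()
  m <- small_arch_mask()
  for (rho in c(-0.8, -0.3, 0, 0.5, 0.8)) {
    pair <- make_correlated_pair(rho, tpl, m)
    expect_lt(abs(pair$truth_r - rho), 1e-10)
    expect_true(all(pair$modality_b$v > 0))
  }
})

test_that("per-sample jitter perturbs samples around the shared profile", {
  mods <- list(phantom_modality("j", "map", u = c(0, 1), v = c(1, 1),
                                noise_sd = 0, jitter_sd = 0.2, n_samples = 5))
  spec <- small_arch_spec(modalities = mods)
  ds <- generate_modality_images(generate_mask(spec), spec)
  tab <- sample_dataset(ds)
  vals <- sapply(1:5, function(s) roi_vector(tab, "j", s))
  expect_gt(sd(vals[1, ]), 0)                      # samples differ
  expect_lt(abs(mean(vals) - 1), 0.2)              # centred on the profile
})
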