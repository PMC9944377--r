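test_that("parasagittal slice indices follow midline +/- round(offset/spacing)", {
  vol <- array(0, dim = c(80, 4, 5))
  vol[36, , ] <- 2; vol[44, , ] <- 4
  mm <- modality_map("t", vol, spacing = c(1, 1, 1), midsagittal_index = 40)
  out <- extract_parasagittal_average(mm, offset_mm = 4)
  expect_true(all(out$data == 3))           # mean of slices 36 and 44
  # identical slices -> the slice itself
  vol[36, , ] <- 5; vol[44, , ] <- 5
  mm <- modality_map("t", vol, spacing = c(1, 1, 1), midsagittal_index = 40)
  expect_true(all(extract_parasagittal_average(mm, 4)$data == 5))
})

test_that("parasagittal extraction warns on rounding and errors out of bounds", {
  vol <- array(1, dim = c(5, 3, 3))
  mm <- modality_map("t", vol, spacing = c(4, 1, 1), midsagittal_index = 3)
  expect_silent(extract_parasagittal_average(mm, 4))      # exactly 1 slice
  expect_warning(extract_parasagittal_average(mm, 6))     # 1.5 voxels
  expect_error(extract_parasagittal_average(mm, 12),
               class = "callomap_bounds_error")
})

test_that("ROI sampling reproduces constants and inherits gradients", {
  tpl <- small_arch_template()
  m <- small_arch_mask()
  const <- matrix(3.25, nrow(m$pixels), ncol(m$pixels))
  v <- sample_rois(const, tpl)
  expect_equal(as.numeric(v), rep(3.25, 92))
  # map = AP pixel coordinate on a rectangle -> strictly increasing per row
  rm <- rect_mask(60, 460)
  rtpl <- build_roi_template(parcellate_witelson(rm))
  apmap <- matrix(rep(seq_len(460) - 0.5, each = 60), 60, 460)
  v <- sample_rois(apmap, rtpl)
  for (r in 1:2) {
    vr <- v[rtpl$row == r][order(rtpl$column[rtpl$row == r])]
    expect_true(all(diff(vr) > 0))
  }
})

test_that("ROI means match a brute-force pixel enumeration", {
  set.seed(5)
  tpl <- small_arch_template()
  m <- small_arch_mask()
  img <- matrix(rnorm(length(m$pixels)), nrow(m$pixels))
  v <- sample_rois(img, tpl)
  for (k in c(1, 17, 46, 92)) {
    expect_equal(v[k],
                 brute_roi_mean(img, m$pixels, tpl$cx[k], tpl$cy[k], tpl$radius[k]),
                 tolerance = 1e-12)
  }
  expect_equal(sum(attr(v, "n_pixels")), sum(lengths(attr(tpl, "pixel_index"))))
  expect_lte(sum(attr(v, "n_pixels")), sum(m$pixels))   # mask consistency
})

test_that("flipping map and mask together reverses the ROI vector column-wise", {
  set.seed(6)
  rm <- rect_mask(60, 460)
  tpl <- build_roi_template(parcellate_witelson(rm))
  img <- matrix(rnorm(60 * 460), 60, 460)
  v <- sample_rois(img, tpl)
  flipped <- img[, 460:1]
  tplf <- build_roi_template(parcellate_witelson(rect_mask(60, 460)))
  vf <- sample_rois(flipped, tplf)
  # ROI (column i, row r) of the flipped map equals ROI (47 - i, row r)
  perm <- (46 - tpl$column) * 2 + tpl$row
  expect_equal(as.numeric(vf[perm]), as.numeric(v), tolerance = 1e-12)
})

test_that("rescale_to_units maps each modality affinely onto [1, 7]", {
  df <- data.frame(modality = "m", sample = 1, roi = 1:3, region = "splenium",
                   value = c(0, 0.5, 1), n_pixels = 5L)
  tab <- roi_sample_table(df)
  out <- rescale_to_units(tab)
  expect_equal(out$value, c(1, 4, 7))
  expect_equal(units_state(out), "rescaled_1_7")
  expect_identical(rescale_to_units(out), out)   # idempotent
  cdf <- df; cdf$value <- 2
  expect_error(rescale_to_units(roi_sample_table(cdf)),
               class = "callomap_degenerate_scale_error")
})

test_that("the 1-7 rescale leaves Pearson correlations unchanged", {
  set.seed(8)
  spec <- small_arch_spec(seed = 8L)
  ds <- generate_modality_images(small_arch_mask(), spec)
  raw <- sample_dataset(ds)
  scaled <- rescale_to_units(raw)
  pairs <- list(c("T1wT2w", "LFB"), c("MWF", "LFB"), c("T1wT2w", "MWF"))
  r_raw <- correlate_all(raw, pairs)$r
  r_scaled <- correlate_all(scaled, pairs)$r
  expect_equal(r_raw, r_scaled, tolerance = 1e-10)
})

test_that("ROI tables survive a CSV round trip with their units state", {
  spec <- small_arch_spec()
  ds <- generate_modality_images(small_arch_mask(), spec)
  tab <- rescale_to_units(sample_dataset(ds))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(tab, path)
  back <- read_roi_table(path)
  expect_equal(units_state(back), "rescaled_1_7")
  expect_equal(back$value, tab$value, tolerance = 1e-9)
})

test_that("NIfTI round trip preserves volume data and voxel spacing", {
  vol <- array(rnorm(3 * 6 * 7), dim = c(3, 6, 7))
  mm <- modality_map("t", vol, spacing = c(4, 0.5, 0.5), midsagittal_index = 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_modality_nifti(mm, path)
  back <- read_modality_nifti(path, name = "t", midsagittal_index = 2)
  expect_equal(as.array(back$data), vol, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, c(4, 0.5, 0.5), tolerance = 1e-6)
})
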