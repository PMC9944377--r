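test_that("rectangle parcellation places region boundaries at the expected columns", {
  m <- callosal_mask(matrix(TRUE, 20, 100))
  p <- parcellate_witelson(m)   # default fractions 1/6, 1/3, 1/2, 2/3, 4/5
  col_label <- apply(p$labels, 2, function(col) unique(col[col > 0]))
  expect_true(all(lengths(col_label) == 1))        # label constant per column
  col_label <- unlist(col_label)
  # first 0-based column of regions 2..6
  starts <- which(diff(col_label) != 0)
  expect_equal(starts, c(17, 33, 50, 67, 80))
  expect_equal(sort(unique(col_label)), 1:6)
})

test_that("boundary pixels are assigned to the posterior region (anterior-closed)", {
  m <- callosal_mask(matrix(TRUE, 10, 99))
  # width 99: column centers u = (j - 0.5)/99; fraction 1/3 hits u exactly
  # at j = 33.5 -> no exact tie there, so craft one: u of col 34 = 33.5/99
  p <- parcellate_witelson(m, fractions = c(0.1, 33.5/99, 0.5, 2/3, 0.8))
  col_label <- apply(p$labels, 2, function(col) unique(col[col > 0]))
  expect_equal(col_label[[34]], 3)   # exactly on the boundary -> posterior
  expect_equal(col_label[[33]], 2)
})

test_that("parcellation of a valid mask yields six non-empty ordered regions", {
  p <- parcellate_witelson(small_arch_mask())
  counts <- region_pixel_counts(p)
  expect_length(counts, 6)
  expect_true(all(counts > 0))
  expect_named(counts, c("rostrum_genu", "rostral_body", "anterior_midbody",
                         "posterior_midbody", "isthmus", "splenium"))
  # partition: region counts sum to the mask pixel count
  expect_equal(sum(counts), sum(small_arch_mask()$pixels))
})

test_that("parcellation rejects invalid inputs", {
  expect_error(parcellate_witelson(small_arch_mask(),
                                   fractions = c(0.5, 0.4, 0.6, 0.7, 0.8)),
               class = "callomap_config_error")
  expect_error(parcellate_witelson(small_arch_mask(), fractions = c(0.2, 0.4)),
               class = "callomap_config_error")
  two_blobs <- matrix(FALSE, 10, 30)
  two_blobs[2:4, 2:4] <- TRUE; two_blobs[7:9, 20:25] <- TRUE
  expect_error(callosal_mask(two_blobs), class = "callomap_input_error")
  expect_error(parcellate_witelson(callosal_mask(matrix(TRUE, 8, 4))),
               class = "callomap_degenerate_mask_error")
})

test_that("the template contains exactly 92 ROIs and is deterministic", {
  tpl <- small_arch_template()
  expect_equal(nrow(tpl), 92)
  expect_equal(tpl$roi, 1:92)
  tpl2 <- build_roi_template(parcellate_witelson(small_arch_mask()))
  expect_equal(as.data.frame(tpl), as.data.frame(tpl2))
})

test_that("ROI labels cover all six regions and are AP-ordered", {
  tpl <- small_arch_template()
  expect_setequal(unique(tpl$region), witelson_regions())
  idx <- match(tpl$region, witelson_regions())
  for (r in 1:2)
    expect_true(!is.unsorted(idx[tpl$row == r][order(tpl$column[tpl$row == r])]))
})

test_that("template geometry invariants hold: tiling, containment, centers in mask", {
  tpl <- small_arch_template()
  m <- small_arch_mask()
  # circles inside their cells
  expect_true(all(tpl$cx - tpl$radius >= tpl$x0 - 1e-9))
  expect_true(all(tpl$cx + tpl$radius <= tpl$x1 + 1e-9))
  expect_true(all(tpl$cy - tpl$radius >= tpl$y0 - 1e-9))
  expect_true(all(tpl$cy + tpl$radius <= tpl$y1 + 1e-9))
  # cells of the two rows in a column share a boundary, columns tile the extent
  for (i in unique(tpl$column)) {
    sub <- tpl[tpl$column == i, ]
    expect_equal(sub$y1[sub$row == 1], sub$y0[sub$row == 2])
    expect_equal(sub$x0[1], sub$x0[2])
  }
  expect_equal(length(unique(tpl$column)), 46)
  # circle centers land on mask pixels
  ok <- mapply(function(cx, cy) m$pixels[floor(cy) + 1, floor(cx) + 1],
               tpl$cx, tpl$cy)
  expect_true(all(ok))
})

test_that("rectangle template matches the closed-form center arithmetic", {
  m <- rect_mask(60, 460)
  tpl <- build_roi_template(parcellate_witelson(m))
  for (k in 1:92) {
    i <- tpl$column[k]; r <- tpl$row[k]
    expect_lt(abs(tpl$cx[k] - (i - 0.5) / 46 * 460), 1)
    expect_lt(abs(tpl$cy[k] - (if (r == 1) 15 else 45)), 1)
  }
})

test_that("template is invariant to 2x mask scaling (labels and columns)", {
  m1 <- small_arch_mask()
  tpl1 <- small_arch_template()
  big <- m1$pixels %x% matrix(TRUE, 2, 2)
  tpl2 <- build_roi_template(parcellate_witelson(callosal_mask(big)))
  expect_equal(tpl2$region, tpl1$region)
  expect_equal(tpl2$column, tpl1$column)
  expect_equal(tpl2$row, tpl1$row)
})

test_that("template construction rejects bad grids and low resolution", {
  p <- parcellate_witelson(small_arch_mask())
  expect_error(build_roi_template(p, grid = c(10, 2)),
               class = "callomap_config_error")
  expect_error(build_roi_template(p, circle_ratio = 0),
               class = "callomap_config_error")
  tiny <- parcellate_witelson(callosal_mask(matrix(TRUE, 20, 100)))
  expect_error(build_roi_template(tiny), class = "callomap_resolution_error")
})

test_that("templates survive a CSV round trip", {
  tpl <- small_arch_template()
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_template(tpl, path)
  back <- read_roi_template(path)
  expect_equal(back$region, tpl$region)
  expect_equal(back$cx, tpl$cx, tolerance = 1e-9)
  expect_equal(nrow(back), 92)
})
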