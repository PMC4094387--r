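test_that("measure_cells computes areas, means and centroids on fixtures", {
  lm <- disk_label_map(64, 64, c(30, 30), 10)
  lm <- make_ring_masks(lm, 0, 3)
  area_expected <- sum(lm$nuclei == 1L)

  const <- matrix(0.42, 64, 64)
  cells <- measure_cells(lm, const, const)
  expect_equal(cells$nuclear_area_px2, area_expected)
  expect_equal(cells$aec_nuclear_mean, 0.42)
  expect_equal(cells$aec_cyto_mean, 0.42)
  expect_equal(cells$centroid_row, 30, tolerance = 0.01)

  # empty map -> empty table; mismatched dims -> error
  empty <- ihcquant:::new_label_map(matrix(0L, 8, 8))
  expect_equal(nrow(measure_cells(empty, matrix(0, 8, 8), matrix(0, 8, 8))), 0)
  expect_error(measure_cells(lm, matrix(0, 8, 8), const), "dimensions")

  # a cell with no ring gets NA, not 0
  lm_noring <- disk_label_map(64, 64, c(30, 30), 10)
  cells2 <- measure_cells(lm_noring, const, const)
  expect_true(is.na(cells2$aec_cyto_mean))
})

test_that("measured nuclear intensity tracks ground truth on a noiseless slide", {
  s <- simulate_slide(small_params(n_cells = 60, noise_sd = 0))
  res <- analyze_slide(s$rgb)
  m <- match_to_truth(res$labelmap, s$nucleus_truth_labels)
  ok <- m$detected_id > 0
  meas <- res$cells$aec_nuclear_mean[match(m$detected_id[ok], res$cells$cell_id)]
  truth <- s$cells$true_nuclear_mean_od[m$truth_id[ok]]
  expect_gte(cor(meas, truth), 0.95)
})

test_that("gates select closed intervals and preserve the table", {
  cells <- data.frame(cell_id = 1:5, nuclear_area_px2 = c(10, 20, 30, 40, 50),
                      hx_nuclear_mean = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      aec_nuclear_mean = 1:5, aec_cyto_mean = c(1, NA, 3, 4, 5),
                      centroid_row = 1:5, centroid_col = 1:5)
  g_all <- gate("all", "nuclear_area_px2", c(10, 50))
  out <- apply_gate(cells, g_all)
  expect_true(all(out$gate_all))                    # boundaries included
  expect_equal(out$cell_id, cells$cell_id)          # order preserved
  expect_equal(out[names(cells)], cells)            # original columns untouched

  g2 <- gate("mid", "nuclear_area_px2", c(20, 40), "hx_nuclear_mean", c(0.2, 0.3))
  out2 <- apply_gate(cells, g2)
  expect_equal(which(out2$gate_mid), 2:3)

  expect_error(apply_gate(cells, gate("bad", "no_such_feature", c(0, 1))),
               "unknown")
  expect_equal(nrow(apply_gate(cells[0, ], g_all)), 0)

  # idempotent and order-independent across disjoint flags
  twice <- apply_gate(apply_gate(cells, g_all), g_all)
  expect_equal(twice, out)
  ab <- apply_gate(apply_gate(cells, g_all), g2)
  ba <- apply_gate(apply_gate(cells, g2), g_all)
  expect_equal(sort(names(ab)), sort(names(ba)))
  expect_equal(ab$gate_all, ba$gate_all)
  expect_equal(ab$gate_mid, ba$gate_mid)
})

test_that("the hepatocyte area gate separates the two nuclear populations", {
  s <- simulate_slide(tissue_sim_params(n_cells = 250, seed = 61))
  lm <- truth_label_map(s)
  maps <- unmix(rgb_to_od(s$rgb), default_stain_matrix())
  cells <- measure_cells(lm, maps$hx, maps$aec)
  cells <- apply_gate(cells, hepatocyte_gate(cells))
  truth <- s$cells[match(cells$cell_id, s$cells$cell_id), ]
  hep_recovered <- mean(cells$gate_hepatocyte[!truth$is_stromal])
  stromal_leak <- mean(cells$gate_hepatocyte[truth$is_stromal])
  expect_gte(hep_recovered, 0.95)
  expect_lte(stromal_leak, 0.05)
})

test_that("forward and backward gating round-trip every cell", {
  s <- small_slide(n_cells = 30, seed = 71)
  res <- analyze_slide(s$rgb)
  cells <- res$cells
  bg <- backward_gate(cells, cells$cell_id)
  expect_equal(nrow(bg), nrow(cells))
  for (i in seq_len(nrow(bg))) {
    id <- forward_gate(res$labelmap, round(bg$centroid_row[i]),
                       round(bg$centroid_col[i]))
    expect_identical(id, bg$cell_id[i])
  }
  expect_error(forward_gate(res$labelmap, -1, 0), "outside")
  expect_error(backward_gate(cells, max(cells$cell_id) + 1L), "unknown")
  # background pixel -> NA
  bgpix <- which(res$labelmap$nuclei == 0L, arr.ind = TRUE)[1, ]
  expect_true(is.na(forward_gate(res$labelmap, bgpix[1] - 1, bgpix[2] - 1)))
})

test_that("ROI filtering keeps only cells with centroids inside the mask", {
  s <- small_slide(n_cells = 30, seed = 81)
  lm <- truth_label_map(s)
  cells <- measure_cells(lm, matrix(0, 192, 192), matrix(0, 192, 192))
  roi <- matrix(FALSE, 192, 192); roi[1:96, ] <- TRUE
  kept <- filter_roi(cells, roi)
  expect_true(all(kept$centroid_row < 96))
  expect_equal(nrow(kept), sum(cells$centroid_row < 95.5))
})
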