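test_that("blank and constructed hematoxylin maps segment as expected", {
  blank <- matrix(0, 48, 48)
  lm <- detect_nuclei(blank)
  expect_equal(length(lm$cell_ids), 0)

  # one disk of radius 10 above threshold -> exactly one label near center
  hx <- matrix(0, 64, 64)
  hx[disk_label_map(64, 64, c(32, 32), 10)$nuclei == 1L] <- 0.6
  lm1 <- detect_nuclei(hx)
  expect_equal(length(lm1$cell_ids), 1)
  cells <- measure_cells(lm1, hx, hx)
  expect_lt(abs(cells$centroid_row - 32), 1)
  expect_lt(abs(cells$centroid_col - 32), 1)

  # second disk below the discrimination area is discarded
  hx[disk_label_map(64, 64, c(10, 52), 2)$nuclei == 1L] <- 0.6
  lm2 <- detect_nuclei(hx, segmentation_params(discrimination_area_px2 = 40))
  expect_equal(length(lm2$cell_ids), 1)

  # discrimination gray removes dim objects
  hx2 <- matrix(0, 64, 64)
  hx2[disk_label_map(64, 64, c(20, 20), 8)$nuclei == 1L] <- 0.6
  hx2[disk_label_map(64, 64, c(45, 45), 8)$nuclei == 1L] <- 0.25
  lm3 <- detect_nuclei(hx2, segmentation_params(background_threshold = 0.1,
                                                discrimination_gray = 0.4))
  expect_equal(length(lm3$cell_ids), 1)
})

test_that("labels are contiguous from 1 and deterministic", {
  s <- small_slide(seed = 41)
  maps <- unmix(rgb_to_od(s$rgb), default_stain_matrix())
  lm_a <- detect_nuclei(maps$hx)
  lm_b <- detect_nuclei(maps$hx)
  expect_identical(lm_a$nuclei, lm_b$nuclei)
  expect_equal(lm_a$cell_ids, seq_along(lm_a$cell_ids))
})

test_that("ring masks form annuli disjoint from every nucleus", {
  lm <- disk_label_map(64, 64, c(32, 32), 10)
  rm3 <- make_ring_masks(lm, ring_gap_px = 0, ring_width_px = 3)
  ring <- rm3$rings == 1L
  expect_true(any(ring))
  expect_true(all(rm3$nuclei[ring] == 0L))
  # every ring pixel within (0, 3] of the disk boundary
  pos <- which(ring, arr.ind = TRUE)
  d <- sqrt((pos[, 1] - 1 - 32)^2 + (pos[, 2] - 1 - 32)^2) - 10
  expect_true(all(d > -1 & d <= 3 + 1))   # disk is pixelized; 1 px slack

  rm0 <- make_ring_masks(lm, ring_width_px = 0)
  expect_true(all(rm0$rings == 0L))
})

test_that("contested ring pixels go to the nearer nucleus, ties to the lower id", {
  h <- 40; w <- 60
  lab <- matrix(0L, h, w)
  mk <- function(center, r, id) {
    for (rr in 1:h) for (cc in 1:w)
      if ((rr - 1 - center[1])^2 + (cc - 1 - center[2])^2 <= r^2)
        lab[rr, cc] <<- id
  }
  mk(c(20, 20), 5, 1L); mk(c(20, 34), 5, 2L)   # boundaries 4 px apart
  lm <- ihcquant:::new_label_map(lab)
  rm <- make_ring_masks(lm, ring_gap_px = 0, ring_width_px = 5)

  # brute-force oracle: nearest nucleus pixel wins, ties -> lower id
  nuc1 <- which(lab == 1L, arr.ind = TRUE); nuc2 <- which(lab == 2L, arr.ind = TRUE)
  for (idx in which(rm$rings > 0L)) {
    rr <- (idx - 1L) %% h + 1L; cc <- (idx - 1L) %/% h + 1L
    d1 <- sqrt(min((nuc1[, 1] - rr)^2 + (nuc1[, 2] - cc)^2))
    d2 <- sqrt(min((nuc2[, 1] - rr)^2 + (nuc2[, 2] - cc)^2))
    expected <- if (d1 < d2 || (d1 == d2)) 1L else 2L
    expect_identical(rm$rings[rr, cc], expected)
  }
  expect_true(all(rm$rings[lab > 0L] == 0L))
})

test_that("segmentation on a default-noise slide matches ground truth", {
  s <- simulate_slide(tissue_sim_params(n_cells = 200, seed = 51))
  maps <- unmix(rgb_to_od(s$rgb), default_stain_matrix())
  lm <- detect_nuclei(maps$hx)
  expect_lt(abs(length(lm$cell_ids) - nrow(s$cells)) / nrow(s$cells), 0.05)
  m <- match_to_truth(lm, s$nucleus_truth_labels)
  expect_gte(median(m$iou), 0.7)
})
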