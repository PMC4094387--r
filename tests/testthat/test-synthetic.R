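test_that("parameter validation rejects out-of-range settings", {
  expect_error(tissue_sim_params(dosage_level = 3), "dosage_level")
  expect_error(tissue_sim_params(stromal_fraction = 1.2))
  expect_error(tissue_sim_params(hepatocyte_nucleus_radius_px = c(-1, 1)))
})

test_that("place_cells respects the stromal fraction and non-overlap", {
  p <- tissue_sim_params(n_cells = 1, stromal_fraction = 0, seed = 5,
                         image_height_px = 64, image_width_px = 64)
  one <- place_cells(p)
  expect_equal(nrow(one), 1)
  expect_false(one$is_stromal)

  p2 <- tissue_sim_params(n_cells = 200, stromal_fraction = 0.15, seed = 7)
  cells <- place_cells(p2)
  # stromal count within the central 99% interval of Binomial(200, 0.15)
  expect_gte(sum(cells$is_stromal), qbinom(0.005, 200, 0.15))
  expect_lte(sum(cells$is_stromal), qbinom(0.995, 200, 0.15))
  # no pair of nuclei closer than the radius sum + 1 px
  d <- as.matrix(dist(cells[, c("row", "col")]))
  rs <- outer(cells$radius_px, cells$radius_px, "+") + 1
  diag(d) <- Inf
  expect_true(all(d > rs | !is.finite(d)))
})

test_that("knockout slides have zero antigen in all non-stromal cells", {
  p <- small_params(dosage_level = 0)
  cells <- place_cells(p)
  expect_true(all(cells$true_antigen_level[!cells$is_stromal] == 0))
  expect_true(all(cells$true_antigen_level[cells$is_stromal] ==
                  p$stromal_antigen_level))
})

test_that("placement failure at impossible density raises a clear error", {
  p <- tissue_sim_params(image_height_px = 60, image_width_px = 60,
                         n_cells = 200, seed = 1)
  expect_error(place_cells(p), "density")
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- small_slide(seed = 21)
  s2 <- small_slide(seed = 21)
  expect_identical(s1$rgb, s2$rgb)
  expect_identical(s1$cells, s2$cells)
  s3 <- small_slide(seed = 22)
  expect_false(identical(s1$rgb, s3$rgb))
})

test_that("rendered slide is a valid 8-bit image with consistent truth labels", {
  s <- small_slide()
  expect_true(all(s$rgb >= 0 & s$rgb <= 255))
  expect_true(all(unique(as.integer(s$nucleus_truth_labels)) %in%
                  c(0L, s$cells$cell_id)))
  expect_equal(s$cells$cell_id, seq_len(nrow(s$cells)))
})

test_that("zero antigen and zero background renders an empty AEC channel", {
  p <- small_params(dosage_level = 0, background_od = 0,
                    stromal_antigen_level = 0, noise_sd = 0)
  s <- simulate_slide(p)
  maps <- unmix(rgb_to_od(s$rgb), default_stain_matrix())
  expect_lt(mean(maps$aec), 5e-3)   # below the 8-bit quantization floor
})

test_that("mean antigen level scales 2:1:0 across dosage levels", {
  means <- sapply(c(2, 1, 0), function(d) {
    cells <- place_cells(tissue_sim_params(n_cells = 400, dosage_level = d,
                                           stromal_fraction = 0, seed = 31))
    mean(cells$true_antigen_level)
  })
  expect_equal(means[1] / means[2], 2, tolerance = 0.1)
  expect_equal(means[3], 0)
})

test_that("ground-truth N/C ratio increases strictly with nuclear_fraction", {
  fr <- c(0.2, 0.4, 0.6, 0.8)
  ratios <- sapply(fr, function(f) {
    cells <- place_cells(small_params(nuclear_fraction = f, background_od = 0))
    mean(cells$true_nuclear_mean_od / cells$true_cyto_mean_od)
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("slide I/O round-trips the RGB image and truth table", {
  s <- small_slide(n_cells = 15)
  d <- withr::local_tempdir()
  paths <- write_slide(s, d, format = "png")
  expect_true(all(file.exists(paths)))
  back <- read_slide_rgb(paths[["rgb"]])
  expect_identical(back, s$rgb)
  tab <- read.csv(paths[["cells"]])
  expect_equal(tab$true_antigen_level, s$cells$true_antigen_level)
  lab <- tiff::readTIFF(paths[["labels"]])
  expect_identical(t(round(lab * 65535)), s$nucleus_truth_labels + 0)
})
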