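#' Virtual IHC slide simulation
#'
#' The simulator emulates a hematoxylin + AEC stained liver or lymphoma
#' section with full per-cell ground truth. Genotype enters only through
#' `dosage_level`: two functional alleles express 2 relative antigen units,
#' one allele 1 unit, the knockout 0 units, on top of a nonspecific
#' `background_od` present throughout the tissue. Parenchymal
#' ("hepatocyte-like") nuclei are large, stromal nuclei small, so a
#' nuclear-area gate has two populations to separate; stromal cells carry
#' their own antigen level independent of genotype (Kupffer/endothelial
#' cells stay positive in knockout livers). A tunable `nuclear_fraction`
#' splits each cell's antigen between nucleus and a perinuclear cytoplasmic
#' annulus, serving as the growth-hormone translocation surrogate.
#'
#' @name synthetic-tissue
NULL

#' Simulation parameters for a virtual slide
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param n_cells number of cells to place.
#' @param stromal_fraction probability that a cell is stromal (small nucleus).
#' @param hepatocyte_nucleus_radius_px numeric(2), mean and sd of the
#'   parenchymal nucleus radius in pixels.
#' @param stromal_nucleus_radius_px numeric(2), mean and sd of the stromal
#'   nucleus radius.
#' @param dosage_level relative antigen dosage: 2 (wildtype), 1
#'   (hemizygous) or 0 (knockout).
#' @param background_od nonspecific AEC optical density present everywhere
#'   in tissue compartments, in all genotypes.
#' @param nuclear_fraction fraction of each cell's specific antigen signal
#'   located in the nucleus (the rest sits in the cytoplasmic annulus);
#'   mock vs stimulated conditions differ only here.
#' @param heterogeneity_cv coefficient of variation of the per-cell
#'   log-normal antigen multiplier (cell-to-cell expression variability).
#' @param stromal_antigen_level fixed antigen level of stromal cells in
#'   relative units, independent of genotype.
#' @param noise_sd additive Gaussian intensity noise, 8-bit units.
#' @param od_per_unit AEC optical density rendered per relative antigen
#'   unit; an arbitrary scale constant that cancels in every ratio and
#'   ordinal quantity the package compares.
#' @param hx_od hematoxylin optical density inside nuclei.
#' @param cyto_width_px width of the true cytoplasmic annulus in pixels.
#' @param seed integer seed; the same (params, seed) pair yields
#'   bit-identical slides.
#' @return A validated `tissue_sim_params` list.
#' @export
tissue_sim_params <- function(image_height_px = 512, image_width_px = 512,
                              n_cells = 300, stromal_fraction = 0.15,
                              hepatocyte_nucleus_radius_px = c(7, 1),
                              stromal_nucleus_radius_px = c(3.5, 0.5),
                              dosage_level = 2, background_od = 0.05,
                              nuclear_fraction = 0.5, heterogeneity_cv = 0.3,
                              stromal_antigen_level = 1.0, noise_sd = 2,
                              od_per_unit = 0.3, hx_od = 0.6,
                              cyto_width_px = 6, seed = 1L) {
  p <- list(image_height_px = as.integer(image_height_px),
            image_width_px = as.integer(image_width_px),
            n_cells = as.integer(n_cells),
            stromal_fraction = stromal_fraction,
            hepatocyte_nucleus_radius_px = as.numeric(hepatocyte_nucleus_radius_px),
            stromal_nucleus_radius_px = as.numeric(stromal_nucleus_radius_px),
            dosage_level = dosage_level,
            background_od = background_od,
            nuclear_fraction = nuclear_fraction,
            heterogeneity_cv = heterogeneity_cv,
            stromal_antigen_level = stromal_antigen_level,
            noise_sd = noise_sd,
            od_per_unit = od_per_unit,
            hx_od = hx_od,
            cyto_width_px = as.integer(cyto_width_px),
            seed = as.integer(seed))
  stopifnot(p$image_height_px > 0, p$image_width_px > 0, p$n_cells > 0,
            p$stromal_fraction >= 0, p$stromal_fraction <= 1,
            p$nuclear_fraction >= 0, p$nuclear_fraction <= 1,
            length(p$hepatocyte_nucleus_radius_px) == 2,
            length(p$stromal_nucleus_radius_px) == 2,
            p$hepatocyte_nucleus_radius_px[1] > 0,
            p$stromal_nucleus_radius_px[1] > 0,
            p$heterogeneity_cv >= 0, p$background_od >= 0,
            p$noise_sd >= 0, p$stromal_antigen_level >= 0)
  if (!p$dosage_level %in% c(2, 1, 0))
    stop("dosage_level must be one of 2, 1, 0")
  class(p) <- "tissue_sim_params"
  p
}

# log-normal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Place non-overlapping cells with ground-truth antigen levels
#'
#' Samples cell centers by bounded rejection so that nuclei never overlap
#' (center distance exceeds the radius sum plus 1 px). Each cell is stromal
#' with probability `stromal_fraction` and then draws its nucleus radius
#' from the corresponding population. Parenchymal cells receive
#' `dosage_level` x LogNormal(mean 1, cv heterogeneity_cv) antigen units;
#' stromal cells a fixed `stromal_antigen_level`.
#'
#' Calls [set.seed()] with `params$seed`; for internal use by
#' [simulate_slide()] pass `use_seed = FALSE` to draw from the current RNG
#' stream.
#'
#' @param params a [tissue_sim_params()] object.
#' @param use_seed seed the RNG from `params$seed` (default TRUE).
#' @return data.frame of cell ground truth: `cell_id`, `row`, `col`,
#'   `radius_px`, `is_stromal`, `true_antigen_level`,
#'   `true_nuclear_mean_od`, `true_cyto_mean_od`.
#' @export
place_cells <- function(params, use_seed = TRUE) {
  stopifnot(inherits(params, "tissue_sim_params"))
  if (use_seed) set.seed(params$seed)
  n <- params$n_cells
  h <- params$image_height_px; w <- params$image_width_px
  margin <- params$cyto_width_px + 1

  is_stromal <- stats::runif(n) < params$stromal_fraction
  r <- numeric(n)
  r[!is_stromal] <- stats::rnorm(sum(!is_stromal),
                                 params$hepatocyte_nucleus_radius_px[1],
                                 params$hepatocyte_nucleus_radius_px[2])
  r[is_stromal] <- stats::rnorm(sum(is_stromal),
                                params$stromal_nucleus_radius_px[1],
                                params$stromal_nucleus_radius_px[2])
  r <- pmax(r, 1.5)

  rows <- numeric(n); cols <- numeric(n)
  max_tries <- 200L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      cand_r <- stats::runif(1, r[i] + margin, h - r[i] - margin)
      cand_c <- stats::runif(1, r[i] + margin, w - r[i] - margin)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        d2 <- (rows[j] - cand_r)^2 + (cols[j] - cand_c)^2
        ok <- all(d2 > (r[j] + r[i] + 1)^2)
      }
      if (ok) { rows[i] <- cand_r; cols[i] <- cand_c; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place cell ", i, " of ", n, " after ", max_tries,
           " tries: requested density too high for a ", h, "x", w, " image")
  }

  level <- numeric(n)
  level[!is_stromal] <- params$dosage_level *
    rlnorm_cv(sum(!is_stromal), params$heterogeneity_cv)
  level[is_stromal] <- params$stromal_antigen_level

  nuc_od <- params$background_od + params$od_per_unit * level * params$nuclear_fraction
  cyt_od <- params$background_od + params$od_per_unit * level * (1 - params$nuclear_fraction)

  data.frame(cell_id = seq_len(n), row = rows, col = cols, radius_px = r,
             is_stromal = is_stromal, true_antigen_level = level,
             true_nuclear_mean_od = nuc_od, true_cyto_mean_od = cyt_od)
}

# Pixel indices (linear, for an h x w matrix in row/col convention) of a
# disk, or of an annulus (r_in, r_out], centered at (row, col). 0-based
# pixel centers; a pixel belongs to the disk if its center lies within
# radius. Returns integer vector.
disk_pixels <- function(center_row, center_col, r_out, h, w, r_in = -1) {
  r0 <- max(0L, floor(center_row - r_out)); r1 <- min(h - 1L, ceiling(center_row + r_out))
  c0 <- max(0L, floor(center_col - r_out)); c1 <- min(w - 1L, ceiling(center_col + r_out))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  d2 <- (g$row - center_row)^2 + (g$col - center_col)^2
  keep <- d2 <= r_out^2 & d2 > r_in^2
  as.integer(g$row[keep] + h * g$col[keep] + 1L)
}

#' Render a virtual slide from placed cells
#'
#' Forward model, the exact inverse of the measurement chain: per pixel,
#' OD = hx_od x v_hx + aec_od x v_aec, with hematoxylin confined to nuclei
#' and the antigen split between nucleus (`nuclear_fraction` share) and a
#' concentric cytoplasmic annulus, plus `background_od` everywhere in
#' tissue (nuclei + annuli). RGB = round(255 x 10^(-OD)) with additive
#' Gaussian noise of sd `noise_sd`, clipped to \[0, 255\].
#'
#' @param cells data.frame from [place_cells()].
#' @param params a [tissue_sim_params()].
#' @param stains a `stain_matrix` (default [default_stain_matrix()]).
#' @param use_seed seed the RNG from `params$seed + 1` for the noise draw
#'   (default TRUE; [simulate_slide()] passes FALSE to use one stream).
#' @return A `virtual_slide`: list with `rgb` (H x W x 3 integer array),
#'   `nucleus_truth_labels` and `cyto_truth_labels` (H x W integer
#'   matrices), `cells` ground-truth table, and `params`.
#' @export
render_slide <- function(cells, params, stains = default_stain_matrix(),
                         use_seed = TRUE) {
  stopifnot(inherits(params, "tissue_sim_params"), inherits(stains, "stain_matrix"))
  if (use_seed) set.seed(params$seed + 1L)
  h <- params$image_height_px; w <- params$image_width_px

  hx_od <- matrix(0, h, w)
  aec_od <- matrix(0, h, w)
  nuc_lab <- matrix(0L, h, w)
  cyt_lab <- matrix(0L, h, w)

  for (i in seq_len(nrow(cells))) {
    nd <- disk_pixels(cells$row[i], cells$col[i], cells$radius_px[i], h, w)
    an <- disk_pixels(cells$row[i], cells$col[i],
                      cells$radius_px[i] + params$cyto_width_px, h, w,
                      r_in = cells$radius_px[i])
    an <- an[nuc_lab[an] == 0L & cyt_lab[an] == 0L]   # earlier cells keep contested pixels
    hx_od[nd] <- params$hx_od
    aec_od[nd] <- cells$true_nuclear_mean_od[i]
    aec_od[an] <- cells$true_cyto_mean_od[i]
    nuc_lab[nd] <- cells$cell_id[i]
    cyt_lab[an] <- cells$cell_id[i]
  }

  od <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    od[, , ch] <- hx_od * stains$v_hx[ch] + aec_od * stains$v_aec[ch]
  rgb <- 255 * 10^(-od)
  if (params$noise_sd > 0)
    rgb <- rgb + stats::rnorm(length(rgb), 0, params$noise_sd)
  rgb <- round(pmin(pmax(rgb, 0), 255))
  storage.mode(rgb) <- "integer"

  structure(list(rgb = rgb, nucleus_truth_labels = nuc_lab,
                 cyto_truth_labels = cyt_lab, cells = cells, params = params),
            class = "virtual_slide")
}

#' Simulate a complete virtual slide
#'
#' Convenience wrapper: seeds the RNG once from `params$seed`, places cells
#' and renders, so the whole slide is a deterministic function of
#' (params, seed).
#'
#' @inheritParams render_slide
#' @return A `virtual_slide`; see [render_slide()].
#' @export
simulate_slide <- function(params, stains = default_stain_matrix()) {
  set.seed(params$seed)
  cells <- place_cells(params, use_seed = FALSE)
  render_slide(cells, params, stains, use_seed = FALSE)
}

#' @export
print.virtual_slide <- function(x, ...) {
  cat("virtual_slide ", x$params$image_height_px, "x", x$params$image_width_px,
      ", ", nrow(x$cells), " cells (", sum(x$cells$is_stromal), " stromal), ",
      "dosage ", x$params$dosage_level, ", nuclear fraction ",
      x$params$nuclear_fraction, "\n", sep = "")
  invisible(x)
}

#' Write a virtual slide to disk
#'
#' Writes the RGB image as 8-bit TIFF or PNG, the nucleus truth labels as a
#' 16-bit single-channel TIFF, and the ground-truth cell table as CSV with
#' header `cell_id,row,col,radius_px,is_stromal,true_antigen_level,`
#' `true_nuclear_mean_od,true_cyto_mean_od`.
#'
#' @param slide a `virtual_slide`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @param format "tiff" or "png" for the RGB image.
#' @return Invisibly, the vector of paths written.
#' @export
write_slide <- function(slide, dir, prefix = "slide", format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"
  rgb_path <- file.path(dir, paste0(prefix, "_rgb.", ext))
  lab_path <- file.path(dir, paste0(prefix, "_nuclei.tif"))
  csv_path <- file.path(dir, paste0(prefix, "_cells.csv"))
  # EBImage images are (x = col, y = row); transpose each channel
  img <- EBImage::Image(aperm(slide$rgb, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(img, rgb_path, type = format, bits.per.sample = 8L)
  if (max(slide$nucleus_truth_labels) > 65535)
    stop("more than 65535 labels; cannot write 16-bit label TIFF")
  tiff::writeTIFF(t(slide$nucleus_truth_labels) / 65535, lab_path,
                  bits.per.sample = 16L)
  utils::write.csv(slide$cells, csv_path, row.names = FALSE)
  invisible(c(rgb = rgb_path, labels = lab_path, cells = csv_path))
}

#' Read a slide image written by [write_slide()]
#'
#' @param path RGB image path (TIFF or PNG).
#' @return H x W x 3 integer array of 8-bit intensities.
#' @export
read_slide_rgb <- function(path) {
  img <- EBImage::readImage(path)
  arr <- aperm(EBImage::imageData(img), c(2, 1, 3))[, , 1:3, drop = FALSE]
  out <- round(arr * 255)
  storage.mode(out) <- "integer"
  out
}
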