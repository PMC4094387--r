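#' Per-cell measurement and scattergram gating
#'
#' [measure_cells()] turns a label map plus unmixed stain maps into one
#' feature record per cell — the tissue-cytometry table behind every dot
#' plot. Gates are rectangular selections in feature space; forward and
#' backward gating map between the scattergram and the image for visual
#' quality control.
#'
#' @name cell-quantification
NULL

#' Measure per-cell features
#'
#' Arithmetic means over mask pixels: hematoxylin in the nucleus (master
#' marker), antigen (AEC) in the nucleus and in the cytoplasmic ring.
#' Cells whose ring is empty get `NA` (not 0) for the cytoplasmic mean.
#'
#' @param labelmap a `label_map` with nuclei (and optionally rings).
#' @param hx_map,aec_map H x W concentration maps from [unmix()].
#' @return data.frame with one row per cell: `cell_id`, `nuclear_area_px2`,
#'   `hx_nuclear_mean`, `aec_nuclear_mean`, `aec_cyto_mean`,
#'   `centroid_row`, `centroid_col`.
#' @export
measure_cells <- function(labelmap, hx_map, aec_map) {
  stopifnot(inherits(labelmap, "label_map"))
  if (!all(dim(labelmap$nuclei) == dim(hx_map)) ||
      !all(dim(labelmap$nuclei) == dim(aec_map)))
    stop("label map and stain maps have mismatched dimensions")
  ids <- labelmap$cell_ids
  if (!length(ids))
    return(data.frame(cell_id = integer(), nuclear_area_px2 = integer(),
                      hx_nuclear_mean = numeric(), aec_nuclear_mean = numeric(),
                      aec_cyto_mean = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  nuc <- labelmap$nuclei
  sel <- nuc > 0L
  f <- factor(nuc[sel], levels = ids)
  area <- as.integer(table(f))
  hx_mean <- as.numeric(tapply(hx_map[sel], f, mean))
  aec_nuc <- as.numeric(tapply(aec_map[sel], f, mean))
  rows <- row(nuc)[sel] - 1L; cols <- col(nuc)[sel] - 1L   # 0-based centroids
  cr <- as.numeric(tapply(rows, f, mean))
  cc <- as.numeric(tapply(cols, f, mean))

  aec_cyt <- rep(NA_real_, length(ids))
  rsel <- labelmap$rings > 0L
  if (any(rsel)) {
    rf <- factor(labelmap$rings[rsel], levels = ids)
    m <- tapply(aec_map[rsel], rf, mean)
    aec_cyt <- as.numeric(m)
  }
  data.frame(cell_id = ids, nuclear_area_px2 = area, hx_nuclear_mean = hx_mean,
             aec_nuclear_mean = aec_nuc, aec_cyto_mean = aec_cyt,
             centroid_row = cr, centroid_col = cc)
}

#' Define a rectangular gate
#'
#' @param name flag name; [apply_gate()] records the result in a logical
#'   column `gate_<name>`.
#' @param x_feature,y_feature feature (column) names in the cell table.
#' @param x_range,y_range closed intervals `c(lo, hi)`; boundary cells are
#'   included.
#' @return A `gate` object.
#' @export
gate <- function(name, x_feature, x_range, y_feature = NULL, y_range = NULL) {
  stopifnot(is.character(name), length(x_range) == 2, x_range[1] < x_range[2])
  if (!is.null(y_feature))
    stopifnot(length(y_range) == 2, y_range[1] < y_range[2])
  structure(list(name = name, x_feature = x_feature, x_range = x_range,
                 y_feature = y_feature, y_range = y_range), class = "gate")
}

#' Apply a gate to a cell table
#'
#' Flags each cell TRUE iff its features fall inside the gate's closed
#' interval(s). Row order and all other columns are untouched; `NA`
#' features flag FALSE.
#'
#' @param cells data.frame from [measure_cells()].
#' @param g a [gate()].
#' @return `cells` with a logical column `gate_<name>` added (replaced if
#'   already present).
#' @export
apply_gate <- function(cells, g) {
  stopifnot(inherits(g, "gate"))
  feats <- c(g$x_feature, g$y_feature)
  missing <- setdiff(feats, names(cells))
  if (length(missing))
    stop("unknown gate feature(s): ", paste(missing, collapse = ", "))
  inx <- cells[[g$x_feature]] >= g$x_range[1] & cells[[g$x_feature]] <= g$x_range[2]
  if (!is.null(g$y_feature))
    inx <- inx & cells[[g$y_feature]] >= g$y_range[1] & cells[[g$y_feature]] <= g$y_range[2]
  inx[is.na(inx)] <- FALSE
  cells[[paste0("gate_", g$name)]] <- inx
  cells
}

# Otsu's criterion on a numeric vector (maximize between-class variance
# over a histogram). Used for the data-driven hepatocyte gate; EBImage's
# otsu() works on Image objects with a fixed range, not plain vectors.
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) return(x[1])
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Data-driven hepatocyte gate on nuclear area
#'
#' Splits the two nuclear-size populations (large parenchymal vs small
#' stromal nuclei) by an Otsu threshold on log nuclear area and gates the
#' larger population, emulating the scattergram gate that restricts
#' analysis to hepatocytes.
#'
#' @param cells cell table with `nuclear_area_px2`.
#' @param min_area_px2 optional explicit area threshold overriding the
#'   Otsu split.
#' @return A [gate()] named `"hepatocyte"` on `nuclear_area_px2`.
#' @export
hepatocyte_gate <- function(cells, min_area_px2 = NULL) {
  if (is.null(min_area_px2)) {
    thr <- otsu_threshold(log(cells$nuclear_area_px2))
    min_area_px2 <- exp(thr)
  }
  gate("hepatocyte", "nuclear_area_px2",
       c(min_area_px2, max(cells$nuclear_area_px2, min_area_px2) + 1))
}

#' Backward gating: selected cells to image coordinates
#'
#' Returns centroid coordinates for exactly the selected cells, for overlay
#' on the original image.
#'
#' @param cells cell table.
#' @param cell_ids integer vector of selected ids.
#' @return data.frame `cell_id`, `centroid_row`, `centroid_col` in the
#'   order requested.
#' @export
backward_gate <- function(cells, cell_ids) {
  idx <- match(cell_ids, cells$cell_id)
  if (anyNA(idx))
    stop("unknown cell id(s): ", paste(cell_ids[is.na(idx)], collapse = ", "))
  cells[idx, c("cell_id", "centroid_row", "centroid_col")]
}

#' Forward gating: image position to cell id
#'
#' @param labelmap a `label_map`.
#' @param row,col 0-based pixel position.
#' @return The nucleus label at the pixel, or `NA` if background.
#' @export
forward_gate <- function(labelmap, row, col) {
  stopifnot(inherits(labelmap, "label_map"))
  h <- nrow(labelmap$nuclei); w <- ncol(labelmap$nuclei)
  if (row < 0 || row >= h || col < 0 || col >= w)
    stop("position (", row, ", ", col, ") outside the ", h, "x", w, " image")
  id <- labelmap$nuclei[row + 1L, col + 1L]
  if (id == 0L) NA_integer_ else id
}

#' Restrict a cell table to a region of interest
#'
#' Keeps cells whose centroid lies inside a logical ROI mask, emulating
#' region-of-interest analysis that excludes surrounding stromal areas.
#'
#' @param cells cell table.
#' @param roi_mask H x W logical matrix (TRUE = inside the ROI).
#' @return The filtered cell table.
#' @export
filter_roi <- function(cells, roi_mask) {
  stopifnot(is.logical(roi_mask) || all(roi_mask %in% c(0, 1)))
  keep <- roi_mask[cbind(round(cells$centroid_row) + 1L,
                         round(cells$centroid_col) + 1L)] > 0
  cells[keep, , drop = FALSE]
}
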