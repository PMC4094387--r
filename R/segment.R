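#' Nuclear segmentation and ring masks
#'
#' Nuclei are detected from the hematoxylin concentration map — the
#' "master marker" — and a ring-shaped virtual mask around each nucleus
#' samples the perinuclear cytoplasm. The four classic tissue-cytometry
#' parameters (average nuclear size, discrimination area, discrimination
#' gray, background threshold) control the pipeline.
#'
#' @name nuclear-segmentation
NULL

#' Segmentation parameters
#'
#' @param background_threshold hematoxylin concentration below which a
#'   pixel is background for the master marker.
#' @param avg_nuclear_size_px expected nucleus diameter in pixels; sets the
#'   Gaussian smoothing scale (sigma = size/8).
#' @param discrimination_area_px2 minimum accepted object area in pixels^2.
#' @param discrimination_gray minimum accepted object mean hematoxylin
#'   concentration.
#' @param ring_gap_px gap between the nucleus boundary and the inner ring
#'   edge, pixels.
#' @param ring_width_px radial width of the cytoplasmic ring, pixels.
#' @param h_maxima_frac watershed seed suppression: regional maxima of the
#'   distance transform shallower than this fraction of its maximum are
#'   merged (default 0.1).
#' @return A validated `segmentation_params` list.
#' @export
segmentation_params <- function(background_threshold = 0.2,
                                avg_nuclear_size_px = 14,
                                discrimination_area_px2 = 20,
                                discrimination_gray = 0.1,
                                ring_gap_px = 0, ring_width_px = 3,
                                h_maxima_frac = 0.1) {
  p <- list(background_threshold = background_threshold,
            avg_nuclear_size_px = avg_nuclear_size_px,
            discrimination_area_px2 = discrimination_area_px2,
            discrimination_gray = discrimination_gray,
            ring_gap_px = as.integer(ring_gap_px),
            ring_width_px = as.integer(ring_width_px),
            h_maxima_frac = h_maxima_frac)
  stopifnot(p$background_threshold >= 0, p$avg_nuclear_size_px > 0,
            p$discrimination_area_px2 >= 0, p$discrimination_gray >= 0,
            p$ring_gap_px >= 0, p$ring_width_px >= 0,
            p$h_maxima_frac > 0, p$h_maxima_frac < 1)
  class(p) <- "segmentation_params"
  p
}

new_label_map <- function(nuclei, rings = NULL) {
  if (is.null(rings)) rings <- matrix(0L, nrow(nuclei), ncol(nuclei))
  ids <- sort(setdiff(unique(as.integer(nuclei)), 0L))
  structure(list(nuclei = nuclei, rings = rings, cell_ids = ids),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("label_map: ", length(x$cell_ids), " nuclei",
      if (any(x$rings > 0)) " with rings", ", ",
      nrow(x$nuclei), "x", ncol(x$nuclei), " px\n", sep = "")
  invisible(x)
}

#' Detect nuclei in a hematoxylin concentration map
#'
#' Pipeline: Gaussian smoothing (sigma = avg_nuclear_size_px / 8) ->
#' threshold at `background_threshold` -> hole filling -> Euclidean
#' distance transform -> watershed with h-maxima seed suppression
#' (h = `h_maxima_frac` x max distance) -> discard objects smaller than
#' `discrimination_area_px2` or with mean hematoxylin (on the unsmoothed
#' map) below `discrimination_gray`. Surviving labels are renumbered
#' contiguously from 1 in scanline order.
#'
#' @param hx_map H x W nonnegative matrix, hematoxylin concentration
#'   (row/col convention).
#' @param params a [segmentation_params()].
#' @return A `label_map` with `nuclei` labels (rings empty).
#' @export
detect_nuclei <- function(hx_map, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"), min(hx_map) >= 0)
  h <- nrow(hx_map); w <- ncol(hx_map)
  img <- EBImage::Image(t(hx_map))               # EBImage is (x, y)
  sm <- EBImage::gblur(img, sigma = params$avg_nuclear_size_px / 8)
  mask <- sm > params$background_threshold
  if (!any(mask)) return(new_label_map(matrix(0L, h, w)))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  wt <- EBImage::watershed(dm, tolerance = params$h_maxima_frac * max(dm), ext = 1)
  lab <- t(EBImage::imageData(wt))               # back to row/col
  storage.mode(lab) <- "integer"

  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids)) {
    area <- tabulate(lab, nbins = max(ids))[ids]
    gray <- as.numeric(tapply(hx_map[lab > 0L], lab[lab > 0L], mean))
    keep <- ids[area >= params$discrimination_area_px2 &
                gray >= params$discrimination_gray]
    remap <- integer(max(ids) + 1L)              # index by label + 1
    remap[keep + 1L] <- seq_along(keep)
    lab <- matrix(remap[lab + 1L], h, w)
  }
  new_label_map(lab)
}

#' Build ring-shaped cytoplasmic masks around segmented nuclei
#'
#' For each cell the ring is the set of pixels at Euclidean distance in
#' (ring_gap_px, ring_gap_px + ring_width_px] from its nucleus, excluding
#' every nucleus. Pixels reachable from several nuclei go to the cell
#' whose nucleus is nearest; exact ties go to the lower cell id. Rings may
#' be empty in crowded regions.
#'
#' @param labelmap a `label_map` from [detect_nuclei()] (or ground-truth
#'   labels wrapped via the same structure).
#' @param ring_gap_px,ring_width_px ring geometry in pixels.
#' @return The `label_map` with `rings` filled in.
#' @export
make_ring_masks <- function(labelmap, ring_gap_px = 0, ring_width_px = 3) {
  stopifnot(inherits(labelmap, "label_map"), ring_gap_px >= 0, ring_width_px >= 0)
  nuc <- labelmap$nuclei
  h <- nrow(nuc); w <- ncol(nuc)
  rings <- matrix(0L, h, w)
  if (ring_width_px == 0 || !length(labelmap$cell_ids)) {
    labelmap$rings <- rings
    return(labelmap)
  }
  reach <- ring_gap_px + ring_width_px
  best <- matrix(Inf, h, w)
  # Per-cell exact Euclidean distance to its own nucleus, computed on a
  # padded bounding box; ascending cell_id order makes ties resolve low.
  for (id in labelmap$cell_ids) {
    px <- which(nuc == id, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1]) - reach); r1 <- min(h, max(px[, 1]) + reach)
    c0 <- max(1L, min(px[, 2]) - reach); c1 <- min(w, max(px[, 2]) + reach)
    sub <- nuc[r0:r1, c0:c1] == id
    d <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(!sub)))))
    upd <- which(d > ring_gap_px & d <= reach & d < best[r0:r1, c0:c1])
    if (length(upd)) {
      full <- cbind(((upd - 1L) %% nrow(d)) + r0,
                    ((upd - 1L) %/% nrow(d)) + c0)
      best[full] <- d[upd]
      rings[full] <- id
    }
  }
  rings[nuc > 0L] <- 0L
  labelmap$rings <- rings
  labelmap
}

#' Wrap ground-truth labels as a label_map
#'
#' Lets the measurement and gating machinery run directly on simulator
#' ground truth, bypassing segmentation.
#'
#' @param slide a `virtual_slide`.
#' @param rings use the slide's true cytoplasm labels as rings (default TRUE).
#' @return A `label_map`.
#' @export
truth_label_map <- function(slide, rings = TRUE) {
  stopifnot(inherits(slide, "virtual_slide"))
  lm <- new_label_map(slide$nucleus_truth_labels)
  if (rings) lm$rings <- slide$cyto_truth_labels
  lm
}

#' Match detected nuclei to ground truth and score overlap
#'
#' Greedy one-to-one matching by overlap: each truth object is paired with
#' the detected label covering most of it, and the pair's
#' intersection-over-union is reported.
#'
#' @param detected a `label_map` from [detect_nuclei()].
#' @param truth_labels H x W integer matrix of ground-truth nucleus labels.
#' @return data.frame with `truth_id`, `detected_id` (0 = missed) and `iou`.
#' @export
match_to_truth <- function(detected, truth_labels) {
  stopifnot(inherits(detected, "label_map"))
  det <- detected$nuclei
  stopifnot(all(dim(det) == dim(truth_labels)))
  t_ids <- sort(setdiff(unique(as.integer(truth_labels)), 0L))
  det_area <- tabulate(det[det > 0L], nbins = max(det, 1L))
  out <- data.frame(truth_id = t_ids, detected_id = 0L, iou = 0)
  for (k in seq_along(t_ids)) {
    sel <- truth_labels == t_ids[k]
    hits <- det[sel]
    hits <- hits[hits > 0L]
    if (!length(hits)) next
    tab <- tabulate(hits)
    d <- which.max(tab)
    inter <- tab[d]
    uni <- sum(sel) + det_area[d] - inter
    out$detected_id[k] <- d
    out$iou[k] <- inter / uni
  }
  out
}
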