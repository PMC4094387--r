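#' Stain matrices and color deconvolution
#'
#' Brightfield chromogens absorb light according to Beer--Lambert: per RGB
#' channel, optical density OD = -log10(I / I0) is linear in chromogen
#' concentration. A `stain_matrix` holds one unit-norm OD color vector per
#' stain (hematoxylin, AEC, and a residual completing the basis), and
#' [unmix()] solves the per-pixel 3x3 linear system to recover per-stain
#' concentration maps ("color separation").
#'
#' @name stain-separation
NULL

#' Construct a stain matrix from two stain vectors
#'
#' Normalizes the hematoxylin and AEC optical-density color vectors to unit
#' Euclidean norm and completes the basis with their normalized cross
#' product as a residual channel.
#'
#' @param v_hx numeric(3), hematoxylin OD per RGB channel (any positive scale).
#' @param v_aec numeric(3), AEC OD per RGB channel.
#' @param source_label free-text provenance tag stored with the matrix.
#' @return An object of class `stain_matrix`: list with unit vectors `v_hx`,
#'   `v_aec`, `v_res`, the 3x3 matrix `M` (stains in columns), its condition
#'   number `kappa`, and `source_label`.
#' @examples
#' complete_stain_matrix(c(1, 0, 0), c(0, 1, 0))$v_res  # (0, 0, 1)
#' @export
complete_stain_matrix <- function(v_hx, v_aec, source_label = "user") {
  v_hx <- as.numeric(v_hx); v_aec <- as.numeric(v_aec)
  stopifnot(length(v_hx) == 3, length(v_aec) == 3)
  n1 <- sqrt(sum(v_hx^2)); n2 <- sqrt(sum(v_aec^2))
  if (n1 == 0 || n2 == 0)
    stop("stain vectors must be nonzero")
  v1 <- v_hx / n1; v2 <- v_aec / n2
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  n3 <- sqrt(sum(v3^2))
  if (n3 < 1e-8)
    stop("stain vectors are collinear; cannot complete an invertible basis")
  v3 <- v3 / n3
  M <- cbind(hx = v1, aec = v2, res = v3)
  kappa <- kappa(M, exact = TRUE)
  if (kappa > 1e6)
    stop("stain matrix is near-singular (condition number ", format(kappa), ")")
  structure(list(v_hx = v1, v_aec = v2, v_res = v3, M = M,
                 kappa = kappa, source_label = source_label),
            class = "stain_matrix")
}

#' Default hematoxylin/AEC stain matrix
#'
#' Hematoxylin uses the published Ruifrok--Johnston color-deconvolution
#' vector; AEC uses (0.27, 0.57, 0.78) before normalization. Both are
#' documented defaults, overridable by passing explicit vectors to
#' [complete_stain_matrix()].
#'
#' @return A `stain_matrix`.
#' @export
default_stain_matrix <- function() {
  complete_stain_matrix(c(0.650, 0.704, 0.286),
                        c(0.270, 0.570, 0.780),
                        source_label = "Ruifrok-Johnston hematoxylin + AEC default")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("stain_matrix (", x$source_label, ")\n", sep = "")
  print(round(x$M, 4))
  cat("condition number:", format(x$kappa, digits = 4), "\n")
  invisible(x)
}

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer--Lambert transform OD = -log10(max(I, eps * i0) / i0)
#' per channel. Negative densities (pixels brighter than the white
#' reference) are clamped to zero.
#'
#' @param rgb H x W x 3 array of intensities in 0..255 (integer or numeric),
#'   or values in \[0, 1\] together with `i0 = 1`.
#' @param i0 white (blank-field) reference intensity; defaults to 255 for
#'   8-bit input. Inputs whose maximum exceeds 255 require an explicit `i0`.
#' @param eps positive floor, as a fraction of `i0`, guarding the logarithm
#'   (default 1/255).
#' @return An `od_image`: list with `od` (H x W x 3 nonnegative array) and `i0`.
#' @export
rgb_to_od <- function(rgb, i0 = 255, eps = 1 / 255) {
  stopifnot(is.numeric(i0), i0 > 0, eps > 0, eps <= 1)
  rgb <- as_rgb_array(rgb)
  if (max(rgb) > 255 && missing(i0))
    stop("input is not 8-bit; supply an explicit white reference `i0`")
  od <- -log10(pmax(rgb, eps * i0) / i0)
  od[od < 0] <- 0
  structure(list(od = od, i0 = i0), class = "od_image")
}

#' Render optical density back to an RGB transmittance image
#'
#' Inverse of [rgb_to_od()] up to the eps floor and 8-bit quantization:
#' I = round(i0 * 10^(-OD)).
#'
#' @param od H x W x 3 nonnegative array of optical densities, or an
#'   `od_image`.
#' @param i0 white reference (default 255).
#' @return H x W x 3 numeric array of intensities in \[0, i0\], rounded to
#'   integers when `i0 = 255`.
#' @export
od_to_rgb <- function(od, i0 = 255) {
  if (inherits(od, "od_image")) { i0 <- od$i0; od <- od$od }
  out <- i0 * 10^(-od)
  if (i0 == 255) out <- round(out)
  out
}

#' Unmix hematoxylin and AEC concentration maps
#'
#' Solves OD = M c per pixel for the stain concentrations c, clamps
#' negative concentrations to zero, and discards the residual channel.
#'
#' @param od an `od_image` from [rgb_to_od()], or a raw H x W x 3 OD array.
#' @param stains a `stain_matrix`.
#' @return List with matrices `hx` and `aec` (H x W concentration maps, in
#'   OD units along each stain vector) and `clamped_fraction`, the fraction
#'   of pixel-stain values that were negative before clamping.
#' @examples
#' sm <- default_stain_matrix()
#' od <- array(0.7 * sm$v_hx, dim = c(1, 1, 3))
#' unmix(od, sm)$hx  # 0.7
#' @export
unmix <- function(od, stains) {
  stopifnot(inherits(stains, "stain_matrix"))
  if (inherits(od, "od_image")) od <- od$od
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 3)
  h <- dim(od)[1]; w <- dim(od)[2]
  flat <- matrix(od, ncol = 3)                   # pixels x channels
  conc <- t(solve(stains$M, t(flat)))            # pixels x stains
  neg <- conc[, 1:2] < 0
  clamped <- mean(neg)
  conc[conc < 0] <- 0
  list(hx = matrix(conc[, 1], h, w),
       aec = matrix(conc[, 2], h, w),
       clamped_fraction = clamped)
}

# Accept EBImage Image (W x H x 3), plain arrays, or integer arrays.
as_rgb_array <- function(rgb) {
  if (inherits(rgb, "Image")) rgb <- EBImage::imageData(rgb) * 255
  rgb <- unclass(rgb)
  storage.mode(rgb) <- "double"
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  rgb
}
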