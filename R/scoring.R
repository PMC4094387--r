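#' Four-level scoring and inter-rater agreement
#'
#' Nuclear mean intensities convert to an ordinal score 0 (no expression)
#' to 3 (strong expression) via three increasing zone boundaries.
#' Agreement between raters — human or software — is quantified by exact
#' percent agreement and by Cohen's kappa with linear disagreement
#' weights, labelled with the Landis--Koch bands.
#'
#' @name scoring-agreement
NULL

#' Scoring matrix: intensity zone boundaries
#'
#' @param boundaries strictly increasing numeric(3) `(b1, b2, b3)`.
#'   Zones are left-closed: score 0 below `b1`, 1 in `[b1, b2)`, 2 in
#'   `[b2, b3)`, 3 at or above `b3`.
#' @return A `score_matrix` object.
#' @export
score_matrix <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  stopifnot(length(boundaries) == 3)
  if (!(boundaries[1] < boundaries[2] && boundaries[2] < boundaries[3]))
    stop("boundaries must be strictly increasing")
  structure(list(boundaries = boundaries), class = "score_matrix")
}

#' Derive zone boundaries from a calibration sample
#'
#' Default: the quartiles (25/50/75% quantiles) of the calibration
#' intensities, so a sample spanning the range populates all four levels.
#' `method = "range"` instead places boundaries at fixed fractions 1/4,
#' 2/4, 3/4 of the observed intensity range. Boundaries are always
#' reported back in experiment output for auditability.
#'
#' @param values calibration intensities.
#' @param method `"quantile"` or `"range"`.
#' @return A [score_matrix()].
#' @export
score_boundaries <- function(values, method = c("quantile", "range")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  b <- switch(method,
    quantile = unname(stats::quantile(values, c(0.25, 0.5, 0.75))),
    range = min(values) + diff(range(values)) * c(0.25, 0.5, 0.75))
  if (any(diff(b) <= 0))
    stop("calibration sample too degenerate for strictly increasing boundaries")
  score_matrix(b)
}

#' Score an intensity against the four-level matrix
#'
#' @param intensity nonnegative intensity (vectorized).
#' @param matrix a [score_matrix()].
#' @return Integer scores in 0..3.
#' @export
score_from_intensity <- function(intensity, matrix) {
  stopifnot(inherits(matrix, "score_matrix"), all(intensity >= 0))
  findInterval(intensity, matrix$boundaries)  # left-closed zones by definition
}

#' Exact percent agreement between two score vectors
#'
#' @param a,b equal-length ordinal score vectors.
#' @return 100 x (fraction of exact matches).
#' @export
percent_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (!length(a)) stop("empty score vectors")
  100 * mean(a == b)
}

#' Cohen's weighted kappa for ordinal scores
#'
#' Linear weights w_ij = 1 - |i - j| / (k - 1): observed weighted
#' agreement Po = sum w_ij p_ij over the joint score distribution,
#' expected agreement Pe from the product of the marginals, and
#' kappa = (Po - Pe) / (1 - Pe). When both raters are constant and
#' identical, Po = Pe = 1 and kappa is returned as 1 by convention (with
#' a message).
#'
#' @param a,b equal-length score vectors with values in `0..(k-1)`.
#' @param k number of ordinal levels (default 4).
#' @param weighting `"linear"` (quadratic weights are not used here).
#' @return Kappa in \[-1, 1\].
#' @export
weighted_kappa <- function(a, b, k = 4, weighting = "linear") {
  stopifnot(weighting == "linear")
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (any(!(a %in% 0:(k - 1))) || any(!(b %in% 0:(k - 1))))
    stop("scores must be integers in 0..", k - 1)
  lev <- 0:(k - 1)
  p <- table(factor(a, lev), factor(b, lev)) / length(a)
  w <- 1 - abs(outer(lev, lev, "-")) / (k - 1)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) {
      message("both raters constant and identical; kappa = 1 by convention")
      return(1)
    }
    stop("degenerate marginals: expected agreement is 1 but observed is not")
  }
  (po - pe) / (1 - pe)
}

#' Landis--Koch agreement category for a kappa value
#'
#' @param kappa numeric in \[-1, 1\] (vectorized).
#' @return Character: `"poor"` (< 0), `"slight"` \[0, 0.20\], `"fair"`
#'   (0.20, 0.40\], `"moderate"` (0.40, 0.60\], `"substantial"`
#'   (0.60, 0.80\], `"almost perfect"` (0.80, 1\].
#' @export
kappa_category <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1))
  bands <- c("poor", "slight", "fair", "moderate", "substantial", "almost perfect")
  idx <- findInterval(kappa, c(0.20, 0.40, 0.60, 0.80), left.open = TRUE) + 2L
  idx[kappa < 0] <- 1L
  bands[idx]
}

#' Agreement report across three raters
#'
#' All three pairwise percent agreements and linearly weighted kappas with
#' categories, plus the percentage of cases on which all three raters
#' agree (the three-way overlap).
#'
#' @param r1,r2,r3 equal-length score vectors; names are taken from the
#'   arguments unless `labels` is given.
#' @param labels character(3) rater labels.
#' @param k number of ordinal levels.
#' @return An `agreement_report`: list with `pairwise` (data.frame of
#'   rater pairs, percent agreement, kappa, category), `triple_percent`,
#'   `n`, `labels`.
#' @export
three_way_overlap <- function(r1, r2, r3, labels = c("rater1", "rater2", "rater3"),
                              k = 4) {
  n <- length(r1)
  if (length(r2) != n || length(r3) != n) stop("score vectors differ in length")
  rs <- list(r1, r2, r3)
  pairs <- utils::combn(3, 2)
  pw <- data.frame(a = labels[pairs[1, ]], b = labels[pairs[2, ]],
                   percent_agreement = NA_real_, kappa = NA_real_,
                   category = NA_character_)
  for (j in seq_len(ncol(pairs))) {
    x <- rs[[pairs[1, j]]]; y <- rs[[pairs[2, j]]]
    pw$percent_agreement[j] <- percent_agreement(x, y)
    kp <- suppressMessages(weighted_kappa(x, y, k = k))
    pw$kappa[j] <- kp
    pw$category[j] <- kappa_category(kp)
  }
  structure(list(pairwise = pw,
                 triple_percent = 100 * mean(r1 == r2 & r2 == r3),
                 n = n, labels = labels),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement over", x$n, "cases\n")
  print(transform(x$pairwise,
                  percent_agreement = round(percent_agreement, 1),
                  kappa = round(kappa, 3)), row.names = FALSE)
  cat("all three agree:", round(x$triple_percent, 1), "%\n")
  invisible(x)
}

#' Simulate an imperfect ordinal rater
#'
#' Symmetric confusion model: each case is miscalled with probability
#' `miscall_prob`; a miscalled score moves one level up or down with equal
#' probability (reflected at the ends of the scale).
#'
#' @param true_scores integer scores in `0..(k-1)`.
#' @param miscall_prob per-case miscall probability.
#' @param k number of levels.
#' @return Integer score vector.
#' @export
simulate_rater <- function(true_scores, miscall_prob, k = 4) {
  stopifnot(miscall_prob >= 0, miscall_prob <= 1)
  n <- length(true_scores)
  flip <- stats::runif(n) < miscall_prob
  step <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  out <- as.integer(true_scores)
  kmax <- as.integer(k) - 1L
  out[flip] <- out[flip] + step[flip]
  out[out < 0L] <- 1L                      # reflect at the scale ends
  out[out > kmax] <- kmax - 1L
  out
}
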