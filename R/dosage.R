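#' Dosage and translocation statistics
#'
#' Gene-dosage models give graded antigen levels — 2, 1 and 0 relative
#' units for two, one and zero functional alleles — on top of a
#' nonspecific background shared by all genotypes. The knockout group
#' anchors that background: its per-cell intensity distribution defines
#' the positive/negative cut-off, and subtracting its mean from every
#' group recovers the 2:1:0 ratio. Nuclear/cytoplasmic ratios quantify
#' transcription-factor translocation.
#'
#' @name dosage-stats
NULL

#' Background cut-off from the null (knockout) group
#'
#' @param ko_values per-cell intensities of the null group.
#' @param method `"quantile"` (empirical quantile at `level`, default) or
#'   `"mean_sd"` (mean + k sd with `k = level`).
#' @param level quantile level (default 0.99) or, for `"mean_sd"`, the sd
#'   multiplier k (default 2 when `method = "mean_sd"`).
#' @return A `cutoff` object: list with `value`, `method`, `source_group`.
#' @export
background_cutoff <- function(ko_values, method = c("quantile", "mean_sd"),
                              level = NULL, source_group = "ko") {
  method <- match.arg(method)
  ko_values <- ko_values[!is.na(ko_values)]
  if (!length(ko_values)) stop("null-group values are empty")
  if (is.null(level)) level <- if (method == "quantile") 0.99 else 2
  value <- switch(method,
    quantile = unname(stats::quantile(ko_values, level, type = 7)),
    mean_sd = mean(ko_values) + level * stats::sd(ko_values))
  if (is.na(value)) value <- mean(ko_values)     # sd undefined for n = 1
  value <- max(value, 0)
  structure(list(value = value, method = method, level = level,
                 source_group = source_group), class = "cutoff")
}

#' @export
print.cutoff <- function(x, ...) {
  cat("cutoff ", format(x$value, digits = 6), " (", x$method, ", level ",
      x$level, ", anchored on group '", x$source_group, "')\n", sep = "")
  invisible(x)
}

#' Background-subtracted dosage ratios on the wildtype = 2 scale
#'
#' Subtracts the null-group mean from each group mean and rescales so the
#' wildtype sits at 2, the anchoring that matches the expected 2:1:0
#' pattern for di-allelic, mono-allelic and null genotypes.
#'
#' @param group_means named numeric: means for `wt`, `hemi`, `ko`.
#' @param background the null-group mean to subtract (defaults to
#'   `group_means["ko"]`).
#' @return Named numeric `(wt = 2, hemi = r, ko = 0)` with `r` the
#'   estimated relative hemizygous level.
#' @examples
#' dosage_ratios(c(wt = 110, hemi = 60, ko = 10))  # 2, 1, 0
#' @export
dosage_ratios <- function(group_means, background = NULL) {
  stopifnot(all(c("wt", "hemi", "ko") %in% names(group_means)))
  if (is.null(background)) background <- group_means[["ko"]]
  denom <- group_means[["wt"]] - background
  if (denom <= 0)
    stop("wildtype mean (", format(group_means[["wt"]]),
         ") does not exceed background (", format(background),
         "); no dynamic range")
  out <- 2 * (unlist(group_means[c("wt", "hemi", "ko")]) - background) / denom
  names(out) <- c("wt", "hemi", "ko")
  out
}

#' Percentage of positive cells in a compartment
#'
#' @param values per-cell compartment means (`NA` = compartment undefined,
#'   excluded from the denominator).
#' @param cutoff a `cutoff` object or a bare threshold.
#' @return Percentage in \[0, 100\] of cells with value strictly above the
#'   cut-off.
#' @export
positive_fraction <- function(values, cutoff) {
  thr <- if (inherits(cutoff, "cutoff")) cutoff$value else cutoff
  values <- values[!is.na(values)]
  if (!length(values)) stop("no cells with a defined compartment value")
  100 * mean(values > thr)
}

#' Per-cell and group nuclear/cytoplasmic ratio
#'
#' Cells with an undefined or nonpositive cytoplasmic mean are excluded
#' (not imputed) and counted.
#'
#' @param cells cell table with `aec_nuclear_mean` and `aec_cyto_mean`.
#' @return List with `per_cell` (data.frame `cell_id`, `nc_ratio`), group
#'   `mean` and `sd`, `n` included and `n_excluded`.
#' @export
nc_ratio <- function(cells) {
  ok <- !is.na(cells$aec_cyto_mean) & cells$aec_cyto_mean > 0 &
        !is.na(cells$aec_nuclear_mean)
  if (!any(ok)) stop("no cell has both compartments defined with cytoplasm > 0")
  r <- cells$aec_nuclear_mean[ok] / cells$aec_cyto_mean[ok]
  list(per_cell = data.frame(cell_id = cells$cell_id[ok], nc_ratio = r),
       mean = mean(r), sd = stats::sd(r),
       n = sum(ok), n_excluded = sum(!ok))
}

#' Compare groups by one-way ANOVA or Student's t-test
#'
#' Inference is reported alongside the estimates and never feeds back into
#' them.
#'
#' @param values numeric vector of per-cell values.
#' @param groups factor or character of group labels, same length.
#' @param test `"one_way_anova"` or `"t_test"` (two-sided, pooled
#'   variance).
#' @return List with `statistic`, `p_value`, `test`, `df`.
#' @export
compare_groups <- function(values, groups, test = c("one_way_anova", "t_test")) {
  test <- match.arg(test)
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least two groups with at least two values each")
  if (test == "t_test") {
    if (length(tab) != 2) stop("t-test requires exactly two groups")
    ht <- stats::t.test(values ~ groups, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "t_test", df = unname(ht$parameter))
  } else {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    list(statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1],
         test = "one_way_anova", df = s$Df)
  }
}

#' Rescale assay values so the maximum is 100
#'
#' Cross-assay comparison on arbitrary-unit scales: each value is
#' multiplied by 100 / max so the highest value sits exactly at 100.
#'
#' @param values nonnegative numeric with a positive maximum.
#' @return Rescaled values; `max(out) == 100` exactly.
#' @export
normalize_to_100 <- function(values) {
  m <- max(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("all values are zero or missing; cannot rescale")
  out <- values * (100 / m)
  out[which(values == m)] <- 100   # pin the maximum exactly despite rounding
  out
}
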