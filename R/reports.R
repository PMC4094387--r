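#' Report output
#'
#' Each experiment driver can write its results to disk: per-cell CSV
#' tables, a plain-text summary embedding the full resolved configuration
#' and every derived threshold (cut-offs, gates, score boundaries), and
#' simple figures. All writers are deterministic so re-running with the
#' same seed reproduces identical CSV bytes.
#'
#' @name reports
#' @keywords internal
NULL

ensure_dir <- function(d) { dir.create(d, recursive = TRUE, showWarnings = FALSE); d }

fmt_params <- function(p) {
  paste(vapply(names(p), function(k) {
    v <- p[[k]]
    paste0("  ", k, " = ", paste(format(unlist(v), digits = 6), collapse = ", "))
  }, ""), collapse = "\n")
}

config_lines <- function(config, seg = NULL, extra = character()) {
  flat <- unclass(config)[!vapply(unclass(config), is.list, TRUE)]
  flat$out_dir <- NULL        # path varies between runs; keep reports comparable
  c("resolved configuration:",
    fmt_params(flat),
    if (length(config$sim)) c("sim overrides:", fmt_params(config$sim)),
    if (!is.null(seg)) c("segmentation parameters:", fmt_params(unclass(seg))),
    extra)
}

write_dosage_report <- function(report) {
  d <- ensure_dir(report$config$out_dir)
  utils::write.csv(report$per_cell, file.path(d, "dosage_cells.csv"),
                   row.names = FALSE)
  summary_lines <- c(
    "gene-dosage experiment",
    config_lines(report$config, report$seg_params),
    sprintf("knockout-anchored cutoff: %.6g (%s, level %s)",
            report$cutoff$value, report$cutoff$method, report$cutoff$level),
    sprintf("group means (nuclear + cytoplasmic antigen OD): wt %.6g, hemi %.6g, ko %.6g",
            report$group_means[["wt"]], report$group_means[["hemi"]],
            report$group_means[["ko"]]),
    sprintf("background-subtracted relative levels (wt = 2 scale): %.4f : %.4f : %.4f",
            report$ratios[["wt"]], report$ratios[["hemi"]], report$ratios[["ko"]]),
    sprintf("one-way ANOVA: F = %.4g, p = %.3g",
            report$anova$statistic, report$anova$p_value),
    "stage log:",
    vapply(report$log, function(l) paste0("  ", paste(names(l), l, sep = "=",
                                                      collapse = " ")), ""))
  writeLines(summary_lines, file.path(d, "dosage_summary.txt"))
  grDevices::png(file.path(d, "dosage_boxplot.png"), 600, 450)
  graphics::boxplot(aec_total_mean ~ factor(genotype, c("wt", "hemi", "ko")),
                    data = report$per_cell, xlab = "genotype",
                    ylab = "antigen mean OD (nucleus + cytoplasm)",
                    main = "per-cell antigen intensity by genotype")
  grDevices::dev.off()
  invisible(d)
}

write_translocation_report <- function(report) {
  d <- ensure_dir(report$config$out_dir)
  utils::write.csv(report$per_cell, file.path(d, "translocation_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(report$positive_fractions,
                   file.path(d, "positive_fractions.csv"), row.names = FALSE)
  summary_lines <- c(
    "translocation experiment",
    config_lines(report$config, report$seg_params),
    sprintf("cutoff nuclear: %.6g; cytoplasmic: %.6g",
            report$cutoffs$nuclear$value, report$cutoffs$cytoplasmic$value),
    sprintf("N/C ratio mock: %.4f +/- %.4f (n=%d, excluded %d)",
            report$nc$mock$mean, report$nc$mock$sd, report$nc$mock$n,
            report$nc$mock$n_excluded),
    sprintf("N/C ratio stim: %.4f +/- %.4f (n=%d, excluded %d)",
            report$nc$stim$mean, report$nc$stim$sd, report$nc$stim$n,
            report$nc$stim$n_excluded),
    sprintf("Student's t-test on per-cell N/C ratios: t = %.4g, p = %.3g",
            report$t_test$statistic, report$t_test$p_value),
    "positive fractions (%):",
    sprintf("  %s %s: %.1f", report$positive_fractions$group,
            report$positive_fractions$compartment,
            report$positive_fractions$percent_positive),
    "stage log:",
    vapply(report$log, function(l) paste0("  ", paste(names(l), l, sep = "=",
                                                      collapse = " ")), ""))
  writeLines(summary_lines, file.path(d, "translocation_summary.txt"))
  grDevices::png(file.path(d, "nc_ratio_boxplot.png"), 500, 450)
  nc_all <- rbind(data.frame(group = "mock", r = report$nc$mock$per_cell$nc_ratio),
                  data.frame(group = "stim", r = report$nc$stim$per_cell$nc_ratio))
  graphics::boxplot(r ~ group, data = nc_all, ylab = "nuclear / cytoplasmic ratio",
                    main = "antigen N/C ratio, mock vs stimulated")
  grDevices::dev.off()
  invisible(d)
}

write_scoring_report <- function(report) {
  d <- ensure_dir(report$config$out_dir)
  utils::write.csv(report$cases, file.path(d, "scoring_cases.csv"),
                   row.names = FALSE)
  utils::write.csv(report$agreement$pairwise, file.path(d, "agreement.csv"),
                   row.names = FALSE)
  summary_lines <- c(
    "scoring / inter-rater agreement experiment",
    config_lines(report$config),
    sprintf("score zone boundaries: %.6g, %.6g, %.6g",
            report$boundaries$boundaries[1], report$boundaries$boundaries[2],
            report$boundaries$boundaries[3]),
    sprintf("pair %s vs %s: agreement %.1f%%, kappa %.3f (%s)",
            report$agreement$pairwise$a, report$agreement$pairwise$b,
            report$agreement$pairwise$percent_agreement,
            report$agreement$pairwise$kappa, report$agreement$pairwise$category),
    sprintf("all three agree: %.1f%%", report$agreement$triple_percent))
  writeLines(summary_lines, file.path(d, "scoring_summary.txt"))
  invisible(d)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values are parsed as numeric vectors when possible
#' (comma-separated), otherwise kept as strings. Keys matching
#' [tissue_sim_params()] fields populate `sim`, keys matching
#' [segmentation_params()] populate `seg`, the rest map onto
#' [experiment_config()] arguments.
#'
#' @param path config file path.
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("cannot parse config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2)
  vals <- lapply(kv, function(m) {
    parts <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else paste(parts, collapse = ",")
  })
  names(vals) <- keys
  sim_keys <- setdiff(names(formals(tissue_sim_params)), c("seed", "n_cells"))
  seg_keys <- names(formals(segmentation_params))
  cfg_keys <- setdiff(names(formals(experiment_config)), c("sim", "seg"))
  args <- vals[intersect(keys, cfg_keys)]
  args$sim <- vals[intersect(keys, sim_keys)]
  args$seg <- vals[intersect(keys, seg_keys)]
  unknown <- setdiff(keys, c(cfg_keys, sim_keys, seg_keys))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(experiment_config, args)
}
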