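#' End-to-end in-silico experiments
#'
#' Three experiments mirror the biological study designs on synthetic
#' slides: (i) gene dosage — wildtype, hemizygous and knockout slides,
#' recovering the 2:1:0 ratio after knockout-anchored background
#' subtraction; (ii) translocation — mock vs stimulated slides differing
#' only in the nuclear fraction of the antigen, quantified by
#' nuclear/cytoplasmic ratios and compartment positive fractions;
#' (iii) scoring — a case series scored by the intensity pipeline and by
#' simulated imperfect raters, summarized by percent agreement and
#' weighted kappa. Every experiment is a deterministic function of
#' (config, seed) and logs cell counts at each stage.
#'
#' @name pipeline
NULL

#' Analyze one slide image end to end
#'
#' Runs the full measurement chain: RGB -> optical density -> stain
#' unmixing -> nuclear segmentation on the hematoxylin master marker ->
#' ring masks -> per-cell feature table.
#'
#' @param rgb H x W x 3 8-bit array (e.g. `virtual_slide$rgb` or
#'   [read_slide_rgb()]).
#' @param stains a `stain_matrix`.
#' @param seg_params a [segmentation_params()].
#' @return List with `cells` (feature table), `labelmap`, `hx`, `aec`
#'   concentration maps, and `log` (named counts).
#' @export
analyze_slide <- function(rgb, stains = default_stain_matrix(),
                          seg_params = segmentation_params()) {
  od <- rgb_to_od(rgb)
  maps <- unmix(od, stains)
  lm <- detect_nuclei(maps$hx, seg_params)
  lm <- make_ring_masks(lm, seg_params$ring_gap_px, seg_params$ring_width_px)
  cells <- measure_cells(lm, maps$hx, maps$aec)
  list(cells = cells, labelmap = lm, hx = maps$hx, aec = maps$aec,
       log = c(nuclei_detected = length(lm$cell_ids),
               rings_nonempty = sum(!is.na(cells$aec_cyto_mean)),
               clamped_fraction = maps$clamped_fraction))
}

# Simulate + analyze one slide; returns gated hepatocyte cells with a
# combined (nuclear + cytoplasmic) antigen intensity column.
run_one_slide <- function(sim_params, stains, seg_params) {
  slide <- simulate_slide(sim_params, stains)
  res <- analyze_slide(slide$rgb, stains, seg_params)
  cells <- res$cells
  g <- hepatocyte_gate(cells)
  cells <- apply_gate(cells, g)
  cells$aec_total_mean <- cells$aec_nuclear_mean + cells$aec_cyto_mean
  list(slide = slide, cells = cells, gate = g, log = res$log)
}

#' Experiment configuration
#'
#' Bundles the simulation, segmentation and analysis settings shared by
#' the experiment drivers. Any field of [tissue_sim_params()] or
#' [segmentation_params()] can be overridden through `sim` / `seg`.
#'
#' @param experiment `"dosage"`, `"translocation"` or `"scoring"`.
#' @param replicates slides per group (dosage/translocation) — or cases
#'   for scoring, see `n_cases`.
#' @param n_cells cells per slide.
#' @param seed master seed; per-slide seeds are derived deterministically.
#' @param sim named list of [tissue_sim_params()] overrides.
#' @param seg named list of [segmentation_params()] overrides.
#' @param mock_nuclear_fraction,stim_nuclear_fraction nuclear antigen
#'   fractions of the control and stimulated groups (translocation).
#' @param n_cases,rater_miscall_prob scoring experiment: number of cases
#'   and per-rater miscall probabilities (length 2).
#' @param out_dir optional output directory; when set, the drivers write
#'   CSV tables, a plain-text summary and figures there.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment = c("dosage", "translocation", "scoring"),
                              replicates = 3, n_cells = 300, seed = 1L,
                              sim = list(), seg = list(),
                              mock_nuclear_fraction = 0.4,
                              stim_nuclear_fraction = 0.8,
                              n_cases = 22, rater_miscall_prob = c(0.3, 0.2),
                              out_dir = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(replicates >= 1, n_cells >= 1, n_cases >= 2,
            length(rater_miscall_prob) == 2)
  structure(list(experiment = experiment, replicates = as.integer(replicates),
                 n_cells = as.integer(n_cells), seed = as.integer(seed),
                 sim = sim, seg = seg,
                 mock_nuclear_fraction = mock_nuclear_fraction,
                 stim_nuclear_fraction = stim_nuclear_fraction,
                 n_cases = as.integer(n_cases),
                 rater_miscall_prob = rater_miscall_prob,
                 out_dir = out_dir),
            class = "experiment_config")
}

sim_params_for <- function(config, seed, ...) {
  over <- utils::modifyList(config$sim, list(...))
  do.call(tissue_sim_params,
          utils::modifyList(c(list(n_cells = config$n_cells, seed = seed), over),
                            list()))
}

seg_params_for <- function(config) do.call(segmentation_params, config$seg)

#' Run the gene-dosage experiment
#'
#' Simulates `replicates` slides for each genotype (wildtype dosage 2,
#' hemizygous 1, knockout 0), runs the full measurement chain with
#' hepatocyte gating, subtracts the knockout group mean and reports the
#' relative levels on the wildtype = 2 scale, with a one-way ANOVA across
#' genotypes.
#'
#' @param config an [experiment_config()].
#' @param stains a `stain_matrix`.
#' @return A `dosage_report`: list with `per_cell` (gated cell table with
#'   genotype and slide columns), `group_means`, `ratios` (wt/hemi/ko on
#'   the 2:1:0 scale), `anova`, `cutoff` (knockout-anchored), `config`,
#'   `log`.
#' @export
run_dosage_experiment <- function(config, stains = default_stain_matrix()) {
  stopifnot(inherits(config, "experiment_config"))
  seg <- seg_params_for(config)
  genotypes <- c(wt = 2, hemi = 1, ko = 0)
  per_cell <- list(); logs <- list()
  k <- 0L
  for (g in names(genotypes)) {
    for (rep in seq_len(config$replicates)) {
      k <- k + 1L
      sp <- sim_params_for(config, seed = config$seed + 1000L * k,
                           dosage_level = genotypes[[g]])
      one <- run_one_slide(sp, stains, seg)
      cells <- one$cells[one$cells$gate_hepatocyte, , drop = FALSE]
      if (nrow(cells)) {
        cells$genotype <- g; cells$slide <- rep
        per_cell[[k]] <- cells
      }
      logs[[k]] <- c(genotype = g, slide = rep, one$log,
                     hepatocytes_gated = nrow(cells))
    }
  }
  per_cell <- do.call(rbind, per_cell)
  group_means <- tapply(per_cell$aec_total_mean, per_cell$genotype, mean,
                        na.rm = TRUE)
  group_means <- as.list(group_means[c("wt", "hemi", "ko")])
  ratios <- dosage_ratios(group_means)
  cutoff <- background_cutoff(
    per_cell$aec_nuclear_mean[per_cell$genotype == "ko"])
  anova <- compare_groups(per_cell$aec_total_mean, per_cell$genotype,
                          "one_way_anova")
  report <- structure(list(per_cell = per_cell,
                           group_means = unlist(group_means),
                           ratios = ratios, anova = anova, cutoff = cutoff,
                           config = config, seg_params = seg, log = logs),
                      class = "dosage_report")
  if (!is.null(config$out_dir)) write_dosage_report(report)
  report
}

#' Run the translocation experiment
#'
#' Mock and stimulated groups share every parameter except the nuclear
#' antigen fraction. Reports per-group nuclear/cytoplasmic ratios with a
#' Student's t-test, and compartment positive fractions against a
#' knockout-anchored cut-off derived from matched knockout slides.
#'
#' @inheritParams run_dosage_experiment
#' @return A `translocation_report`: list with `per_cell`, `nc` (per-group
#'   [nc_ratio()] summaries), `t_test` on per-cell N/C ratios,
#'   `positive_fractions` (group x compartment percentages), `cutoffs`,
#'   `config`, `log`.
#' @export
run_translocation_experiment <- function(config, stains = default_stain_matrix()) {
  stopifnot(inherits(config, "experiment_config"))
  seg <- seg_params_for(config)
  groups <- c(mock = config$mock_nuclear_fraction,
              stim = config$stim_nuclear_fraction)
  per_cell <- list(); logs <- list(); ko_cells <- list()
  k <- 0L
  for (g in names(groups)) {
    for (rep in seq_len(config$replicates)) {
      k <- k + 1L
      sp <- sim_params_for(config, seed = config$seed + 1000L * k,
                           dosage_level = 2, nuclear_fraction = groups[[g]])
      one <- run_one_slide(sp, stains, seg)
      cells <- one$cells[one$cells$gate_hepatocyte, , drop = FALSE]
      cells$group <- g; cells$slide <- rep
      per_cell[[k]] <- cells
      logs[[k]] <- c(group = g, slide = rep, one$log,
                     hepatocytes_gated = nrow(cells))
      # matched knockout slide for the background anchor
      spk <- sim_params_for(config, seed = config$seed + 1000L * k + 500L,
                            dosage_level = 0, nuclear_fraction = groups[[g]])
      onek <- run_one_slide(spk, stains, seg)
      ko_cells[[k]] <- onek$cells[onek$cells$gate_hepatocyte, , drop = FALSE]
    }
  }
  per_cell <- do.call(rbind, per_cell)
  ko <- do.call(rbind, ko_cells)
  cutoffs <- list(
    nuclear = background_cutoff(ko$aec_nuclear_mean, source_group = "ko"),
    cytoplasmic = background_cutoff(ko$aec_cyto_mean, source_group = "ko"))

  nc <- lapply(split(per_cell, per_cell$group), nc_ratio)
  rmock <- nc$mock$per_cell$nc_ratio; rstim <- nc$stim$per_cell$nc_ratio
  t_test <- compare_groups(c(rmock, rstim),
                           rep(c("mock", "stim"), c(length(rmock), length(rstim))),
                           "t_test")
  pf <- expand.grid(group = names(groups), compartment = c("nuclear", "cytoplasmic"),
                    stringsAsFactors = FALSE)
  pf$percent_positive <- mapply(function(g, comp) {
    v <- if (comp == "nuclear") per_cell$aec_nuclear_mean[per_cell$group == g]
         else per_cell$aec_cyto_mean[per_cell$group == g]
    positive_fraction(v, cutoffs[[comp]])
  }, pf$group, pf$compartment)
  mean_int <- expand.grid(group = names(groups),
                          compartment = c("nuclear", "cytoplasmic"),
                          stringsAsFactors = FALSE)
  mean_int$mean_intensity <- mapply(function(g, comp) {
    v <- if (comp == "nuclear") per_cell$aec_nuclear_mean[per_cell$group == g]
         else per_cell$aec_cyto_mean[per_cell$group == g]
    mean(v, na.rm = TRUE)
  }, mean_int$group, mean_int$compartment)

  report <- structure(list(per_cell = per_cell, nc = nc, t_test = t_test,
                           positive_fractions = pf,
                           compartment_means = mean_int,
                           cutoffs = cutoffs, config = config,
                           seg_params = seg, log = logs),
                      class = "translocation_report")
  if (!is.null(config$out_dir)) write_translocation_report(report)
  report
}

#' Run the scoring / inter-rater agreement experiment
#'
#' Simulates a case series with known true scores 0..3: each case is one
#' small slide whose dosage scales with the true score. The software score
#' comes from the measured nuclear intensities via calibration-derived
#' zone boundaries; two raters with symmetric miscall noise score the same
#' cases. Reports all pairwise agreements, weighted kappas with
#' Landis--Koch categories and the three-way overlap.
#'
#' @inheritParams run_dosage_experiment
#' @return A `scoring_report`: list with `cases` (true score, measured
#'   intensity, software + rater scores), `agreement` (an
#'   `agreement_report`), `boundaries`, `config`.
#' @export
run_scoring_experiment <- function(config, stains = default_stain_matrix()) {
  stopifnot(inherits(config, "experiment_config"))
  seg <- seg_params_for(config)
  n <- config$n_cases
  set.seed(config$seed)
  true_scores <- rep_len(0:3, n)[sample.int(n)]
  intensity <- numeric(n)
  for (i in seq_len(n)) {
    # one compact slide per case; expression scales with the true score
    # via the rendered OD per antigen unit (dosage stays at 2 alleles)
    sp <- sim_params_for(config, seed = config$seed + 10L * i,
                         dosage_level = 2,
                         image_height_px = 192L, image_width_px = 192L)
    sp$n_cells <- min(sp$n_cells, 40L)
    sp$od_per_unit <- sp$od_per_unit * true_scores[i] / 3
    one <- run_one_slide(sp, stains, seg)
    cells <- one$cells[one$cells$gate_hepatocyte, , drop = FALSE]
    intensity[i] <- mean(cells$aec_nuclear_mean)
  }
  boundaries <- score_boundaries(intensity)
  software <- score_from_intensity(intensity, boundaries)
  set.seed(config$seed + 7L)
  rater1 <- simulate_rater(true_scores, config$rater_miscall_prob[1])
  rater2 <- simulate_rater(true_scores, config$rater_miscall_prob[2])
  agreement <- three_way_overlap(rater1, rater2, software,
                                 labels = c("rater1", "rater2", "software"))
  cases <- data.frame(case_id = seq_len(n), true_score = true_scores,
                      nuclear_mean_intensity = intensity,
                      software = software, rater1 = rater1, rater2 = rater2)
  report <- structure(list(cases = cases, agreement = agreement,
                           boundaries = boundaries, config = config),
                      class = "scoring_report")
  if (!is.null(config$out_dir)) write_scoring_report(report)
  report
}
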