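#' Pipeline configuration
#'
#' Collects every knob of the two-stage analysis in one object. Defaults
#' mirror the printed choices of the study design the package implements:
#' detection filter at p > 0.01 in > 10 percent of samples, forests with
#' `mtry = 0.1p`, `ntree = 500` and a balanced 50/50 per-class bootstrap,
#' global-minimum stopping on the focal (atopic) class, family-wise alpha
#' 0.05 split over the selected sites, and replication at alpha 0.05.
#'
#' @param simulation A [simulation_config()] used when `input_dir` is
#'   `NULL`.
#' @param input_dir Optional directory of plain-text inputs in the layout
#'   written by [write_methylation_dataset()].
#' @param p_threshold,sample_fraction Detection-filter settings.
#' @param mtry,ntree,sampsize Forest settings (see [forest_params()]).
#' @param stop_policy,focal_class,max_iterations Recursive-elimination
#'   settings (see [recursive_rf()]); `focal_class` defaults to the
#'   outcome-positive class `"1"`.
#' @param stage2_design `"pooled"` (default): stage 2 tests the joint sample,
#'   stage-1 subsample included, with sex as covariate — mirroring the
#'   discovery design and inheriting its acknowledged stage-1/stage-2
#'   non-independence. `"disjoint"`: stage 2 uses only the samples not seen
#'   by stage-1 selection, so its p-values are free of selection bias.
#' @param family_alpha Family-wise error rate for stage 2.
#' @param replication_alpha Replication significance level.
#' @param fence_k Tukey fence multiplier for stage-2 outlier recoding.
#' @param batch_adjust Apply the location-scale batch aligner to M-values.
#' @param seed Master seed for generation and forests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            p_threshold = 0.01, sample_fraction = 0.10,
                            mtry = "0.1p", ntree = 500, sampsize = c(50, 50),
                            stop_policy = "global_min", focal_class = "1",
                            max_iterations = 25L,
                            stage2_design = c("pooled", "disjoint"),
                            family_alpha = 0.05, replication_alpha = 0.05,
                            fence_k = 3, batch_adjust = TRUE, seed = 1L) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  stage2_design <- match.arg(stage2_design)
  structure(list(simulation = simulation, input_dir = input_dir,
                 p_threshold = p_threshold, sample_fraction = sample_fraction,
                 mtry = mtry, ntree = as.integer(ntree), sampsize = sampsize,
                 stop_policy = stop_policy, focal_class = focal_class,
                 max_iterations = as.integer(max_iterations),
                 stage2_design = stage2_design,
                 family_alpha = family_alpha,
                 replication_alpha = replication_alpha,
                 fence_k = fence_k, batch_adjust = isTRUE(batch_adjust),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map one-to-one onto [pipeline_config()] arguments; an
#' optional `simulation` block maps onto [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(simulation_config, raw$simulation)
  do.call(pipeline_config, raw)
}

#' Run the full two-stage pipeline
#'
#' Executes, in order: data acquisition (simulation or plain-text input),
#' the QC funnel (detection filter, sex-chromosome removal, SNP-probe
#' removal), beta-to-M conversion with optional batch alignment, cell-type
#' deconvolution, stage-1 recursive Random-Forest selection on the stage-1
#' subsample (beta scale), stage-2 covariate-adjusted logistic association
#' for atopy and high IgE on the pooled sample (M scale, outlier-recoded,
#' Bonferroni threshold `family_alpha / n_selected`), and, when an external
#' result set is supplied, the replication filter.
#'
#' Identical configuration and seed give identical results end to end.
#'
#' @param config A [pipeline_config()].
#' @param external Optional external-cohort association results for
#'   [replicate_associations()].
#' @param out_dir Optional directory; when given, the filter report and run
#'   summary (JSON), selection trace, association and replication tables
#'   (CSV) are written there.
#' @return An `ewas_pipeline` report object.
#' @export
run_pipeline <- function(config, external = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- if (is.null(config$input_dir)) {
    cfg <- config$simulation
    cfg$seed <- config$seed
    generate_methylation_dataset(cfg)
  } else {
    read_methylation_dataset(config$input_dir)
  }
  phen <- sim$phenotype
  ds0 <- sim$dataset

  # ---- QC funnel (fixed order: detection -> sex -> SNP) ----
  entry <- length(ds0$probe_ids)
  ds1 <- filter_detection(ds0, config$p_threshold, config$sample_fraction)
  n_det <- length(attr(ds1, "removed"))
  ds2 <- remove_sex_chromosomes(ds1, sim$annotation)
  n_sex <- length(attr(ds2, "removed"))
  ds3 <- remove_snp_probes(ds2, sim$annotation)
  n_snp <- length(attr(ds3, "removed"))
  report <- probe_accounting(entry - n_det, detection_removed = n_det,
                             sex_removed = n_sex, snp_removed = n_snp)

  # ---- transforms ----
  m <- beta_to_m(ds3$beta, clip = 1e-6)
  batch <- phen$batch[match(ds3$sample_ids, phen$sample_id)]
  if (config$batch_adjust && length(unique(batch)) > 1 &&
      all(table(batch) >= 2))
    m <- adjust_batch(m, batch)

  # ---- cell-type deconvolution ----
  cell_props <- estimate_cell_proportions(ds3$beta, sim$cell_reference)
  cell_cols <- setdiff(names(cell_props), c("sample_id", "residual_norm"))

  # ---- stage 1: recursive selection on the stage-1 subsample ----
  idx <- match(ds3$sample_ids, phen$sample_id)
  stage1 <- which(phen$stage[idx] == 1L)
  x1 <- t(ds3$beta[, stage1, drop = FALSE])
  if (anyNA(x1))
    x1 <- t(impute_class_mean(t(x1), phen$atopy[idx][stage1]))
  y1 <- factor(phen$atopy[idx][stage1], levels = c(0, 1))
  fp <- forest_params(ntree = config$ntree, mtry = config$mtry,
                      sampsize = config$sampsize, seed = config$seed)
  selection <- recursive_rf(x1, y1, fp, focal_class = config$focal_class,
                            stop_policy = config$stop_policy,
                            max_iterations = config$max_iterations)
  selected <- selection$selected_variables

  # ---- stage 2: association with covariates (pooled or disjoint sample) ----
  s2 <- if (config$stage2_design == "pooled") seq_along(ds3$sample_ids) else
    which(phen$stage[idx] == 2L)
  if (!length(s2))
    stop("disjoint stage-2 design requested but no stage-2 samples exist")
  m_sel <- m[selected, s2, drop = FALSE]
  m_sel <- recode_outliers(m_sel, strata = phen$atopy[idx][s2],
                           fence_k = config$fence_k)
  recoded <- attr(m_sel, "recoded")
  covs <- cell_props[match(ds3$sample_ids[s2], cell_props$sample_id),
                     cell_cols, drop = FALSE]
  covs <- drop_collinear_celltypes(covs)
  sex <- phen$sex[idx][s2]
  if (length(unique(sex)) > 1) covs$sex_male <- as.integer(sex == "M")
  assoc_atopy <- test_associations(m_sel, phen$atopy[idx][s2], covs,
                                   outcome_name = "atopy",
                                   family_alpha = config$family_alpha)
  assoc_ige <- if ("high_ige" %in% names(phen))
    test_associations(m_sel, phen$high_ige[idx][s2], covs,
                      outcome_name = "high_ige",
                      family_alpha = config$family_alpha)
  sig_atopy <- significance_filter(assoc_atopy, attr(assoc_atopy, "alpha"))

  replication <- if (!is.null(external))
    replicate_associations(sig_atopy, external, config$replication_alpha)

  out <- structure(
    list(config = config,
         filter_report = report,
         cell_proportions = cell_props,
         selection = selection,
         associations = list(atopy = assoc_atopy, high_ige = assoc_ige),
         recoded_cells = recoded,
         replication = replication,
         counts = list(
           probes_entry = entry,
           probes_analysed = report$remaining,
           n_stage1 = length(stage1),
           n_stage2 = length(s2),
           n_selected = length(selected),
           n_tested_atopy = nrow(assoc_atopy),
           n_significant_atopy = attr(sig_atopy, "n_retained"),
           n_significant_ige = if (!is.null(assoc_ige))
             attr(significance_filter(assoc_ige, attr(assoc_ige, "alpha")),
                  "n_retained"),
           n_replication_tested = replication$n_tested,
           n_replicated = replication$n_replicated),
         truth = sim$truth,
         seed = config$seed),
    class = "ewas_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# guard against an ill-conditioned covariate block: drop the
# largest-mean-proportion cell type if the design is near-singular
drop_collinear_celltypes <- function(covs) {
  mm <- as.matrix(covs)
  if (ncol(mm) < 2 || !nrow(mm)) return(covs)
  k <- kappa(cbind(1, mm), exact = FALSE)
  if (is.finite(k) && k < 1e8) return(covs)
  drop <- names(which.max(colMeans(mm, na.rm = TRUE)))
  message("dropping near-collinear cell-type covariate: ", drop)
  covs[, setdiff(names(covs), drop), drop = FALSE]
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$selection$trace,
                   file.path(out_dir, "selection_trace.csv"),
                   row.names = FALSE)
  writeLines(report$selection$selected_variables,
             file.path(out_dir, "selected_probes.txt"))
  utils::write.csv(report$associations$atopy,
                   file.path(out_dir, "associations_atopy.csv"),
                   row.names = FALSE)
  if (!is.null(report$associations$high_ige))
    utils::write.csv(report$associations$high_ige,
                     file.path(out_dir, "associations_high_ige.csv"),
                     row.names = FALSE)
  utils::write.csv(report$cell_proportions,
                   file.path(out_dir, "cell_proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$recoded_cells,
                   file.path(out_dir, "recoded_cells.csv"), row.names = FALSE)
  if (!is.null(report$replication))
    utils::write.csv(report$replication$records,
                     file.path(out_dir, "replication.csv"), row.names = FALSE)
  audit <- list(
    seed = report$seed,
    parameters = report$config[setdiff(names(report$config),
                                       c("simulation", "input_dir"))],
    filter_report = unclass(report$filter_report),
    counts = report$counts,
    selected_iteration = report$selection$selected_iteration,
    alpha_stage2 = attr(report$associations$atopy, "alpha"))
  jsonlite::write_json(audit, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ewas_pipeline <- function(x, ...) {
  cat("Two-stage EWAS pipeline run (seed", x$seed, ")\n")
  print(x$filter_report)
  cat(sprintf("stage 1: %d samples, selected iteration %d -> %d CpGs\n",
              x$counts$n_stage1, x$selection$selected_iteration,
              x$counts$n_selected))
  cat(sprintf("stage 2: %d samples, %d CpGs tested, %d atopy-significant at alpha %.3g\n",
              x$counts$n_stage2, x$counts$n_tested_atopy,
              x$counts$n_significant_atopy,
              attr(x$associations$atopy, "alpha")))
  if (!is.null(x$counts$n_significant_ige))
    cat(sprintf("         %d high-IgE-significant\n", x$counts$n_significant_ige))
  if (!is.null(x$replication))
    cat(sprintf("replication: %d of %d tested sites replicated\n",
                x$replication$n_replicated, x$replication$n_tested))
  invisible(x)
}
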