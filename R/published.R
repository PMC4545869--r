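#' Published cohort summary statistics shipped with the package
#'
#' Small plain-text tables of published summary statistics from the two
#' birth cohorts the package's design mirrors (an Isle of Wight age-18
#' discovery sample and a BAMSE age-8 replication sample), shipped so that
#' the threshold, significance and replication logic can be exercised and
#' audited on real printed numbers without access to individual-level data.
#'
#' * `stage2_summary()` — per-CpG adjusted odds ratios and Wald p-values for
#'   atopy and high IgE in the discovery cohort, plus the replication
#'   cohort's adjusted OR and p (`NA` where a probe was unavailable there).
#' * `selection_trajectory()` — the published recursive-elimination error
#'   trajectory: variable count, overall OOB error and per-class
#'   misclassification (percent) at each of 15 iterations starting from
#'   254,460 CpGs.
#' * `stage1_cell_adjustment()` — crude versus cell-type-adjusted logistic
#'   coefficients and the percent coefficient change for the 62 selected
#'   CpGs.
#'
#' @return A data frame.
#' @name published_tables
NULL

published_table <- function(file) {
  path <- system.file("extdata", file, package = "rrfews", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname published_tables
#' @export
stage2_summary <- function() published_table("stage2_discovery_replication.csv")

#' @rdname published_tables
#' @export
selection_trajectory <- function() {
  published_table("stage1_selection_trajectory.csv")
}

#' @rdname published_tables
#' @export
stage1_cell_adjustment <- function() published_table("stage1_crude_adjusted.csv")
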