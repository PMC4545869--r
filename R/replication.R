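#' Independent-cohort replication filter
#'
#' Applies the replication criterion to a discovery result set and an
#' external cohort's result set: a probe replicates when it is available in
#' the external set, the adjusted odds ratios lie on the same side of 1 in
#' both cohorts, and the external p-value is strictly below `alpha`. An
#' external odds ratio exactly 1 has no direction and counts as
#' non-concordant. Probes absent from the external set (or with missing
#' OR/p there) are marked unavailable and excluded from the tested
#' denominator.
#'
#' @param discovery Data frame with columns `probe_id` and an odds-ratio
#'   column (`or_column`, default `"adjusted_or"`).
#' @param external Data frame with `probe_id`, an odds-ratio column and a
#'   p-value column (`p_column`, default `"wald_p"`).
#' @param alpha Replication significance level (default 0.05).
#' @param or_column,p_column Column names in the two inputs.
#'
#' @return List: `records` (one row per discovery probe: directions,
#'   external p, `available`, `replicated`), `n_discovery`, `n_tested`,
#'   `n_replicated`.
#' @export
replicate_associations <- function(discovery, external, alpha = 0.05,
                                   or_column = "adjusted_or",
                                   p_column = "wald_p") {
  stopifnot(is.data.frame(discovery), is.data.frame(external),
            "probe_id" %in% names(discovery), "probe_id" %in% names(external))
  if (anyDuplicated(external$probe_id))
    stop("probe id join is not well-defined: duplicated ids in external set")
  d_or <- discovery[[or_column]]
  e_or <- external[[or_column]][match(discovery$probe_id, external$probe_id)]
  e_p <- external[[p_column]][match(discovery$probe_id, external$probe_id)]
  if (any(!is.na(d_or) & d_or <= 0) || any(!is.na(e_or) & e_or <= 0))
    stop("odds ratios must be positive")
  available <- !is.na(e_or) & !is.na(e_p)
  d_dir <- sign(log(d_or))
  e_dir <- sign(log(e_or))
  replicated <- available & !is.na(d_dir) & d_dir != 0 & e_dir == d_dir &
    e_p < alpha
  records <- data.frame(
    probe_id = discovery$probe_id,
    discovery_direction = d_dir,
    replication_direction = e_dir,
    replication_p = e_p,
    available = available,
    replicated = replicated,
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records,
       n_discovery = nrow(discovery),
       n_tested = sum(available),
       n_replicated = sum(replicated))
}
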