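#' Logistic association fit for one CpG
#'
#' Maximum-likelihood logistic regression of a binary outcome on an
#' M-value exposure, optionally adjusted for covariates, via iteratively
#' reweighted least squares ([stats::glm()] with a tight convergence
#' tolerance and up to 100 iterations). Rows with missing values are dropped
#' case-wise. The p-value is a two-sided Wald test of the exposure
#' coefficient.
#'
#' Complete or quasi-complete separation (diverging coefficient, fitted
#' probabilities at the boundary) and collinear covariates are errors, so a
#' caller scanning many probes can skip and log the offending probe.
#'
#' @param outcome Binary vector (0/1 or two-level factor).
#' @param exposure Numeric vector (M-values).
#' @param covariates Optional numeric matrix or data frame of covariates.
#'
#' @return List: `beta` (log-odds per unit exposure), `se`, `p`, `or`,
#'   `n_used`.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  dat <- data.frame(.y = y, .x = as.numeric(exposure))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_par <- ncol(dat)  # intercept + exposure + covariates
  if (nrow(dat) <= n_par)
    stop("too few complete observations for the number of parameters")
  if (length(unique(dat$.y)) < 2)
    stop("outcome is constant after case-wise deletion")

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    stop("collinear covariate(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  if (separation && (abs(co[".x"]) > 10 || sm[".x", "Std. Error"] > 100))
    stop("complete or quasi-complete separation on the exposure")
  beta <- unname(co[".x"])
  se <- unname(sm[".x", "Std. Error"])
  p <- unname(sm[".x", "Pr(>|z|)"])
  list(beta = beta, se = se, p = p, or = exp(beta), n_used = nrow(dat))
}

#' Crude versus adjusted association for one CpG
#'
#' Fits the crude (exposure-only) and covariate-adjusted logistic models and
#' reports the percent change of the exposure coefficient,
#' `100 * (adjusted - crude) / crude`, the confounding diagnostic used to
#' judge whether cell-type composition drove a probe's selection. (Note the
#' orientation: an adjustment that strengthens a negative coefficient from
#' -1.18 to -1.43 is reported as +21 percent.)
#'
#' @inheritParams fit_logistic
#' @param covariates Covariate matrix/data frame for the adjusted model.
#' @param alpha Significance level applied to the adjusted Wald p.
#' @return One-row data frame: crude and adjusted coefficients, standard
#'   errors and p-values, `adjusted_or`, `pct_diff_beta` (`NA` when the
#'   crude coefficient is 0), `n_used`, `significant`.
#' @export
crude_vs_adjusted <- function(outcome, exposure, covariates, alpha = 0.05) {
  crude <- fit_logistic(outcome, exposure)
  adj <- fit_logistic(outcome, exposure, covariates)
  pct <- if (crude$beta == 0) NA_real_ else
    100 * (adj$beta - crude$beta) / crude$beta
  data.frame(crude_beta = crude$beta, crude_se = crude$se, crude_p = crude$p,
             adjusted_beta = adj$beta, adjusted_se = adj$se,
             adjusted_p = adj$p, adjusted_or = adj$or,
             pct_diff_beta = pct, n_used = adj$n_used,
             significant = adj$p < alpha)
}

#' Bonferroni-adjusted significance level
#'
#' @param n_tests Number of tests in the family (>= 1).
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return `family_alpha / n_tests`.
#' @examples
#' signif(bonferroni_alpha(62), 3)  # 8.06e-04
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  family_alpha / n_tests
}

#' Filter results by significance threshold
#'
#' Retains entries with p-value strictly below `alpha`, preserving input
#' order. Accepts a bare p-value vector or a data frame with a p-value
#' column.
#'
#' @param results Numeric p-value vector, or data frame.
#' @param alpha Significance level.
#' @param p_column Column holding p-values when `results` is a data frame.
#' @return The retained subset, with attribute `"n_retained"`.
#' @export
significance_filter <- function(results, alpha, p_column = "wald_p") {
  p <- if (is.data.frame(results)) results[[p_column]] else as.numeric(results)
  if (is.null(p)) stop("no p-value column '", p_column, "' in results")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("invalid p-values")
  keep <- !is.na(p) & p < alpha
  out <- if (is.data.frame(results)) results[keep, , drop = FALSE] else
    results[keep]
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Pearson chi-square test for a 2x2 prevalence table
#'
#' Pearson's chi-square with 1 degree of freedom for a 2x2 contingency
#' table. With `continuity_correction` (the default), the Yates correction
#' reduces `|ad - bc|` by `n/2`, clamped at zero, before squaring. The
#' p-value is the upper tail of the chi-square distribution.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param continuity_correction Apply the Yates correction (default `TRUE`).
#' @return List: `statistic`, `p_value`, `df` (always 1), `corrected`.
#' @examples
#' # high-IgE prevalence, 24/77 females vs 18/25 males
#' prevalence_chi2(matrix(c(24, 77, 18, 25), 2))$p_value  # ~0.047
#' @export
prevalence_chi2 <- function(table, continuity_correction = TRUE) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != floor(table)))
    stop("cells must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in the contingency table")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  n <- sum(table)
  dev <- abs(a * d - b * c_)
  if (continuity_correction) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / (prod(rowSums(table)) * prod(colSums(table)))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, corrected = continuity_correction)
}

#' Per-CpG association scan
#'
#' Runs [crude_vs_adjusted()] for every probe of an M-value matrix against a
#' binary outcome, applies the Bonferroni threshold
#' `family_alpha / n_probes`, and collects the results. Probes whose fit
#' fails (separation, constant outcome after deletion, too few complete
#' cases) are skipped and logged in the `"skipped"` attribute rather than
#' aborting the scan.
#'
#' @param m_matrix Probes-by-samples M-value matrix (missing values allowed;
#'   case-wise deletion per probe).
#' @param outcome Binary outcome per sample.
#' @param covariates Covariate data frame/matrix (samples in rows), e.g.
#'   cell proportions and sex.
#' @param outcome_name Label stored in the result rows.
#' @param family_alpha Family-wise error rate for the Bonferroni threshold.
#' @return Data frame of class `association_scan`, one row per tested
#'   probe, with `probe_id`, `outcome`, crude/adjusted coefficients,
#'   `adjusted_or`, `wald_p` (adjusted), `pct_diff_beta`, `n_used`,
#'   `significant`; attributes `alpha` and `skipped`.
#' @export
test_associations <- function(m_matrix, outcome, covariates = NULL,
                              outcome_name = "outcome", family_alpha = 0.05) {
  stopifnot(is.matrix(m_matrix), ncol(m_matrix) == length(outcome))
  alpha <- bonferroni_alpha(nrow(m_matrix), family_alpha)
  rows <- list(); skipped <- list()
  for (probe in rownames(m_matrix)) {
    res <- tryCatch(
      crude_vs_adjusted(outcome, m_matrix[probe, ], covariates, alpha),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(probe_id = probe, reason = res, stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(probe_id = probe, outcome = outcome_name,
                 stringsAsFactors = FALSE),
      res)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), outcome = character())
  names(out)[names(out) == "adjusted_p"] <- "wald_p"
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(probe_id = character(), reason = character())
  class(out) <- c("association_scan", class(out))
  out
}
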