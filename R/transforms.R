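#' Methylation beta value from probe intensities
#'
#' Computes the proportion-scale methylation estimate
#' \eqn{\beta = M / (c + M + U)} from methylated (\eqn{M}) and unmethylated
#' (\eqn{U}) probe intensities. The offset \eqn{c} guards against a zero
#' denominator for probes with negligible total signal; with \eqn{c > 0} the
#' result is strictly below 1.
#'
#' @param methylated Non-negative methylated-channel intensity (vectorised).
#' @param unmethylated Non-negative unmethylated-channel intensity.
#' @param offset Non-negative denominator offset \eqn{c}. The Illumina
#'   convention of 100 is the default.
#'
#' @return Numeric vector of beta values in `[0, 1)` (in `[0, 1]` when
#'   `offset = 0`).
#' @examples
#' beta_from_intensities(300, 100, offset = 0)  # 0.75
#' beta_from_intensities(100, 0, offset = 100)  # 0.5
#' @export
beta_from_intensities <- function(methylated, unmethylated, offset = 100) {
  if (any(methylated < 0) || any(unmethylated < 0) || any(offset < 0))
    stop("intensities and offset must be non-negative")
  denom <- offset + methylated + unmethylated
  if (any(denom == 0))
    stop("degenerate input: methylated, unmethylated and offset are all zero")
  methylated / denom
}

#' Beta/M-value transforms
#'
#' `beta_to_m()` maps proportion-scale beta values to logit2 ("M") scale via
#' \eqn{\log_2(\beta / (1 - \beta))}; `m_to_beta()` is its exact inverse.
#' M-values are approximately homoscedastic and are the working scale for the
#' stage-2 logistic models, while beta values stay bounded and interpretable
#' as percent methylation.
#'
#' Beta values of exactly 0 or 1 have no finite M-value. By default they are
#' an error; passing a positive `clip` instead clamps beta into
#' `[clip, 1 - clip]` before the transform (an explicit opt-in, never silent).
#'
#' @param beta Numeric vector with values in (0, 1) (or \[0, 1\] when `clip`
#'   is given).
#' @param m Numeric vector of M-values.
#' @param clip `NULL` (default, strict domain) or a small positive epsilon.
#'
#' @return Numeric vector of the same length.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' m_to_beta(beta_to_m(0.73))   # 0.73
#' @export
beta_to_m <- function(beta, clip = NULL) {
  if (!is.null(clip)) {
    stopifnot(is.numeric(clip), length(clip) == 1L, clip > 0, clip < 0.5)
    beta <- pmin(pmax(beta, clip), 1 - clip)
  }
  bad <- !is.na(beta) & (beta <= 0 | beta >= 1)
  if (any(bad))
    stop("beta values must lie strictly in (0, 1); ",
         "use `clip` to clamp boundary values explicitly")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # 1 / (1 + 2^-m) is overflow-safe for large |m|
  ifelse(m > 0, 1 / (1 + 2^(-m)), 2^m / (1 + 2^m))
}
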