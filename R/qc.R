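#' Methylation dataset container
#'
#' Bundles a probes-by-samples beta-value matrix with an optional
#' same-shape detection p-value matrix. Probe and sample identifiers are
#' taken from the dimnames and must be unique. Missing beta entries are
#' permitted (they arise after outlier recoding); non-missing entries must
#' lie in `[0, 1]`.
#'
#' @param beta Numeric matrix, probes in rows, samples in columns, with
#'   dimnames.
#' @param detection_p Optional numeric matrix of detection p-values with the
#'   same shape and dimnames.
#'
#' @return An object of class `methylation_dataset` with elements `beta`,
#'   `detection_p`, `probe_ids`, `sample_ids`.
#' @export
methylation_dataset <- function(beta, detection_p = NULL) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (anyDuplicated(rownames(beta))) stop("probe ids must be unique")
  if (anyDuplicated(colnames(beta))) stop("sample ids must be unique")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1] wherever non-missing")
  if (!is.null(detection_p)) {
    if (!identical(dim(beta), dim(detection_p)))
      stop("beta and detection_p shapes disagree")
    if (!identical(dimnames(beta), dimnames(detection_p)))
      stop("beta and detection_p dimnames disagree")
    if (min(detection_p, na.rm = TRUE) < 0 || max(detection_p, na.rm = TRUE) > 1)
      stop("detection p-values must lie in [0, 1]")
  }
  structure(
    list(beta = beta, detection_p = detection_p,
         probe_ids = rownames(beta), sample_ids = colnames(beta)),
    class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("methylation_dataset:", length(x$probe_ids), "probes x",
      length(x$sample_ids), "samples\n")
  cat("  detection p-values:", if (is.null(x$detection_p)) "absent" else "present", "\n")
  cat("  missing beta entries:", sum(is.na(x$beta)), "\n")
  invisible(x)
}

keep_probes <- function(dataset, keep) {
  methylation_dataset(
    dataset$beta[keep, , drop = FALSE],
    if (!is.null(dataset$detection_p)) dataset$detection_p[keep, , drop = FALSE])
}

#' Detection p-value probe filter
#'
#' Removes probes whose measurement failed in too many samples. A probe is
#' removed when the fraction of samples with detection p-value above
#' `p_threshold` is strictly greater than `sample_fraction`; a probe failing
#' in exactly `sample_fraction` of samples is retained.
#'
#' @param dataset A [methylation_dataset()] with detection p-values present.
#' @param p_threshold Detection p-value above which a single measurement
#'   counts as failed (default 0.01).
#' @param sample_fraction Tolerated failing-sample fraction (default 0.10).
#'
#' @return The filtered `methylation_dataset`, with attribute `"removed"`
#'   holding the removed probe ids.
#' @export
filter_detection <- function(dataset, p_threshold = 0.01, sample_fraction = 0.10) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  if (is.null(dataset$detection_p))
    stop("detection p-value matrix is absent; cannot apply the detection filter")
  n <- length(dataset$sample_ids)
  fail_frac <- rowSums(dataset$detection_p > p_threshold, na.rm = TRUE) / n
  keep <- fail_frac <= sample_fraction
  out <- keep_probes(dataset, keep)
  attr(out, "removed") <- dataset$probe_ids[!keep]
  out
}

#' Remove sex-chromosome probes
#'
#' Drops every probe whose manifest chromosome label is `"X"` or `"Y"`.
#'
#' @param dataset A [methylation_dataset()].
#' @param annotation A probe annotation data frame (see
#'   [probe_annotation()]) covering every probe in `dataset`.
#'
#' @return Filtered dataset with attribute `"removed"`.
#' @export
remove_sex_chromosomes <- function(dataset, annotation) {
  chr <- annotation_lookup(dataset, annotation, "chr")
  keep <- !(chr %in% c("X", "Y"))
  out <- keep_probes(dataset, keep)
  attr(out, "removed") <- dataset$probe_ids[!keep]
  out
}

#' Remove SNP-affected probes
#'
#' Drops every probe flagged in the manifest as having a potential SNP in the
#' probe binding region or at the base-pair extension. Leaving such probes in
#' would let genotype masquerade as methylation and, because forest-based
#' selection is conditional on the other retained variables, bias the
#' selection of unaffected probes too.
#'
#' @inheritParams remove_sex_chromosomes
#' @return Filtered dataset with attribute `"removed"`.
#' @export
remove_snp_probes <- function(dataset, annotation) {
  flag <- annotation_lookup(dataset, annotation, "snp_flag")
  keep <- !as.logical(flag)
  out <- keep_probes(dataset, keep)
  attr(out, "removed") <- dataset$probe_ids[!keep]
  out
}

annotation_lookup <- function(dataset, annotation, column) {
  stopifnot(inherits(dataset, "methylation_dataset"), is.data.frame(annotation))
  idx <- match(dataset$probe_ids, annotation$probe_id)
  if (anyNA(idx)) {
    missing <- dataset$probe_ids[is.na(idx)]
    stop("unannotated probe(s): ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  annotation[[column]][idx]
}

#' Probe annotation table
#'
#' Validates a manifest-style annotation: one record per probe with
#' chromosome label (1-22, X, Y), 1-based coordinate, gene name(s), gene
#' region(s), CpG-island relation and a SNP flag.
#'
#' @param probe_id,chr,coordinate,gene,gene_region,island_relation,snp_flag
#'   Equal-length vectors (gene/region/island may be `NA`).
#' @return A `data.frame` with those columns.
#' @export
probe_annotation <- function(probe_id, chr, coordinate, gene = NA,
                             gene_region = NA, island_relation = NA,
                             snp_flag = FALSE) {
  chr <- as.character(chr)
  allowed <- c(as.character(1:22), "X", "Y")
  if (!all(chr %in% allowed))
    stop("chromosome labels must be one of 1-22, X, Y")
  if (anyDuplicated(probe_id)) stop("one record per probe required")
  data.frame(probe_id = as.character(probe_id), chr = chr,
             coordinate = as.integer(coordinate),
             gene = as.character(gene), gene_region = as.character(gene_region),
             island_relation = as.character(island_relation),
             snp_flag = as.logical(snp_flag),
             stringsAsFactors = FALSE)
}

#' Probe-filtering funnel accounting
#'
#' Reconciles probe counts through the fixed cleaning funnel
#' (detection filter, then sex chromosomes, then SNP-flagged probes).
#' `entry` is the probe count at the head of the funnel being reconciled;
#' when mirroring a published funnel whose entry count already reflects the
#' detection filter, pass that filtered count as `entry` and the detection
#' removals are recorded but not subtracted again.
#'
#' @param entry Probes entering the funnel.
#' @param detection_removed Probes removed by the detection filter (already
#'   reflected in `entry`; recorded for the report).
#' @param sex_removed,snp_removed Probes removed at the two later stages.
#'
#' @return A `filter_report` list: per-stage counts, the implied `remaining`
#'   count, and the stage order.
#' @examples
#' probe_accounting(383998, sex_removed = 9650, snp_removed = 119888)$remaining
#' @export
probe_accounting <- function(entry, detection_removed = 0,
                             sex_removed = 0, snp_removed = 0) {
  counts <- c(entry, detection_removed, sex_removed, snp_removed)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  remaining <- entry - sex_removed - snp_removed
  if (remaining < 0)
    stop("inconsistent funnel: removals exceed the entry count")
  structure(
    list(entry = as.integer(entry),
         detection_removed = as.integer(detection_removed),
         sex_removed = as.integer(sex_removed),
         snp_removed = as.integer(snp_removed),
         remaining = as.integer(remaining),
         stage_order = c("detection", "sex_chromosomes", "snp_probes")),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("probe filtering funnel\n")
  cat(sprintf("  entry:              %8d\n", x$entry))
  cat(sprintf("  detection removed:  %8d\n", x$detection_removed))
  cat(sprintf("  sex-chr removed:    %8d\n", x$sex_removed))
  cat(sprintf("  SNP-flag removed:   %8d\n", x$snp_removed))
  cat(sprintf("  remaining:          %8d\n", x$remaining))
  invisible(x)
}

#' Location-scale batch adjustment
#'
#' Aligns each probe's per-batch location and scale to the pooled mean and
#' pooled standard deviation, removing additive and multiplicative
#' inter-array (batch) differences. This is a deliberately simple
#' location-scale aligner, not an empirical-Bayes adjuster: it shrinks
#' nothing across probes, so it is exact per probe and is the package's
#' default extension point for plugging in a heavier batch model.
#'
#' Probes with zero variance inside any batch pass through unchanged.
#' Singleton batches have no scale estimate and are an error unless
#' `location_only = TRUE`, which aligns batch means only.
#'
#' @param m_matrix Probes-by-samples numeric matrix (M scale).
#' @param batch Batch label per sample (coerced to factor).
#' @param location_only Align means only (permits singleton batches).
#'
#' @return Adjusted matrix of the same shape.
#' @export
adjust_batch <- function(m_matrix, batch, location_only = FALSE) {
  stopifnot(is.matrix(m_matrix), ncol(m_matrix) == length(batch))
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(m_matrix)
  sizes <- table(batch)
  if (any(sizes < 2) && !location_only)
    stop("singleton batch; use location_only = TRUE for a mean-only alignment")
  out <- m_matrix
  for (i in seq_len(nrow(m_matrix))) {
    x <- m_matrix[i, ]
    ok <- !is.na(x)
    pooled_mean <- mean(x[ok])
    pooled_sd <- stats::sd(x[ok])
    bm <- tapply(x[ok], batch[ok], mean)
    if (location_only) {
      out[i, ok] <- x[ok] - bm[as.character(batch[ok])] + pooled_mean
      next
    }
    bs <- tapply(x[ok], batch[ok], stats::sd)
    if (any(is.na(bs)) || any(bs == 0)) next  # degenerate probe: leave as is
    z <- (x[ok] - bm[as.character(batch[ok])]) / bs[as.character(batch[ok])]
    out[i, ok] <- z * pooled_sd + pooled_mean
  }
  out
}

#' Recode extreme outliers as missing
#'
#' Within each outcome stratum, values outside the Tukey fences
#' `[Q1 - k * IQR, Q3 + k * IQR]` are set to `NA`. Stratifying by outcome
#' avoids recoding genuine class differences as outliers. The default
#' `fence_k = 3` targets only far-out observations of the kind a boxplot
#' inspection would flag.
#'
#' @param m_matrix Probes-by-samples numeric matrix.
#' @param strata Outcome label per sample (single stratum when `NULL`).
#' @param fence_k Positive fence multiplier.
#'
#' @return The matrix with outliers set `NA`; attribute `"recoded"` is a
#'   data frame enumerating the recoded (probe, sample) cells and their
#'   former values.
#' @export
recode_outliers <- function(m_matrix, strata = NULL, fence_k = 3.0) {
  stopifnot(is.matrix(m_matrix), fence_k > 0)
  if (is.null(strata)) strata <- rep("all", ncol(m_matrix))
  stopifnot(length(strata) == ncol(m_matrix))
  strata <- as.character(strata)
  recoded <- list()
  out <- m_matrix
  for (s in unique(strata[!is.na(strata)])) {
    cols <- which(!is.na(strata) & strata == s)
    for (i in seq_len(nrow(m_matrix))) {
      x <- m_matrix[i, cols]
      q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - fence_k * iqr
      hi <- q[2] + fence_k * iqr
      bad <- which(!is.na(x) & (x < lo | x > hi))
      if (length(bad)) {
        recoded[[length(recoded) + 1L]] <- data.frame(
          probe_id = rep(rownames(m_matrix)[i] %||% as.character(i), length(bad)),
          sample_id = colnames(m_matrix)[cols[bad]] %||% as.character(cols[bad]),
          stratum = s, value = unname(x[bad]), stringsAsFactors = FALSE)
        out[i, cols[bad]] <- NA
      }
    }
  }
  attr(out, "recoded") <- if (length(recoded)) do.call(rbind, recoded) else
    data.frame(probe_id = character(), sample_id = character(),
               stratum = character(), value = numeric(), stringsAsFactors = FALSE)
  out
}

#' Mean-impute missing values within outcome class
#'
#' Forest input must be complete; missing cells are replaced by the probe's
#' mean within the sample's outcome class (falling back to the overall probe
#' mean when a class is entirely missing).
#'
#' @param m_matrix Probes-by-samples matrix.
#' @param outcome Class label per sample.
#' @return Completed matrix.
#' @export
impute_class_mean <- function(m_matrix, outcome) {
  stopifnot(is.matrix(m_matrix), length(outcome) == ncol(m_matrix))
  if (!anyNA(m_matrix)) return(m_matrix)
  outcome <- as.character(outcome)
  out <- m_matrix
  for (cl in unique(outcome)) {
    cols <- which(outcome == cl)
    sub <- out[, cols, drop = FALSE]
    if (!anyNA(sub)) next
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- rowMeans(out, na.rm = TRUE)[is.nan(mu)]
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- mu[idx[, 1]]
    out[, cols] <- sub
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
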