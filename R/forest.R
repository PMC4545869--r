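#' Forest hyperparameters
#'
#' @param ntree Number of trees.
#' @param mtry Candidate variables per split: a positive integer or one of
#'   the rule tags `"sqrt_p"`, `"2sqrt_p"`, `"0.05p"`, `"0.1p"`, `"0.5p"`
#'   resolved against the current variable count by [resolve_mtry()].
#' @param sampsize `NULL` for the ordinary (imbalanced) bootstrap, or a
#'   length-2 vector of per-class draw counts for a balanced bootstrap,
#'   e.g. `c(50, 50)`; drawn with replacement within each class, with each
#'   draw count clamped at its class frequency. Name the entries by class
#'   label to fix the order, otherwise they follow the factor levels of the
#'   outcome.
#' @param seed Integer seed; identical seeds give identical forests.
#' @return A `forest_params` list.
#' @export
forest_params <- function(ntree = 500, mtry = "sqrt_p", sampsize = NULL,
                          seed = 1L) {
  stopifnot(ntree >= 1)
  if (!is.null(sampsize)) stopifnot(length(sampsize) == 2, all(sampsize >= 1))
  structure(list(ntree = as.integer(ntree), mtry = mtry, sampsize = sampsize,
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Resolve an mtry rule against the variable count
#'
#' Rule tags are resolved with `floor()` and the result clamped into
#' `[1, p]`.
#'
#' @param rule Integer or one of `"sqrt_p"`, `"2sqrt_p"`, `"0.05p"`,
#'   `"0.1p"`, `"0.5p"`.
#' @param p Number of variables (>= 1).
#' @return Integer in `[1, p]`.
#' @examples
#' resolve_mtry("sqrt_p", 254460)  # 504
#' resolve_mtry("0.1p", 254460)    # 25446
#' @export
resolve_mtry <- function(rule, p) {
  stopifnot(p >= 1)
  val <- if (is.numeric(rule)) {
    rule
  } else {
    switch(as.character(rule),
           sqrt_p = sqrt(p),
           `2sqrt_p` = 2 * sqrt(p),
           `0.05p` = 0.05 * p,
           `0.1p` = 0.1 * p,
           `0.5p` = 0.5 * p,
           stop("unknown mtry rule: ", rule))
  }
  max(1L, min(as.integer(floor(val)), as.integer(p)))
}

#' Grow a classification forest with OOB bookkeeping
#'
#' Grows a Random Forest on a samples-by-variables matrix and a binary
#' outcome and returns the three quantities the recursive elimination loop
#' consumes: the overall out-of-bag (OOB) error, per-class OOB
#' misclassification rates, and per-variable mean-decrease-Gini importance.
#'
#' Trees are built by the randomForest package; with `sampsize` set, each
#' tree's bootstrap draws the configured number of samples per class, with
#' replacement (balanced sampling). OOB predictions are recomputed here from
#' the forest's OOB vote matrix: a sample's prediction is the class with the
#' most votes among trees whose bootstrap excluded it, ties broken toward
#' the class with lower factor-level order. Samples never out-of-bag
#' (possible at very small `ntree`) are excluded from all error denominators
#' and counted in `n_oob_covered`.
#'
#' @param x Numeric matrix, samples in rows, variables in columns, no
#'   missing values (impute upstream, e.g. [impute_class_mean()]).
#' @param y Binary outcome, coerced to factor.
#' @param params A [forest_params()].
#'
#' @return An `rf_fit` list: `oob_error`, `class_error` (named),
#'   `vim` (named mean-decrease-Gini vector), `votes` (per-sample OOB vote
#'   fractions), `oob_times`, `oob_pred`, `confusion`, `n_oob_covered`,
#'   `levels`, and the resolved `params`.
#' @export
grow_forest <- function(x, y, params = forest_params()) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("x contains missing values; impute before growing a forest")
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("outcome has a single class")
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  mtry <- resolve_mtry(params$mtry, ncol(x))

  set.seed(params$seed)
  if (is.null(params$sampsize)) {
    rf <- randomForest::randomForest(x, y, ntree = params$ntree, mtry = mtry,
                                     replace = TRUE, keep.forest = FALSE)
  } else {
    ss <- params$sampsize
    if (!is.null(names(ss))) {
      if (!setequal(names(ss), levels(y)))
        stop("sampsize names must match the outcome classes")
      ss <- ss[levels(y)]
    } else {
      names(ss) <- levels(y)
    }
    # the stratified bootstrap backend bounds per-class draws by the class
    # frequency; clamp so small classes stay usable
    ss <- pmin(ss, table(y)[names(ss)])
    rf <- randomForest::randomForest(x, y, ntree = params$ntree, mtry = mtry,
                                     replace = TRUE, strata = y,
                                     sampsize = ss, keep.forest = FALSE)
  }

  votes <- rf$votes                     # OOB vote fractions, samples x classes
  covered <- rf$oob.times > 0
  pred <- oob_predict_from_votes(votes, levels(y))
  pred[!covered] <- NA
  confusion <- table(truth = y[covered], predicted = pred[covered])
  class_error <- vapply(levels(y), function(cl) {
    idx <- covered & y == cl
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] != cl)
  }, numeric(1))
  oob_error <- mean(pred[covered] != as.character(y)[covered])

  structure(
    list(oob_error = oob_error,
         class_error = class_error,
         vim = stats::setNames(rf$importance[, "MeanDecreaseGini"],
                               rownames(rf$importance)),
         votes = votes,
         oob_times = rf$oob.times,
         oob_pred = pred,
         confusion = confusion,
         n_oob_covered = sum(covered),
         levels = levels(y),
         params = list(ntree = params$ntree, mtry = mtry,
                       sampsize = params$sampsize, seed = params$seed)),
    class = "rf_fit")
}

# class with the most OOB votes; ties go to the class with lower level order
oob_predict_from_votes <- function(votes, classes) {
  stopifnot(identical(colnames(votes), classes))
  votes[is.na(votes)] <- -Inf  # never-OOB samples have 0/0 vote fractions
  idx <- apply(votes, 1, which.max)  # which.max returns the first maximum
  classes[idx]
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, mtry %d, %d variables\n",
              x$params$ntree, x$params$mtry, length(x$vim)))
  if (!is.null(x$params$sampsize))
    cat("  balanced bootstrap, sampsize:",
        paste(x$params$sampsize, collapse = "/"), "\n")
  cat(sprintf("  OOB error %.4f (%d/%d samples OOB-covered)\n",
              x$oob_error, x$n_oob_covered, nrow(x$votes)))
  for (cl in x$levels)
    cat(sprintf("  class %-8s misclassification %.4f\n", cl,
                x$class_error[[cl]]))
  invisible(x)
}

#' Forest hyperparameter tuning table
#'
#' Runs one independently seeded forest per (`mtry` rule, `ntree`)
#' combination, plus a balanced-versus-imbalanced comparison pair at the
#' default `mtry`/`ntree`, and tabulates OOB and per-class errors.
#'
#' @param x,y As in [grow_forest()].
#' @param mtry_rules Character/numeric vector of mtry rules.
#' @param ntree_grid Integer vector of forest sizes.
#' @param sampsize Balanced per-class draw counts used for every grid row
#'   and for the balanced comparison row.
#' @param default_mtry,default_ntree Settings for the comparison pair.
#' @param seed Master seed; row `i` uses `seed + i`.
#' @return Data frame, one row per run: `phase` (`"balance"` or `"grid"`),
#'   `mtry_rule`, `mtry`, `ntree`, `balanced`, `oob_error` and one error
#'   column per class.
#' @export
tune_parameters <- function(x, y, mtry_rules = c("sqrt_p", "2sqrt_p", "0.05p",
                                                 "0.1p", "0.5p"),
                            ntree_grid = c(200, 300, 400, 500, 1000, 2000),
                            sampsize = c(50, 50),
                            default_mtry = "sqrt_p", default_ntree = 500,
                            seed = 1L) {
  if (!length(mtry_rules) || !length(ntree_grid))
    stop("mtry_rules and ntree_grid must be non-empty")
  runs <- list()
  add_run <- function(phase, rule, ntree, ss) {
    i <- length(runs) + 1L
    fit <- grow_forest(x, y, forest_params(ntree = ntree, mtry = rule,
                                           sampsize = ss, seed = seed + i))
    runs[[i]] <<- data.frame(
      phase = phase, mtry_rule = as.character(rule), mtry = fit$params$mtry,
      ntree = as.integer(ntree), balanced = !is.null(ss),
      oob_error = fit$oob_error,
      t(fit$class_error), check.names = FALSE, stringsAsFactors = FALSE)
  }
  add_run("balance", default_mtry, default_ntree, NULL)
  add_run("balance", default_mtry, default_ntree, sampsize)
  for (rule in mtry_rules)
    for (nt in ntree_grid)
      add_run("grid", rule, nt, sampsize)
  out <- do.call(rbind, runs)
  names(out)[-(1:6)] <- paste0("class_error_", names(out)[-(1:6)])
  rownames(out) <- NULL
  out
}
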