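#' Floor-halving elimination schedule
#'
#' Variable counts visited by the recursive elimination: the first entry is
#' `p0` and each subsequent entry is `floor()` of half the previous one,
#' stopping early once 1 is reached.
#'
#' @param p0 Starting variable count (>= 1).
#' @param n_iterations Maximum schedule length.
#' @return Integer vector of counts.
#' @examples
#' halving_schedule(254460, 15)[13]  # 62
#' @export
halving_schedule <- function(p0, n_iterations) {
  if (p0 < 1) stop("p0 must be at least 1")
  stopifnot(n_iterations >= 1)
  counts <- integer(0)
  count <- as.integer(p0)
  for (i in seq_len(n_iterations)) {
    counts[i] <- count
    if (count <= 1L) break
    count <- count %/% 2L
  }
  counts
}

#' Keep the top variables by importance
#'
#' Sorts variables by importance score, descending, with ties broken by
#' lexicographic variable id (a stable, documented rule), and returns the
#' top `keep_n` ids in rank order.
#'
#' @param vim Named numeric importance vector.
#' @param keep_n Number of variables to retain (`0 <= keep_n <= length(vim)`).
#' @return Character vector of variable ids.
#' @export
rank_and_keep <- function(vim, keep_n) {
  stopifnot(!is.null(names(vim)))
  if (keep_n > length(vim)) stop("keep_n exceeds the number of variables")
  if (keep_n < 0) stop("keep_n must be non-negative")
  ord <- order(-vim, names(vim))
  names(vim)[ord][seq_len(keep_n)]
}

#' Select the stopping iteration from an error trajectory
#'
#' Implements the two stopping policies of the recursive elimination.
#' `"global_min"` picks the iteration minimising the focal-class error,
#' ties broken by fewer variables, then by lower overall OOB error.
#' `"first_increase"` picks the iteration immediately before the first
#' strict rise of the focal-class error (the whole trajectory is scanned;
#' if the error never rises, the last iteration is selected).
#'
#' @param focal_error Focal-class misclassification per iteration.
#' @param n_variables Variable count per iteration.
#' @param oob_error Overall OOB error per iteration.
#' @param stop_policy `"global_min"` or `"first_increase"`.
#' @return The selected iteration index.
#' @examples
#' e <- c(.30, .20, .25, .10, .15)
#' select_iteration(e, c(100, 50, 25, 12, 6), e, "global_min")      # 4
#' select_iteration(e, c(100, 50, 25, 12, 6), e, "first_increase")  # 2
#' @export
select_iteration <- function(focal_error, n_variables, oob_error,
                             stop_policy = c("global_min", "first_increase")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(length(focal_error) >= 1,
            length(n_variables) == length(focal_error),
            length(oob_error) == length(focal_error))
  if (stop_policy == "first_increase") {
    rises <- which(diff(focal_error) > 0)
    return(if (length(rises)) rises[1] else length(focal_error))
  }
  cand <- which(focal_error == min(focal_error))
  cand <- cand[n_variables[cand] == min(n_variables[cand])]
  cand[which.min(oob_error[cand])]
}

#' Recursive Random-Forest feature elimination
#'
#' Fits the package's core selection estimator. Starting from all variables,
#' each iteration grows a forest ([grow_forest()]), records the out-of-bag
#' and per-class errors, ranks variables by mean-decrease-Gini importance
#' and retains the top `floor(p/2)` ([rank_and_keep()]); the loop stops when
#' fewer than 2 variables would remain or after `max_iterations`. The
#' selected iteration is chosen by [select_iteration()]: by default the
#' global minimum of the focal-class misclassification rate
#' (`"global_min"`); the `"first_increase"` policy instead ends the trace at
#' the first strict rise of the focal-class error and selects the iteration
#' before it. The focal class is the one whose correct classification the
#' study cares most about (e.g. the atopic class).
#'
#' Iteration `i` reseeds its forest deterministically with
#' `params$seed + i`, so a fit is reproducible end-to-end from the master
#' seed.
#'
#' @param x Numeric matrix, samples in rows, variables (CpGs) in columns,
#'   complete (no missing values).
#' @param y Binary outcome, coerced to factor.
#' @param params A [forest_params()]; its `seed` is the master seed.
#' @param focal_class Outcome level whose misclassification drives the
#'   stopping rule (default: the second factor level).
#' @param stop_policy `"global_min"` (default) or `"first_increase"`.
#' @param max_iterations Upper bound on iterations (>= 1).
#' @param forest_fun Forest backend, `grow_forest` by default (injectable
#'   for testing the selection logic in isolation).
#'
#' @return An object of class `recursive_rf` with components `trace` (one
#'   row per iteration: iteration, n_variables, oob_error, per-class
#'   errors, focal_error), `selected_iteration`, `selected_variables`,
#'   `retained` (list of per-iteration variable sets), `focal_class`,
#'   `stop_policy`, `params`, `call`.
#' @seealso [plot.recursive_rf()], [summary.recursive_rf()]
#' @export
recursive_rf <- function(x, y, params = forest_params(),
                         focal_class = NULL,
                         stop_policy = c("global_min", "first_increase"),
                         max_iterations = 25L, forest_fun = grow_forest) {
  stop_policy <- match.arg(stop_policy)
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  stopifnot(is.matrix(x))
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (is.null(focal_class)) focal_class <- levels(y)[nlevels(y)]
  focal_class <- as.character(focal_class)
  if (!focal_class %in% levels(y))
    stop("focal_class ", focal_class, " not present in the outcome")

  vars <- colnames(x)
  rows <- list()
  retained <- list()
  i <- 0L
  repeat {
    i <- i + 1L
    it_params <- params
    it_params$seed <- params$seed + i
    fit <- forest_fun(x[, vars, drop = FALSE], y, it_params)
    retained[[i]] <- vars
    rows[[i]] <- data.frame(
      iteration = i, n_variables = length(vars),
      oob_error = fit$oob_error,
      t(stats::setNames(fit$class_error,
                        paste0("class_error_", names(fit$class_error)))),
      focal_error = fit$class_error[[focal_class]],
      check.names = FALSE)
    if (stop_policy == "first_increase" && i > 1 &&
        rows[[i]]$focal_error > rows[[i - 1L]]$focal_error) break
    next_n <- length(vars) %/% 2L
    if (next_n < 2L || i >= max_iterations) break
    vars <- rank_and_keep(fit$vim, next_n)
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  sel <- select_iteration(trace$focal_error, trace$n_variables,
                          trace$oob_error, stop_policy)
  structure(
    list(trace = trace,
         selected_iteration = sel,
         selected_variables = retained[[sel]],
         retained = retained,
         focal_class = focal_class,
         stop_policy = stop_policy,
         params = params,
         call = match.call()),
    class = "recursive_rf")
}

#' @export
print.recursive_rf <- function(x, ...) {
  cat("Recursive Random-Forest feature elimination\n")
  cat(sprintf("  %d iteration(s), %d -> %d variables (floor halving)\n",
              nrow(x$trace), x$trace$n_variables[1],
              x$trace$n_variables[nrow(x$trace)]))
  cat(sprintf("  stop policy: %s; focal class: %s\n", x$stop_policy,
              x$focal_class))
  cat(sprintf("  selected iteration %d: %d variables, focal-class error %.4f, OOB error %.4f\n",
              x$selected_iteration,
              x$trace$n_variables[x$selected_iteration],
              x$trace$focal_error[x$selected_iteration],
              x$trace$oob_error[x$selected_iteration]))
  invisible(x)
}

#' @export
summary.recursive_rf <- function(object, ...) {
  structure(list(trace = object$trace,
                 selected_iteration = object$selected_iteration,
                 n_selected = length(object$selected_variables),
                 focal_class = object$focal_class,
                 stop_policy = object$stop_policy),
            class = "summary.recursive_rf")
}

#' @export
print.summary.recursive_rf <- function(x, ...) {
  cat("Recursive elimination trace (selected iteration marked *)\n")
  tr <- x$trace
  tr$iteration <- paste0(ifelse(tr$iteration == x$selected_iteration,
                                "*", " "), tr$iteration)
  print(tr, row.names = FALSE, digits = 4)
  cat(sprintf("\n%d variables selected (policy %s, focal class %s)\n",
              x$n_selected, x$stop_policy, x$focal_class))
  invisible(x)
}

#' Plot the misclassification trajectory of a recursive fit
#'
#' Draws the overall OOB error and the per-class misclassification rates
#' against the (log-scaled) variable count, marking the selected iteration.
#'
#' @param x A [recursive_rf()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.recursive_rf <- function(x, ...) {
  tr <- x$trace
  err_cols <- c("oob_error", grep("^class_error_", names(tr), value = TRUE))
  graphics::matplot(tr$iteration, tr[, err_cols], type = "b", pch = 19,
                    lty = 1, xlab = "Iteration",
                    ylab = "Misclassification rate", ...)
  graphics::abline(v = x$selected_iteration, lty = 2, col = "grey40")
  graphics::legend("topright", legend = err_cols, col = seq_along(err_cols),
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  graphics::axis(3, at = tr$iteration, labels = tr$n_variables,
                 cex.axis = 0.7)
  graphics::mtext("Variables", side = 3, line = 2, cex = 0.8)
  invisible(x)
}

#' @export
coef.recursive_rf <- function(object, ...) object$selected_variables
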