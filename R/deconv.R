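#' Reference-based cell-type deconvolution
#'
#' Estimates the mixture proportions of leukocyte subtypes in a bulk
#' methylation profile by constrained least-squares projection onto a
#' sorted-cell reference panel: minimise \eqn{\|y - R\omega\|_2^2} subject to
#' \eqn{\omega \ge 0} and either \eqn{\sum_k \omega_k \le 1} (default, the
#' unexplained remainder is reported) or \eqn{\sum_k \omega_k = 1}
#' (`normalized` mode).
#'
#' The projection is performed on the beta scale (bounded, like the
#' reference profiles), which keeps the non-negativity geometry simple; pass
#' M-scale inputs for an M-scale fit if both sides are transformed
#' consistently. The quadratic program is solved exactly: with a handful of
#' cell types the optimum's active set can be found by enumerating all
#' zero-patterns and checking primal feasibility, which is deterministic and
#' free of step-size tuning.
#'
#' @param profile Named numeric vector of per-probe values for one sample.
#' @param reference Probes-by-cell-types numeric matrix with dimnames.
#' @param mode `"sum_le_one"` (default) or `"normalized"`.
#'
#' @return A list with `proportions` (named, one per cell type),
#'   `residual_norm`, and `n_probes_used`.
#' @examples
#' ref <- matrix(runif(40), 20, 2, dimnames = list(sprintf("cg%02d", 1:20),
#'                                                 c("A", "B")))
#' estimate_proportions(0.5 * ref[, 1] + 0.5 * ref[, 2], ref)$proportions
#' @export
estimate_proportions <- function(profile, reference,
                                 mode = c("sum_le_one", "normalized")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(reference), ncol(reference) >= 2)
  shared <- intersect(names(profile), rownames(reference))
  if (length(shared) < ncol(reference))
    stop("insufficient shared probes: need at least as many as cell types")
  A <- reference[shared, , drop = FALSE]
  y <- as.numeric(profile[shared])
  ok <- !is.na(y) & stats::complete.cases(A)
  A <- A[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(A) < ncol(A))
    stop("insufficient shared probes after removing missing values")
  if (qr(A)$rank < ncol(A))
    stop("rank-deficient reference: cell-type profiles are linearly ",
         "dependent on the shared probes")
  w <- solve_constrained_ls(A, y, mode)
  resid <- y - A %*% w
  list(proportions = stats::setNames(as.numeric(w), colnames(reference)),
       residual_norm = sqrt(sum(resid^2)),
       n_probes_used = nrow(A))
}

# Exact solution of min ||y - Aw||^2, w >= 0, sum(w) <= 1 (or = 1).
# The optimum of this convex QP is the equality-constrained minimiser for
# some active set; enumerate every zero-pattern (and sum-constraint state),
# keep primal-feasible candidates, return the one with least objective.
solve_constrained_ls <- function(A, y, mode) {
  K <- ncol(A)
  AtA <- crossprod(A)
  Aty <- drop(crossprod(A, y))
  yty <- sum(y^2)
  tol <- 1e-9
  best_w <- rep(0, K)
  best_obj <- if (mode == "sum_le_one") yty else Inf

  objective <- function(w) yty - 2 * sum(w * Aty) + drop(t(w) %*% AtA %*% w)

  for (code in seq_len(2^K - 1)) {
    free <- which(bitwAnd(code, 2^(seq_len(K) - 1)) > 0)
    Af <- AtA[free, free, drop = FALSE]
    states <- if (mode == "normalized") TRUE else c(FALSE, TRUE)
    for (tight in states) {
      w_free <- tryCatch({
        if (tight) {
          nf <- length(free)
          kkt <- rbind(cbind(2 * Af, rep(1, nf)), c(rep(1, nf), 0))
          sol <- solve(kkt, c(2 * Aty[free], 1))
          sol[seq_len(nf)]
        } else {
          solve(Af, Aty[free])
        }
      }, error = function(e) NULL)
      if (is.null(w_free)) next
      if (any(w_free < -tol)) next
      s <- sum(w_free)
      if (mode == "sum_le_one" && !tight && s > 1 + tol) next
      w <- rep(0, K)
      w[free] <- pmax(w_free, 0)
      if (tight) w[free] <- w[free] / sum(w[free])  # renormalise clamp drift
      obj <- objective(w)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best_w <- w
      }
    }
  }
  if (mode == "normalized" && !is.finite(best_obj))
    stop("no feasible solution found for the normalized fit")
  best_w
}

#' Cell proportions for every sample of a dataset
#'
#' Applies [estimate_proportions()] column-wise to a beta matrix (or a
#' [methylation_dataset()]) and returns a covariate-ready table.
#'
#' @param x Beta matrix (probes x samples) or a `methylation_dataset`.
#' @param reference Probes-by-cell-types reference matrix.
#' @param mode Constraint mode, see [estimate_proportions()].
#' @return Data frame: `sample_id`, one column per cell type, and
#'   `residual_norm`.
#' @export
estimate_cell_proportions <- function(x, reference,
                                      mode = c("sum_le_one", "normalized")) {
  mode <- match.arg(mode)
  beta <- if (inherits(x, "methylation_dataset")) x$beta else x
  stopifnot(is.matrix(beta))
  fits <- lapply(seq_len(ncol(beta)), function(j)
    estimate_proportions(beta[, j], reference, mode))
  props <- do.call(rbind, lapply(fits, `[[`, "proportions"))
  out <- data.frame(sample_id = colnames(beta), props,
                    residual_norm = vapply(fits, `[[`, numeric(1),
                                           "residual_norm"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
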