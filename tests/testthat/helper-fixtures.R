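# fixtures and independent oracles used across the test files

toy_dataset <- function(p = 6, n = 10, seed = 1, detection = TRUE) {
  set.seed(seed)
  beta <- matrix(runif(p * n, 0.05, 0.95), p, n,
                 dimnames = list(sprintf("cg%03d", seq_len(p)),
                                 sprintf("S%02d", seq_len(n))))
  det <- if (detection)
    matrix(runif(p * n, 0, 0.005), p, n, dimnames = dimnames(beta))
  methylation_dataset(beta, det)
}

toy_annotation <- function(probe_ids, chr = NULL, snp = NULL) {
  probe_annotation(
    probe_id = probe_ids,
    chr = chr %||% rep("1", length(probe_ids)),
    coordinate = seq_along(probe_ids),
    snp_flag = snp %||% rep(FALSE, length(probe_ids)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive simplex search: independent oracle for the deconvolution QP
grid_search_simplex <- function(A, y, step = 0.01, mode = "sum_le_one") {
  K <- ncol(A)
  stopifnot(K <= 3)
  grid <- seq(0, 1, by = step)
  best <- NULL; best_obj <- Inf
  if (K == 2) {
    for (w1 in grid) for (w2 in grid) {
      if (mode == "sum_le_one" && w1 + w2 > 1 + 1e-12) next
      if (mode == "normalized" && abs(w1 + w2 - 1) > step / 2) next
      obj <- sum((y - A %*% c(w1, w2))^2)
      if (obj < best_obj) { best_obj <- obj; best <- c(w1, w2) }
    }
  } else {
    for (w1 in grid) for (w2 in grid) {
      w3 <- 1 - w1 - w2
      if (mode == "normalized") {
        if (w3 < -1e-12) next
        w <- c(w1, w2, w3)
        obj <- sum((y - A %*% w)^2)
        if (obj < best_obj) { best_obj <- obj; best <- w }
      } else {
        for (w3 in grid) {
          if (w1 + w2 + w3 > 1 + 1e-12) next
          w <- c(w1, w2, w3)
          obj <- sum((y - A %*% w)^2)
          if (obj < best_obj) { best_obj <- obj; best <- w }
        }
      }
    }
  }
  list(weights = best, objective = best_obj)
}

# deterministic fake forest backend: replays a scripted per-iteration error
# sequence and ranks variables by a fixed importance ordering, so the
# elimination logic can be tested in isolation from randomForest
scripted_forest <- function(focal_seq, other_seq = NULL, focal_level = "1") {
  it <- 0L
  function(x, y, params) {
    it <<- it + 1L
    lv <- levels(droplevels(as.factor(y)))
    other <- setdiff(lv, focal_level)
    ce <- stats::setNames(numeric(2), lv)
    ce[focal_level] <- focal_seq[it]
    ce[other] <- if (is.null(other_seq)) focal_seq[it] else other_seq[it]
    vim <- stats::setNames(rev(seq_len(ncol(x))), colnames(x))
    list(oob_error = mean(ce), class_error = ce, vim = vim,
         votes = NULL, n_oob_covered = nrow(x), levels = lv)
  }
}
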