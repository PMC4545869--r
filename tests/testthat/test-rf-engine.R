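planted_data <- function(n = 100, p = 50, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c(0, 1), each = n / 2))
  x <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, sprintf("V%03d", 1:p)))
  # V001 separates the classes perfectly
  x[, 1] <- as.numeric(y) - 1 + runif(n, 0, 0.2)
  list(x = x, y = y)
}

test_that("mtry rules resolve with floor and clamping", {
  expect_identical(resolve_mtry("sqrt_p", 254460), 504L)
  expect_identical(resolve_mtry("0.1p", 254460), 25446L)
  expect_identical(resolve_mtry("0.05p", 254460), 12723L)
  expect_identical(resolve_mtry("2sqrt_p", 4), 4L)   # clamped to p
  expect_identical(resolve_mtry("0.5p", 7), 3L)      # floor
  expect_identical(resolve_mtry(10, 50), 10L)
  expect_identical(resolve_mtry(100, 50), 50L)
  expect_error(resolve_mtry("cube_p", 10), "unknown")
})

test_that("a perfectly separating variable dominates importance and error", {
  d <- planted_data(n = 100, p = 500, seed = 2)
  fit <- grow_forest(d$x, d$y,
                     forest_params(ntree = 500, mtry = "0.1p",
                                   sampsize = c(25, 25), seed = 2))
  expect_identical(names(which.max(fit$vim)), "V001")
  expect_true(all(fit$class_error < 0.05))
  expect_true(all(fit$vim >= 0))
  expect_gt(sum(fit$vim), 0)
})

test_that("permuted labels give chance-level OOB error under balanced sampling", {
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(runif(100 * 50), 100, 50)
    y <- factor(sample(rep(c(0, 1), each = 50)))
    grow_forest(x, y, forest_params(ntree = 200, sampsize = c(25, 25),
                                    seed = s))$oob_error
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("reported errors are exactly reproducible from the OOB votes", {
  d <- planted_data(seed = 3)
  fit <- grow_forest(d$x, d$y, forest_params(ntree = 100, seed = 3))
  covered <- fit$oob_times > 0
  votes <- fit$votes
  votes[is.na(votes)] <- -Inf
  pred <- fit$levels[apply(votes, 1, which.max)]
  expect_identical(mean(pred[covered] != as.character(d$y)[covered]),
                   fit$oob_error)
  for (cl in fit$levels) {
    idx <- covered & d$y == cl
    expect_identical(mean(pred[idx] != cl), fit$class_error[[cl]])
  }
  # confusion row sums equal per-class OOB-covered counts
  expect_equal(as.vector(rowSums(fit$confusion)),
               as.vector(table(d$y[covered])[fit$levels]))
  expect_identical(fit$n_oob_covered, sum(covered))
})

test_that("forests are deterministic under a fixed seed", {
  d <- planted_data(seed = 4)
  a <- grow_forest(d$x, d$y, forest_params(ntree = 150, seed = 9))
  b <- grow_forest(d$x, d$y, forest_params(ntree = 150, seed = 9))
  expect_identical(a$vim, b$vim)
  expect_identical(a$oob_error, b$oob_error)
  c <- grow_forest(d$x, d$y, forest_params(ntree = 150, seed = 10))
  expect_false(identical(a$vim, c$vim))
})

test_that("degenerate inputs are rejected", {
  d <- planted_data()
  expect_error(grow_forest(d$x, factor(rep(1, 100))), "single class")
  xna <- d$x; xna[1, 1] <- NA
  expect_error(grow_forest(xna, d$y), "missing")
})

test_that("adding trees does not degrade planted-signal accuracy", {
  d <- planted_data(n = 100, p = 100, seed = 5)
  e200 <- grow_forest(d$x, d$y, forest_params(ntree = 200, seed = 5))$oob_error
  e2000 <- grow_forest(d$x, d$y, forest_params(ntree = 2000, seed = 5))$oob_error
  expect_lte(e2000, e200 + 0.05)
})

test_that("the tuning table enumerates the grid plus a balance comparison", {
  d <- planted_data(n = 80, p = 30, seed = 6)
  tab <- tune_parameters(d$x, d$y, mtry_rules = c("sqrt_p", "0.1p"),
                         ntree_grid = c(100, 200), sampsize = c(20, 20),
                         default_mtry = "sqrt_p", default_ntree = 100,
                         seed = 6)
  expect_identical(nrow(tab), 6L)   # 2x2 grid + 2 balance rows
  expect_identical(sum(tab$phase == "balance"), 2L)
  expect_identical(tab$balanced[tab$phase == "balance"], c(FALSE, TRUE))
  # grid contains the default combination, so its focal-class minimum
  # cannot exceed the default run's error by construction of the search
  grid <- tab[tab$phase == "grid", ]
  default_row <- grid[grid$mtry_rule == "sqrt_p" & grid$ntree == 100, ]
  expect_lte(min(grid$class_error_1), default_row$class_error_1)
  # identical seed and grid reproduce the table
  tab2 <- tune_parameters(d$x, d$y, mtry_rules = c("sqrt_p", "0.1p"),
                          ntree_grid = c(100, 200), sampsize = c(20, 20),
                          default_mtry = "sqrt_p", default_ntree = 100,
                          seed = 6)
  expect_identical(tab, tab2)
  expect_error(tune_parameters(d$x, d$y, mtry_rules = character(0)),
               "non-empty")
})
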