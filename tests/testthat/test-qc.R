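test_that("detection filter removes probes failing in strictly more than the tolerated fraction", {
  ds <- toy_dataset(p = 3, n = 10, seed = 2)
  det <- ds$detection_p
  det["cg001", 1:2] <- 0.5   # 20% failing -> removed
  det["cg002", 1] <- 0.5     # exactly 10% -> retained (boundary)
  ds <- methylation_dataset(ds$beta, det)
  out <- filter_detection(ds)
  expect_identical(attr(out, "removed"), "cg001")
  expect_setequal(out$probe_ids, c("cg002", "cg003"))
  expect_identical(out$sample_ids, ds$sample_ids)
  expect_error(filter_detection(toy_dataset(detection = FALSE)), "absent")
})

test_that("detection filter agrees with a brute-force row scan", {
  set.seed(33)
  p <- 100; n <- 20
  beta <- matrix(runif(p * n), p, n,
                 dimnames = list(sprintf("cg%03d", 1:p), sprintf("S%02d", 1:n)))
  det <- matrix(ifelse(runif(p * n) < 0.12, runif(p * n, 0.02, 1),
                       runif(p * n, 0, 0.009)), p, n,
                dimnames = dimnames(beta))
  out <- filter_detection(methylation_dataset(beta, det))
  expected <- character(0)
  for (i in 1:p) {
    fails <- 0L
    for (j in 1:n) if (det[i, j] > 0.01) fails <- fails + 1L
    if (fails / n <= 0.10) expected <- c(expected, rownames(beta)[i])
  }
  expect_identical(out$probe_ids, expected)
})

test_that("sex-chromosome and SNP-probe removal follow the manifest", {
  ds <- toy_dataset(p = 6, n = 5, seed = 3)
  ann <- toy_annotation(ds$probe_ids,
                        chr = c("1", "X", "2", "X", "X", "Y"),
                        snp = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- remove_sex_chromosomes(ds, ann)
  expect_setequal(attr(out, "removed"), c("cg002", "cg004", "cg005", "cg006"))
  out2 <- remove_snp_probes(ds, ann)
  expect_setequal(attr(out2, "removed"), c("cg001", "cg005"))
  # identity cases
  ann0 <- toy_annotation(ds$probe_ids)
  expect_identical(remove_sex_chromosomes(ds, ann0)$probe_ids, ds$probe_ids)
  expect_identical(remove_snp_probes(ds, ann0)$probe_ids, ds$probe_ids)
  # unannotated probe is an error naming the probe
  expect_error(remove_sex_chromosomes(ds, ann[-2, ]), "cg002")
})

test_that("filters recover the generator's truth sets and never touch samples", {
  sim <- generate_methylation_dataset(
    simulation_config(n_stage1 = 30, n_stage2 = 10, n_probes = 80,
                      n_informative = 5, n_snp_probes = 15, n_sex_probes = 12,
                      detection_fail_rate = 0, seed = 6))
  ds <- sim$dataset
  out_sex <- remove_sex_chromosomes(ds, sim$annotation)
  expect_setequal(attr(out_sex, "removed"), sim$truth$sex_probes)
  out_snp <- remove_snp_probes(out_sex, sim$annotation)
  expect_setequal(attr(out_snp, "removed"), sim$truth$snp_probes)
  expect_identical(out_snp$sample_ids, ds$sample_ids)
})

test_that("probe accounting reconciles the funnel", {
  rep <- probe_accounting(383998, sex_removed = 9650, snp_removed = 119888)
  expect_identical(rep$remaining, 254460L)
  expect_identical(probe_accounting(100)$remaining, 100L)
  expect_error(probe_accounting(10, sex_removed = 20), "inconsistent")
  expect_error(probe_accounting(-5), "non-negative")
  # random funnels equal sequential set-difference cardinalities
  set.seed(7)
  for (r in 1:20) {
    ids <- sprintf("cg%04d", 1:500)
    sex <- sample(ids, sample(0:100, 1))
    snp <- sample(setdiff(ids, sex), sample(0:100, 1))
    remaining <- setdiff(setdiff(ids, sex), snp)
    rep <- probe_accounting(length(ids), sex_removed = length(sex),
                            snp_removed = length(snp))
    expect_identical(rep$remaining, length(remaining))
  }
})

test_that("batch adjustment aligns batch means and scales", {
  set.seed(10)
  m <- matrix(rnorm(50 * 20), 50, 20)
  batch <- rep(c("b1", "b2"), each = 10)
  m[, batch == "b2"] <- m[, batch == "b2"] + 1
  adj <- adjust_batch(m, batch)
  for (i in 1:50)
    expect_lt(abs(mean(adj[i, batch == "b1"]) - mean(adj[i, batch == "b2"])),
              1e-9)
  # single batch is the identity
  expect_identical(adjust_batch(m, rep("b1", 20)), m)
  # singleton batch errors unless location-only
  expect_error(adjust_batch(m, c(rep("b1", 19), "b2")), "singleton")
  expect_silent(adjust_batch(m, c(rep("b1", 19), "b2"), location_only = TRUE))
})

test_that("batch term vanishes in per-probe ANOVA after adjustment", {
  sim <- generate_methylation_dataset(
    simulation_config(n_stage1 = 30, n_stage2 = 30, n_probes = 200,
                      n_informative = 0, n_snp_probes = 0, n_sex_probes = 0,
                      batch_shift = 0.5, detection_fail_rate = 0, seed = 13))
  m <- beta_to_m(sim$dataset$beta, clip = 1e-6)
  batch <- sim$phenotype$batch
  adj <- adjust_batch(m, batch)
  pvals <- apply(adj, 1, function(x)
    summary(stats::aov(x ~ batch))[[1]]$`Pr(>F)`[1])
  expect_gte(mean(pvals > 0.05), 0.95)
})

test_that("outlier recoding flags only far-out cells within strata", {
  # constant probe: nothing to recode
  m <- matrix(1, 3, 50, dimnames = list(paste0("p", 1:3), paste0("s", 1:50)))
  out <- recode_outliers(m)
  expect_identical(nrow(attr(out, "recoded")), 0L)
  # one value at mean + 10 SD among N(0,1) draws is recoded
  set.seed(14)
  x <- rnorm(100)
  x[7] <- mean(x) + 10 * sd(x)
  m2 <- matrix(x, 1, 100, dimnames = list("p1", sprintf("s%03d", 1:100)))
  out2 <- recode_outliers(m2)
  rec <- attr(out2, "recoded")
  # quantile oracle: recompute the fences directly
  q <- quantile(x, c(.25, .75), names = FALSE)
  oracle <- which(x < q[1] - 3 * (q[2] - q[1]) | x > q[2] + 3 * (q[2] - q[1]))
  expect_setequal(rec$sample_id, sprintf("s%03d", oracle))
  expect_true("s007" %in% rec$sample_id)
  expect_true(is.na(out2["p1", "s007"]))
  # an effectively infinite fence recodes nothing
  out3 <- recode_outliers(m2, fence_k = 1e9)
  expect_identical(nrow(attr(out3, "recoded")), 0L)
  # stratification: an extreme value relative to its own stratum only
  strata <- rep(c("a", "b"), each = 50)
  m4 <- matrix(c(rnorm(50), rnorm(50, mean = 20)), 1, 100,
               dimnames = list("p1", sprintf("s%03d", 1:100)))
  out4 <- recode_outliers(m4, strata = strata)
  expect_identical(nrow(attr(out4, "recoded")), 0L)
})

test_that("class-mean imputation completes a matrix", {
  m <- matrix(c(1, 2, NA, 10, NA, 12), 1)
  colnames(m) <- paste0("s", 1:6); rownames(m) <- "p1"
  out <- impute_class_mean(m, outcome = c(0, 0, 0, 1, 1, 1))
  expect_equal(out[1, 3], 1.5)
  expect_equal(out[1, 5], 11)
  expect_false(anyNA(out))
})
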