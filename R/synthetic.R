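#' Simulation configuration for 450K-like synthetic data
#'
#' Defines the conditions the generator emulates: a two-class atopy outcome
#' with realistic class imbalance, a probe panel in which a small planted
#' subset is outcome-informative on the M (logit2) scale, whole-blood
#' cell-mixture structure whose composition shifts with the outcome
#' (confounding), sex- and batch-structured probes, SNP-affected trimodal
#' probes, and sporadic detection failures.
#'
#' Default sample sizes mirror a discovery design in which stage 1 runs on a
#' single-sex subsample and stage 2 pools in an additional batch of the other
#' sex: 245 stage-1 and 122 stage-2 samples, outcome prevalence 0.35. The
#' probe panel defaults to 2,000 probes — a desk-scale stand-in for a 450K
#' array that preserves the large-p-small-n character.
#'
#' @param n_stage1 Samples in the stage-1 subsample (female, batch 1).
#' @param n_stage2 Additional stage-2 samples (male, batch 2).
#' @param n_probes Total probes, including special probes.
#' @param n_informative Outcome-informative probes planted among them.
#' @param effect_size Mean M-value shift between outcome classes at
#'   informative probes (sign randomised per probe).
#' @param n_cell_types Cell types in the mixture (default 6: CD8T, CD4T, NK,
#'   Bcell, Mono, Gran).
#' @param confound_strength Shift of the granulocyte mean proportion in the
#'   outcome-positive class (other means rescaled to keep the simplex).
#' @param n_snp_probes SNP-affected probes with trimodal beta values.
#' @param n_sex_probes Sex-chromosome probes (X/Y labelled, sex-shifted).
#' @param batch_shift Additive M-scale offset applied to batch 2.
#' @param detection_fail_rate Per-cell probability of a detection failure.
#' @param prevalence P(outcome = 1), strictly in (0, 1).
#' @param noise_sd Residual M-scale noise standard deviation.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_stage1 = 245, n_stage2 = 122,
                              n_probes = 2000, n_informative = 10,
                              effect_size = 1.5, n_cell_types = 6,
                              confound_strength = 0.10,
                              n_snp_probes = 100, n_sex_probes = 100,
                              batch_shift = 0.25, detection_fail_rate = 0.005,
                              prevalence = 0.35, noise_sd = 1.5, seed = 1L) {
  cfg <- list(n_stage1 = as.integer(n_stage1), n_stage2 = as.integer(n_stage2),
              n_probes = as.integer(n_probes),
              n_informative = as.integer(n_informative),
              effect_size = effect_size, n_cell_types = as.integer(n_cell_types),
              confound_strength = confound_strength,
              n_snp_probes = as.integer(n_snp_probes),
              n_sex_probes = as.integer(n_sex_probes),
              batch_shift = batch_shift,
              detection_fail_rate = detection_fail_rate,
              prevalence = prevalence, noise_sd = noise_sd,
              seed = as.integer(seed))
  counts <- c(cfg$n_stage1, cfg$n_stage2, cfg$n_probes, cfg$n_informative,
              cfg$n_snp_probes, cfg$n_sex_probes)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (cfg$n_informative + cfg$n_snp_probes + cfg$n_sex_probes > cfg$n_probes)
    stop("informative + SNP + sex probes exceed n_probes")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)")
  if (cfg$detection_fail_rate < 0 || cfg$detection_fail_rate > 1)
    stop("detection_fail_rate must lie in [0, 1]")
  if (cfg$n_cell_types < 2) stop("need at least 2 cell types")
  structure(cfg, class = "simulation_config")
}

blood_cell_means <- function(k) {
  base <- c(CD8T = 0.08, CD4T = 0.15, NK = 0.05, Bcell = 0.07,
            Mono = 0.08, Gran = 0.57)
  if (k == 6) return(base)
  if (k < 6) return(base[seq_len(k)] / sum(base[seq_len(k)]))
  extra <- rep(0.02, k - 6); names(extra) <- paste0("Cell", 7:k)
  out <- c(base, extra)
  out / sum(out)
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic 450K-like dataset with known ground truth
#'
#' Draws a complete synthetic study from a [simulation_config()]: a beta /
#' detection-p matrix pair, a probe manifest, a phenotype table, a
#' cell-type reference panel, and the ground-truth channel used by
#' parameter-recovery tests.
#'
#' Generation happens on the M scale: per-cell-type baseline methylomes are
#' probe-wise independent beta draws, mixed by per-sample Dirichlet cell
#' proportions whose granulocyte mean shifts with the outcome by
#' `confound_strength`; planted effects, sex shifts and batch offsets are
#' added to the logit2 of the mixed value, plus Gaussian noise; the result is
#' mapped back to (0, 1) with the logistic inverse. SNP probes instead follow
#' a three-component genotype mixture near 0, 0.5 and 1.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` ([methylation_dataset()]),
#'   `annotation`, `phenotype`, `cell_reference` (probes x cell types beta
#'   matrix), and `truth` (informative/SNP/sex probe sets, per-probe signed
#'   effects, true per-sample cell proportions).
#' @export
generate_methylation_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_stage1 + config$n_stage2
  p <- config$n_probes
  k <- config$n_cell_types

  sample_id <- sprintf("S%04d", seq_len(n))
  probe_id <- sprintf("cg%08d", seq_len(p))
  stage <- rep(c(1L, 2L), c(config$n_stage1, config$n_stage2))
  sex <- ifelse(stage == 1L, "F", "M")
  batch <- ifelse(stage == 1L, "b1", "b2")
  atopy <- stats::rbinom(n, 1L, config$prevalence)
  # high IgE: alternate outcome correlated with atopy
  high_ige <- ifelse(atopy == 1L,
                     stats::rbinom(n, 1L, 0.60),
                     stats::rbinom(n, 1L, 0.15))

  # disjoint special probe sets
  special <- sample(probe_id, config$n_informative + config$n_snp_probes +
                      config$n_sex_probes)
  informative <- sort(utils::head(special, config$n_informative))
  snp_probes <- sort(special[seq_len(config$n_snp_probes) + config$n_informative])
  sex_probes <- sort(utils::tail(special, config$n_sex_probes))

  # cell-type reference methylomes (probe-wise independent, bimodal-ish)
  cell_names <- names(blood_cell_means(k))
  reference <- matrix(stats::rbeta(p * k, 0.6, 0.6), nrow = p,
                      dimnames = list(probe_id, cell_names))

  # per-sample cell proportions; granulocyte mean shifts with outcome
  mu0 <- blood_cell_means(k)
  mu1 <- mu0
  gran <- if ("Gran" %in% cell_names) "Gran" else cell_names[k]
  mu1[gran] <- mu0[gran] + config$confound_strength
  mu1 <- mu1 / sum(mu1)
  conc <- 60
  props <- t(vapply(seq_len(n), function(i)
    rdirichlet_one(conc * (if (atopy[i] == 1L) mu1 else mu0)),
    numeric(k)))
  dimnames(props) <- list(sample_id, cell_names)

  # bulk mixture on the beta scale, then shifts on the M scale
  eps <- 1e-6
  mix <- reference %*% t(props)               # p x n
  m <- log2(pmin(pmax(mix, eps), 1 - eps) /
              (1 - pmin(pmax(mix, eps), 1 - eps)))
  m <- m + matrix(stats::rnorm(p * n, sd = config$noise_sd), p, n)
  m <- m + matrix(config$batch_shift * (batch == "b2"), p, n, byrow = TRUE)

  true_effect <- numeric(0)
  if (config$n_informative > 0) {
    true_effect <- config$effect_size *
      sample(c(-1, 1), config$n_informative, replace = TRUE)
    names(true_effect) <- informative
    m[informative, ] <- m[informative, ] +
      outer(true_effect, as.numeric(atopy))
  }
  if (config$n_sex_probes > 0) {
    sex_shift <- sample(c(-2, 2), config$n_sex_probes, replace = TRUE)
    m[sex_probes, ] <- m[sex_probes, ] +
      outer(sex_shift, as.numeric(sex == "M"))
  }
  beta <- m_to_beta(m)
  dimnames(beta) <- list(probe_id, sample_id)

  if (config$n_snp_probes > 0) {
    maf <- stats::runif(config$n_snp_probes, 0.1, 0.5)
    geno <- matrix(stats::rbinom(config$n_snp_probes * n, 2L,
                                 rep(maf, times = n)),
                   nrow = config$n_snp_probes)
    centers <- 0.05 + 0.45 * geno
    beta[snp_probes, ] <- pmin(pmax(
      centers + matrix(stats::rnorm(length(centers), sd = 0.02), nrow(centers)),
      eps), 1 - eps)
  }

  detection_p <- matrix(stats::runif(p * n, 0, 0.005), p, n,
                        dimnames = dimnames(beta))
  fails <- matrix(stats::runif(p * n) < config$detection_fail_rate, p, n)
  detection_p[fails] <- stats::runif(sum(fails), 0.02, 0.8)

  chr <- sample(as.character(1:22), p, replace = TRUE)
  if (config$n_sex_probes > 0) {
    sex_chr <- sample(c("X", "Y"), config$n_sex_probes, replace = TRUE,
                      prob = c(0.9, 0.1))
    chr[match(sex_probes, probe_id)] <- sex_chr
  }
  annotation <- probe_annotation(
    probe_id = probe_id, chr = chr,
    coordinate = sample.int(2e8, p, replace = TRUE),
    gene = ifelse(stats::runif(p) < 0.7, sprintf("GENE%04d",
                                                 sample.int(500, p, replace = TRUE)), NA),
    gene_region = sample(c("TSS200", "TSS1500", "Body", "5'UTR", "3'UTR",
                           "1stExon"), p, replace = TRUE),
    island_relation = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf",
                               "S_Shelf", "OpenSea"), p, replace = TRUE),
    snp_flag = probe_id %in% snp_probes)

  phenotype <- data.frame(
    sample_id = sample_id, atopy = atopy, high_ige = high_ige,
    sex = sex, batch = batch, stage = stage, stringsAsFactors = FALSE)

  list(dataset = methylation_dataset(beta, detection_p),
       annotation = annotation,
       phenotype = phenotype,
       cell_reference = reference,
       truth = list(informative_probes = informative,
                    snp_probes = snp_probes,
                    sex_probes = sex_probes,
                    true_effect = true_effect,
                    true_cell_proportions = props))
}

#' Write / read a synthetic dataset as plain-text files
#'
#' `write_methylation_dataset()` writes the GenomeStudio-export-like file
#' set: `beta.tsv` and `detection_p.tsv` (probes in rows, samples in
#' columns), `manifest.csv`, `phenotype.csv`, `cell_reference.csv` and
#' `truth.json`. `read_methylation_dataset()` reads it back into the same
#' structure.
#'
#' @param sim Output of [generate_methylation_dataset()].
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly; for the reader, the dataset list.
#' @export
write_methylation_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(mat, file) {
    df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, file), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  write_mat(sim$dataset$beta, "beta.tsv")
  if (!is.null(sim$dataset$detection_p))
    write_mat(sim$dataset$detection_p, "detection_p.tsv")
  man <- sim$annotation
  names(man) <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
                  "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island",
                  "SNP_flag")
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(sim$phenotype, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  ref <- data.frame(probe_id = rownames(sim$cell_reference),
                    sim$cell_reference, check.names = FALSE)
  utils::write.csv(ref, file.path(dir, "cell_reference.csv"), row.names = FALSE)
  truth <- sim$truth
  truth$true_cell_proportions <- as.data.frame(truth$true_cell_proportions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       dataframe = "columns")
  invisible(dir)
}

#' @rdname write_methylation_dataset
#' @export
read_methylation_dataset <- function(dir) {
  read_mat <- function(file) {
    df <- utils::read.delim(file.path(dir, file), check.names = FALSE,
                            stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$probe_id
    mat
  }
  beta <- read_mat("beta.tsv")
  det <- if (file.exists(file.path(dir, "detection_p.tsv")))
    read_mat("detection_p.tsv")
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  annotation <- probe_annotation(man$IlmnID, man$CHR, man$MAPINFO,
                                 man$UCSC_RefGene_Name, man$UCSC_RefGene_Group,
                                 man$Relation_to_UCSC_CpG_Island, man$SNP_flag)
  phenotype <- utils::read.csv(file.path(dir, "phenotype.csv"),
                               stringsAsFactors = FALSE)
  refdf <- utils::read.csv(file.path(dir, "cell_reference.csv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  reference <- as.matrix(refdf[, -1, drop = FALSE])
  rownames(reference) <- refdf$probe_id
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    if (!is.null(truth$true_cell_proportions))
      truth$true_cell_proportions <- as.matrix(
        as.data.frame(truth$true_cell_proportions))
    if (!is.null(truth$true_effect) && !is.null(truth$informative_probes) &&
        length(truth$true_effect) == length(truth$informative_probes))
      names(truth$true_effect) <- truth$informative_probes
  }
  list(dataset = methylation_dataset(beta, det), annotation = annotation,
       phenotype = phenotype, cell_reference = reference, truth = truth)
}
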