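---
title: "Two-stage EWAS with recursive Random-Forest feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage EWAS with recursive Random-Forest feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rrfews)
```

## The problem

Epigenome-wide association studies (EWAS) of DNA methylation face a severe
small-*n*-large-*p* problem: an Illumina 450K array measures hundreds of
thousands of CpG sites on at most a few hundred subjects, and the vast
majority of probes are uninformative for any given phenotype. Classical
per-probe regression with multiple-testing control has low power at
genome-wide stringency; `rrfews` implements the alternative two-stage design
used for blood-methylation studies of atopy (positive skin-prick test, or
total serum IgE ≥ 200 kU/L as an alternate biomarker):

1. **Stage 1 — selection.** A recursive Random-Forest (RF) elimination
   reduces the probe panel to a small candidate set on a subsample,
   without imposing any model on how CpGs combine.
2. **Stage 2 — inference.** Only the selected candidates are tested by
   logistic regression with biological covariates, so the Bonferroni
   penalty is divided by dozens rather than hundreds of thousands.
3. **Replication.** Candidates surviving stage 2 are checked in an
   independent cohort: same direction of association and a nominal
   p-value below 0.05.

## Value scales

Array intensities give the beta value
$\beta = M/(c + M + U)$ (`beta_from_intensities()`, offset $c$ defaulting to
the Illumina convention of 100), interpretable as percent methylation but
heteroscedastic near its bounds. The logit2 transform
$\mathrm{M} = \log_2\!\big(\beta/(1-\beta)\big)$ (`beta_to_m()`) is
approximately homoscedastic. Forests — non-parametric, scale-invariant per
split — consume beta values; the stage-2 logistic models consume M-values.
Boundary betas (0 or 1) have no finite M-value and raise an error unless an
explicit epsilon clip is requested; nothing is clipped silently.

## Quality control

The cleaning funnel is fixed and recorded (`probe_accounting()` reconciles
it exactly):

* **Detection filter** — a probe is dropped when its detection p-value
  exceeds 0.01 in *strictly more than* 10 % of samples; failing in exactly
  10 % retains the probe.
* **Sex chromosomes** — probes with manifest chromosome X or Y are dropped
  (sex-linked methylation would otherwise dominate selection in any
  mixed-sex analysis).
* **SNP-flagged probes** — a conservative full exclusion. Because forest
  selection is conditional on the other retained variables, a
  genotype-driven trimodal probe does not only contaminate itself; it can
  displace genuinely informative probes during elimination.

Filters only ever remove probes; the sample set is never altered. Batch
structure is aligned by a per-probe location-scale adjuster
(`adjust_batch()`): each batch is standardised to the pooled mean and SD.
This is deliberately *not* an empirical-Bayes adjuster — it shrinks nothing
across probes — and is the documented extension point if one is wanted.
Probes with zero within-batch variance pass through unchanged; singleton
batches are an error unless a location-only alignment is requested.

## Stage 1: the recursive elimination

Each iteration grows a forest (`grow_forest()`, backed by the randomForest
package) and records three outputs:

* the overall out-of-bag error (OOB-ER),
* per-class OOB misclassification rates,
* per-variable mean-decrease-Gini importance (MDG). MDG is preferred over
  mean-decrease-accuracy for its robustness to small data perturbations.

Class imbalance (roughly a third of subjects atopic) would otherwise let the
forest buy accuracy by favouring the majority class, so each tree's
bootstrap draws a fixed number of subjects *per class*, with replacement
(`sampsize`, default 50/50; draws are clamped at the class frequency, a
bound imposed by the stratified bootstrap implementation). OOB predictions
are recomputed here from the vote matrix: majority vote among trees not
containing the sample, ties broken toward the class with lower factor-level
order; samples never out-of-bag are excluded from every error denominator
and counted separately. The reported OOB error is therefore *exactly*
reproducible from the stored votes — a conservation property the tests
assert.

`recursive_rf()` then iterates: rank by MDG, keep the top
$\lfloor p/2 \rfloor$ (ties broken by lexicographic probe ID — stable and
reproducible), regrow, and stop when fewer than two variables would remain.
With an odd count the larger "bottom half" is removed, matching the
published count sequence (e.g. 63,615 → 31,807). Iteration $i$ reseeds the
forest as `master_seed + i`, so an entire trace is reproducible from one
integer.

**Stopping.** Two policies are provided because the narrative rule and the
published trajectory differ subtly. The stated rule — stop at the first
increase of the focal-class (atopic) misclassification — is
`"first_increase"`. But the published trajectory itself passes over an
early uptick (63.15 → 65.78 % at iteration 4) and settles on the global
minimum of the atopic error (14.47 % at 62 variables, iteration 13), which
is what `"global_min"` (the default) reproduces: it runs the loop out and
selects the iteration minimising focal-class error, ties broken by fewer
variables, then by lower overall OOB error.

**Selection bias.** Because later iterations use variables chosen by
earlier forests on the same samples, the OOB error of late iterations is
optimistic. On pure-noise data the focal-class error at the selected
iteration sits below 50 % — around 36 % at $n = 200$, and lower still at
smaller $n$ where error estimates are noisier. This is a property of
non-cross-validated recursive elimination, not a defect; the package
reproduces it as-is and the test suite asserts the medium-$n$ magnitude so
a regression cannot silently change it.

## Cell-type deconvolution

Whole-blood methylation is a mixture over leukocyte subtypes whose
composition shifts with allergic status (granulocytes in particular), so
cell composition is the canonical confounder. `estimate_proportions()`
projects each bulk profile onto a sorted-cell reference panel (CD8T, CD4T,
NK, B cells, monocytes, granulocytes) by constrained least squares:
$\min_\omega \|y - R\omega\|^2$ with $\omega \ge 0$ and
$\sum_k \omega_k \le 1$ (default; the unexplained remainder is reported) or
$= 1$ (normalised mode). The projection runs on the beta scale, where the
reference lives and the non-negativity geometry is simple.

With at most a handful of cell types the quadratic program is solved
*exactly* by enumerating active sets ($2^K$ zero-patterns × sum-constraint
state, solving each equality-constrained system and keeping the feasible
candidate with least error). This is deterministic, step-size-free, and is
cross-checked in the tests against a 0.01-step simplex grid search.
Estimating the reference itself from sorted cells is out of scope — the
panel is an input — and eosinophils are not distinguished within
granulocytes.

## Stage 2: association and replication

For each selected CpG, `test_associations()` fits crude and
covariate-adjusted logistic models (`stats::glm`, IRLS, tight tolerance,
up to 100 iterations) of the outcome on the probe's M-values, with the six
cell proportions and sex as covariates. Wald tests are two-sided.
Separation and collinearity are flagged errors — the probe is skipped and
logged, never silently reported. A condition-number guard drops the
largest-proportion cell type if the covariate block is near-singular.

The confounding diagnostic is the percent coefficient change
$100\,(\beta_{adj} - \beta_{crude})/\beta_{crude}$. Note the orientation:
a published table whose crude −1.18 strengthens to −1.43 under adjustment
reports +21 % — i.e. (adjusted − crude)/crude — even though the
accompanying footnote writes the subtraction the other way; the package
implements the orientation consistent with the printed values.

Significance uses the strict inequality $p < \alpha/m$ with $m$ the number
of *selected* sites (0.05/62 = 8.06E−4 in the motivating study). Before
model fitting, extreme values are recoded to missing by a Tukey-fence rule
within outcome strata (`recode_outliers()`, default $k = 3$): the published
analysis identified such outliers by boxplot inspection, which is not
reproducible; a $k=3$ fence within strata is conservative, deterministic
and configurable. Missing values are handled case-wise per model fit;
forest input is mean-imputed within outcome class (both logged).

`replicate_associations()` marks a site replicated when it is available in
the external cohort, its odds ratios lie on the same side of 1 in both
cohorts (exactly 1 counts as non-concordant), and the external p-value is
strictly below 0.05. Sites absent externally are excluded from the tested
denominator.

Prevalence comparisons between sample strata use Pearson's chi-square with
the Yates continuity correction on by default: recomputing the published
high-IgE comparison (24/77 females vs 18/25 males) from its printed counts
yields p = 0.047 only with the correction.

### Pooled versus disjoint stage 2

The motivating design pools the stage-1 subsample into stage 2 (with sex as
covariate), which its authors note induces stage-1/stage-2 non-independence
and possible over-fitting. The package reproduces this default
(`stage2_design = "pooled"`) and also offers `"disjoint"`, where stage 2
uses only samples the selection never saw. Under the pooled design the
stage-2 p-values at selected probes are optimistic and Bonferroni control
of the family-wise error cannot be guaranteed; under the disjoint design it
holds at the nominal level. The null-pipeline property in the test suite
(and the corresponding acceptance-script quantity) is therefore measured
under the disjoint design, where control is actually expected.

## The synthetic-data generator

`generate_methylation_dataset()` exists so every stage is testable with a
known truth channel. It emulates, on a desk-scale probe panel:

* a two-class outcome with realistic imbalance (prevalence 0.35 by
  default, inside the 31–41 % range of the motivating cohorts);
* default sample sizes 245 + 122, mirroring a single-sex stage-1 subsample
  (female, batch 1) pooled with an opposite-sex stage-2 addition (male,
  batch 2) — sex and batch deliberately confounded, as in the design it
  emulates;
* per-cell-type baseline methylomes as probe-wise independent beta draws,
  mixed by per-sample Dirichlet proportions (concentration 60 around
  realistic whole-blood means, granulocytes ≈ 57 %); the granulocyte mean
  shifts by `confound_strength` in the outcome-positive class;
* planted outcome effects on the M scale (`effect_size`, sign randomised
  per probe), applied before the logistic back-transform so effect-size
  semantics stay linear where the stage-2 models operate;
* sex-shifted X/Y probes, SNP probes as a three-component genotype mixture
  near 0/0.5/1, an additive M-scale batch offset, and sporadic detection
  failures.

**Calibration.** Residual M-scale noise defaults to SD 1.5, so the default
`effect_size = 1.5` is a standardised per-probe effect of about 1 — strong
at the single-probe level, yet leaving the classes far from separable and
producing selection-error trajectories in the realistic non-zero range.
Much smaller noise would make planted panels perfectly separable, a regime
no methylation study exhibits and one that degenerates the stopping rule
(every late iteration ties at zero error). Effect sizes are free
parameters, deliberately not calibrated to any cohort.

What the generator does *not* emulate — probe-type (Infinium I/II)
chemistry, genomic autocorrelation along the chromosome, correlated CpG
blocks, raw IDAT structure — bounds what passing tests show: they validate
the algorithmic contracts and the statistical behaviour under the stated
generative model, not performance on any particular real cohort.

## Numerical choices and degenerate inputs

* `mtry` rules (√p, 2√p, 0.05p, 0.1p, 0.5p) resolve with `floor()` and
  clamp to `[1, p]`.
* Deconvolution tolerances: non-negativity and sum constraints enforced to
  1e−9; rank-deficient references and too-few shared probes are errors.
* Logistic convergence: IRLS to 1e−10, 100 iterations; separation flagged
  via boundary-probability warnings plus a diverging coefficient or
  exploding standard error.
* The beta/M round trip is exact to 1e−12 across (0.001, 0.999); beyond
  that range `1 − beta` underflows and exactness is not promised.
* All ties anywhere (vote ties, importance ties, stopping ties) break by a
  documented deterministic rule, so identical seeds give bit-identical
  results end to end.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale, chosen as the smallest sizes at which each property is
stable: recovery experiments at $n = 200$, $p = 500$ with 5 planted probes
over 10 seeds; the null-pipeline experiment at 100 replicates of
$n = 140$, $p = 100$; deconvolution recovery on 200 mixtures of 6 cell
types at noise SD 0.02 (mean absolute error well under 0.05). Published
printed numbers that are pure functions of other printed numbers — the
probe funnel, the halving schedule, the Bonferroni threshold, the
prevalence chi-square, the significance and replication counts — are
recomputed exactly from the shipped summary tables.

## Known limitations

* The pooled stage-2 default inherits the selection bias discussed above;
  use `"disjoint"` when unbiased stage-2 inference matters more than
  sample size.
* MDG importance degrades when predictors are strongly correlated or on
  wildly different scales; methylation M/beta panels are homogeneous in
  scale, but correlated CpG blocks (not simulated here) would dilute
  importance across neighbours.
* The batch adjuster is location-scale only, by design.
* Forests never see missing values; the class-mean imputation used for
  forest input is simple and logged, and a richer imputation model is out
  of scope.
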