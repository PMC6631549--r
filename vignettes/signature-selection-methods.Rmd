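---
title: "Selecting survival-predictive gene signatures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting survival-predictive gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsga)
```

`plsga` models one biological setting: clutches of fish eggs whose embryonic
survival rate at 48 hours post-fertilization is partly determined by the
maternal transcriptome deposited in the egg. This vignette is the package's
own account of the statistical machinery — the models fitted, every tunable
parameter that matters, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

## 1. The two analyses

### Differential expression between quality groups

Clutches are labeled **good** when survival strictly exceeds 93% and **bad**
when strictly below 38% (both thresholds in % survival at 48 hpf; samples in
between stay unlabeled). On log2, per-array median-centered intensities,
each gene is tested with a two-sample t-test between the groups and p-values
are adjusted by the Benjamini–Hochberg step-up rule; genes with q < 0.05 are
reported with a signed fold change of bad relative to good
(ratio r = 2^(Δlog2) reported as r when r ≥ 1, else −1/r, so that
down-regulation in bad eggs appears as a negative value of magnitude ≥ 1).

* **t-test flavor.** Welch's unequal-variance test is the default
  (`var_equal = FALSE`): egg transcriptome variance differs visibly between
  quality groups, and Welch is the safer default when group variances are
  unknown. The pooled-variance test is available for exact-replication
  attempts.
* **Degenerate genes.** When both groups are constant: p = 1 if the means
  agree, p = 0 if they differ — the limits of the t statistic.
* **Normalization order.** log2 first, then per-array median centering
  (the standard single-channel convention). A matrix already in log space
  is only centered, so the operation is idempotent-safe. Note that median
  centering is only meaningful for genome-scale arrays: with a handful of
  genes the array median tracks the genes themselves and centering
  *removes* biological signal. Package tests on tiny (≤ 12-gene) fixtures
  therefore work on uncentered log2 values.
* **Presence rule.** A gene must be detected above background in at least
  80% of the samples of at least one group (`min_fraction = 0.8`),
  evaluated on the detection mask, not on intensity.

### The PLS–GA signature search

The multivariate analysis asks for a subset S of 1–20 genes maximizing the
predictive quality of a PLS regression of survival on the expression of S.

**PLS1 (NIPALS).** Predictors are centered and autoscaled to unit variance;
components t = Xw are extracted by iterative deflation with weights
proportional to X'y; regression coefficients are folded back to the
original scale. With as many components as (full-rank) predictors the fit
equals ordinary least squares — a property the test suite checks against
`lm` on random problems. Constant predictors get weight 0 rather than an
error.

**Component cap.** `ga_config(n_components = 2)` by default. Two-fold CV
trains on n/2 samples (16 in the reference design), so generously
parameterized fits overfit the training fold; empirically, on the synthetic
designs below, a cap of 2 dominates a cap of 3 both in the CV score of the
true subset and in the search's ability to find it. The cap is
configurable, and is always further limited to min(p, n_train − 1).

**Fitness: 2-FCV R².** Samples are split at random into two halves; each
half's model predicts the other; the pooled out-of-fold predictions ŷ give
R² = cor(y, ŷ)². One pooled correlation (not a mean of per-fold
correlations) is used, and predictions are *not* clamped to [0, 100] —
correlation is scale-free and clamping would silently change it. If either
vector is constant the score is defined as 0. During evolution each
individual is scored with a single split, shared by the whole generation so
fitness values are comparable (and identical subsets tie exactly); final
populations are re-scored by the mean of 10 independent splits.

**The genetic algorithm.** Populations of 500 subsets (desk-scale analyses
use 50–100) evolve for 200 (desk: 50) generations:

1. *Selection*: individuals ranked ascending by fitness; selection
   probability = rank / Σranks; sampled with replacement to the population
   size. Ties share ordinal ranks by stable input order.
2. *Crossover* (50% of individuals, paired at random; an odd count leaves
   one unpaired): each parent's gene set is randomly bipartitioned and one
   part exchanged. Genes common to both parents remain in both children —
   exchanging shared material is a semantic no-op, and this is the only
   behavior under which identical parents reproduce themselves exactly.
   Children over the size cap are trimmed at random; under the minimum they
   receive random pool genes.
3. *Mutation* (90% of individuals): one operation drawn uniformly among the
   *feasible* subset of {add, remove, replace}; adds never occur at the
   maximum size nor removals at the minimum.
4. *Elitism*: the top `n_elite = 5` individuals of each generation carry
   over unchanged. Single-elite carryover is the textbook default, but at
   desk-scale budgets (100 × 50 per population) it proved too weak: with
   90% mutation and 50% crossover nearly every good individual is disrupted
   every generation, and the assembly of multi-gene signatures stalls.
   Five elites (5% of a desk population, 1% of a full-scale one) preserve
   enough building blocks for reliable convergence while leaving the
   permutation-null comparison intact (the null runs use the same
   machinery). `elitism = FALSE` restores the bare scheme.

Multiple independent populations (70 at full scale, 5 at desk scale) are
run from seeds derived from one master seed by a counter-based scheme
(`derive_seed`), so adding populations never shifts existing ones; their
final individuals are pooled.

### The permutation null

The same multi-population search is re-run on survival vectors permuted
uniformly at random across samples — one fresh permutation per null
population, matched in number to the actual populations. Two readouts:

* **Selection frequencies.** For each gene, the fraction of final solutions
  containing it. The 95th and 99th percentiles of the *null* per-gene
  frequency distribution (linear interpolation between order statistics,
  `quantile` type 7) become cutoffs; genes whose *actual* frequency
  strictly exceeds a cutoff are reported. Strict exceedance and the
  interpolation rule are deliberate, documented conventions so replication
  differences are traceable.
* **R² comparison.** A one-sided Mann–Whitney test of whether actual final
  R² values are stochastically larger than null ones; exact when both
  samples have ≤ 20 untied values, tie-corrected normal approximation
  otherwise.

**A calibration caveat.** Final-population R² values within one run are
positively dependent: all individuals share the same dataset (and the GA's
selection concentrates populations on related subsets), while the
Mann–Whitney test assumes independent observations. On signal-free
synthetic data, miniature actual-vs-permuted comparisons reject at roughly
10–20% rather than the nominal 5%, symmetrically in both tails — an
intrinsic property of this comparison design, not an implementation
artifact. The test remains useful as a descriptive contrast (with real
signal the separation is enormous; p-values below 1e-40 at desk scale), but
its nominal level should not be taken literally for borderline cases. The
package reports the p-value as the procedure defines it and leaves the
interpretation caveat here.

## 2. The synthetic-data generator

`generate_dataset(synth_config(...))` emulates a single-channel microarray
egg-quality study:

* **Intensities.** log2 intensities are Normal: gene baselines around
  `intensity_log_mean` (SD 2 across genes) plus within-gene noise
  `intensity_log_sd` (default 1). Raw intensities `2^log2` are emitted, so
  the pipeline's normalization is exercised.
* **Planted signal.** `n_signal_genes` (default 4) form a co-expressed
  module: each shares a latent per-sample factor giving pairwise
  correlation `signal_cor` (default 0.6). Survival is linear in the
  *standardized* log2 expression of these genes,
  `survival = clamp(μ + Σ w_k z_k + ε, 0, 100)` with weights
  `effect_weights` (% survival per SD; default 5, 4.5, 4, 3.5), baseline
  `survival_mean = 65`, and noise `noise_sd = 3.3`, giving an oracle
  R² = w'Σw / (w'Σw + σ²) ≈ 0.95.
* **Why a module, and why graded weights?** Biologically, maternal
  transcripts controlling developmental competence are co-regulated, and
  real signature genes co-vary (the analysis even needs a redundancy-pruning
  step because of it). Statistically, the module structure is what makes a
  32-sample study design coherent: with 2,000 genes and n = 32, the largest
  *chance* absolute correlation with survival is ≈ 0.6, so four independent
  genes splitting an R² of 0.95 (each r ≈ 0.49) would be individually
  indistinguishable from background noise — no wrapper search faithful to
  the operators above, at any desk-scale budget, could find them, and the
  planted "signature" would not be a recoverable signal at all. With the
  module, each planted gene carries r ≈ 0.8 marginally while the joint
  model still explains 95% of survival variance, mirroring a study in which
  the method demonstrably works. The defaults were chosen once, on this
  reasoning, as the package's reference study condition.
* **Absent genes.** A fraction `frac_absent_genes` of genes (disjoint from
  the signal) is forced below background in >20% of the samples of *every*
  quality group, so the 80% presence filter removes them deterministically;
  absence is a detection-flag property, not low intensity.
* **Duplicate blocks.** `n_duplicate_blocks` blocks of
  `duplicate_block_size` genes share a latent profile with jitter set for
  pairwise correlation `duplicate_within_r = 0.99`. The target is
  deliberately above the nominal 0.95 pruning threshold: at n = 32 the
  sampling error of a correlation of 0.96 would let empirical block
  correlations dip below 0.95 about 8% of the time, violating the
  generator's own contract; at 0.99 the failure probability is ≈ 5·10⁻⁶.
* **What is *not* emulated.** Probe-level effects, dye/batch structure,
  heavy-tailed intensity distributions, missing values, and any nonlinear
  gene–survival relationship. Passing tests on this generator therefore
  show that the machinery is correct and that the method works under its
  own assumptions — not that any particular real dataset contains a
  recoverable signature.

Reference configurations used throughout the tests and `scripts/acceptance.R`:

| study | n samples | genes | purpose |
|---|---|---|---|
| signature search | 32 | 2,000 | GA + null recovery of the planted module |
| DE study | 136 | 2,000 | good/bad labeling (≈ 12% tails each), presence filter, DE |
| tiny pool | 32 | 12 | exhaustive-search oracle for the GA |
| null calibration | 16 | 200 | signal-free behavior of the permutation comparison |

The 136-clutch DE study scales the weights to (9, 8, 7, 6) with
`noise_sd = 5.5` (same oracle R²) so that survival spans the full range and
the >93 / <38 thresholds yield two usable groups; about 7% of clutches clamp
at 100% survival, which is biologically realistic (perfect clutches exist).

## 3. Numerical and degenerate-case conventions

* Correlation of a constant vector is defined as 0 wherever it arises
  (clustering distances, correlation filter, R² scoring).
* The correlation filter keeps genes with p ≤ α (default 0.1), Pearson test
  with t = r√(n−2)/√(1−r²) on n − 2 df; no multiplicity correction at this
  stage (the null model downstream is the error control).
* Redundancy groups are connected components of the graph with edges at
  raw r > 0.95 (`use_abs = TRUE` switches to |r|); each component keeps the
  member with the largest |r| to survival, ties broken by input order.
* Two-fold splits differ in size by at most 1 for odd n; folds below 2
  samples are an error.
* NIPALS stops early when the weight or score norm falls below 1e-12
  (exhausted rank); zero extracted components yield the intercept-only
  model.
* All randomness flows through explicit seeds; `derive_seed(master, ...)`
  is a documented LCG-based counter scheme with outputs in [0, 2³¹ − 2].

## 4. Problem sizes

The package's own studies are desk-scale by design: 5 populations ×
100 individuals × 50 generations for the signature search (and the matched
null), 100 repetitions of the 16-sample miniature for null calibration, and
200 simulated datasets for the FDR check. These sizes make the full suite
reproducible in minutes on one CPU while keeping every statistical assertion
distributional rather than anecdotal. Full-scale defaults
(`ga_config()`: 70 × 500 × 200) reproduce the reference design and run in
hours, not minutes.

## 5. Known limitations

* The wrapper search optimizes CV R² over thousands of subsets; the best
  *score* is therefore optimistically biased even with honest CV (model
  selection leakage). The permutation null is the package's answer: judge a
  signature by its selection-frequency exceedance and by the actual-vs-null
  contrast, not by its raw R².
* The Mann–Whitney calibration caveat above.
* Redundancy pruning keeps exactly one representative per correlated group;
  biologically interchangeable co-regulated genes are therefore
  under-reported by design (the kept gene stands for its component).
* Pairwise-correlation matrices are computed densely; pools beyond ~20,000
  genes should be correlation-prefiltered first.
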