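---
title: "Methods: genetic risk, stress-induced reward learning, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk, stress-induced reward learning, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsreward)
```

## The problem this package addresses

Anhedonia — blunted ability to experience or pursue reward — is a core
depressive phenotype that can be measured at several levels: what people
report about themselves (the SHAPS questionnaire), how their behavior
adapts to asymmetric rewards under stress (the probabilistic reward task,
PRT), and how their striatal circuits encode reward prediction errors
(RPEs) and are built (NAc and putamen volume).  A natural question for
depression genetics is whether a polygenic score assembled from
depression-related GWAS hits predicts these markers, and whether the
predicted variance grows as the measure sits "closer to the genes"
(self-report < behavior < circuits).

`grsreward` implements that full analysis chain as reusable, tested
components, and pairs it with a synthetic-cohort generator that reproduces
the statistical structure the analysis assumes.  Because the motivating
human dataset sits in an access-controlled archive, the generator is not a
test fixture but a first-class module: it defines the conditions under
which every claim in the test suite is checked.

## Genetics

**Quality control.**  SNVs are dropped when missingness exceeds 5%
(strictly) or imputation INFO is not above 0.8; individuals are then
dropped when their missingness across *surviving* SNVs exceeds 2%.  The
marker-before-sample order is fixed and documented because the two orders
differ on edge cases; `apply_qc()` is idempotent.

**Scoring.**  `compute_grs()` needs dosages oriented to the effect allele,
so `align_effect_alleles()` complements (`2 − d`) any SNV whose counted
allele is the weight table's other allele, flags strand-ambiguous A/T and
C/G pairs in its log, and fails loudly on irreconcilable allele pairs.
Missing dosages default to frequency mean-imputation
(`2·p̂·β`, the common scoring-tool behavior); a `skip` policy is available
for sensitivity analysis, and both the raw sum and a per-allele average are
emitted because scoring conventions differ between tools.  The
`transform_weights()` default is `identity`: published effect sizes here
are linear-scale betas that may legitimately be negative, and a logarithm
of a signed beta is undefined.  The `log` mode exists for odds-ratio-scale
inputs and errors, naming the SNV, on non-positive values — the pipeline
must never fabricate weights silently.

**Ancestry.**  `ancestry_pcs()` performs standard genotype PCA
(centering by `2p̂`, scaling by `sqrt(2p̂(1−p̂))`, monomorphic SNVs dropped,
deterministic sign fix).  By default the pipeline computes PCs from the
scored panel itself.  A 14-SNV panel is a weak ancestry proxy — with
realistic divergence the leading PC still tracks a two-component mixture,
which is what the confounding correction needs in simulation, but real
analyses should substitute genome-wide PCs; every downstream function
accepts an external PC matrix.

## PRT behavior

The response-bias statistic is the standard signal-detection log b with ½
added to every cell, in base-10 logarithms — the convention of the task's
originating literature; the formula and base are documented and the base is
configurable.  The behavioral outcome is the double difference
(B2 − B1)_post − (B2 − B1)_pre, computed per subject by `prt_summary()`;
subjects missing any of the four blocks are excluded from the behavioral
unit only, which is why per-measure sample sizes differ.  No behavioral
outlier rule is applied by default (the association stage has its own
configurable z-score screen).

## The Q-learning model

Values update as `Q ← Q + α (R − Q)` with `R ∈ {+1, −1, 0}` for win, loss
and neutral outcomes, and choices follow the normalized softmax
`P(A) = exp(Qa/β) / (exp(Qa/β) + exp(Qb/β))`, evaluated overflow-safely as
a logistic in `(Qa − Qb)/β`.  Two conventions matter:

* **β is a divisor** (temperature): larger β means more random choice.
  Packages using a multiplier convention should pass `1/β`.
* **Q resets at stress-condition boundaries.**  Whether values should also
  reset between the two runs within a condition is not determined by the
  task description; the package defaults to per-condition resets (values
  plausibly persist across a short break within the same stress state) and
  exposes `reset = "run"` for the alternative.

RPE regressors are generated by replaying the update over observed choices
with fixed population-level parameters (defaults: gain α = 0.28, β = 2.24;
loss α = 0.46, β = 5.23), the recommended practice for event-related fMRI
modeling; `delta == outcome − Q_chosen` holds exactly on replay, and the
module deliberately stops at the regressor (no hemodynamic convolution or
voxelwise statistics).

### Estimating group-level parameters

`qlearn_fit()` maximizes the per-subject choice log-likelihood by a grid
search (α in steps of 0.01, log-spaced β) followed by Nelder–Mead
refinement inside the box, with exact ties broken toward smaller α then
smaller β, and degenerate all-one-choice subjects flagged rather than
failed.

The obvious group summary — the mean of per-subject MLEs — turns out to be
the wrong estimator at this task's trial counts, and the package does not
use it as its headline value.  With 144 trials per valence and the default
temperatures, single-subject likelihood surfaces are shallow: a
non-negligible fraction of per-subject α estimates lands on the parameter
bounds, and the resulting group mean is substantially displaced from the
generating value even though the per-subject median sits on target (the
test suite demonstrates both, and also that per-subject error shrinks as
trials increase).  The package therefore reports, and recommends, the
**pooled MLE**: the maximizer of the summed likelihood under a shared-
parameter model, which is exactly the homogeneity assumption the
population-level regressor generation already makes.  Replicate-cohort
recovery runs at the default parameters show the pooled estimate centered
on the generating values for both valences; the loss pair remains the
noisier of the two because β = 5.23 compresses value differences to
near-chance choice probabilities, so its recovery benchmark uses more
subjects and a median across replicates for the temperature.  Per-subject
estimates, their mean and median remain available on the fitted object for
comparison.

`qlearn_recovery()` packages the recovery benchmark: replicate cohorts of
200 subjects × 144 trials per valence, pooled refits, estimates averaged
across replicates.  Those sizes are the package's standard recovery
conditions; they keep the Monte-Carlo error of the averaged estimate well
inside the benchmark's tolerances.

## Hierarchical association

`hreg()` fits nested OLS blocks and reports, per step, ΔR², the F-change
statistic with `(q, n − p_cum − 1)` degrees of freedom, and its upper-tail
p.  The raw ΔR² of a null predictor has positive expectation (roughly
`q/(n − p − 1)`), so `hreg()` also reports a **bias-adjusted ΔR²** — the
difference of Wherry-adjusted R² between the cumulative and previous
models.  A simulation at the design sizes used throughout this package
(n = 73, two PCs, one score) shows the adjusted difference is essentially
unbiased for the population incremental variance, which is why the
calibration suite and the acceptance script report it.

Supporting choices:

* **Listwise deletion per outcome**, never imputation of outcomes — each
  measure's row reports its own `n`.
* **ICV adjustment** of regional volumes is residual-based by default
  (volume regressed on intracranial volume, residuals re-centered at the
  mean volume); ratio rescaling is available but distorts whenever the
  volume–ICV slope is not strict proportionality.
* **Outliers**: a per-outcome `|z| > 3` screen, logged and configurable
  (`Inf` disables it); calibration simulations disable it so the null
  distribution is untouched.
* **Bonferroni control** over the two circuit regions (threshold
  0.05/2 = 0.025) on the circuit rows only.
* The unit-of-analysis summary reports the self-report and behavior
  measures' ΔR² directly and averages the two regional rows within each
  circuit level, as percentages.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults encode the reference study conditions: 83
individuals, a 22-SNV panel with 8 designated QC failures (so 14 survive),
two ancestry components mixed 70/30 with Balding–Nichols divergence 0.1,
incremental-variance targets (1.7%, 3.5%, 6.5%, 7.4%, 6.4%, 9.5%) with a
negative GRS direction, and per-unit observed sample sizes (82, 59, 62, 63,
73, 73).

**Exact calibration.**  Phenotypes are built from the *analysis-grade* GRS
and PCs (computed by the same QC/alignment/scoring/PCA code the analysis
will run): with `z` the unit-variance residual of the GRS on the
orthonormalized PCs, each standardized unit is
`sign·sqrt(r²)·z + Σ sqrt(pc_r²_k)·PC_k + noise`, the noise completing the
variance budget to 1.  Because `z` is exactly orthogonal to the PCs, the
population incremental variance of the GRS beyond the PCs equals the
target exactly — the quantity the two-step regression estimates.  Default
PC contributions are 2% each: enough to make ancestry adjustment
consequential, small enough to leave the budget feasible for every target.

**PRT wiring.**  Each behavioral subject's calibrated stress-change score
sets their generative block biases through a closed form: with response
accuracy `plogis(d ± b)` (d = 1.1, about 75% accuracy at zero bias), the
expected log b estimate is `b/ln 10`, so block biases (0.05, 0.20) log₁₀
units prestress and (0.05, 0.20 + stress_change) poststress reproduce the
target in expectation.  Reward delivery is quota-based — exactly 24 rich
and 8 lean rewarded corrects per block when available, all available
otherwise with the shortfall logged — because the task fixes the counts,
not the rates.  The full pipeline computes the behavioral row from these
trial records, so its ΔR² is mildly attenuated relative to the calibrated
column by binomial measurement noise, exactly as a real estimated change
score would be.

**Missingness.**  The generator's default `snv_missing_rate` is 0: with a
14-SNV panel, one missing genotype is already 7% of an individual's panel
and would trip the 2% sample-QC rule, emptying the cohort.  Missing-data
behavior is exercised instead through non-zero rates in the test suite and
through the two scoring policies.  When missingness is injected, the
per-SNV missing count is fixed at `round(rate·n)` so the 5% marker rule
binds predictably rather than stochastically.

**Not emulated:** linkage disequilibrium between the panel SNVs (they are
independent), voxelwise BOLD data (ROI-level RPE-change betas are generated
directly), genotype imputation itself (INFO scores are attached, not
computed), and any coupling between the RL task choices and the RPE-change
phenotypes — the fMRI path from δ regressors to ROI betas is out of scope,
so passing tests validate the regressor computation and the association
machinery, not a generative model of BOLD.

## Numerical choices and degenerate inputs

* Cell corrections (+½) keep log b finite for empty cells; softmax
  probabilities are floored at 1e−300 inside likelihoods.
* `hreg()` errors on rank deficiency (naming the collinear columns) and on
  fewer complete rows than predictors + 2; an exactly zero residual
  variance reports ΔF = ∞ with p = 0 and a warning rather than NaN.
* PCA drops monomorphic SNVs and errors when fewer polymorphic SNVs than
  components remain; component signs follow a deterministic
  largest-loading-positive rule so runs are reproducible.
* All generators draw from one seeded stream per dataset; the pipeline fans
  a master seed into per-stage seeds deterministically, and identical
  config + seed yields byte-identical outputs (digest-verified in the test
  suite).

## Problem sizes used by the validation suites

The test and acceptance suites run entirely on generated data at sizes
chosen to make Monte-Carlo error small relative to the tolerances being
checked: 2000 replicate cohorts of n = 73 for the incremental-variance
calibration (±0.015 band), 1000 null cohorts of n = 83 for p-value
uniformity, 8–10 replicate cohorts of 200 subjects × 144 trials for RL
recovery, and 50,000 individuals for the single-cohort calibration spot
check (±0.005 band).

## Known limitations

* The pooled RL estimator assumes parameter homogeneity across subjects;
  with real, heterogeneous subjects it estimates a likelihood-weighted
  typical value, and a hierarchical random-effects fit would be the next
  step up.  The per-subject machinery is in place for that extension.
* The PRT generator holds bias constant within a block rather than letting
  it develop trial by trial with reward history; it reproduces block-level
  statistics, not within-block learning curves.
* The 14-SNV panel doubles as the PC source in simulation; real analyses
  should supply genome-wide PCs.
* Calibration targets are population quantities; any single simulated
  cohort of n ≈ 60–80 shows the large sampling scatter in ΔR² that real
  cohorts of that size have.
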