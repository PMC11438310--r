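---
title: "Mendelian randomization of cardiovascular health on epigenetic aging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization of cardiovascular health on epigenetic aging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvhmr)
```

## The scientific question

Observational studies consistently find that people with better composite
cardiovascular health (CVH) — favourable cholesterol, glucose, blood
pressure, body-mass index, smoking and exercise habits — show slower
epigenetic aging, measured as epigenetic age acceleration (EAA): the
residual of a DNA-methylation age predictor regressed on chronological
age. Association is not causation; shared confounders (age, sex, alcohol
use, education, ancestry) plausibly drive both. Mendelian randomization
(MR) addresses this by using genetic variants as instrumental variables:
alleles are assigned at conception, so a variant that shifts CVH cannot
itself be confounded by adult lifestyle, and any effect it transmits to
EAA must (under the instrumental-variable assumptions) flow through CVH.

`cvhmr` implements the full analytic pipeline for this design in both of
its standard forms:

* **one-sample MR**: individual-level genotypes, CVH metrics and EAA in
  one cohort, analysed with a weighted genetic risk score (wGRS) and
  two-stage least squares (2SLS);
* **two-sample MR**: per-SNP summary statistics from separate exposure
  and outcome GWAS, analysed with the estimator suite of
  inverse-variance weighting (IVW), the weighted median, MR-Egger and
  MR-PRESSO, plus multivariable IVW for joint exposures.

Because the individual-level biobank data behind such studies are not
publicly downloadable, the package ships a synthetic-cohort generator
with known ground truth; every stage of the pipeline is exercised and
calibrated against it.

## The CVH score

The exposure is the 12-point CVH score: six metrics, each graded 0
(poor), 1 (intermediate) or 2 (ideal) and summed. The grading follows
the standard clinical thresholds (lower bounds inclusive, upper bounds
exclusive):

| metric | poor (0) | intermediate (1) | ideal (2) |
|---|---|---|---|
| BMI (kg/m²) | ≥ 27 | 24–27 | < 24 |
| Smoking | current | former, quit < 6 mo | never / quit ≥ 6 mo |
| Physical activity | never | in between | ≥ 30 min three times/wk |
| Total cholesterol (mg/dL) | ≥ 240 | 200–240 | < 200 |
| Fasting glucose (mg/dL) | ≥ 126 | 100–126 | < 100 |
| Blood pressure (mmHg) | SBP ≥ 140 or DBP ≥ 90 | otherwise | SBP < 120 and DBP < 80 |

The blood-pressure rule is implemented poor-first, then ideal, with
everything else intermediate. This is provably equivalent to the
explicit compound intermediate clause ("(120 ≤ SBP < 140 and DBP < 90)
or (80 ≤ DBP < 90 and SBP < 140)") and leaves no gaps or overlaps at the
compound boundaries; the test suite asserts one-and-only-one category on
an exhaustive threshold grid. The diet metric of the 14-point score is
out of scope (dietary exposures enter only as two-sample summary
statistics). Outcomes on arbitrary laboratory scales (such as a
DNA-methylation surrogate protein in pg/mL) can be standardized with
`zscore()`, which uses the sample (n−1) standard deviation — stated
explicitly because either convention is defensible and the choice
matters for reproducing effect sizes in SD units.

## One-sample arm

**GWAS.** `assoc_scan()` fits, per SNP, ordinary least squares of the
phenotype on the allele dosage (additive model) plus covariates — by
default age, sex, drinking status, educational attainment, and any
supplied ancestry principal components. Missing dosages are dropped per
SNP (complete-case), the simplest defensible convention. Markers first
pass `qc_filter()`: call rate ≥ 95%, exact Hardy–Weinberg p ≥ 5.7e-7,
and minor allele frequency strictly above 1% (recomputed from data, not
trusted from metadata). The HWE test is the conditional exact test
(two-sided by probability mass), the convention under which the 5.7e-7
threshold is quoted, not the chi-squared approximation.

**Clumping.** `clump()` reduces the scan to nearly independent index
SNPs: greedily take the smallest-p SNP with p < 5e-8, claim every SNP
within 10,000 kb on the same chromosome with r² ≥ 0.01 against it,
repeat. Ties in p are broken by (chromosome, position, id) so the
procedure is fully deterministic. LD is the squared Pearson correlation
of dosages (composite-genotype r²).

**Instrument.** `build_wgrs()` forms wGRS_i = Σ_j ŵ_j g_ij with the
index SNPs' scan betas as weights, after aligning each weight's effect
allele to the genotype matrix (counting 2 − g when the alleles are
swapped; rejecting irreconcilable allele pairs). Missing dosages are
mean-imputed at twice the effect-allele frequency, which keeps the
sample constant across SNP subsets during pruning. The base data used to
estimate weights and the target data where the wGRS is applied should be
disjoint; `run_pipeline()` enforces this with an internal split
(`target_frac`).

**Assumption checks.** Of the three IV assumptions, relevance is
quantified by the first-stage partial F statistic (`f_statistic()`,
F > 10 conventionally "strong"); independence and exclusion cannot be
proven but can be falsified. `assumption_report()` tests, at α = 0.05:

* independence — the wGRS against each confounder: a two-sample t-test
  for binary confounders, a Pearson correlation test for continuous
  ones;
* exclusion — the Wald test of the wGRS coefficient in a regression of
  the outcome on wGRS + exposure + confounders: a significant
  coefficient means the score reaches the outcome around the exposure.

When a check fails, `prune_instrument()` scans every instrument SNP
against the violated variable — Cochran–Armitage trend test for binary
confounders, one-way ANOVA across genotype groups for continuous ones,
and the same adjusted regression with the single SNP in place of the
wGRS for exclusion failures — removes the single most-associated SNP,
rebuilds the score, and repeats until all checks pass (or the instrument
would drop below `min_snps`, default 2, in which case it aborts naming
the unresolved check). Every decision is appended to an audit log from
which `replay_check_log()` reproduces the final instrument exactly. One
SNP is removed per iteration because a removal changes the wGRS and can
resolve several marginal violations at once.

A sample-level fluke (the wGRS marginally associated with a confounder
through no individual SNP) cannot always be repaired by removing SNPs;
the abort is then the honest outcome. For this reason `run_pipeline()`
exposes pruning as a stage toggle: calibration studies on cohorts whose
instruments are valid by construction run with `prune = FALSE` (the
assumption report is still attached), while the pruning procedure itself
is validated on planted violations.

**Estimation.** `tsls()` regresses the exposure on the instrument
(stage 1) and the outcome on the predicted exposure (stage 2), with the
same covariates in both stages when supplied. The reported standard
error is the IV-corrected one, computed from structural residuals
(outcome − coefficients applied to the *observed* exposure); the naive
stage-2 OLS standard error, which understates the noise, is kept in the
diagnostics for comparison since published tables rarely say which
convention they used. Inference is normal-based. A first-stage F below
10 flags (but does not suppress) the result.

## Two-sample arm

**Harmonization.** `harmonize()` aligns outcome effects onto the
exposure's effect allele: direct matches kept, swapped alleles
sign-flipped, strand complements resolved, incompatible allele sets
dropped. Palindromic SNPs (A/T, C/G) cannot be resolved from allele
letters; by default their orientation is inferred from effect-allele
frequencies when both are outside 0.5 ± 0.08, otherwise they are
dropped (`palindromic_policy = "drop"` drops them all). The 0.08
tolerance mirrors common two-sample practice; it is configurable because
no single value is canonical. Multi-base alleles (indels) are rejected
by the strict reader — the strand logic is undefined for them — but can
be retained with `allow_indels = TRUE`, in which case they skip the
palindrome checks.

**Estimators.** All methods consume the per-SNP pairs (bx, se_x, by,
se_y) and return the shared `mr_result` contract (β, SE, 95% CI, p,
nsnp):

* `mr_ivw()` — weighted regression of by on bx through the origin,
  weights 1/se_y²; the fixed-effect SE is (Σ bx²/se_y²)^−1/2, and under
  heterogeneity (Cochran's Q p < 0.05 in `mode = "auto"`) the SE is
  inflated multiplicatively by √(max(1, Q/(J−1))). With one SNP the
  estimate collapses to that SNP's Wald ratio.
* `cochrans_q()` — heterogeneity of the per-SNP Wald ratios about the
  IVW estimate, χ²(J−1).
* `mr_weighted_median()` — the weighted median of ordered Wald ratios
  under normalized inverse-variance weights, interpolated at the
  cumulative-midpoint 0.5; consistent when valid instruments carry at
  least half the weight. The SE comes from a parametric bootstrap
  (default 1000 draws, explicit seed) because no closed form exists.
* `mr_egger()` — weighted least squares of by on bx *with* intercept
  after orienting all bx ≥ 0; the slope is the causal estimate and the
  intercept its average-pleiotropy test, both on t(J−2) with the
  estimated residual dispersion (which keeps the intercept test exactly
  sized, as the calibration tests verify).
* `mr_presso()` — detects outlier SNPs by comparing each SNP's weighted
  squared residual about the leave-one-out IVW fit against a simulated
  null (default 1000 simulations), Bonferroni-adjusted over J; the
  global test compares the total residual sum of squares against the
  same null, and the distortion test compares the outlier-corrected IVW
  estimate with the full one against random equally-sized removals. The
  global p uses the add-one empirical estimator (never exactly zero);
  the per-SNP outlier p uses the plain empirical proportion so that
  Bonferroni flagging of gross outliers is not floored at J/n_sim.
* `mv_ivw()` — multivariable IVW: weighted no-intercept regression of
  outcome effects on the SNP × exposure effect matrix; coefficient k is
  exposure k's direct effect conditional on the others. With one
  exposure it reduces exactly to `mr_ivw()`; an exposure whose
  instrument effects are all zero is excluded (unidentified) rather
  than poisoning the fit; residual heterogeneity is reported as Q with
  J − K degrees of freedom. `mv_instruments()` assembles the joint
  instrument set: union of SNPs significant in any exposure, clumped by
  smallest p across exposures against an explicit LD reference, all
  tables harmonized to one orientation.

Multiple exposures tested against one outcome are corrected with
`bh_fdr()` (Benjamini–Hochberg step-up, within each method), matching
how composite-score components are usually reported.

## The synthetic cohort generator

`simulate_cohort()` draws genotypes in Hardy–Weinberg proportions
(independent SNPs by default; an optional Gaussian-copula block mode
induces within-block LD solely to exercise clumping), confounders (age
truncated-Normal(50, 11) on [30, 70], sex Bernoulli(0.5), drinking
Bernoulli(0.07), education uniform on 1..7 — distributions chosen once
to resemble an East-Asian biobank cohort profile), and raw clinical
metrics as linear structural equations: SNP effects + confounder
effects + Gaussian noise, centred so the realized metric means sit near
the clinical thresholds (population means ≈ TC 195, FG 97, BP 122/76,
BMI 24, giving component-score means close to the cohort the design
emulates). Smoking and activity are sampled categorically with no
genetic effects by default, mirroring how few genome-wide significant
hits such behavioural scores yield. Each outcome is then

> EAA = θ · (CVH total) + confounder effects + Σ_j pleiotropy_j g_j + noise,

with θ = −1 outcome unit per CVH point by default and horizontal
pleiotropy acting on the outcome directly (never through other
components), so instrument validity is exact in the truth record.
Missingness is completely at random.

Two generator choices deserve emphasis:

* **Effect scaling.** The real design estimated instrument weights on
  more than 10⁵ individuals; desk-scale tests use thousands. Default
  per-SNP effects are therefore scaled up (≈ 20 mg/dL TC, 7.5 mg/dL FG,
  7.5/5 mmHg BP, 1.1 kg/m² BMI per allele) so that the probability a
  true instrument reaches p < 5e-8 in the base scan is comparable to
  the original regime. This preserves the pipeline's selection dynamics
  at tractable sample sizes; it makes the per-variant biology
  unrealistically strong, which is irrelevant to what the tests
  measure.
* **What passing tests do and do not show.** The generator has no real
  LD structure, no population stratification (the "ancestry PCs" it
  emits are pure noise columns), no assortative mating, no dynastic
  effects, and Gaussian noise throughout. Calibration and recovery
  results on it validate the *statistics* — that the estimators are
  unbiased, sized and robust exactly when their assumptions hold — not
  the biology of any real cohort.

`simulate_summary_stats()` plays the same role for the two-sample arm:
β̂_X ~ Normal(β_X, se_x), β̂_Y ~ Normal(θβ_X + α, se_y), with
configurable directional/balanced pleiotropy α, planted outliers scaled
in units of se_y, and a configurable fraction of palindromic alleles
with consistent cross-study frequencies, so harmonization is exercised
end to end. Defaults (11 SNPs, small se_x, θ = −0.5) mirror the
conditions of a CVH-score instrument looked up in a large EAA GWAS
meta-analysis.

## Numerical choices and degenerate inputs

* All weighted least squares go through QR (`lm.fit`/`chol2inv`);
  nothing inverts a normal matrix formed in double precision from raw
  data.
* The exact HWE p-value is computed from log-probabilities normalized
  within the support, with the standard (1 + 1e-7) slack when summing
  masses "≤ observed" to absorb rounding; monomorphic SNPs return p = 1.
* Constant SNPs in a scan are flagged (`NA` row), not fatal; constant
  vectors are errors where a correlation is the deliverable (`ld_r2`,
  `zscore`).
* `clump()` ties are broken by (chromosome, position, id); `mr_egger()`
  refuses instances with no spread in |bx| (no leverage); `tsls()`
  refuses constant instruments and perfect collinearity;
  `cochran_armitage_trend()` flags tables with zero trend variance as
  untestable rather than dividing by zero.
* Every stochastic routine (bootstrap, PRESSO simulations, generators)
  takes an explicit seed; `run_pipeline()` fans a single master seed
  out to its stages, so a configuration reruns bit-identically.

## Problem sizes in the test suite

The shipped tests validate calibration at sizes chosen for a
single-CPU desk run: type-I error of Cochran's Q and the Egger
intercept over 1000 replicates (J = 30); IVW coverage over 500
summary-level replicates; 2SLS coverage over 500 full synthetic-cohort
pipeline runs (n = 5000, 12 SNPs, 70/30 base/target split); 2SLS-vs-OLS
confounding recovery over 200 replicates at n = 5000; weighted-median
robustness with 40% directional-pleiotropy instruments over 500
replicates; MR-PRESSO outlier detection over 200 replicates with a
planted 20·se_y outlier. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands (e.g. ±0.01 on a 95% coverage
estimate at 500 replicates).

## Known limitations

* No LIML or weak-instrument-robust (Anderson–Rubin) inference; weak
  instruments are flagged, not repaired.
* No Steiger directionality filtering, mode-based estimators,
  MR-RAPS, or contamination-mixture methods; no MVMR-Egger or
  conditional F statistics.
* Genotype pre-phasing/imputation, kinship pruning, ancestry PC
  computation and DNA-methylation clock estimation are upstream of this
  package: it consumes dosages, PCs and EAA columns as given.
* The ordinal CVH score is treated as a continuous phenotype in the
  scan and in 2SLS, as is conventional; no ordinal-model alternative is
  provided.
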