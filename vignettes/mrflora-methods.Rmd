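---
title: "Two-sample MR screening of gut microbial taxa: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening of gut microbial taxa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflora)
```

## The question and the design

Gut microbiota composition has been linked observationally to functional
recovery after ischemic stroke, but observational associations are
confounded (diet, severity, medication) and plausibly reverse-causal:
stroke itself disturbs the microbiome. Two-sample Mendelian randomization
(MR) sidesteps both problems by using germline variants as instruments.
Per-taxon abundance GWAS (exposure side, a microbiota-QTL meta-analysis of
211 taxa across 9 phyla, 16 classes, 20 orders, 35 families and 131
genera, N = 18,340) supply variant–abundance effects; stroke-outcome GWAS
(a dichotomized modified Rankin Scale phenotype, N = 6,021, and an NIHSS
motor-drift recovery phenotype, N = 488) supply variant–outcome effects on
the log-odds scale. If a variant affects the outcome only through the
taxon it instruments, the ratio of the two effects estimates the causal
effect of taxon abundance on the outcome.

The three instrumental-variable assumptions — relevance, independence
from confounders, and exclusion restriction — are not jointly testable.
The package therefore pairs every causal estimate with the standard
sensitivity battery (heterogeneity, pleiotropy, influence diagnostics)
and with decision rules that discard taxa whose estimators disagree in
direction.

## Instrument selection

Instruments are selected per taxon in a fixed order:

1. **Significance**: `pval < 1e-5`, the locus-wide threshold customary in
   microbiome MR, where genome-wide significant hits are too few to
   instrument most taxa.
2. **LD clumping**: greedy pruning at `r2 < 0.001` within a ±10,000 kb
   window. Records are processed in ascending p-value order (ties broken
   by position, then identifier, so the result is a pure function of the
   input set); a record is kept iff its LD with every already-kept record
   on the same chromosome inside the window is below threshold. SNP pairs
   absent from the LD table count as unlinked — conservative for
   retention and explicitly logged.
3. **Palindrome exclusion**: A/T and C/G variants are removed outright;
   their strand cannot be resolved from alleles alone, and allele
   frequencies are deliberately not used to rescue them.
4. **Instrument strength**: F = (beta/se)^2 must be at least 10, the
   conventional weak-instrument bound.

The filter order matters only for the audit trail (each stage's
attrition count is recorded in `provenance`); the retained set is
invariant to moving the palindrome filter before clumping.

## Harmonization

Exposure and outcome records are intersected on variant identifier and
aligned to the exposure's effect allele: identical pairs pass, swapped
pairs have the outcome effect negated (Wald ratios are invariant to this
convention flip), and strand-complementary non-palindromic pairs are
complemented first (disable with `strand_flip = FALSE` to treat them as
mismatches). Everything else is dropped with a machine-readable reason.
MR-Egger additionally requires the convention that every exposure effect
is non-negative; `orient_positive_exposure()` applies it and provably
leaves IVW, median, mode and maximum-likelihood estimates unchanged.

## The five estimators

Let `(bx_j, sx_j)` and `(by_j, sy_j)` be the aligned exposure and outcome
effects of instrument j = 1..J, and `r_j = by_j / bx_j` the per-variant
Wald ratio.

* **IVW** — weighted least squares of `by` on `bx` through the origin
  with weights `1/sy^2`, i.e. the inverse-variance meta-analysis of the
  Wald ratios. The default variance model is multiplicative random
  effects: the fixed-effect SE is inflated by `max(1, sqrt(Q/(J-1)))`,
  never deflated, so it is at least as conservative as fixed effects.
* **MR-Egger** — the same regression with a free intercept. The slope is
  the causal estimate under InSIDE (instrument strength independent of
  direct effects); the intercept estimates directional pleiotropy.
  Coefficient SEs carry the same `max(1, sigma_hat)` inflation with
  `sigma_hat^2` the weighted residual mean square on J − 2 df.
* **Weighted median** — ratios sorted ascending with normalized weights
  `bx^2/sy^2`; the estimate interpolates the weighted cumulative
  distribution at 1/2. Consistent while valid instruments hold more than
  half the weight. The SE is a parametric bootstrap (betas resampled
  from normals at their SEs; 1000 replicates and a fixed seed by
  default).
* **Weighted mode** — the argmax over a 512-point grid of the weighted
  normal-kernel density of the ratios, bandwidth
  `phi * 0.9 * min(sd, 1.4826 mad) * J^(-1/5)` (modified Silverman;
  `phi = 1` default; floor 1e-12), ties resolved toward the smaller
  value. Consistent when the largest cluster of ratio estimates comes
  from valid instruments. Bootstrap SE as for the median.
* **Maximum likelihood** — joint normal likelihood in `(theta, b_1..b_J)`
  with the per-variant true exposure effects profiled out in closed
  form; `theta` maximized by bounded one-dimensional optimization
  started at the IVW estimate, SE from the numerically differentiated
  curvature of the profile log-likelihood. Unlike IVW it models exposure
  measurement error, so its SE is slightly smaller when the model holds.

Estimates are reported as log-odds per unit (variance-standardized)
exposure and as odds ratios with `exp(theta ± 1.96 se)` intervals. The
constant 1.96 is used exactly — not a higher-precision quantile — so
that published OR/CI/p triples can be checked for internal consistency
with `p_from_or_ci()`, which inverts the same convention.

## Sensitivity suite

* **Cochran's Q** against the fixed-effect IVW fit (df J − 1) or the
  Egger line (df J − 2), chi-squared upper-tail p.
* **Egger intercept test** for directional pleiotropy.
* **Leave-one-out** IVW re-estimates; a row is "stable" when all J
  re-estimates share the full estimate's sign.
* **MR-PRESSO**: the observed residual sum of squares (each variant's
  outcome effect against its leave-one-out IVW prediction, weighted by
  `1/sy^2`) is compared with parametric simulations under the
  no-pleiotropy model; per-variant squared residuals give outlier
  p-values, Bonferroni-multiplied by J; the outlier-corrected IVW and a
  distortion test complete the block. Empirical p-values use the
  add-one estimator, so they are floored at `1/(n_sim+1)`; consequently
  the Bonferroni-adjusted per-variant p can only fall below
  `outlier_alpha = 0.05` when `n_sim > J/0.05` — with 30 instruments,
  1000 simulations suffice and 400 cannot flag anything. Internally the
  variant order is canonicalized before simulation, making results
  independent of input row order at a fixed seed.

## Screening and decision rules

`run_forward_screen()` applies the full pipeline per taxon and attaches
flags: *suggestive* (IVW p < 0.05), *Bonferroni-significant* at
0.05 divided by the number of taxa of the same rank (9, 16, 20, 35 or
131; a whole-registry divisor 0.05/211 is available by flag — the
published rule "0.05 divided by the number of each bacterial taxon" is
ambiguous between the two readings, and the per-rank one matches common
practice in microbiome MR), *Egger-direction-consistent* and
*all-methods-direction-consistent*. Taxa whose Egger slope opposes the
IVW sign get status `excluded_direction`; taxa left with fewer than 3
usable instruments are reported as `skipped_insufficient_ivs`, never
silently dropped. `run_reverse()` repeats the pipeline with exposure and
outcome swapped, at identical selection thresholds, to screen for
reverse causation.

## Nearest-gene enrichment

Causal variants are mapped to the nearest gene on the same chromosome
(containment wins at distance 0; otherwise the smaller of the distances
to the two interval boundaries; ties break by interval start, then
identifier; no assignment when the chromosome has no interval), and the
resulting gene list is tested for over-representation against
user-supplied GMT gene sets by the hypergeometric upper tail with
Benjamini–Hochberg adjustment. The original analysis used a web
meta-analysis service over GO/Reactome/KEGG; reproducing its specific
terms requires those databases, which are deliberately not bundled —
the analysis here is the standard offline equivalent on whatever
collections the user supplies.

## The synthetic-data generator

The generator emulates the *statistical* structure of the study inputs,
not their biology. For each of J variants: MAF ~ Uniform(`maf_range`);
a true exposure effect, half-normal with SD `instrument_effect_sd` (the
recorded effect allele is the exposure-increasing allele, the deposited
microbiota-QTL convention — this is what makes directional pleiotropy a
well-defined, recoverable quantity for the Egger intercept) or exactly
zero with probability `prop_null_instruments`; a pleiotropic direct
effect `alpha ~ N(pleiotropy_mean, pleiotropy_sd^2)`, optionally
correlated with standardized instrument strength
(`inside_violation_corr`, an InSIDE violation); the true outcome effect
`theta_true * b_x + alpha` on the log-odds scale. Observed effects add
normal noise with `se = 1/sqrt(2 maf (1-maf) n)` — the unit-variance
trait approximation, which couples SE to MAF and sample size the way
real summary statistics do. Defaults mirror the study: `n_exposure =
18340`, `n_outcome = 6021`, `instrument_effect_sd = 0.15` (locus-wide
significant mbQTL effects on a rank-normalized abundance scale),
`maf_range = c(0.05, 0.5)`, 20% palindromic variants, LD blocks of 5
with within-block r² = 0.8, one pseudo-chromosome per block so the
clumping window rule is exercised both within and across windows.
Optional `n_outliers`/`outlier_offset_se` inject gross pleiotropic
outliers (recorded in the returned truth) for outlier-detection
experiments. Outcome effects are generated directly on the log-odds
scale with normal errors rather than via individual-level logistic
simulation: two-sample MR consumes only summary statistics, and the
analytic truth makes recovery tests exact.

What the generator does *not* emulate: realistic human LD maps, allele
frequency spectra, winner's-curse correlation between selection and
estimation samples beyond what same-sample selection induces, 16S
measurement error, or compositionality of abundances. Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to every artefact of real microbiome
GWAS.

## Numerical choices and problem sizes

* Exposure trait scale: the source GWAS's abundance transform is not
  public; the generator treats the exposure as unit-variance continuous
  and all effects are interpreted per SD of abundance.
* Monte-Carlo suites use 200 replicates of J = 50 independent
  instruments; estimator-recovery replicates use
  `instrument_effect_sd = 1` so that every instrument is genuinely
  strong — with weaker instruments IVW exhibits its well-known
  regression-dilution and (under same-sample re-selection)
  winner's-curse bias of the order of the Monte-Carlo error itself,
  which is a property of the method, not of the implementation.
* Bootstrap SEs default to 1000 replicates; the test suite uses smaller
  counts where only point estimates are asserted.
* The weighted-median 50%-breakdown demonstration uses equal-strength
  instruments, because the guarantee is about the *weight* fraction held
  by valid instruments: with random strengths, 51% of the variants can
  hold less than half the weight and the bound genuinely fails.
* Degenerate inputs: single-instrument sets delegate IVW and maximum
  likelihood to the Wald ratio; identical ratios give Q = 0 and p = 1;
  zero kernel bandwidth is floored at 1e-12; empty instrument sets warn
  and propagate as skipped screen rows.

## Known limitations

Proxy-SNP lookup, multivariable MR, Steiger filtering and radial MR are
out of scope. The harmonizer never frequency-rescues palindromes. The
LD model is block-diagonal; clumping against a realistic panel will
behave differently in degree, not in kind. Reported ORs for the real
taxa require the consortium summary statistics, which are not
redistributable here; the package reproduces the published OR/CI/p
internal-consistency checks and all method-level guarantees instead.
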