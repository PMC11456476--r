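# mrflora

Two-sample Mendelian randomization (MR) screening of gut microbial taxa
against post-stroke functional outcomes, from GWAS summary statistics.

Observational links between gut microbiota composition and recovery after
ischemic stroke are confounded and plausibly reverse-causal. MR uses
germline variants as instruments: if variant *j* shifts the abundance of a
taxon by `bx_j` (per SD of abundance) and shifts the log-odds of a good
functional outcome by `by_j`, then under the instrumental-variable
assumptions the Wald ratio `by_j / bx_j` estimates the causal effect
`theta` of the taxon on the outcome. `mrflora` implements the complete
screening pipeline used in microbiome-outcome MR studies:

* **instrument selection** — locus-wide significance (p < 1e-5), greedy LD
  clumping (r² < 0.001 within ±10,000 kb), palindrome exclusion, and the
  F = (β/se)² ≥ 10 strength filter, with per-stage attrition audit;
* **harmonization** of exposure and outcome effects to a shared effect
  allele (swap and strand-complement rules, palindromes dropped);
* **five estimators** — inverse-variance weighted (multiplicative
  random-effects by default), MR-Egger, weighted median, weighted mode,
  and profile maximum likelihood — reported as OR with 95% CI;
* **sensitivity suite** — Cochran's Q (IVW and Egger), the Egger
  intercept pleiotropy test, MR-PRESSO (global, outlier and distortion
  tests), and leave-one-out influence analysis;
* **batch screening** over a 211-taxon registry (9 phyla / 16 classes /
  20 orders / 35 families / 131 genera) with suggestive (p < 0.05) and
  per-rank Bonferroni calls, Egger/IVW direction-consistency exclusion,
  reverse-causation MR, and plot-data export (scatter / forest /
  leave-one-out);
* **nearest-gene ORA** — hypergeometric over-representation of
  nearest-gene sets against user-supplied GMT collections with BH
  adjustment;
* a **synthetic-data generator** reproducing the statistical structure of
  the real inputs (MAF-coupled standard errors, LD blocks, palindromic
  alleles, tunable pleiotropy and instrument strength, known truth), so
  the whole pipeline is testable without consortium downloads.

## Worked example

Simulate one taxon with a true causal effect of 0.4 log-odds per SD of
abundance, run the full pipeline, and inspect the results:

```r
library(mrflora)

cfg <- synth_config(n_snps = 50, theta_true = 0.4, seed = 42,
                    palindromic_fraction = 0.1)
sim <- simulate_summary_pair(cfg)   # exposure + outcome tables + truth
ld  <- simulate_ld_table(cfg)

iv <- select_instruments(sim$exposure, ld)
#> Instrument set: 10 SNP(s)
#> Attrition: input=50 -> after_threshold=38 -> after_clump=10 -> after_palindrome=10 -> after_f=10

hs   <- harmonize(iv, sim$outcome)
ests <- mr_all_methods(hs, n_boot = 1000, seed = 7)
#> ivw (10 SNPs): theta = 0.4045 (SE 0.0262), OR = 1.499 [1.424, 1.577], p = 7.68e-54
#> egger (10 SNPs): theta = 0.3560 (SE 0.0739), OR = 1.428 [1.235, 1.650], p = 1.44e-06
#> weighted_median (10 SNPs): theta = 0.3801 (SE 0.0341), OR = 1.462 [1.368, 1.564], p = 8.05e-29
#> weighted_mode (10 SNPs): theta = 0.3798 (SE 0.0396), OR = 1.462 [1.353, 1.580], p = 8.83e-22
#> max_likelihood (10 SNPs): theta = 0.4051 (SE 0.0269), OR = 1.500 [1.423, 1.581], p = 2.93e-51

sens <- sensitivity_suite(hs, n_sim = 1000, seed = 7)
#> Cochran Q (IVW): Q = 7.53, df = 9, p = 0.582
#> Egger intercept: 0.0121 (p = 0.483)
#> MR-PRESSO: RSS = 9.154, global p = 0.6553, 0 outlier(s)
#> LOO stable: TRUE
```

Of the 50 simulated SNPs, 38 reach locus-wide significance and clumping
keeps one per LD block, leaving 10 independent instruments, all with
F > 10. Every estimator recovers the true effect (0.4) within its
standard error; an OR of ~1.5 means each SD increase in taxon abundance
multiplies the odds of a favorable outcome by 1.5 in this simulation.
The non-significant Q, Egger intercept and MR-PRESSO global test
correctly report no heterogeneity or pleiotropy (none was simulated),
and the leave-one-out estimates all keep the same sign.

Published OR/CI/p triples can be checked for internal consistency:

```r
p_from_or_ci(0.40, 0.21, 0.77)   # -> 0.006
p_from_or_ci(2.12, 1.10, 4.11)   # -> 0.025
```

For batch work, `run_forward_screen()` takes a named list of per-taxon
exposure tables, an outcome table and the taxon registry
(`simulate_taxonomy_registry()` gives the 211-taxon census), and returns
one row per taxon with all estimates, flags and the sensitivity block;
`run_reverse()` swaps the roles; `export_report()` /
`export_plot_data()` write delimited tables.

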