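Package: mrflora
Title: Two-Sample Mendelian Randomization Screening of Gut Microbial Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of gut
    microbiota abundance traits against post-stroke functional outcomes
    using GWAS summary statistics. Covers instrument selection (locus-wide
    significance, greedy LD clumping, palindrome exclusion, F-statistic
    filtering), exposure/outcome harmonization, five causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, weighted mode,
    maximum likelihood), a sensitivity suite (Cochran's Q, Egger intercept,
    MR-PRESSO, leave-one-out), batch screening with Bonferroni and
    direction-consistency decision rules, reverse-causation analysis, and
    nearest-gene over-representation analysis on user-supplied gene sets.
    A synthetic-data module generates summary statistics, taxonomy
    registries, LD tables and gene annotations with the statistical
    structure the analysis assumes, so the whole pipeline is testable
    without consortium data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
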