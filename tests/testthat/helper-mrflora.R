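# Shared fixtures for the test suite. Everything is generated in code;
# no files on disk.

# A harmonized set built directly from aligned vectors.
make_set <- function(beta_x, beta_y, se_x = NULL, se_y = NULL) {
  j <- length(beta_x)
  if (is.null(se_x)) se_x <- rep(0.02, j)
  if (is.null(se_y)) se_y <- rep(0.05, j)
  harmonized_set(beta_x, se_x, beta_y, se_y)
}

# A random harmonized set for oracle-equivalence checks.
random_set <- function(j = 20, seed = 1) {
  set.seed(seed)
  harmonized_set(
    beta_x = stats::rnorm(j, 0.2, 0.1),
    se_x = stats::runif(j, 0.01, 0.05),
    beta_y = stats::rnorm(j, 0.08, 0.05),
    se_y = stats::runif(j, 0.02, 0.08)
  )
}

# Simulate independent SNPs and harmonize against the outcome,
# optionally applying the study's instrument filters (p < 1e-5,
# F >= 10) first. Used for the Monte-Carlo recovery and calibration
# suites; `filter = FALSE` keeps all J instruments (the fixed-J strong-
# instrument condition).
sim_harmonized <- function(seed, n_snps = 50, theta_true = 0.4,
                           pleiotropy_mean = 0, pleiotropy_sd = 0,
                           inside_violation_corr = 0, filter = TRUE, ...) {
  cfg <- synth_config(
    n_snps = n_snps, theta_true = theta_true,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    inside_violation_corr = inside_violation_corr,
    palindromic_fraction = 0, ld_block_size = 1L, seed = seed, ...
  )
  sim <- simulate_summary_pair(cfg)
  keep <- if (filter) {
    sim$exposure$pval < 1e-5 &
      f_statistic(sim$exposure$beta, sim$exposure$se) >= 10
  } else rep(TRUE, nrow(sim$exposure))
  exp_df <- sim$exposure[keep, ]
  out_df <- sim$outcome[keep, ]
  list(set = harmonize(exp_df, out_df), truth = sim$truth)
}

# Monte-Carlo standard error of a mean.
mc_se <- function(x) stats::sd(x) / sqrt(length(x))

# Random clumping instance: SNPs scattered over blocks (chromosomes)
# with cubed-uniform p-values.
clump_fixture <- function(j = 50, seed = 3, n_blocks = 10) {
  set.seed(seed)
  block <- sample.int(n_blocks, j, replace = TRUE)
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(j)),
    chrom = paste0("chr", block),
    pos = 1000000L + as.integer(sample.int(500, j)) * 1000L,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = rnorm(j, 0, 0.1), se = 0.02,
    pval = runif(j)^3, n = 1000L, stringsAsFactors = FALSE
  )
}

# Long-format LD table for the fixture: same-block pairs share r2.
clump_ld <- function(records, r2 = 0.5) {
  pairs <- utils::combn(nrow(records), 2)
  same <- records$chrom[pairs[1, ]] == records$chrom[pairs[2, ]]
  data.frame(snp_a = records$snp_id[pairs[1, same]],
             snp_b = records$snp_id[pairs[2, same]],
             r2 = r2, stringsAsFactors = FALSE)
}

# Independent brute-force clumping oracle working off an explicit dense
# r2 matrix and a straightforward double loop.
clump_oracle <- function(records, r2_mat, r2_threshold, window_bp) {
  ord <- order(records$pval, records$pos, records$snp_id)
  rec <- records[ord, ]
  retained <- integer(0)
  for (i in seq_len(nrow(rec))) {
    conflict <- FALSE
    for (k in retained) {
      if (rec$chrom[k] != rec$chrom[i]) next
      if (abs(rec$pos[k] - rec$pos[i]) > window_bp) next
      if (r2_mat[rec$snp_id[i], rec$snp_id[k]] >= r2_threshold) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) retained <- c(retained, i)
  }
  sort(rec$snp_id[retained])
}

# Exhaustive hypergeometric upper tail P(X >= k) by direct summation.
hyper_tail_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
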