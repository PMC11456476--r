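# Synthetic GWAS summary statistics, taxonomy registries, LD tables and
# gene annotations emulating the statistical structure of two-sample MR
# inputs (microbiota abundance exposure, binary stroke-outcome phenotype).

#' Configuration for the synthetic summary-statistic generator
#'
#' Defines the generative model for a paired exposure/outcome GWAS:
#' per-SNP true exposure effects, horizontal pleiotropy, sampling noise
#' driven by minor-allele frequency and sample size, allele-pair
#' composition and LD-block layout.
#'
#' @param n_snps Number of SNPs J.
#' @param theta_true Causal effect of the exposure on the outcome,
#'   log-odds per unit exposure.
#' @param prop_null_instruments Fraction of SNPs with zero true exposure
#'   effect.
#' @param instrument_effect_sd SD of the true exposure effects among
#'   non-null SNPs (unit-variance exposure scale).
#' @param pleiotropy_mean Mean of the per-SNP direct (pleiotropic) effect
#'   on the outcome; nonzero values give directional pleiotropy.
#' @param pleiotropy_sd SD of the pleiotropic effects; nonzero with zero
#'   mean gives balanced pleiotropy.
#' @param inside_violation_corr Correlation between the pleiotropic effect
#'   and the true exposure effect of non-null SNPs; nonzero values violate
#'   the InSIDE assumption underlying MR-Egger.
#' @param n_exposure,n_outcome GWAS sample sizes; they set the
#'   summary-statistic standard errors through
#'   \code{se = 1/sqrt(2 maf (1-maf) n)}.
#' @param maf_range Range the minor-allele frequency is drawn from,
#'   within (0, 0.5].
#' @param palindromic_fraction Expected fraction of SNPs with A/T or C/G
#'   allele pairs.
#' @param ld_block_size Number of consecutive SNPs per LD block; each
#'   block is laid out on its own pseudo-chromosome.
#' @param ld_within_block_r2 Pairwise r-squared between SNPs of the same
#'   block in the companion LD table.
#' @param n_outliers Number of SNPs given an additional pleiotropic
#'   offset on the outcome (for outlier-detection experiments).
#' @param outlier_offset_se Size of that offset in outcome-SE units.
#' @param seed Integer seed; identical config and seed give identical
#'   output.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_snps = 50L,
                         theta_true = 0,
                         prop_null_instruments = 0,
                         instrument_effect_sd = 0.15,
                         pleiotropy_mean = 0,
                         pleiotropy_sd = 0,
                         inside_violation_corr = 0,
                         n_exposure = 18340L,
                         n_outcome = 6021L,
                         maf_range = c(0.05, 0.5),
                         palindromic_fraction = 0.2,
                         ld_block_size = 5L,
                         ld_within_block_r2 = 0.8,
                         n_outliers = 0L,
                         outlier_offset_se = 0,
                         seed = 1L) {
  cfg <- list(
    n_snps = n_snps, theta_true = theta_true,
    prop_null_instruments = prop_null_instruments,
    instrument_effect_sd = instrument_effect_sd,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    inside_violation_corr = inside_violation_corr,
    n_exposure = n_exposure, n_outcome = n_outcome,
    maf_range = maf_range, palindromic_fraction = palindromic_fraction,
    ld_block_size = ld_block_size, ld_within_block_r2 = ld_within_block_r2,
    n_outliers = n_outliers, outlier_offset_se = outlier_offset_se,
    seed = seed
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid synth_config field '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(cfg$n_snps) && length(cfg$n_snps) == 1 && cfg$n_snps >= 1,
      "n_snps", "must be a positive integer")
  chk(is.numeric(cfg$theta_true) && length(cfg$theta_true) == 1,
      "theta_true", "must be a single real")
  chk(cfg$prop_null_instruments >= 0 && cfg$prop_null_instruments <= 1,
      "prop_null_instruments", "must lie in [0, 1]")
  chk(cfg$instrument_effect_sd > 0, "instrument_effect_sd", "must be > 0")
  chk(cfg$pleiotropy_sd >= 0, "pleiotropy_sd", "must be >= 0")
  chk(abs(cfg$inside_violation_corr) <= 1, "inside_violation_corr",
      "must lie in [-1, 1]")
  chk(cfg$n_exposure >= 1, "n_exposure", "must be a positive integer")
  chk(cfg$n_outcome >= 1, "n_outcome", "must be a positive integer")
  chk(length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
        cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2],
      "maf_range", "must be an increasing pair within (0, 0.5]")
  chk(cfg$palindromic_fraction >= 0 && cfg$palindromic_fraction <= 1,
      "palindromic_fraction", "must lie in [0, 1]")
  chk(cfg$ld_block_size >= 1, "ld_block_size", "must be a positive integer")
  chk(cfg$ld_within_block_r2 >= 0 && cfg$ld_within_block_r2 <= 1,
      "ld_within_block_r2", "must lie in [0, 1]")
  chk(cfg$n_outliers >= 0 && cfg$n_outliers <= cfg$n_snps, "n_outliers",
      "must lie in [0, n_snps]")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "must be a single integer")
  invisible(cfg)
}

# Non-palindromic unordered allele pairs over {A,C,G,T}.
.NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "G", "A",
  "T", "C", "T", "G", "C", "T", "G", "T"
), ncol = 2, byrow = TRUE)
.PALINDROMIC_PAIRS <- matrix(c(
  "A", "T", "T", "A", "C", "G", "G", "C"
), ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome GWAS
#'
#' Draws per-SNP true exposure effects and pleiotropic direct effects,
#' propagates them through the causal model
#' \code{b_y = theta_true * b_x + alpha}, and adds sampling noise with
#' MAF- and sample-size-driven standard errors. Exposure betas are on a
#' unit-variance continuous trait scale; outcome betas are log-odds.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list with components \code{exposure} and \code{outcome}
#'   (summary-statistic data frames with columns snp_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, pval, n) and
#'   \code{truth} (list: theta_true, b_x, alpha, outlier_indices).
#' @export
simulate_summary_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)
  j <- as.integer(config$n_snps)

  maf <- stats::runif(j, config$maf_range[1], config$maf_range[2])
  nonnull <- stats::runif(j) >= config$prop_null_instruments
  # The recorded effect allele is the exposure-increasing allele (the
  # deposited-mbQTL convention), so true exposure effects are
  # half-normal; directional pleiotropy is expressed in this frame and
  # is therefore recoverable by the MR-Egger intercept.
  b_x <- ifelse(nonnull,
                abs(stats::rnorm(j, 0, config$instrument_effect_sd)), 0)

  # Pleiotropic effects, correlated with the (standardized half-normal)
  # instrument strength when an InSIDE violation is requested.
  z_ind <- stats::rnorm(j)
  rho <- config$inside_violation_corr
  hn_mean <- sqrt(2 / pi)
  hn_sd <- sqrt(1 - 2 / pi)
  z_b <- ifelse(nonnull,
                (b_x / config$instrument_effect_sd - hn_mean) / hn_sd, 0)
  z <- ifelse(nonnull, rho * z_b + sqrt(max(0, 1 - rho^2)) * z_ind, z_ind)
  alpha <- config$pleiotropy_mean + config$pleiotropy_sd * z

  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)

  outlier_idx <- integer(0)
  if (config$n_outliers > 0) {
    outlier_idx <- sort(sample.int(j, config$n_outliers))
    alpha[outlier_idx] <- alpha[outlier_idx] +
      config$outlier_offset_se * se_y[outlier_idx]
  }
  b_y <- config$theta_true * b_x + alpha

  beta_x <- stats::rnorm(j, b_x, se_x)
  beta_y <- stats::rnorm(j, b_y, se_y)
  p_x <- 2 * stats::pnorm(-abs(beta_x / se_x))
  p_y <- 2 * stats::pnorm(-abs(beta_y / se_y))

  pal <- stats::runif(j) < config$palindromic_fraction
  pick_pal <- sample.int(nrow(.PALINDROMIC_PAIRS), j, replace = TRUE)
  pick_non <- sample.int(nrow(.NONPALINDROMIC_PAIRS), j, replace = TRUE)
  ea <- ifelse(pal, .PALINDROMIC_PAIRS[pick_pal, 1],
               .NONPALINDROMIC_PAIRS[pick_non, 1])
  oa <- ifelse(pal, .PALINDROMIC_PAIRS[pick_pal, 2],
               .NONPALINDROMIC_PAIRS[pick_non, 2])

  # One pseudo-chromosome per LD block; SNPs of a block sit 100 kb apart
  # so any same-block pair is well inside a 10,000 kb clumping window.
  block <- (seq_len(j) - 1L) %/% as.integer(config$ld_block_size) + 1L
  within <- (seq_len(j) - 1L) %% as.integer(config$ld_block_size)
  chrom <- paste0("chr", block)
  pos <- 1000000L + within * 100000L

  make_tbl <- function(beta, se, pval, n) {
    data.frame(
      snp_id = sprintf("rs%06d", seq_len(j)),
      chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa,
      eaf = maf, beta = beta, se = se, pval = pmax(pval, .Machine$double.xmin),
      n = as.integer(n), stringsAsFactors = FALSE
    )
  }

  list(
    exposure = make_tbl(beta_x, se_x, p_x, config$n_exposure),
    outcome = make_tbl(beta_y, se_y, p_y, config$n_outcome),
    truth = list(theta_true = config$theta_true, b_x = b_x, alpha = alpha,
                 outlier_indices = outlier_idx)
  )
}

#' Synthetic taxonomy registry
#'
#' Builds a registry of 211 bacterial taxa with the rank composition of
#' the MiBioGen abundance GWAS: 9 phyla, 16 classes, 20 orders, 35
#' families and 131 genera.
#'
#' @return Data frame with columns taxon_id, rank, name.
#' @export
simulate_taxonomy_registry <- function() {
  counts <- c(phylum = 9L, class = 16L, order = 20L, family = 35L,
              genus = 131L)
  rank <- rep(names(counts), counts)
  idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  data.frame(
    taxon_id = sprintf("%s.%03d", rank, idx),
    rank = rank,
    name = sprintf("%s_taxon_%03d", rank, idx),
    stringsAsFactors = FALSE
  )
}

#' Synthetic pairwise-LD table
#'
#' Produces the long-format LD table matching a
#' \code{\link{simulate_summary_pair}} layout: SNPs of the same block
#' share \code{ld_within_block_r2}; cross-block pairs have r-squared 0
#' and are omitted from the table (absent pairs are read as unlinked).
#'
#' @param config A \code{\link{synth_config}}.
#' @return Data frame with columns snp_a, snp_b, r2 (one row per
#'   unordered within-block pair).
#' @export
simulate_ld_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  j <- as.integer(config$n_snps)
  ids <- sprintf("rs%06d", seq_len(j))
  block <- (seq_len(j) - 1L) %/% as.integer(config$ld_block_size) + 1L
  rows <- list()
  for (b in unique(block)) {
    members <- which(block == b)
    if (length(members) < 2) next
    pr <- utils::combn(members, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_a = ids[pr[1, ]], snp_b = ids[pr[2, ]],
      r2 = config$ld_within_block_r2, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Synthetic gene intervals and gene sets
#'
#' Generates non-identical, possibly overlapping 1-based inclusive gene
#' intervals on the synthetic pseudo-chromosomes, plus gene sets sampled
#' from them without replacement (a fixture for nearest-gene
#' over-representation analysis).
#'
#' @param n_genes Number of gene intervals (>= 2).
#' @param n_sets Number of gene sets (>= 1).
#' @param seed Integer seed.
#' @return List with \code{intervals} (data frame gene_id, chrom, start,
#'   end) and \code{sets} (named list of gene-id character vectors).
#' @export
simulate_gene_annotation <- function(n_genes, n_sets, seed = 1L) {
  stopifnot(n_genes >= 2, n_sets >= 1)
  set.seed(seed)
  chrom <- paste0("chr", sample.int(max(2L, n_genes %/% 4L), n_genes,
                                    replace = TRUE))
  start <- sample.int(5000000L, n_genes, replace = TRUE)
  len <- sample.int(200000L, n_genes, replace = TRUE) + 999L
  intervals <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = chrom, start = start, end = start + len,
    stringsAsFactors = FALSE
  )
  sets <- stats::setNames(lapply(seq_len(n_sets), function(s) {
    k <- sample(2:max(2L, n_genes %/% 2L), 1L)
    sample(intervals$gene_id, min(k, n_genes))
  }), sprintf("set%03d", seq_len(n_sets)))
  list(intervals = intervals, sets = sets)
}
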