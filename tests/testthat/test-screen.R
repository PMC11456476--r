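test_that("Bonferroni thresholds divide 0.05 by the per-rank counts", {
  reg <- simulate_taxonomy_registry()
  expect_equal(bonferroni_threshold("genus", reg), 0.05 / 131)
  expect_equal(bonferroni_threshold("family", reg), 0.05 / 35)
  expect_equal(bonferroni_threshold("phylum", reg), 0.05 / 9)
  expect_equal(bonferroni_threshold("genus", reg, scope = "registry"),
               0.05 / 211)
  single <- data.frame(taxon_id = "t1", rank = "genus", name = "t1")
  expect_equal(bonferroni_threshold("genus", single), 0.05)
  expect_error(bonferroni_threshold("species", reg), "species")
})

make_screen_fixture <- function(n_taxa = 6, causal = 1, theta = 0.6,
                                seed = 100) {
  reg <- data.frame(
    taxon_id = sprintf("genus.%03d", seq_len(n_taxa)),
    rank = "genus", name = sprintf("genus_%03d", seq_len(n_taxa)),
    stringsAsFactors = FALSE
  )
  exposures <- list()
  outcome <- NULL
  for (i in seq_len(n_taxa)) {
    th <- if (i == causal) theta else 0
    cfg <- synth_config(n_snps = 40, theta_true = th,
                        palindromic_fraction = 0, ld_block_size = 1L,
                        seed = seed + i)
    sim <- simulate_summary_pair(cfg)
    sim$exposure$snp_id <- sprintf("t%02d_%s", i, sim$exposure$snp_id)
    sim$outcome$snp_id <- sim$exposure$snp_id
    exposures[[reg$taxon_id[i]]] <- sim$exposure
    outcome <- rbind(outcome, sim$outcome)
  }
  list(registry = reg, exposures = exposures, outcome = outcome)
}

test_that("forward screen flags the causal taxon and carries flags", {
  fx <- make_screen_fixture()
  rep <- run_forward_screen(fx$exposures, fx$outcome, fx$registry,
                            outcome_label = "overall stroke outcome",
                            n_boot = 30, n_sim = 100, seed = 9)
  expect_s3_class(rep, "screen_report")
  expect_length(rep, 6)

  suggestive <- vapply(rep, function(r) isTRUE(r$suggestive), logical(1))
  expect_true(suggestive[1])  # the causal taxon
  expect_lte(sum(suggestive[-1]), 2)  # null taxa rarely cross 0.05

  r1 <- rep[[1]]
  expect_equal(r1$bonferroni_threshold, 0.05 / 6)
  expect_equal(r1$n_snp, nrow(r1$harmonized$data))
  expect_true(all(c("ivw", "egger", "weighted_median", "weighted_mode",
                    "max_likelihood") %in% names(r1$estimates)))
  expect_true(r1$status %in% c("retained", "excluded_direction"))
  # bonferroni_significant implies suggestive on every row
  for (r in rep) {
    if (isTRUE(r$bonferroni_significant)) expect_true(r$suggestive)
  }
})

test_that("screen is deterministic and exports byte-identical files", {
  fx <- make_screen_fixture(n_taxa = 2)
  rep1 <- run_forward_screen(fx$exposures, fx$outcome, fx$registry,
                             n_boot = 20, n_sim = 50, seed = 4)
  rep2 <- run_forward_screen(fx$exposures, fx$outcome, fx$registry,
                             n_boot = 20, n_sim = 50, seed = 4)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_report(rep1, f1)
  export_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))

  df <- as.data.frame(rep1)
  expect_true(all(c("or_point", "or_ci_low", "or_ci_high", "pval",
                    "status") %in% names(df)))
})

test_that("insufficient instruments produce a skipped row, not an error", {
  fx <- make_screen_fixture(n_taxa = 2)
  # cripple the second taxon: no SNP passes the significance threshold
  fx$exposures[[2]]$pval <- 0.5
  rep <- suppressWarnings(
    run_forward_screen(fx$exposures, fx$outcome, fx$registry,
                       n_boot = 20, n_sim = 50, seed = 4)
  )
  expect_equal(rep[[2]]$status, "skipped_insufficient_ivs")
  expect_equal(rep[[2]]$n_snp, 0)
  # the report still carries the row
  df <- as.data.frame(rep)
  expect_true("skipped_insufficient_ivs" %in% df$status)
})

test_that("Egger/IVW sign disagreement yields excluded_direction", {
  # strong InSIDE-violating directional pleiotropy drags the Egger
  # slope below zero while IVW stays positive
  set.seed(31)
  j <- 30
  bx <- runif(j, 0.1, 0.5)
  alpha <- 0.25 - 0.6 * bx          # direct effect anti-correlated with bx
  by <- 0.05 * bx + alpha
  exp_df <- data.frame(
    snp_id = sprintf("rs%03d", 1:j), chrom = paste0("chr", 1:j),
    pos = 1000000L, effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = bx, se = 0.01, pval = 1e-10, n = 18340L,
    stringsAsFactors = FALSE
  )
  out_df <- exp_df
  out_df$beta <- by
  out_df$se <- 0.05
  out_df$pval <- 2 * pnorm(-abs(by / 0.05))
  reg <- data.frame(taxon_id = "genus.001", rank = "genus",
                    name = "g1", stringsAsFactors = FALSE)
  rep <- run_forward_screen(list(genus.001 = exp_df), out_df, reg,
                            n_boot = 20, n_sim = 50, seed = 2)
  r <- rep[[1]]
  expect_false(r$egger_direction_consistent)
  expect_equal(r$status, "excluded_direction")
  expect_false(r$all_methods_direction_consistent)
})

test_that("direction-consistency flag matches the shared-sign property", {
  fx <- make_screen_fixture(n_taxa = 3, causal = 2)
  rep <- run_forward_screen(fx$exposures, fx$outcome, fx$registry,
                            n_boot = 20, n_sim = 50, seed = 8)
  for (r in rep) {
    if (length(r$estimates) < 2) next
    signs <- vapply(r$estimates, function(e) sign(e$theta), numeric(1))
    expect_equal(r$all_methods_direction_consistent,
                 length(unique(signs)) == 1)
  }
})

test_that("reverse analysis swaps roles and is null when causality is forward-only", {
  # the outcome trait has its own instruments but no causal effect on
  # the taxon: exposure = outcome GWAS, outcome = taxon GWAS, theta = 0
  cfg <- synth_config(n_snps = 40, theta_true = 0,
                      palindromic_fraction = 0, ld_block_size = 1L,
                      seed = 901)
  sim <- simulate_summary_pair(cfg)
  reg <- data.frame(taxon_id = "genus.001", rank = "genus", name = "g1",
                    stringsAsFactors = FALSE)
  rev <- run_reverse(sim$exposure, list(genus.001 = sim$outcome), reg,
                     outcome_label = "overall stroke outcome",
                     n_boot = 20, n_sim = 50, seed = 3)
  expect_length(rev, 1)
  r <- rev[[1]]
  expect_true(r$reverse)
  expect_equal(r$outcome_label, "genus.001")
  expect_gte(r$n_snp, 3)
  expect_gt(r$estimates$ivw$pval, 0.05)
  # zero positive rows -> empty reverse report
  empty <- run_reverse(sim$exposure, list(), reg)
  expect_length(empty, 0)
})

test_that("plot-data exports follow their format contracts", {
  fx <- make_screen_fixture(n_taxa = 1)
  rep <- run_forward_screen(fx$exposures, fx$outcome, fx$registry,
                            n_boot = 20, n_sim = 50, seed = 5)
  j <- rep[[1]]$n_snp
  n_methods <- length(rep[[1]]$estimates)

  scatter <- withr::local_tempfile(fileext = ".tsv")
  export_plot_data(rep, "scatter", scatter)
  expect_equal(length(readLines(scatter)) - 1, j + n_methods)

  forest <- withr::local_tempfile(fileext = ".tsv")
  export_plot_data(rep, "forest", forest)
  ftab <- utils::read.delim(forest)
  expect_equal(sum(ftab$record == "snp"), j)
  expect_equal(sum(ftab$record == "combined"), n_methods)

  loo <- withr::local_tempfile(fileext = ".tsv")
  export_plot_data(rep, "loo", loo)
  ltab <- utils::read.delim(loo)
  expect_equal(nrow(ltab), j)
})

test_that("homogeneous two-SNP fixture exports ratio 0.5 everywhere", {
  exp_df <- data.frame(
    snp_id = c("rs1", "rs2"), chrom = c("chr1", "chr2"),
    pos = 1000000L, effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = c(0.5, 0.2), se = 0.02, pval = 1e-10, n = 18340L,
    stringsAsFactors = FALSE
  )
  out_df <- exp_df
  out_df$beta <- c(0.25, 0.10)
  out_df$se <- 0.1
  reg <- data.frame(taxon_id = "genus.001", rank = "genus", name = "g1")
  rep <- run_forward_screen(list(genus.001 = exp_df), out_df, reg,
                            n_boot = 10, n_sim = 50, seed = 1)
  forest <- withr::local_tempfile(fileext = ".tsv")
  export_plot_data(rep, "forest", forest)
  ftab <- utils::read.delim(forest)
  expect_equal(ftab$theta[ftab$record == "snp"], c(0.5, 0.5),
               tolerance = 1e-10)
  expect_equal(ftab$theta[ftab$id == "ivw"], 0.5, tolerance = 1e-10)
})
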