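# Batch screening: forward MR of every taxon against an outcome,
# suggestive / Bonferroni calls, direction-consistency decision rules,
# reverse-causation analysis, and report / plot-data export.

#' Bonferroni threshold for a taxonomic rank
#'
#' 0.05 divided by the number of taxa tested: by default the count of
#' taxa sharing the rank in the registry (per-rank correction); a
#' whole-registry divisor is available via \code{scope}.
#'
#' @param rank One of phylum, class, order, family, genus.
#' @param registry Taxon registry data frame (taxon_id, rank, name).
#' @param scope "per_rank" (default) or "registry".
#' @return The significance threshold.
#' @export
bonferroni_threshold <- function(rank, registry,
                                 scope = c("per_rank", "registry")) {
  scope <- match.arg(scope)
  if (scope == "registry") return(0.05 / nrow(registry))
  n <- sum(registry$rank == rank)
  if (n == 0) stop("rank '", rank, "' absent from the registry",
                   call. = FALSE)
  0.05 / n
}

.sign0 <- function(x) if (is.null(x) || is.na(x)) NA else sign(x)

.screen_one <- function(taxon_id, rank, name, exposure, outcome, ld,
                        selection, outcome_label, bonf, n_boot, n_sim,
                        seed, reverse = FALSE) {
  iv <- suppressWarnings(select_instruments(exposure, ld, selection))
  hs <- if (nrow(iv$records) > 0) {
    harmonize(iv, outcome)
  } else {
    harmonized_set(numeric(0), numeric(0), numeric(0), numeric(0))
  }
  j <- nrow(hs$data)
  estimates <- if (j >= 1) {
    mr_all_methods(hs, n_boot = n_boot, seed = seed)
  } else list()
  sens <- if (j >= 2) sensitivity_suite(hs, n_sim = n_sim, seed = seed) else NULL

  theta_ivw <- if (!is.null(estimates$ivw)) estimates$ivw$theta else NA_real_
  p_ivw <- if (!is.null(estimates$ivw)) estimates$ivw$pval else NA_real_
  theta_egger <- if (!is.null(estimates$egger)) estimates$egger$theta else NA_real_

  suggestive <- isTRUE(p_ivw < 0.05)
  bonf_sig <- isTRUE(p_ivw < bonf)
  egger_dir <- if (is.na(theta_egger) || is.na(theta_ivw)) NA else
    sign(theta_egger) == sign(theta_ivw)
  signs <- vapply(estimates, function(e) sign(e$theta), numeric(1))
  all_dir <- if (length(signs) >= 2) length(unique(signs)) == 1 else NA

  status <- if (j < 3) {
    "skipped_insufficient_ivs"
  } else if (isFALSE(egger_dir)) {
    "excluded_direction"
  } else {
    "retained"
  }

  structure(list(
    taxon_id = taxon_id, rank = rank, name = name,
    outcome_label = outcome_label, reverse = reverse,
    estimates = estimates, n_snp = j,
    harmonized = hs, instruments = iv,
    suggestive = suggestive, bonferroni_threshold = bonf,
    bonferroni_significant = bonf_sig,
    egger_direction_consistent = egger_dir,
    all_methods_direction_consistent = all_dir,
    sensitivity = sens, status = status
  ), class = "screen_row")
}

#' Forward MR screen of taxa against an outcome
#'
#' For each taxon: instrument selection, harmonization against the
#' outcome, the five estimators, the sensitivity suite and the decision
#' flags. Taxa left with fewer than 3 harmonized instruments get status
#' \code{skipped_insufficient_ivs} (with whatever estimates their J
#' permits); taxa whose MR-Egger slope disagrees in sign with IVW get
#' \code{excluded_direction}.
#'
#' @param exposures Named list of exposure summary-statistic data
#'   frames, keyed by taxon_id.
#' @param outcome Outcome summary-statistics data frame.
#' @param registry Taxon registry (taxon_id, rank, name) supplying the
#'   Bonferroni divisors.
#' @param ld LD table or NULL.
#' @param selection An \code{\link{instrument_config}}.
#' @param outcome_label Label recorded on every row.
#' @param bonferroni_scope "per_rank" or "registry".
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param n_sim MR-PRESSO simulations.
#' @param seed Base seed; each taxon uses a distinct offset.
#' @return Object of class \code{screen_report} (list of
#'   \code{screen_row}).
#' @export
run_forward_screen <- function(exposures, outcome, registry, ld = NULL,
                               selection = instrument_config(),
                               outcome_label = "outcome",
                               bonferroni_scope = "per_rank",
                               n_boot = 200L, n_sim = 500L, seed = 1L) {
  rows <- vector("list", length(exposures))
  ids <- names(exposures)
  for (i in seq_along(exposures)) {
    tid <- ids[i]
    hit <- match(tid, registry$taxon_id)
    rank <- if (is.na(hit)) NA_character_ else registry$rank[hit]
    name <- if (is.na(hit)) tid else registry$name[hit]
    bonf <- if (is.na(hit)) 0.05 else
      bonferroni_threshold(rank, registry, bonferroni_scope)
    rows[[i]] <- .screen_one(tid, rank, name, exposures[[i]], outcome, ld,
                             selection, outcome_label, bonf,
                             n_boot, n_sim, seed + i, reverse = FALSE)
  }
  structure(rows, class = "screen_report")
}

#' Reverse-causation MR analysis
#'
#' Re-runs the same pipeline with roles swapped: the outcome GWAS
#' serves as the exposure and each (forward-positive) taxon GWAS as the
#' outcome, with the identical instrument-selection criteria.
#'
#' @param outcome_as_exposure The outcome GWAS used as exposure.
#' @param taxon_outcomes Named list of taxon summary-statistic data
#'   frames (the new outcomes), keyed by taxon_id.
#' @param registry Taxon registry.
#' @param ld LD table or NULL.
#' @param selection An \code{\link{instrument_config}} (same thresholds
#'   as the forward screen).
#' @param outcome_label Label of the trait acting as exposure.
#' @param n_boot,n_sim,seed As in \code{\link{run_forward_screen}}.
#' @return A \code{screen_report} with \code{reverse = TRUE} rows.
#' @export
run_reverse <- function(outcome_as_exposure, taxon_outcomes, registry,
                        ld = NULL, selection = instrument_config(),
                        outcome_label = "outcome", n_boot = 200L,
                        n_sim = 500L, seed = 1L) {
  rows <- vector("list", length(taxon_outcomes))
  ids <- names(taxon_outcomes)
  for (i in seq_along(taxon_outcomes)) {
    tid <- ids[i]
    hit <- match(tid, registry$taxon_id)
    rank <- if (is.na(hit)) NA_character_ else registry$rank[hit]
    name <- if (is.na(hit)) tid else registry$name[hit]
    rows[[i]] <- .screen_one(
      paste0(outcome_label, "->", tid), rank, name,
      outcome_as_exposure, taxon_outcomes[[i]], ld, selection,
      outcome_label = tid, bonf = 0.05, n_boot = n_boot, n_sim = n_sim,
      seed = seed + i, reverse = TRUE
    )
  }
  structure(rows, class = "screen_report")
}

#' Flatten a screen report to a long data frame
#'
#' One row per taxon x outcome x method with theta, SE, OR, CI, p and
#' the decision flags.
#'
#' @param x A \code{screen_report}.
#' @param ... Unused.
#' @return Data frame.
#' @export
as.data.frame.screen_report <- function(x, ...) {
  out <- lapply(x, function(row) {
    if (length(row$estimates) == 0) {
      return(data.frame(
        taxon_id = row$taxon_id, rank = row$rank, name = row$name,
        outcome = row$outcome_label, method = NA_character_,
        n_snp = row$n_snp, theta = NA_real_, se = NA_real_,
        or_point = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
        pval = NA_real_, suggestive = row$suggestive,
        bonferroni_threshold = row$bonferroni_threshold,
        bonferroni_significant = row$bonferroni_significant,
        egger_direction_consistent = NA,
        all_methods_direction_consistent = NA,
        status = row$status, stringsAsFactors = FALSE
      ))
    }
    do.call(rbind, lapply(row$estimates, function(e) {
      data.frame(
        taxon_id = row$taxon_id, rank = row$rank, name = row$name,
        outcome = row$outcome_label, method = e$method,
        n_snp = e$n_snp, theta = e$theta, se = e$se,
        or_point = e$or_point, or_ci_low = e$or_ci95[1],
        or_ci_high = e$or_ci95[2], pval = e$pval,
        suggestive = row$suggestive,
        bonferroni_threshold = row$bonferroni_threshold,
        bonferroni_significant = row$bonferroni_significant,
        egger_direction_consistent = row$egger_direction_consistent,
        all_methods_direction_consistent =
          row$all_methods_direction_consistent,
        status = row$status, stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a screen report as a delimited table
#'
#' @param rows A \code{screen_report}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
export_report <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export plot-ready data for scatter, forest or leave-one-out figures
#'
#' Scatter: per-SNP (beta_x, se_x, beta_y, se_y) points plus one
#' (slope, intercept) line per method. Forest: per-SNP Wald ratios with
#' 95% CIs plus the combined estimates. LOO: the leave-one-out rows.
#'
#' @param rows A \code{screen_report}.
#' @param kind "scatter", "forest" or "loo".
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
export_plot_data <- function(rows, kind = c("scatter", "forest", "loo"),
                             path) {
  kind <- match.arg(kind)
  blocks <- lapply(rows, function(row) {
    d <- row$harmonized$data
    if (nrow(d) == 0) return(NULL)
    tag <- data.frame(taxon_id = row$taxon_id,
                      outcome = row$outcome_label,
                      stringsAsFactors = FALSE)
    if (kind == "scatter") {
      pts <- cbind(tag, record = "snp", id = d$snp_id,
                   beta_x = d$beta_x, se_x = d$se_x,
                   beta_y = d$beta_y, se_y = d$se_y,
                   slope = NA_real_, intercept = NA_real_)
      lines <- do.call(rbind, lapply(row$estimates, function(e) {
        cbind(tag, record = "method", id = e$method,
              beta_x = NA_real_, se_x = NA_real_,
              beta_y = NA_real_, se_y = NA_real_,
              slope = e$theta,
              intercept = if (e$method == "egger") e$extras$alpha else 0)
      }))
      rbind(pts, lines)
    } else if (kind == "forest") {
      ratios <- d$beta_y / d$beta_x
      ses <- d$se_y / abs(d$beta_x)
      pts <- cbind(tag, record = "snp", id = d$snp_id, theta = ratios,
                   ci_low = ratios - 1.96 * ses,
                   ci_high = ratios + 1.96 * ses)
      comb <- do.call(rbind, lapply(row$estimates, function(e) {
        cbind(tag, record = "combined", id = e$method, theta = e$theta,
              ci_low = e$theta - 1.96 * e$se,
              ci_high = e$theta + 1.96 * e$se)
      }))
      rbind(pts, comb)
    } else {
      if (is.null(row$sensitivity) || is.null(row$sensitivity$loo)) {
        return(NULL)
      }
      loo <- row$sensitivity$loo$rows
      cbind(tag, loo)
    }
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  out <- if (length(blocks) > 0) do.call(rbind, blocks) else data.frame()
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.screen_report <- function(x, ...) {
  df <- as.data.frame(x)
  ivw_rows <- df[is.na(df$method) | df$method == "ivw", ]
  cat("Screen report:", length(x), "taxon-outcome pair(s)\n")
  cat("  suggestive (IVW p < 0.05):", sum(ivw_rows$suggestive), "\n")
  cat("  status:", paste(names(table(ivw_rows$status)),
                         table(ivw_rows$status), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}
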