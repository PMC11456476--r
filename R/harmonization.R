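# Harmonization of exposure and outcome summary statistics to a common
# effect allele, with palindromes dropped outright and optional strand
# flipping for unambiguous (non-palindromic) complement matches.

.complement_allele <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on snp_id and aligns the outcome effect to
#' the exposure's effect allele. Identical allele pairs are kept as-is;
#' swapped pairs (effect/other exchanged) have the outcome beta negated
#' and eaf complemented; strand-complementary pairs are complemented
#' first (when \code{strand_flip} is TRUE) and then resolved the same
#' way; anything else is dropped as an allele mismatch. Palindromic
#' SNPs reaching this stage are dropped outright (their strand is
#' unresolvable from alleles).
#'
#' @param exposure An \code{instrument_set} or summary-statistics data
#'   frame for the exposure.
#' @param outcome Summary-statistics data frame for the outcome.
#' @param strand_flip Attempt strand-complement matching for
#'   non-palindromic SNPs (default TRUE); when FALSE such pairs are
#'   dropped as mismatches.
#' @param exclude_palindromic Safety-net palindrome drop (default TRUE).
#' @return Object of class \code{harmonized_set}: list with \code{data}
#'   (snp_id, beta_x, se_x, beta_y, se_y, flipped) and \code{dropped}
#'   (snp_id, reason).
#' @export
harmonize <- function(exposure, outcome, strand_flip = TRUE,
                      exclude_palindromic = TRUE) {
  exp_df <- if (inherits(exposure, "instrument_set")) exposure$records else exposure
  exp_df <- validate_sumstats(exp_df, warn = FALSE)
  out_df <- validate_sumstats(outcome, warn = FALSE)
  if (anyDuplicated(exp_df$snp_id)) {
    stop("duplicate snp_id in exposure: ",
         exp_df$snp_id[duplicated(exp_df$snp_id)][1], call. = FALSE)
  }
  if (anyDuplicated(out_df$snp_id)) {
    stop("duplicate snp_id in outcome: ",
         out_df$snp_id[duplicated(out_df$snp_id)][1], call. = FALSE)
  }
  shared <- intersect(exp_df$snp_id, out_df$snp_id)
  exp_df <- exp_df[match(shared, exp_df$snp_id), , drop = FALSE]
  out_df <- out_df[match(shared, out_df$snp_id), , drop = FALSE]

  n <- length(shared)
  keep <- logical(n)
  flipped <- logical(n)
  beta_y <- out_df$beta
  reason <- character(n)

  for (i in seq_len(n)) {
    ea_x <- exp_df$effect_allele[i]; oa_x <- exp_df$other_allele[i]
    ea_y <- out_df$effect_allele[i]; oa_y <- out_df$other_allele[i]
    if (exclude_palindromic && is_palindromic(ea_x, oa_x)) {
      reason[i] <- "palindromic"
      next
    }
    direct <- ea_y == ea_x && oa_y == oa_x
    swapped <- ea_y == oa_x && oa_y == ea_x
    if (!direct && !swapped && strand_flip &&
        nchar(ea_y) == 1 && nchar(oa_y) == 1) {
      ea_y <- .complement_allele(ea_y)
      oa_y <- .complement_allele(oa_y)
      direct <- ea_y == ea_x && oa_y == oa_x
      swapped <- ea_y == oa_x && oa_y == ea_x
    }
    if (direct) {
      keep[i] <- TRUE
    } else if (swapped) {
      keep[i] <- TRUE
      flipped[i] <- TRUE
      beta_y[i] <- -beta_y[i]
    } else {
      reason[i] <- "allele_mismatch"
    }
  }

  data <- data.frame(
    snp_id = shared[keep],
    beta_x = exp_df$beta[keep], se_x = exp_df$se[keep],
    beta_y = beta_y[keep], se_y = out_df$se[keep],
    flipped = flipped[keep], stringsAsFactors = FALSE
  )
  rownames(data) <- NULL
  dropped <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  structure(list(data = data, dropped = dropped),
            class = "harmonized_set")
}

#' Construct a harmonized set directly from aligned vectors
#'
#' Convenience constructor for already-aligned effect pairs (used by
#' the estimators' tests and by resampling procedures).
#'
#' @param beta_x,se_x Exposure effects and SEs.
#' @param beta_y,se_y Outcome effects (log-odds) and SEs.
#' @param snp_id Optional identifiers.
#' @return A \code{harmonized_set}.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y, snp_id = NULL) {
  j <- length(beta_x)
  stopifnot(length(se_x) == j, length(beta_y) == j, length(se_y) == j,
            all(se_x > 0), all(se_y > 0))
  if (is.null(snp_id)) snp_id <- sprintf("snp%04d", seq_len(j))
  structure(list(
    data = data.frame(snp_id = snp_id, beta_x = beta_x, se_x = se_x,
                      beta_y = beta_y, se_y = se_y, flipped = logical(j),
                      stringsAsFactors = FALSE),
    dropped = data.frame(snp_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  ), class = "harmonized_set")
}

#' Orient a harmonized set to positive exposure effects
#'
#' For every SNP with a negative exposure beta, negates both betas.
#' Wald ratios are unchanged; orientation-invariant estimators (IVW,
#' median, mode, maximum likelihood) give identical results, while
#' MR-Egger regression requires this orientation.
#'
#' @param set A \code{harmonized_set}.
#' @return The oriented \code{harmonized_set}.
#' @export
orient_positive_exposure <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  neg <- set$data$beta_x < 0
  set$data$beta_x[neg] <- -set$data$beta_x[neg]
  set$data$beta_y[neg] <- -set$data$beta_y[neg]
  set
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set:", nrow(x$data), "SNP(s) retained,",
      nrow(x$dropped), "dropped\n")
  if (nrow(x$dropped) > 0) {
    print(table(x$dropped$reason))
  }
  invisible(x)
}
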