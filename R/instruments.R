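# Instrumental-variable selection: locus-wide significance threshold,
# greedy LD clumping, palindrome exclusion, weak-instrument (F) filter.

#' Instrument-selection configuration
#'
#' Defaults reproduce the standard microbiome-MR recipe: locus-wide
#' significance p < 1e-5, clumping at r-squared < 0.001 within a
#' +/- 10,000 kb window, palindromic SNPs excluded, and instruments with
#' F < 10 removed as weak.
#'
#' @param pval_threshold Significance threshold for instrument inclusion.
#' @param clump_r2 r-squared threshold for LD clumping.
#' @param clump_window_kb Clumping window half-width in kilobases.
#' @param f_min Minimum F-statistic retained.
#' @param exclude_palindromic Drop A/T and C/G SNPs.
#' @return Object of class \code{instrument_config}.
#' @export
instrument_config <- function(pval_threshold = 1e-5, clump_r2 = 0.001,
                              clump_window_kb = 10000L, f_min = 10,
                              exclude_palindromic = TRUE) {
  stopifnot(pval_threshold > 0, pval_threshold <= 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0, f_min >= 0)
  structure(list(pval_threshold = pval_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 exclude_palindromic = exclude_palindromic),
            class = "instrument_config")
}

#' Instrument strength F-statistic
#'
#' F = (beta / se)^2, the squared Wald statistic of the
#' variant-exposure association; F < 10 conventionally marks a weak
#' instrument.
#'
#' @param beta Effect estimate.
#' @param se Standard error, > 0.
#' @return Non-negative F value (vectorized).
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  (beta / se)^2
}

#' Is an allele pair palindromic?
#'
#' TRUE iff the pair is A/T or C/G (either order), whose strand cannot
#' be resolved from alleles alone. Multi-base alleles are never
#' palindromic.
#'
#' @param effect_allele,other_allele Uppercase allele strings.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  if (length(effect_allele) == 0) return(logical(0))
  pair <- paste0(effect_allele, "/", other_allele)
  pair %in% c("A/T", "T/A", "C/G", "G/C")
}

.ld_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0) return(new.env(parent = emptyenv()))
  if (any(ld$r2 < 0)) stop("negative r2 in LD table", call. = FALSE)
  env <- new.env(parent = emptyenv(), size = nrow(ld) * 2L)
  key <- ifelse(ld$snp_a <= ld$snp_b,
                paste0(ld$snp_a, "\r", ld$snp_b),
                paste0(ld$snp_b, "\r", ld$snp_a))
  for (i in seq_along(key)) assign(key[i], ld$r2[i], envir = env)
  env
}

.ld_r2 <- function(env, a, b) {
  if (a == b) return(1)
  key <- if (a <= b) paste0(a, "\r", b) else paste0(b, "\r", a)
  val <- get0(key, envir = env, ifnotfound = 0)
  val
}

#' Greedy LD clumping of summary statistics
#'
#' Processes records in ascending p-value order (ties: ascending
#' position, then snp_id) and retains a record iff its r-squared with
#' every already-retained record on the same chromosome within
#' +/- window_kb is below the threshold. SNP pairs absent from the LD
#' table are treated as unlinked; SNPs absent entirely trigger a single
#' warning.
#'
#' @param records Summary-statistics data frame.
#' @param ld LD table (snp_a, snp_b, r2) or NULL.
#' @param r2_threshold Retention threshold on r-squared.
#' @param window_kb Window half-width in kilobases.
#' @return The retained rows, in the processing order.
#' @export
greedy_clump <- function(records, ld, r2_threshold = 0.001,
                         window_kb = 10000L) {
  if (nrow(records) == 0) return(records)
  env <- .ld_lookup(ld)
  if (!is.null(ld) && nrow(ld) > 0) {
    known <- unique(c(ld$snp_a, ld$snp_b))
    absent <- setdiff(records$snp_id, known)
    if (length(absent) > 0) {
      warning(length(absent), " SNP(s) absent from the LD table; ",
              "treated as unlinked", call. = FALSE)
    }
  }
  ord <- order(records$pval, records$pos, records$snp_id)
  records <- records[ord, , drop = FALSE]
  window_bp <- as.numeric(window_kb) * 1000
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    ok <- TRUE
    for (k in which(keep)) {
      if (records$chrom[k] != records$chrom[i]) next
      if (abs(records$pos[k] - records$pos[i]) > window_bp) next
      if (.ld_r2(env, records$snp_id[i], records$snp_id[k]) >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select instrumental variables
#'
#' Applies, in order: significance threshold, greedy LD clumping,
#' palindrome exclusion (if enabled), and the F >= f_min strength
#' filter, recording per-stage attrition counts.
#'
#' @param records Exposure summary-statistics data frame.
#' @param ld LD table or NULL.
#' @param config An \code{\link{instrument_config}}.
#' @return Object of class \code{instrument_set}: list with
#'   \code{records}, \code{F} (aligned F-statistics) and
#'   \code{provenance} (named stage counts).
#' @export
select_instruments <- function(records, ld = NULL,
                               config = instrument_config()) {
  stopifnot(inherits(config, "instrument_config"))
  records <- validate_sumstats(records, warn = FALSE)
  prov <- c(input = nrow(records))

  records <- records[records$pval < config$pval_threshold, , drop = FALSE]
  prov["after_threshold"] <- nrow(records)

  records <- greedy_clump(records, ld, config$clump_r2,
                          config$clump_window_kb)
  prov["after_clump"] <- nrow(records)

  if (config$exclude_palindromic) {
    pal <- is_palindromic(records$effect_allele, records$other_allele)
    records <- records[!pal, , drop = FALSE]
  }
  prov["after_palindrome"] <- nrow(records)

  f <- if (nrow(records) > 0) f_statistic(records$beta, records$se) else numeric(0)
  keepf <- f >= config$f_min
  records <- records[keepf, , drop = FALSE]
  f <- f[keepf]
  prov["after_f"] <- nrow(records)
  rownames(records) <- NULL

  if (nrow(records) == 0) {
    warning("no SNPs survive instrument selection", call. = FALSE)
  }
  structure(list(records = records, F = f, provenance = prov,
                 config = config),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", nrow(x$records), "SNP(s)\n")
  cat("Attrition:", paste(names(x$provenance), x$provenance,
                          sep = "=", collapse = " -> "), "\n")
  invisible(x)
}
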