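# Readers and writers for GWAS summary statistics, LD tables, gene
# intervals (BED or 1-based) and GMT gene sets. All internal coordinates
# are 1-based inclusive; BED is converted at the boundary.

.SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pval", "n")

#' Validate a summary-statistics data frame
#'
#' Enforces the per-record contract: positive SE, p in (0, 1], distinct
#' uppercase alleles over A/C/G/T (multi-base alleles accepted but
#' flagged), position >= 1. Invalid rows are dropped with a row-numbered
#' warning; alleles are uppercased.
#'
#' @param df Data frame with the standard summary-statistic columns.
#' @param warn Emit a warning naming rejected rows.
#' @return The validated data frame (possibly fewer rows).
#' @export
validate_sumstats <- function(df, warn = TRUE) {
  missing_cols <- setdiff(setdiff(.SUMSTATS_COLS, c("eaf", "n")), names(df))
  if (length(missing_cols) > 0) {
    stop("summary-statistics table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("eaf" %in% names(df))) df$eaf <- NA_real_
  if (!("n" %in% names(df))) df$n <- NA_integer_
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$pos <- as.integer(df$pos)
  ok <- !is.na(df$beta) & !is.na(df$se) & df$se > 0 &
    !is.na(df$pval) & df$pval > 0 & df$pval <= 1 &
    !is.na(df$pos) & df$pos >= 1 &
    nzchar(df$effect_allele) & nzchar(df$other_allele) &
    df$effect_allele != df$other_allele &
    grepl("^[ACGT]+$", df$effect_allele) &
    grepl("^[ACGT]+$", df$other_allele) &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1))
  if (any(!ok) && warn) {
    warning(sum(!ok), " row(s) rejected during validation (rows ",
            paste(utils::head(which(!ok), 10), collapse = ", "), ")",
            call. = FALSE)
  }
  multi <- nchar(df$effect_allele) > 1 | nchar(df$other_allele) > 1
  if (any(multi[ok]) && warn) {
    warning(sum(multi[ok]), " record(s) carry multi-base alleles ",
            "(accepted; never treated as palindromic)", call. = FALSE)
  }
  out <- df[ok, .SUMSTATS_COLS, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' @param path File path; tab- or comma-delimited with a header row.
#' @param column_map Named character vector mapping the standard roles
#'   (snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#'   pval, n) to column names in the file. Roles absent from the map are
#'   assumed to use the standard names; eaf and n are optional.
#' @param na Missing-value token, default "NA".
#' @return Validated summary-statistics data frame.
#' @export
read_sumstats <- function(path, column_map = character(0), na = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (nrow(df) == 0 && ncol(df) == 0) {
    stop("empty summary-statistics file: ", path, call. = FALSE)
  }
  for (role in names(column_map)) {
    src <- column_map[[role]]
    if (!(src %in% names(df))) {
      stop("mapped column '", src, "' (role ", role, ") absent from ",
           path, call. = FALSE)
    }
    names(df)[names(df) == src] <- role
  }
  need <- setdiff(setdiff(.SUMSTATS_COLS, c("eaf", "n")), names(df))
  if (length(need) > 0) {
    stop("summary-statistics file lacks column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  validate_sumstats(df)
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Write GWAS summary statistics to tab-delimited text
#'
#' Round-trip safe: \code{read_sumstats(write_sumstats(x))} returns
#' \code{x} field-for-field. Missing eaf/n written as "NA".
#'
#' @param records Validated summary-statistics data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sumstats <- function(records, path) {
  records <- validate_sumstats(records, warn = FALSE)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene intervals (BED or 1-based dialect)
#'
#' BED input (0-based half-open) is converted to the internal 1-based
#' inclusive convention: start + 1, end unchanged. Columns: chrom,
#' start, end, gene_id, no header.
#'
#' @param path File path.
#' @param dialect "bed" (0-based half-open) or "one_based" (1-based
#'   inclusive).
#' @return Data frame with gene_id, chrom, start, end.
#' @export
read_gene_intervals <- function(path, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene interval file needs 4 columns", call. = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (dialect == "bed") df$start <- df$start + 1L
  bad <- df$start > df$end
  if (any(bad)) {
    stop("interval with start > end after conversion at line(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  df[, c("gene_id", "chrom", "start", "end")]
}

#' Read a GMT gene-set file
#'
#' Standard GMT: set name, description, then member genes,
#' tab-separated. Duplicate members within a line are de-duplicated.
#'
#' @param path File path.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene-id character vectors.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format LD table
#'
#' Three delimited columns (snp_a, snp_b, r2). Pairs absent from the
#' table are treated as unlinked (r-squared 0) downstream.
#'
#' @param path File path.
#' @return Data frame snp_a, snp_b, r2.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- setdiff(c("snp_a", "snp_b", "r2"), names(df))
  if (length(need) > 0) {
    stop("LD table lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$r2 < 0, na.rm = TRUE)) {
    stop("negative r2 in LD table", call. = FALSE)
  }
  df[, c("snp_a", "snp_b", "r2")]
}

#' Write a long-format LD table
#' @param ld Data frame snp_a, snp_b, r2.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ld_table <- function(ld, path) {
  utils::write.table(ld[, c("snp_a", "snp_b", "r2")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
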