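# Nearest-gene assignment of causal SNPs and hypergeometric
# over-representation analysis against user-supplied gene sets.

#' Nearest gene to a SNP position
#'
#' A SNP inside an interval maps to that gene (distance 0); otherwise
#' to the gene on the same chromosome minimizing the distance to the
#' nearer interval boundary. Ties break by smaller start, then
#' lexicographic gene_id. No interval on the SNP's chromosome gives an
#' NA assignment.
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param intervals Gene interval data frame (gene_id, chrom, start,
#'   end; 1-based inclusive).
#' @return List with gene_id (or NA) and distance (or NA).
#' @export
nearest_gene <- function(chrom, pos, intervals) {
  cand <- intervals[intervals$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(gene_id = NA_character_, distance = NA_real_))
  }
  inside <- pos >= cand$start & pos <= cand$end
  dist <- ifelse(inside, 0,
                 pmin(abs(pos - cand$start), abs(pos - cand$end)))
  ord <- order(dist, cand$start, cand$gene_id)
  best <- ord[1]
  list(gene_id = cand$gene_id[best], distance = dist[best])
}

#' Map a table of SNPs to their nearest genes
#'
#' @param snps Data frame with chrom and pos columns (snp_id optional).
#' @param intervals Gene interval data frame.
#' @return Data frame snp_id, chrom, pos, gene_id, distance; SNPs with
#'   no same-chromosome interval carry NA.
#' @export
nearest_genes <- function(snps, intervals) {
  res <- lapply(seq_len(nrow(snps)), function(i) {
    ng <- nearest_gene(snps$chrom[i], snps$pos[i], intervals)
    data.frame(
      snp_id = if ("snp_id" %in% names(snps)) snps$snp_id[i] else
        sprintf("snp%04d", i),
      chrom = snps$chrom[i], pos = snps$pos[i],
      gene_id = ng$gene_id, distance = ng$distance,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order.
#'
#' @param pvals p-values in (0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability
#' P(X >= k) of observing k query genes in the set, with population the
#' gene universe; Benjamini-Hochberg adjustment across sets. Query
#' genes outside the universe are dropped with a warning, and each set
#' is intersected with the universe.
#'
#' @param query Character vector of query gene ids.
#' @param sets Named list of gene-id character vectors.
#' @param universe Character vector of universe gene ids.
#' @return Data frame set_name, overlap, set_size, query_size,
#'   universe_size, pval, fdr_q, sorted by pval.
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("empty query after universe restriction",
                               call. = FALSE)
  n_univ <- length(universe)
  n_query <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(query, s))
    bigk <- length(s)
    # P(X >= k) for X ~ Hypergeom(N = n_univ, K = bigk, n = n_query)
    p <- stats::phyper(k - 1, bigk, n_univ - bigk, n_query,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = bigk,
               query_size = n_query, universe_size = n_univ,
               pval = min(1, max(p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_q <- bh_adjust(out$pval)
  out <- out[order(out$pval, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
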