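#' Isoform-switch score of a gene
#'
#' Quantifies how much of a gene's expression variance lives at the level
#' of transcript-isoform switching rather than overall gene-level change:
#' the mean, over the gene's isoforms, of the across-sample variance of the
#' residual `log2(isoform + 1) - log2(gene + 1)`.  Genes whose isoforms
#' track the gene total proportionally score ~0; genes with see-sawing
#' short/long usage score high.
#'
#' @param iso_expr isoform-level `expr_matrix` (normalized counts).
#' @param gene_expr gene-level `expr_matrix` on the same samples.
#' @param gene gene id.
#' @return non-negative score, or `NA` for genes with < 2 isoforms.
#' @export
switch_score <- function(iso_expr, gene_expr, gene) {
  feats <- em_gene_features(iso_expr, gene)
  if (length(feats) < 2) return(NA_real_)
  g <- log2p1(gene_expr$values[, gene])
  res <- log2p1(iso_expr$values[, feats, drop = FALSE]) - g
  mean(apply(res, 2, stats::var))
}

#' Call alternatively-transcribed (AT) genes and their short/long clusters
#'
#' AT genes are genes whose switch score exceeds the given quantile of all
#' scorable genes AND whose isoforms split into two anti-correlated
#' clusters (bimodal usage).  Clustering is average-linkage on
#' `1 - Pearson r` of `log2(x+1)` isoform profiles, cut into 2 groups; the
#' call requires a negative mean between-cluster correlation.  Correlations
#' are computed on the usage residual `log2(isoform+1) - log2(gene+1)`, so
#' overall gene-level expression variation cancels and the see-saw of
#' mutually exclusive short/long usage is what drives the split.  The cluster
#' with the smaller mean transcript length is labeled `short`.
#'
#' @param iso_expr isoform-level `expr_matrix`.
#' @param gene_expr gene-level `expr_matrix` sharing samples with `iso_expr`.
#' @param isoform_lengths named numeric vector of transcript lengths (bp)
#'   for every isoform feature.
#' @param quantile score quantile above which genes are AT candidates
#'   (default 0.90).
#' @return data.frame with one row per scorable gene: `gene_id`,
#'   `switch_score`, `is_AT`, `short_cluster`, `long_cluster`
#'   (comma-joined isoform ids; empty when not AT).
#' @export
call_at_genes <- function(iso_expr, gene_expr, isoform_lengths,
                          quantile = 0.90) {
  stopifnot(identical(em_samples(iso_expr), em_samples(gene_expr)))
  genes <- intersect(unique(iso_expr$feature_gene), em_features(gene_expr))
  scores <- vapply(genes, function(g) switch_score(iso_expr, gene_expr, g),
                   numeric(1))
  keep <- !is.na(scores)
  cutoff <- stats::quantile(scores[keep], quantile, names = FALSE)
  out <- data.frame(gene_id = genes, switch_score = scores,
                    is_AT = FALSE, short_cluster = "", long_cluster = "",
                    stringsAsFactors = FALSE)
  for (i in which(keep & scores > cutoff)) {
    cl <- .split_isoform_clusters(iso_expr, gene_expr, genes[i],
                                  isoform_lengths)
    if (is.null(cl)) next
    out$is_AT[i] <- TRUE
    out$short_cluster[i] <- paste(cl$short, collapse = ",")
    out$long_cluster[i] <- paste(cl$long, collapse = ",")
  }
  out
}

# 2-cluster average-linkage split on (1 - Pearson r) of usage residuals
# (log2 isoform - log2 gene, so gene-level co-variation cancels); NULL when
# the split is not anti-correlated (no bimodal pattern) or correlations are
# degenerate.
.split_isoform_clusters <- function(iso_expr, gene_expr, gene, isoform_lengths) {
  feats <- em_gene_features(iso_expr, gene)
  x <- log2p1(iso_expr$values[, feats, drop = FALSE]) -
    log2p1(gene_expr$values[, gene])
  cm <- suppressWarnings(stats::cor(x, method = "pearson"))
  if (anyNA(cm)) return(NULL)
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  grp <- stats::cutree(hc, k = 2)
  c1 <- feats[grp == 1]; c2 <- feats[grp == 2]
  if (mean(cm[c1, c2]) >= 0) return(NULL)
  m1 <- mean(isoform_lengths[c1]); m2 <- mean(isoform_lengths[c2])
  if (m1 <= m2) list(short = c1, long = c2) else list(short = c2, long = c1)
}

#' Parse comma-joined cluster columns of an AT-gene call table
#' @param at_calls data.frame from [call_at_genes()].
#' @return list with character vectors `short` and `long` pooled over all
#'   AT genes.
#' @export
at_cluster_isoforms <- function(at_calls) {
  at <- at_calls[at_calls$is_AT, , drop = FALSE]
  split_ids <- function(x) unlist(strsplit(x[nzchar(x)], ","), use.names = FALSE)
  list(short = split_ids(at$short_cluster), long = split_ids(at$long_cluster))
}
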