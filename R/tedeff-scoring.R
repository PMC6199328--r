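#' Per-sample TEdeff score
#'
#' The TEdeff (transcript-shortening) score of a sample is the log2 ratio
#' of the average expression of short-cluster isoforms of AT genes to the
#' average expression of long-cluster isoforms, with a pseudocount of 1:
#' `log2((mean(short) + 1) / (mean(long) + 1))`.  By default the average
#' pools all short (resp. long) isoform x sample cells across AT genes;
#' `per_gene = TRUE` instead averages the per-gene log ratios.
#'
#' @param iso_expr isoform-level `expr_matrix` (normalized counts).
#' @param at_calls AT-gene call table from [call_at_genes()].
#' @param samples sample ids to score (default all).
#' @param per_gene average within genes before pooling (default `FALSE`).
#' @return named numeric vector of scores.
#' @export
tedeff_score <- function(iso_expr, at_calls, samples = em_samples(iso_expr),
                         per_gene = FALSE) {
  cl <- at_cluster_isoforms(at_calls)
  if (!length(cl$short) || !length(cl$long))
    stop("no AT genes callable")
  v <- iso_expr$values
  if (!per_gene) {
    s <- rowMeans(v[samples, cl$short, drop = FALSE])
    l <- rowMeans(v[samples, cl$long, drop = FALSE])
    return(log2((s + 1) / (l + 1)))
  }
  at <- at_calls[at_calls$is_AT, , drop = FALSE]
  per <- vapply(seq_len(nrow(at)), function(i) {
    sh <- strsplit(at$short_cluster[i], ",")[[1]]
    lo <- strsplit(at$long_cluster[i], ",")[[1]]
    log2((rowMeans(v[samples, sh, drop = FALSE]) + 1) /
         (rowMeans(v[samples, lo, drop = FALSE]) + 1))
  }, numeric(length(samples)))
  per <- matrix(per, nrow = length(samples))
  stats::setNames(rowMeans(per), samples)
}

#' Classify TEdeff status from a score
#'
#' Samples with score strictly above the cutoff are TEdeff; a score exactly
#' at the cutoff is TEprof (the cutoff is strict).
#'
#' @param score numeric score(s).
#' @param cutoff log2-ratio cutoff (default -1).
#' @return character vector `"TEdeff"`/`"TEprof"` (`NA` for `NA` scores).
#' @export
classify_tedeff <- function(score, cutoff = -1) {
  ifelse(is.na(score), NA_character_,
         ifelse(score > cutoff, "TEdeff", "TEprof"))
}

#' TEdeff transcriptomic signature
#'
#' Per-gene Welch t-statistic of the TEdeff vs TEprof gene-level expression
#' difference on `log2(x+1)` values (TEdeff minus TEprof orientation).
#'
#' @param gene_expr gene-level `expr_matrix`.
#' @param labels named character vector (`"TEdeff"`/`"TEprof"`) over the
#'   matrix samples; each group needs >= 2 samples.
#' @return named numeric vector of t-statistics (one per gene).
#' @export
tedeff_signature <- function(gene_expr, labels) {
  labels <- labels[em_samples(gene_expr)]
  a <- which(labels == "TEdeff"); b <- which(labels == "TEprof")
  if (length(a) < 2 || length(b) < 2)
    stop("tedeff_signature: each group needs >= 2 samples")
  res <- welch_t(log2p1(gene_expr$values), a, b)
  stats::setNames(res$t, rownames(res))
}

#' Correlate a sample profile with the TEdeff signature
#'
#' Spearman rank correlation (with two-sided p) over the gene intersection
#' of a z-normalized per-gene sample profile and a TEdeff signature.
#'
#' @param sample_profile named numeric vector (per-gene values).
#' @param sig named numeric vector from [tedeff_signature()].
#' @return list with `rho`, `p`, `n_genes`.
#' @export
signature_correlation <- function(sample_profile, sig) {
  genes <- intersect(names(sample_profile), names(sig))
  if (length(genes) < 10) stop("signature_correlation: < 10 shared genes")
  x <- sample_profile[genes]; y <- sig[genes]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n_genes = length(genes)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_genes = length(genes))
}
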