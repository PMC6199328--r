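#' Expression matrix container
#'
#' Samples x features matrix of non-negative normalized counts (or RPKM),
#' with a feature-to-gene map and optional per-feature metadata (used for
#' exon matrices, which carry a transcription-order `exon_index`).
#'
#' @param values numeric matrix, rows = samples, columns = features; both
#'   dimnames required, no duplicated ids, all values >= 0.
#' @param feature_gene named character vector mapping feature id -> gene id;
#'   defaults to the identity map (gene-level matrix).
#' @param feature_meta optional data.frame keyed by `feature_id`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, feature_gene = NULL, feature_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || (ncol(values) > 0 && is.null(colnames(values))))
    stop("expr_matrix: sample and feature ids required as dimnames")
  if (ncol(values) == 0) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("expr_matrix: duplicate ids")
  if (any(values < 0, na.rm = TRUE)) stop("expr_matrix: negative values")
  if (is.null(feature_gene))
    feature_gene <- stats::setNames(colnames(values), colnames(values))
  if (!all(colnames(values) %in% names(feature_gene)))
    stop("expr_matrix: every feature must map to a gene")
  structure(list(values = values,
                 feature_gene = feature_gene[colnames(values)],
                 feature_meta = feature_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d features (%d genes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$feature_gene))))
  invisible(x)
}

#' Sample ids of an expression matrix
#' @param x an `expr_matrix`.
#' @export
em_samples <- function(x) rownames(x$values)

#' Feature ids of an expression matrix
#' @param x an `expr_matrix`.
#' @export
em_features <- function(x) colnames(x$values)

#' Features belonging to one gene
#' @param x an `expr_matrix`.
#' @param gene gene id.
#' @export
em_gene_features <- function(x, gene) {
  names(x$feature_gene)[x$feature_gene == gene]
}

#' Write an expression matrix as TSV (features as rows)
#'
#' Layout: `feature_id`, `gene_id`, then one column per sample.  Exon
#' matrices additionally carry an `exon_index` column.
#'
#' @param x an `expr_matrix`.
#' @param path output file.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(feature_id = em_features(x),
                   gene_id = unname(x$feature_gene),
                   stringsAsFactors = FALSE)
  if (!is.null(x$feature_meta) && "exon_index" %in% names(x$feature_meta))
    df$exon_index <- x$feature_meta$exon_index[
      match(df$feature_id, x$feature_meta$feature_id)]
  df <- cbind(df, as.data.frame(t(x$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV written by [write_expression_tsv()]
#' @param path TSV file.
#' @return an `expr_matrix`.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("feature_id", "gene_id", "exon_index"), names(df))
  vals <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(vals) <- df$feature_id
  fm <- NULL
  if ("exon_index" %in% meta_cols)
    fm <- data.frame(feature_id = df$feature_id, exon_index = df$exon_index,
                     stringsAsFactors = FALSE)
  expr_matrix(vals, stats::setNames(df$gene_id, df$feature_id), fm)
}

#' Vectorized Welch two-sample t-statistic over features
#'
#' Computes, for every column of `values`, the unequal-variance t-statistic
#' of `group a - group b` (a row-wise analogue of `t.test(..., var.equal =
#' FALSE)`).  Columns with zero variance in both groups get t = 0 and are
#' flagged.
#'
#' @param values samples x features numeric matrix.
#' @param a,b logical or index vectors selecting the two sample groups
#'   (each needs >= 2 samples).
#' @return data.frame with `t`, `df`, `p`, `zero_var`.
#' @export
welch_t <- function(values, a, b) {
  xa <- values[a, , drop = FALSE]; xb <- values[b, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2 || nb < 2) stop("welch_t: each group needs >= 2 samples")
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(sweep(xa, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(xb, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  zero <- se2 == 0
  t <- ifelse(zero, 0, (ma - mb) / sqrt(se2))
  df <- ifelse(zero, NA_real_,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)))
  p <- ifelse(zero, NA_real_, 2 * stats::pt(-abs(t), df))
  data.frame(t = t, df = df, p = p, zero_var = zero,
             row.names = colnames(values))
}

# log2 with the package-wide pseudocount of 1
log2p1 <- function(x) log2(x + 1)
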