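#' Expressed-gene filter
#'
#' Keeps genes whose 90th-percentile normalized count across samples is
#' strictly greater than the threshold (linear-interpolation percentile,
#' `stats::quantile` type 7).
#'
#' @param gene_expr gene-level `expr_matrix`.
#' @param threshold count threshold (default 30).
#' @param prob percentile (default 0.9).
#' @return character vector of gene ids.
#' @export
expressed_filter <- function(gene_expr, threshold = 30, prob = 0.9) {
  v <- gene_expr$values
  if (!ncol(v)) return(character(0))
  q <- apply(v, 2, stats::quantile, probs = prob, names = FALSE)
  colnames(v)[q > threshold]
}

#' Per-exon differential t-statistics
#'
#' Welch t of TEdeff minus TEprof per exon feature (RPKM).  Exons with zero
#' variance in both groups get t = 0 and are flagged.  For cell-line data
#' the emitted statistic can be switched to signed `-log10 p`.
#'
#' @param exon_expr exon-level `expr_matrix`; `feature_meta` must carry
#'   `exon_index` (transcription order, 1 = 5'-most).
#' @param labels named `"TEdeff"`/`"TEprof"` vector over samples.
#' @param stat `"t"` (default) or `"neglog10p"` (signed `-log10 p`).
#' @return data.frame: `feature_id`, `gene_id`, `exon_index`, `stat`,
#'   `zero_var`.
#' @export
exon_t_stats <- function(exon_expr, labels, stat = c("t", "neglog10p")) {
  stat <- match.arg(stat)
  labels <- labels[em_samples(exon_expr)]
  a <- which(labels == "TEdeff"); b <- which(labels == "TEprof")
  res <- welch_t(exon_expr$values, a, b)
  idx <- exon_expr$feature_meta$exon_index[
    match(em_features(exon_expr), exon_expr$feature_meta$feature_id)]
  s <- if (stat == "t") res$t else {
    ifelse(res$zero_var, 0, sign(res$t) * -log10(pmax(res$p, 1e-300)))
  }
  data.frame(feature_id = em_features(exon_expr),
             gene_id = unname(exon_expr$feature_gene),
             exon_index = idx, stat = s, zero_var = res$zero_var,
             stringsAsFactors = FALSE)
}

#' Map a per-exon vector onto 20 positional bins
#'
#' Exon i of n has fractional position `(i - 0.5) / n` along the 5'->3'
#' axis.  Genes with >= 20 exons are compressed: bin j is the mean of exons
#' whose position falls in `((j-1)/20, j/20]`.  Genes with < 20 exons are
#' stretched: each bin takes the exon whose position is nearest the bin
#' center, so every bin is filled.  A 20-exon gene maps to itself.
#'
#' @param values per-exon numeric vector in 5'->3' order.
#' @param n_bins number of bins (default 20).
#' @return numeric vector of length `n_bins`.
#' @export
bin20 <- function(values, n_bins = 20) {
  n <- length(values)
  if (n == 0) stop("bin20: empty exon vector")
  pos <- (seq_len(n) - 0.5) / n
  if (n >= n_bins) {
    bin <- ceiling(pos * n_bins)
    as.numeric(tapply(values, factor(bin, levels = seq_len(n_bins)), mean))
  } else {
    centers <- (seq_len(n_bins) - 0.5) / n_bins
    idx <- vapply(centers, function(cc) which.min(abs(pos - cc)), integer(1))
    values[idx]
  }
}

#' Build 20-bin exon profiles for a set of genes
#'
#' @param tstats data.frame from [exon_t_stats()].
#' @param genes gene ids to profile (default all in `tstats`).
#' @return data.frame with `gene_id`, `bin01`..`bin20`, `body_mean_t`
#'   (bins 2-17), `terminal_t` (bin 20), `overall_mean_t`.
#' @export
exon_bin_profiles <- function(tstats, genes = unique(tstats$gene_id)) {
  rows <- lapply(genes, function(g) {
    d <- tstats[tstats$gene_id == g, , drop = FALSE]
    d <- d[order(d$exon_index), , drop = FALSE]
    bin20(d$stat)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("bin%02d", 1:20)
  data.frame(gene_id = genes, m,
             body_mean_t = rowMeans(m[, 2:17, drop = FALSE]),
             terminal_t = m[, 20],
             overall_mean_t = rowMeans(m),
             stringsAsFactors = FALSE)
}

#' Call Class I / Class II genes from exon-bin profiles
#'
#' Class I: gene-body loss plus 3'-terminal gain in TEdeff samples
#' (`body_mean_t <= -t0` and `terminal_t >= +t0`).  Class II: broadly
#' overexpressed (`overall_mean_t >= +t0`) and not Class I.  Everything
#' else is neutral.  The thresholds are package conventions (the class
#' structure is visual in origin) and are exposed as arguments.
#'
#' @param profiles data.frame from [exon_bin_profiles()].
#' @param t0 t-statistic threshold (default 2).
#' @return input with a `gene_class` column (`"I"`, `"II"`, `"neutral"`).
#' @export
call_gene_classes <- function(profiles, t0 = 2) {
  cls <- ifelse(profiles$body_mean_t <= -t0 & profiles$terminal_t >= t0, "I",
         ifelse(profiles$overall_mean_t >= t0, "II", "neutral"))
  profiles$gene_class <- cls
  profiles
}

#' Structural contrast of Class I vs Class II genes
#'
#' Two-sample t-tests of log10 genomic length and of exon density (full
#' mRNA length / genomic length) between the two classes.
#'
#' @param classes data.frame with `gene_id`, `gene_class`.
#' @param models named list of `gene_model` objects.
#' @return list with per-class summaries and the two t-tests.
#' @export
class_feature_contrast <- function(classes, models) {
  g1 <- classes$gene_id[classes$gene_class == "I"]
  g2 <- classes$gene_id[classes$gene_class == "II"]
  if (!length(g1) || !length(g2))
    return(list(length_test = NA, density_test = NA,
                summary = data.frame()))
  feat <- function(gs) {
    len <- vapply(models[gs], `[[`, 0, "genomic_length")
    mrna <- vapply(models[gs], `[[`, 0, "mrna_length")
    data.frame(gene_id = gs, genomic_length = len, density = mrna / len)
  }
  f1 <- feat(g1); f2 <- feat(g2)
  list(
    length_test = stats::t.test(log10(f1$genomic_length),
                                log10(f2$genomic_length)),
    density_test = stats::t.test(f1$density, f2$density),
    summary = data.frame(
      gene_class = c("I", "II"),
      n = c(nrow(f1), nrow(f2)),
      median_length = c(stats::median(f1$genomic_length),
                        stats::median(f2$genomic_length)),
      median_density = c(stats::median(f1$density),
                         stats::median(f2$density))))
}

#' Methylation meta-profile of TEdeff vs TEprof
#'
#' Probes are expected on a transcript-relative coordinate: `[-1, 0)` =
#' upstream flank, `[0, 1]` = gene body scaled to unit length (0 = TSS,
#' 1 = TTS), `(1, 2]` = downstream flank.  Within each positional bin,
#' per-sample mean beta values are compared by Welch t (TEdeff minus
#' TEprof).  Bins with fewer than 3 probes are `NA`.
#'
#' @param beta probes x samples matrix of beta values.
#' @param positions numeric vector of transcript-relative probe positions.
#' @param labels named `"TEdeff"`/`"TEprof"` vector over samples.
#' @param breaks bin boundaries (default 30 bins over `[-1, 2]`).
#' @return data.frame with `mid` (bin center), `t`, `n_probes`.
#' @export
methylation_metaprofile <- function(beta, positions, labels,
                                    breaks = seq(-1, 2, by = 0.1)) {
  stopifnot(nrow(beta) == length(positions))
  labels <- labels[colnames(beta)]
  a <- which(labels == "TEdeff"); b <- which(labels == "TEprof")
  if (length(a) < 2 || length(b) < 2)
    stop("methylation_metaprofile: each group needs >= 2 samples")
  bin <- cut(positions, breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(mid = mids, t = NA_real_,
                    n_probes = as.integer(table(bin)))
  for (i in seq_along(levels(bin))) {
    sel <- bin == levels(bin)[i]
    if (sum(sel, na.rm = TRUE) < 3) next
    samp_mean <- colMeans(beta[which(sel), , drop = FALSE])
    out$t[i] <- welch_t(matrix(samp_mean, ncol = 1,
                               dimnames = list(names(samp_mean), "b")),
                        a, b)$t
  }
  out
}
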