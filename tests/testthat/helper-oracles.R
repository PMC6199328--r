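# Independent brute-force oracles and small fixture builders shared across
# the suite.  The oracles deliberately use per-base / per-read enumeration,
# not the interval arithmetic of the implementation they check.

# --- per-read, per-base junction scanner -----------------------------------

# expand one CIGAR into per-base reference position sets
.oracle_read_bases <- function(cigar, start0) {
  ops <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  n <- as.numeric(substr(ops, 1, nchar(ops) - 1))
  op <- substr(ops, nchar(ops), nchar(ops))
  if (any(!op %in% c("M", "I", "D", "N", "S"))) return(NULL)
  aligned <- numeric(0); gap_runs <- list()
  ref <- start0
  for (i in seq_along(op)) {
    if (op[i] == "M") { aligned <- c(aligned, ref:(ref + n[i] - 1)); ref <- ref + n[i] }
    else if (op[i] == "D") ref <- ref + n[i]
    else if (op[i] == "N") { gap_runs[[length(gap_runs) + 1]] <- c(ref, ref + n[i]); ref <- ref + n[i] }
  }
  list(aligned = aligned, gap_runs = gap_runs, start = start0)
}

oracle_count_junctions <- function(sam_df, model, mapq_min = 20, anchor = 8,
                                   window = 150) {
  ex <- model$exons
  n_j <- nrow(ex) - 1
  out <- data.frame(gene_id = rep(model$gene_id, n_j),
                    donor = ex[-nrow(ex), 2], acceptor = ex[-1, 1],
                    ee = 0L, ei = 0L, ie = 0L)
  out$intron_length <- out$acceptor - out$donor
  r <- sam_df[sam_df$rname == model$chrom & sam_df$mapq > mapq_min, ,
              drop = FALSE]
  for (k in seq_len(nrow(r))) {
    rb <- .oracle_read_bases(r$cigar[k], r$pos[k] - 1)
    if (is.null(rb)) next
    for (j in seq_len(n_j)) {
      d <- out$donor[j]; a <- out$acceptor[j]
      gap_match <- any(vapply(rb$gap_runs, function(gr)
        gr[1] == d && gr[2] == a, logical(1)))
      if (gap_match &&
          sum(rb$aligned < d) >= anchor && sum(rb$aligned >= a) >= anchor)
        out$ee[j] <- out$ee[j] + 1L
      covers <- function(b) all((b - anchor):(b + anchor - 1) %in% rb$aligned)
      if (abs(rb$start - d) <= window && covers(d)) out$ei[j] <- out$ei[j] + 1L
      if (abs(rb$start - a) <= window && covers(a)) out$ie[j] <- out$ie[j] + 1L
    }
  }
  out
}

# --- per-base interval overlap marker --------------------------------------

oracle_observed_overlap <- function(regions, dataset) {
  hits <- logical(nrow(regions))
  for (ch in unique(regions$chrom)) {
    d <- dataset[dataset$chrom == ch, , drop = FALSE]
    marked <- logical(max(c(regions$end[regions$chrom == ch], d$end, 1)))
    for (i in seq_len(nrow(d)))
      if (d$end[i] > d$start[i])
        marked[(d$start[i] + 1):d$end[i]] <- TRUE
    sel <- which(regions$chrom == ch)
    for (i in sel)
      hits[i] <- any(marked[(regions$start[i] + 1):regions$end[i]])
  }
  if ("gene_id" %in% names(regions))
    sum(vapply(split(hits, regions$gene_id), any, logical(1)))
  else sum(hits)
}

# --- fixture builders -------------------------------------------------------

# two-exon plus-strand gene: exons [1000,1200) and [1800,2000)
toy_gene <- function(gene_id = "TG1", chrom = "chrT", strand = "+",
                     exons = cbind(c(1000, 1800), c(1200, 2000))) {
  gene_model(gene_id, chrom, strand, exons)
}

sam_record <- function(pos1, cigar, mapq = 60, rname = "chrT",
                       qname = "r1", flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos1,
             mapq = mapq, cigar = cigar, stringsAsFactors = FALSE)
}

# transcript lengths of every isoform in a cohort bundle
bundle_iso_lengths <- function(bundle) {
  isos <- unlist(lapply(bundle$models, function(g) g$isoforms),
                 recursive = FALSE)
  stats::setNames(vapply(isos, `[[`, 0, "transcript_length"),
                  vapply(isos, `[[`, "", "isoform_id"))
}

# small expression matrix from a samples x features value matrix
make_em <- function(values, feature_gene = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("F%02d", seq_len(ncol(values)))
  expr_matrix(values, feature_gene)
}

# background pool fixture for enrichment null calibration: n_bg promoters of
# identical length, a fixed fraction overlapping the peak set
null_enrichment_fixture <- function(n_bg = 2000, frac_overlap = 0.3) {
  s <- (seq_len(n_bg) - 1) * 4000
  ids <- sprintf("N%04d", seq_len(n_bg))
  models <- lapply(seq_len(n_bg), function(i)
    gene_model(ids[i], "chrN", "+", cbind(s[i] + 1000, s[i] + 1500)))
  names(models) <- ids
  k <- round(n_bg * frac_overlap)
  overlapping <- which(seq_len(n_bg) %% round(1 / frac_overlap) == 0)[seq_len(k)]
  peaks <- data.frame(chrom = "chrN", start = s[overlapping] + 400,
                      end = s[overlapping] + 600)
  list(models = models, gene_ids = ids, peaks = peaks)
}
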