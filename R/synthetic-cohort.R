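#' Synthetic-cohort configuration
#'
#' Parameters of the planted TEdeff structure.  Defaults are the package's
#' study conditions: 60 tumors of which 25% are TEdeff, a +2 log2 shift of
#' short/long isoform usage in TEdeff samples on a TEprof baseline of
#' -2.5 (so the two groups straddle the -1 score cutoff), long Class I
#' genes (50-200 kb) with gene-body exon loss and terminal-exon gain,
#' short Class II genes (2-10 kb) broadly overexpressed, group-dependent
#' intron-retention rates and RNAP II traveling ratios, and an exponential
#' survival model with a group hazard effect.
#'
#' @param n_samples number of tumor samples.
#' @param frac_tedeff fraction of TEdeff samples.
#' @param n_genes number of genes.
#' @param frac_at fraction of genes that are AT (short/long switching).
#' @param frac_class1,frac_class2 fractions of Class I / Class II genes.
#' @param class1_length_range,class2_length_range,neutral_length_range
#'   genomic-length ranges (bp) per class.
#' @param isoform_shift log2 shift of short/long usage in TEdeff samples.
#' @param baseline_log_ratio TEprof mean log2 short/long usage ratio.
#' @param body_loss multiplicative gene-body exon RPKM factor in TEdeff
#'   Class I genes.
#' @param terminal_gain multiplicative 3'-terminal-exon factor in TEdeff
#'   Class I genes.
#' @param class2_gain multiplicative factor on Class II genes in TEdeff.
#' @param retention_rate_tedeff,retention_rate_teprof per-junction rate of
#'   unspliced (EI/IE) reads relative to the spliced read rate.
#' @param tr_tedeff,tr_teprof target traveling ratios per group.
#' @param hazard_ratio TEdeff vs TEprof event hazard ratio.
#' @param dispersion negative-binomial dispersion of counts.
#' @param read_length synthetic read length (bp).
#' @param mean_ee_reads mean spliced reads per junction per sample.
#' @param seed RNG seed; identical seeds give byte-identical bundles.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 60, frac_tedeff = 0.25, n_genes = 120,
                          frac_at = 0.10, frac_class1 = 0.15,
                          frac_class2 = 0.15,
                          class1_length_range = c(5e4, 2e5),
                          class2_length_range = c(2e3, 1e4),
                          neutral_length_range = c(1e4, 5e4),
                          isoform_shift = 2, baseline_log_ratio = -2.5,
                          body_loss = 0.4, terminal_gain = 2.5,
                          class2_gain = 2,
                          retention_rate_tedeff = 0.15,
                          retention_rate_teprof = 0.02,
                          tr_tedeff = 0.2, tr_teprof = 0.8,
                          hazard_ratio = 3, dispersion = 0.2,
                          read_length = 50, mean_ee_reads = 12, seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_tedeff, frac_at, frac_class1, frac_class2,
          retention_rate_tedeff, retention_rate_teprof)
  if (any(fr < 0 | fr > 1)) stop("cohort_config: fractions/rates must be in [0,1]")
  if (n_genes < 1) stop("cohort_config: n_genes must be positive")
  if (n_samples * frac_tedeff < 1)
    stop("cohort_config: need at least one TEdeff sample")
  class(cfg) <- "cohort_config"
  cfg
}

# per-component reseeding keeps each component reproducible regardless of
# which other components are generated
.reseed <- function(cfg, k) set.seed((cfg$seed * 101 + k) %% .Machine$integer.max)

.gen_annotation <- function(cfg) {
  .reseed(cfg, 1)
  n <- cfg$n_genes
  n1 <- round(n * cfg$frac_class1); n2 <- round(n * cfg$frac_class2)
  cls <- sample(c(rep("I", n1), rep("II", n2), rep("neutral", n - n1 - n2)))
  gene_ids <- sprintf("G%03d", seq_len(n))
  neutral_idx <- which(cls == "neutral")
  n_at <- round(n * cfg$frac_at)
  at_idx <- sort(sample(neutral_idx, min(n_at, length(neutral_idx))))
  rng <- list(I = cfg$class1_length_range, II = cfg$class2_length_range,
              neutral = cfg$neutral_length_range)
  models <- vector("list", n)
  cursor <- 10000
  for (i in seq_len(n)) {
    L <- round(stats::runif(1, rng[[cls[i]]][1], rng[[cls[i]]][2]))
    n_ex <- max(4, min(15, round(L / 12000) + 3))
    ex_len <- round(stats::runif(n_ex, 100, 300))
    w <- stats::runif(n_ex - 1)
    intron_len <- pmax(20, floor((L - sum(ex_len)) * w / sum(w)))
    starts <- cursor + cumsum(c(0, ex_len[-n_ex] + intron_len))
    ex <- cbind(starts, starts + ex_len)
    strand <- if (i %% 2 == 0) "-" else "+"
    # isoforms: canonical full-length + either a truncated 5' short isoform
    # (AT genes) or a skipped-exon variant (others)
    tx_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    full <- list(isoform_id = paste0(gene_ids[i], ".L"), exons = ex,
                 coding_class = "full-length")
    if (i %in% at_idx) {
      k <- ceiling(n_ex / 3)
      short_rows <- tx_order[seq_len(max(2, k))]
      alt <- list(isoform_id = paste0(gene_ids[i], ".S"),
                  exons = ex[short_rows, , drop = FALSE],
                  coding_class = "truncated")
    } else {
      drop_row <- tx_order[ceiling(n_ex / 2)]
      alt <- list(isoform_id = paste0(gene_ids[i], ".V"),
                  exons = ex[-drop_row, , drop = FALSE],
                  coding_class = "full-length")
    }
    models[[i]] <- gene_model(gene_ids[i], "chrS", strand, ex,
                              isoforms = list(full, alt))
    cursor <- max(ex) + 10000
  }
  names(models) <- gene_ids
  list(models = models, gene_class = stats::setNames(cls, gene_ids),
       at_genes = gene_ids[at_idx], chrom_len = cursor + 10000)
}

.gen_labels <- function(cfg) {
  .reseed(cfg, 2)
  ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  n_td <- round(cfg$n_samples * cfg$frac_tedeff)
  lab <- sample(c(rep("TEdeff", n_td), rep("TEprof", cfg$n_samples - n_td)))
  stats::setNames(lab, ids)
}

.gen_expression <- function(cfg, ann, labels) {
  .reseed(cfg, 3)
  genes <- names(ann$models)
  n_s <- cfg$n_samples
  mu <- stats::rlnorm(length(genes), log(300), 0.7)
  is_td <- labels == "TEdeff"
  size <- 1 / cfg$dispersion
  gvals <- matrix(0, n_s, length(genes),
                  dimnames = list(names(labels), genes))
  for (j in seq_along(genes)) {
    eff <- rep(1, n_s)
    if (ann$gene_class[j] == "I") eff[is_td] <- 0.6
    if (ann$gene_class[j] == "II") eff[is_td] <- cfg$class2_gain
    gvals[, j] <- stats::rnbinom(n_s, mu = mu[j] * eff, size = size)
  }
  iso_ids <- character(0); iso_gene <- character(0)
  ivals <- NULL
  short_of <- character(0); long_of <- character(0)
  icols <- list()
  for (j in seq_along(genes)) {
    g <- ann$models[[genes[j]]]
    iso <- names(g$isoforms)
    if (genes[j] %in% ann$at_genes) {
      r <- cfg$baseline_log_ratio + cfg$isoform_shift * is_td +
        stats::rnorm(n_s, 0, 0.5)
      p <- 2^r / (1 + 2^r)
      short <- stats::rbinom(n_s, gvals[, j], p)
      m <- cbind(short, gvals[, j] - short)
      colnames(m) <- paste0(genes[j], c(".S", ".L"))
      short_of <- c(short_of, paste0(genes[j], ".S"))
      long_of <- c(long_of, paste0(genes[j], ".L"))
    } else {
      a <- stats::rbinom(n_s, gvals[, j], 0.5)
      m <- cbind(a, gvals[, j] - a)
      colnames(m) <- paste0(genes[j], c(".L", ".V"))
    }
    icols[[j]] <- m
    iso_gene <- c(iso_gene, rep(genes[j], 2))
  }
  ivals <- do.call(cbind, icols)
  rownames(ivals) <- names(labels)
  list(gene_expr = expr_matrix(gvals),
       iso_expr = expr_matrix(ivals, stats::setNames(iso_gene, colnames(ivals))),
       short_isoforms = short_of, long_isoforms = long_of)
}

.gen_exons <- function(cfg, ann, labels) {
  .reseed(cfg, 4)
  is_td <- labels == "TEdeff"
  n_s <- cfg$n_samples
  n_ex <- vapply(ann$models, function(g) nrow(g$exons), 0L)
  gid_rep <- rep(names(ann$models), n_ex)
  idx <- unlist(lapply(n_ex, seq_len), use.names = FALSE)
  cls_rep <- ann$gene_class[gid_rep]
  terminal <- idx == n_ex[gid_rep]
  # per-feature TEdeff effect: Class I body loss / terminal gain, Class II gain
  eff_td <- ifelse(cls_rep == "I",
                   ifelse(terminal, cfg$terminal_gain, cfg$body_loss),
                   ifelse(cls_rep == "II", cfg$class2_gain, 1))
  base <- stats::rlnorm(length(idx), log(100), 0.5)
  eff <- outer(is_td, eff_td, function(td, e) ifelse(td, e, 1))
  noise <- matrix(stats::rlnorm(n_s * length(idx), 0, 0.25), nrow = n_s)
  vals <- sweep(noise * eff, 2, base, `*`)
  meta <- data.frame(feature_id = sprintf("%s:%02d", gid_rep, idx),
                     gene_id = gid_rep, exon_index = idx,
                     stringsAsFactors = FALSE)
  dimnames(vals) <- list(names(labels), meta$feature_id)
  expr_matrix(vals, stats::setNames(meta$gene_id, meta$feature_id),
              meta[, c("feature_id", "exon_index")])
}

# spliced + unspliced junction reads for the Class I gene panel of one
# cohort; returns a list of per-sample SAM record data.frames
.gen_sam <- function(cfg, ann, labels) {
  .reseed(cfg, 5)
  panel <- names(ann$gene_class)[ann$gene_class == "I"]
  rl <- cfg$read_length
  out <- vector("list", cfg$n_samples)
  names(out) <- names(labels)
  for (s in seq_along(labels)) {
    rate <- if (labels[s] == "TEdeff") cfg$retention_rate_tedeff
            else cfg$retention_rate_teprof
    qn <- 0L
    recs <- list()
    for (gid in panel) {
      g <- ann$models[[gid]]
      ex <- g$exons
      for (j in seq_len(nrow(ex) - 1)) {
        d <- ex[j, 2]; a <- ex[j + 1, 1]; il <- a - d
        n_ee <- stats::rpois(1, cfg$mean_ee_reads)
        n_ei <- stats::rpois(1, cfg$mean_ee_reads * rate)
        n_ie <- stats::rpois(1, cfg$mean_ee_reads * rate)
        if (n_ee) {
          anch <- sample(8:(rl - 8), n_ee, replace = TRUE)
          recs[[length(recs) + 1]] <- data.frame(
            pos = d - anch + 1,
            cigar = sprintf("%dM%dN%dM", anch, il, rl - anch),
            mapq = 60L)
        }
        if (n_ei) {
          e <- sample(8:(rl - 8), n_ei, replace = TRUE)
          recs[[length(recs) + 1]] <- data.frame(
            pos = d - e + 1, cigar = sprintf("%dM", rl), mapq = 60L)
        }
        if (n_ie) {
          i2 <- sample(8:(rl - 8), n_ie, replace = TRUE)
          recs[[length(recs) + 1]] <- data.frame(
            pos = a - i2 + 1, cigar = sprintf("%dM", rl), mapq = 60L)
        }
      }
      # one low-quality read per gene, removed by the MAPQ filter
      recs[[length(recs) + 1]] <- data.frame(
        pos = ex[1, 1] + 1, cigar = sprintf("%dM", rl), mapq = 10L)
    }
    df <- do.call(rbind, recs)
    df$qname <- sprintf("r%06d", seq_len(nrow(df)))
    df$flag <- 0L; df$rname <- "chrS"
    out[[s]] <- df[, c("qname", "flag", "rname", "pos", "mapq", "cigar")]
  }
  out
}

#' Write SAM records generated by the cohort simulator
#' @param recs data.frame with `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`.
#' @param path output SAM file.
#' @param chrom_len reference length for the header.
#' @param read_length read length (placeholder bases).
#' @export
write_sam <- function(recs, path, chrom_len, read_length = 50) {
  seq <- strrep("A", read_length); qual <- strrep("I", read_length)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", recs$rname[1], chrom_len))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  recs$qname, recs$flag, recs$rname, recs$pos, recs$mapq,
                  recs$cigar, seq, qual)
  writeLines(c(header, body), path)
  invisible(path)
}

.gen_coverage <- function(cfg, ann, labels) {
  .reseed(cfg, 6)
  n_g <- length(ann$models)
  amp <- stats::rlnorm(n_g, log(50), 0.3)
  tss <- vapply(ann$models, `[[`, 0, "tss")
  tts <- vapply(ann$models, `[[`, 0, "tts")
  strand <- vapply(ann$models, `[[`, "", "strand")
  chrom <- vapply(ann$models, `[[`, "", "chrom")
  plus <- strand == "+"
  # per gene: three TSS-peak segments (0.6a / a / 0.6a) plus the gene body;
  # minus-strand segments mirror around the TSS base
  seg_s <- cbind(tss - 300, tss - 100, tss + 100)
  seg_e <- cbind(tss - 100, tss + 100, tss + 301)
  for (k in 1:3) {
    s0 <- seg_s[, k]; e0 <- seg_e[, k]
    seg_s[!plus, k] <- (2 * tss - e0 + 1)[!plus]
    seg_e[!plus, k] <- (2 * tss - s0 + 1)[!plus]
  }
  body_s <- ifelse(plus, tss + 301, tts)
  body_e <- ifelse(plus, tts + 1, tss - 300)
  starts <- c(t(cbind(seg_s, body_s)))
  ends <- c(t(cbind(seg_e, body_e)))
  chrom4 <- rep(chrom, each = 4)
  amp4 <- rep(amp, each = 4)
  mult_peak <- rep(c(0.6, 1, 0.6, NA), n_g)   # NA marks the body slot
  tracks <- vector("list", cfg$n_samples)
  names(tracks) <- names(labels)
  for (s in seq_along(labels)) {
    tr0 <- if (labels[s] == "TEdeff") cfg$tr_tedeff else cfg$tr_teprof
    trg <- tr0 * stats::rlnorm(n_g, 0, 0.15)
    mult <- mult_peak
    mult[is.na(mult)] <- trg
    r <- data.frame(chrom = chrom4, start = starts, end = ends,
                    depth = amp4 * mult)
    r <- r[r$end > r$start, , drop = FALSE]
    tracks[[s]] <- coverage_track(r, read_length = cfg$read_length)
  }
  tracks
}

.gen_methylation <- function(cfg, ann, labels, n_probes = 500) {
  .reseed(cfg, 7)
  pos <- stats::runif(n_probes, -1, 2)
  base <- stats::runif(n_probes, 0.2, 0.8)
  is_td <- labels == "TEdeff"
  eff <- numeric(n_probes)
  eff[pos >= -0.5 & pos <= 0.1] <- -0.15   # promoter hypomethylation
  eff[pos > 0.25 & pos < 0.8] <- 0.10      # gene-body hypermethylation
  beta <- sapply(seq_along(labels), function(s) {
    pmin(pmax(base + eff * is_td[s] + stats::rnorm(n_probes, 0, 0.05),
              0.01), 0.99)
  })
  dimnames(beta) <- list(sprintf("cg%04d", seq_len(n_probes)), names(labels))
  list(beta = beta, positions = pos)
}

.gen_clinical <- function(cfg, labels) {
  .reseed(cfg, 8)
  n <- cfg$n_samples
  lambda0 <- 1 / 1000
  rate <- ifelse(labels == "TEdeff", lambda0 * cfg$hazard_ratio, lambda0)
  t_event <- stats::rexp(n, rate)
  cens <- stats::runif(n, 300, 2500)
  drugs <- c("Interferon alfa-2b", "Proleukin", "IL-2", "Ipilimumab",
             "pembrolizumab", "Sunitinib", "Pazopanib", "unknown")
  data.frame(sample_id = names(labels),
             time = round(pmin(t_event, cens), 1),
             event = as.integer(t_event <= cens),
             therapy = sample(drugs, n, replace = TRUE,
                              prob = c(.15, .1, .1, .1, .1, .2, .15, .1)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic tumor cohort with planted TEdeff structure
#'
#' Produces a self-contained bundle: gene annotation, gene/isoform/exon
#' expression matrices, per-sample spliced alignments (SAM) over the
#' Class I gene panel, per-sample coverage tracks, a methylation matrix on
#' transcript-relative probe positions, a clinical table, and the planted
#' truth.  With `out_dir` set, every component is also written in its
#' standard text format (GTF, TSV, SAM, bedGraph, JSON); identical
#' configurations give byte-identical files.
#'
#' @param cfg a [cohort_config()].
#' @param out_dir optional output directory.
#' @param components which components to generate (annotation, labels and
#'   clinical are always included).
#' @return a list bundle with elements `models`, `truth`, and the requested
#'   components (`gene_expr`, `iso_expr`, `exon_expr`, `sam`, `coverage`,
#'   `methylation`, `clinical`).
#' @export
generate_cohort <- function(cfg, out_dir = NULL,
                            components = c("expression", "exons", "sam",
                                           "coverage", "methylation")) {
  stopifnot(inherits(cfg, "cohort_config"))
  ann <- .gen_annotation(cfg)
  labels <- .gen_labels(cfg)
  bundle <- list(models = ann$models, chrom_len = ann$chrom_len)
  truth <- list(labels = labels, gene_class = ann$gene_class,
                at_genes = ann$at_genes, config = unclass(cfg))
  if ("expression" %in% components) {
    e <- .gen_expression(cfg, ann, labels)
    bundle$gene_expr <- e$gene_expr; bundle$iso_expr <- e$iso_expr
    truth$short_isoforms <- e$short_isoforms
    truth$long_isoforms <- e$long_isoforms
  }
  if ("exons" %in% components) bundle$exon_expr <- .gen_exons(cfg, ann, labels)
  if ("sam" %in% components) bundle$sam <- .gen_sam(cfg, ann, labels)
  if ("coverage" %in% components)
    bundle$coverage <- .gen_coverage(cfg, ann, labels)
  if ("methylation" %in% components)
    bundle$methylation <- .gen_methylation(cfg, ann, labels)
  bundle$clinical <- .gen_clinical(cfg, labels)
  bundle$truth <- truth
  if (!is.null(out_dir)) .write_cohort(bundle, out_dir, cfg)
  bundle
}

.write_cohort <- function(bundle, out_dir, cfg) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("generate_cohort: cannot create output directory ", out_dir)
  write_annotation(bundle$models, file.path(out_dir, "annotation.gtf"))
  if (!is.null(bundle$gene_expr)) {
    write_expression_tsv(bundle$gene_expr, file.path(out_dir, "gene_expr.tsv"))
    write_expression_tsv(bundle$iso_expr, file.path(out_dir, "isoform_expr.tsv"))
  }
  if (!is.null(bundle$exon_expr))
    write_expression_tsv(bundle$exon_expr, file.path(out_dir, "exon_rpkm.tsv"))
  if (!is.null(bundle$sam))
    for (s in names(bundle$sam))
      write_sam(bundle$sam[[s]], file.path(out_dir, paste0(s, ".sam")),
                bundle$chrom_len, cfg$read_length)
  if (!is.null(bundle$coverage))
    for (s in names(bundle$coverage))
      write_bedgraph(bundle$coverage[[s]],
                     file.path(out_dir, paste0(s, ".bedGraph")))
  if (!is.null(bundle$methylation)) {
    m <- bundle$methylation
    utils::write.table(
      data.frame(probe_id = rownames(m$beta), rel_pos = m$positions,
                 m$beta, check.names = FALSE),
      file.path(out_dir, "methylation_beta.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$clinical, file.path(out_dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Worked-example fixtures
#'
#' Tiny deterministic inputs reproducing the two printed scenarios the
#' pipeline's documentation walks through: (1) a promoter-enrichment set of
#' 100 query promoters of which exactly 50 overlap a peak set, on a
#' background calibrated so the length-matched permutation expectation is
#' about 10 overlaps (the printed scenario numbers observed = 50, expected
#' 10 +/- 5, Z = 8 are carried in `printed`); (2) a 42-sample retention
#' score vector whose median split gives two groups of 21.
#'
#' @return list with `enrichment` (elements `models`, `query_genes`,
#'   `background_genes`, `peaks`, `empty_peaks`, `printed`) and
#'   `retention_scores` (named 42-vector).
#' @export
worked_example_fixtures <- function() {
  n_bg <- 1000
  s <- (seq_len(n_bg) - 1) * 4000     # promoter [s, s+1001) via tss = s+1000
  gene_ids <- sprintf("B%04d", seq_len(n_bg))
  models <- lapply(seq_len(n_bg), function(i)
    gene_model(gene_ids[i], "chrF", "+",
               cbind(s[i] + 1000, s[i] + 1500)))
  names(models) <- gene_ids
  overlapping <- seq(1, n_bg, by = 10)          # 10% of the background
  peaks <- data.frame(chrom = "chrF",
                      start = s[overlapping] + 400,
                      end = s[overlapping] + 600)
  query <- c(gene_ids[overlapping[1:50]],       # 50 overlapping
             gene_ids[setdiff(seq(6, n_bg, by = 10), overlapping)[1:50]])
  scores <- stats::setNames(seq(0.01, 0.42, by = 0.01),
                            sprintf("S%02d", 1:42))
  list(enrichment = list(models = models, query_genes = query,
                         background_genes = gene_ids, peaks = peaks,
                         empty_peaks = peaks[0, , drop = FALSE],
                         printed = list(observed = 50, expected_mean = 10,
                                        expected_sd = 5, z = 8)),
       retention_scores = scores)
}
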