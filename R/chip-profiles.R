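#' Coverage track
#'
#' Run-length representation of per-base depth over one or more
#' chromosomes, with the library size (total reads) used for per-million
#' normalization.
#'
#' @param runs data.frame with `chrom`, `start`, `end`, `depth`
#'   (non-negative; 0-based half-open, non-overlapping per chromosome).
#' @param library_size total mapped reads of the library; when `NULL` it is
#'   estimated as total covered area / `read_length`.
#' @param read_length read length for the library-size estimate (default 50).
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(runs, library_size = NULL, read_length = 50) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(runs)))
  if (any(runs$depth < 0)) stop("coverage_track: negative depth")
  runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  if (is.null(library_size))
    library_size <- sum(runs$depth * (runs$end - runs$start)) / read_length
  structure(list(runs = runs, library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d runs on %d chromosome(s), library %.3g reads\n",
              nrow(x$runs), length(unique(x$runs$chrom)), x$library_size))
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#' @param path bedGraph file (0-based half-open, as the format specifies).
#' @param library_size see [coverage_track()].
#' @export
read_bedgraph <- function(path, library_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1,
                            end = GenomicRanges::end(gr),
                            depth = gr$score, stringsAsFactors = FALSE),
                 library_size = library_size)
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  r <- track$runs
  utils::write.table(
    data.frame(r$chrom, format(r$start, scientific = FALSE, trim = TRUE),
               format(r$end, scientific = FALSE, trim = TRUE), r$depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# depth at single 0-based positions (vectorized; 0 outside any run)
.depth_at <- function(track, chrom, pos) {
  r <- track$runs[track$runs$chrom == chrom, , drop = FALSE]
  if (!nrow(r)) return(numeric(length(pos)))
  i <- findInterval(pos, r$start)
  d <- ifelse(i >= 1 & pos < r$end[pmax(i, 1)], r$depth[pmax(i, 1)], 0)
  d[i < 1] <- 0
  d
}

# mean depth over [start, end), run-weighted
.mean_depth <- function(track, chrom, start, end) {
  r <- track$runs[track$runs$chrom == chrom, , drop = FALSE]
  if (!nrow(r) || end <= start) return(0)
  ov <- pmax(pmin(r$end, end) - pmax(r$start, start), 0)
  sum(r$depth * ov) / (end - start)
}

#' Meta-gene coverage profile
#'
#' Each gene's body (TSS to TTS) is length-normalized by sampling the
#' base-resolution coverage at `n_body` (default 101) equally spaced
#' positions; fixed-length flanks are sampled at `n_flank` positions each.
#' Profiles are oriented 5' to 3' (minus-strand genes reversed), normalized
#' per million reads, and averaged across genes.
#'
#' @param track a `coverage_track`.
#' @param models named list of `gene_model` objects.
#' @param flank flank size in bp (default 2000).
#' @param n_body body grid points (default 101).
#' @param n_flank points per flank (default 40).
#' @return data.frame with `position` (grid label: -flank..TSS..TTS..+flank
#'   as a numeric axis in [-1, 2]), `mean_depth` (per million reads), and
#'   `n_genes`.
#' @export
metagene_profile <- function(track, models, flank = 2000, n_body = 101,
                             n_flank = 40) {
  grid_len <- n_flank + n_body + n_flank
  acc <- numeric(grid_len); n_used <- 0L
  for (g in models) {
    span <- range(g$exons)
    if (span[2] - span[1] < 2) next
    body <- round(seq(span[1], span[2] - 1, length.out = n_body))
    up <- round(seq(span[1] - flank, span[1] - 1, length.out = n_flank))
    down <- round(seq(span[2], span[2] + flank - 1, length.out = n_flank))
    pos <- c(up, body, down)
    d <- .depth_at(track, g$chrom, pos)
    if (g$strand == "-") d <- rev(d)
    acc <- acc + d
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("metagene_profile: no usable genes")
  axis <- c(seq(-1, 0, length.out = n_flank + 1)[-(n_flank + 1)],
            seq(0, 1, length.out = n_body),
            seq(1, 2, length.out = n_flank + 1)[-1])
  data.frame(position = axis,
             mean_depth = acc / n_used * 1e6 / track$library_size,
             n_genes = n_used)
}

#' RNAP II traveling ratio of a gene
#'
#' Ratio of mean occupancy along the gene body (from `tss_halfwin` bp past
#' the TSS to the TTS) to mean occupancy in the TSS window (TSS +/-
#' `tss_halfwin` bp).  Low values indicate promoter-proximal stalling.
#'
#' @param track a `coverage_track`.
#' @param model a `gene_model`.
#' @param tss_halfwin TSS window half-width in bp (default 300).
#' @return data.frame with `gene_id`, `tss_occupancy`, `body_occupancy`,
#'   `tr` (`NA` when TSS occupancy is 0).
#' @export
traveling_ratio <- function(track, model, tss_halfwin = 300) {
  tss <- model$tss
  tss_occ <- .mean_depth(track, model$chrom, tss - tss_halfwin,
                         tss + tss_halfwin + 1)
  if (model$strand == "+") {
    body <- c(tss + tss_halfwin + 1, model$tts + 1)
  } else {
    body <- c(model$tts, tss - tss_halfwin)
  }
  body_occ <- if (body[2] > body[1])
    .mean_depth(track, model$chrom, body[1], body[2]) else NA_real_
  data.frame(gene_id = model$gene_id,
             tss_occupancy = tss_occ, body_occupancy = body_occ,
             tr = if (is.na(body_occ) || tss_occ == 0) NA_real_
                  else body_occ / tss_occ)
}

#' Traveling ratios for a set of genes
#' @param track a `coverage_track`.
#' @param models named list of `gene_model` objects.
#' @param ... passed to [traveling_ratio()].
#' @export
traveling_ratio_all <- function(track, models, ...) {
  do.call(rbind, c(lapply(models, traveling_ratio, track = track, ...),
                   make.row.names = FALSE))
}

#' Correlation of gene-body occupancy with expression
#'
#' Spearman rank correlation of per-gene body occupancy with the sample's
#' gene-level expression over the shared genes.
#'
#' @param trs data.frame from [traveling_ratio_all()].
#' @param gene_expr gene-level `expr_matrix`.
#' @param sample sample id.
#' @return list with `rho`, `p`, `n_genes`.
#' @export
occupancy_expression_correlation <- function(trs, gene_expr, sample) {
  genes <- intersect(trs$gene_id, em_features(gene_expr))
  if (length(genes) < 20)
    stop("occupancy_expression_correlation: < 20 shared genes")
  occ <- trs$body_occupancy[match(genes, trs$gene_id)]
  expr <- gene_expr$values[sample, genes]
  if (stats::sd(occ) == 0 || stats::sd(expr) == 0)
    return(list(rho = NA_real_, p = NA_real_, n_genes = length(genes)))
  ct <- suppressWarnings(stats::cor.test(occ, expr, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_genes = length(genes))
}
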