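#' Genomic interval
#'
#' A minimal interval record used throughout the package.  Internal
#' coordinates are always 0-based half-open (`[start, end)`); GTF input is
#' converted on read, BED passes through unchanged.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must satisfy `start < end`.
#' @param strand optional `"+"` or `"-"` (or `NA`).
#' @return a one-row `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("genomic_interval: start must be < end")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Gene model
#'
#' A gene with its exon union in transcription order, per-isoform exon
#' structures, and derived lengths.  The transcription start site (`tss`)
#' is the 0-based coordinate of the first transcribed base (the span start
#' on `+`, the last base of the span on `-`); `tts` is the last transcribed
#' base.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (`start`, `end`) of the gene's exon union,
#'   0-based half-open, in genomic order.  Overlapping records are merged.
#' @param isoforms named list of isoform models, each a list with elements
#'   `isoform_id`, `exons` (matrix as above), and optionally `coding_class`
#'   (`"full-length"` or `"truncated"`).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, isoforms = list()) {
  stopifnot(strand %in% c("+", "-"))
  exons <- .exon_union(exons)
  span <- c(min(exons[, 1]), max(exons[, 2]))
  isoforms <- lapply(isoforms, function(iso) {
    ex <- .as_exon_matrix(iso$exons)
    iso$exons <- ex[order(ex[, 1]), , drop = FALSE]
    iso$transcript_length <- sum(iso$exons[, 2] - iso$exons[, 1])
    if (is.null(iso$coding_class)) iso$coding_class <- "full-length"
    iso
  })
  if (length(isoforms)) names(isoforms) <- vapply(isoforms, `[[`, "", "isoform_id")
  mrna_length <- if (length(isoforms)) {
    max(vapply(isoforms, `[[`, 0, "transcript_length"))
  } else sum(exons[, 2] - exons[, 1])
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tss = if (strand == "+") span[1] else span[2] - 1,
    tts = if (strand == "+") span[2] - 1 else span[1],
    exons = exons, isoforms = isoforms,
    genomic_length = span[2] - span[1],
    mrna_length = mrna_length
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exons, %d isoform(s)\n",
              x$gene_id, x$chrom, min(x$exons[, 1]), max(x$exons[, 2]),
              x$strand, nrow(x$exons), length(x$isoforms)))
  invisible(x)
}

.as_exon_matrix <- function(exons) {
  m <- matrix(as.numeric(as.matrix(exons)[, 1:2]), ncol = 2)
  colnames(m) <- c("start", "end")
  if (any(m[, 1] >= m[, 2])) stop("exon with start >= end")
  m
}

# merge overlapping/adjacent-overlap records into a sorted union
.exon_union <- function(exons) {
  m <- .as_exon_matrix(exons)
  ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1] + 1, end = m[, 2]))
  cbind(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

#' Exons of a gene model in transcription (5' to 3') order
#'
#' @param g a `gene_model`.
#' @return two-column matrix of exon intervals, 5'-most first.
#' @export
exons_tx_order <- function(g) {
  ex <- g$exons
  if (g$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Promoter window of a gene
#'
#' The window covers 1000 bp upstream of and 1 bp past the TSS (1001 bp
#' total), strand-aware, clipped at the chromosome start.
#'
#' @param g a `gene_model`.
#' @param upstream bp upstream of the TSS (default 1000).
#' @return a `genomic_interval` row.
#' @export
promoter_region <- function(g, upstream = 1000) {
  if (g$strand == "+") {
    genomic_interval(g$chrom, max(0, g$tss - upstream), g$tss + 1, g$strand)
  } else {
    genomic_interval(g$chrom, g$tss, g$tss + upstream + 1, g$strand)
  }
}

#' Gene regions: promoter, exon union, or introns
#'
#' Introns are the genomic gaps between consecutive exons of the per-gene
#' exon union; a single-exon gene has none.
#'
#' @param g a `gene_model`.
#' @param which one of `"promoter"`, `"exons"`, `"introns"`.
#' @return a `data.frame` of intervals (possibly 0 rows).
#' @export
gene_regions <- function(g, which = c("promoter", "exons", "introns")) {
  which <- match.arg(which)
  if (which == "promoter") return(promoter_region(g))
  ex <- g$exons
  if (which == "exons") {
    return(genomic_interval(g$chrom, ex[, 1], ex[, 2], g$strand))
  }
  if (nrow(ex) < 2) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character()))
  }
  genomic_interval(g$chrom, ex[-nrow(ex), 2], ex[-1, 1], g$strand)
}

#' Read a GTF annotation into gene models
#'
#' GTF 1-based closed coordinates are converted to the internal 0-based
#' half-open convention.  One `gene_model` is built per `gene_id`; its exon
#' union is taken across all transcripts.  Transcripts without exon records
#' are skipped with a warning.
#'
#' @param path GTF file.
#' @return named list of `gene_model` objects.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("read_annotation: no exon records in ", path)
  if (is.null(ex$gene_id) || is.null(ex$transcript_id))
    stop("read_annotation: gene_id/transcript_id attributes required")
  # transcripts declared but lacking exon children
  tx <- gr[gr$type == "transcript"]
  if (length(tx)) {
    orphan <- setdiff(tx$transcript_id, unique(ex$transcript_id))
    if (length(orphan))
      warning("skipping transcript(s) without exons: ",
              paste(orphan, collapse = ", "))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1,   # to 0-based half-open
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    stringsAsFactors = FALSE)
  models <- lapply(split(df, df$gene_id), function(d) {
    isoforms <- lapply(split(d, d$transcript_id), function(t)
      list(isoform_id = t$transcript_id[1],
           exons = cbind(t$start, t$end)))
    gene_model(d$gene_id[1], d$chrom[1], d$strand[1],
               cbind(d$start, d$end), isoforms = unname(isoforms))
  })
  models[order(names(models))]
}

#' Write gene models as GTF
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates
#' are converted back to GTF 1-based closed.
#'
#' @param models named list of `gene_model` objects.
#' @param path output file.
#' @export
write_annotation <- function(models, path) {
  lines <- unlist(lapply(models, function(g) {
    rows <- character(0)
    span <- range(g$exons)
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    rows <- c(rows, sprintf("%s\ttedeff\tgene\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, span[1] + 1, span[2], g$strand, attr_g))
    for (iso in g$isoforms) {
      a <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, iso$isoform_id)
      tspan <- range(iso$exons)
      rows <- c(rows, sprintf("%s\ttedeff\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, tspan[1] + 1, tspan[2], g$strand, a))
      rows <- c(rows, sprintf("%s\ttedeff\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, iso$exons[, 1] + 1, iso$exons[, 2],
                              g$strand, a))
    }
    rows
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 file of intervals
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#'
#' @param path BED file.
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(
    data.frame(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
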