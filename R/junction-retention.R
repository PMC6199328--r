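#' Read a SAM file's alignment records
#'
#' Minimal reader for the text SAM lines this package consumes (header
#' lines skipped, unmapped records dropped).  Coordinates stay 1-based as
#' in SAM; the junction counter converts internally.
#'
#' @param path SAM file.
#' @return data.frame with `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 11
  if (any(bad)) stop("read_sam: malformed record at line ", which(bad)[1])
  df <- data.frame(
    qname = vapply(f, `[[`, "", 1),
    flag = as.integer(vapply(f, `[[`, "", 2)),
    rname = vapply(f, `[[`, "", 3),
    pos = as.integer(vapply(f, `[[`, "", 4)),
    mapq = as.integer(vapply(f, `[[`, "", 5)),
    cigar = vapply(f, `[[`, "", 6),
    stringsAsFactors = FALSE)
  df[!bitwAnd(df$flag, 4L) & df$rname != "*", , drop = FALSE]
}

# Walk a CIGAR string from a 0-based start position.  Returns M blocks and
# N gaps in reference coordinates, or NULL if an unsupported op occurs.
.cigar_blocks <- function(cigar, start0) {
  ops <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  n <- as.numeric(substr(ops, 1, nchar(ops) - 1))
  op <- substr(ops, nchar(ops), nchar(ops))
  if (any(!op %in% c("M", "I", "D", "N", "S"))) return(NULL)
  mb <- matrix(numeric(0), ncol = 2); gaps <- matrix(numeric(0), ncol = 2)
  ref <- start0
  for (i in seq_along(op)) {
    if (op[i] == "M") { mb <- rbind(mb, c(ref, ref + n[i])); ref <- ref + n[i] }
    else if (op[i] == "D") ref <- ref + n[i]
    else if (op[i] == "N") { gaps <- rbind(gaps, c(ref, ref + n[i])); ref <- ref + n[i] }
    # I and S consume no reference
  }
  list(m = mb, gaps = gaps, start = start0, end = ref)
}

# TRUE if [lo, hi) is fully covered by M blocks (per-base matched)
.m_covers <- function(blocks, lo, hi) {
  if (!nrow(blocks$m)) return(FALSE)
  cov <- pmin(blocks$m[, 2], hi) - pmax(blocks$m[, 1], lo)
  sum(pmax(cov, 0)) == (hi - lo) &&
    all(blocks$gaps[, 1] >= hi | blocks$gaps[, 2] <= lo)
}

#' Count exon-exon and exon-intron junction reads for a gene
#'
#' Junctions are enumerated from the gene's exon union (annotation-anchored;
#' de novo gaps are ignored).  An exon-exon (EE) read is a gapped alignment
#' whose gap coincides exactly with the annotated intron, with at least
#' `anchor` matched bases on each flanking exon and mapping quality strictly
#' above `mapq_min`.  An exon-intron (EI) or intron-exon (IE) read is an
#' alignment whose matched bases continuously cover `anchor` bp on both
#' sides of the exon/intron boundary (no gap across it) and whose start
#' lies within `window` bp of the boundary.  Reads spanning several
#' junction windows are tallied once per junction they satisfy.  Reads
#' with unsupported CIGAR operations are skipped and counted in the
#' `skipped` attribute.
#'
#' @param sam SAM path or data.frame from [read_sam()].
#' @param model a `gene_model`.
#' @param mapq_min reads must have MAPQ strictly greater (default 20).
#' @param anchor minimum matched bases on each side (default 8).
#' @param window maximum distance of the read start from the boundary for
#'   EI/IE reads (default 150).
#' @return data.frame: `gene_id`, `donor`, `acceptor`, `ee`, `ei`, `ie`,
#'   `intron_length`; one row per annotated intron.
#' @export
count_junctions <- function(sam, model, mapq_min = 20, anchor = 8,
                            window = 150) {
  if (is.character(sam)) sam <- read_sam(sam)
  ex <- model$exons
  n_j <- nrow(ex) - 1
  out <- data.frame(gene_id = rep(model$gene_id, max(n_j, 0)),
                    donor = numeric(max(n_j, 0)),
                    acceptor = numeric(max(n_j, 0)),
                    ee = 0L, ei = 0L, ie = 0L,
                    intron_length = numeric(max(n_j, 0)))
  attr(out, "skipped") <- 0L
  if (n_j < 1) return(out)
  out$donor <- ex[-nrow(ex), 2]; out$acceptor <- ex[-1, 1]
  out$intron_length <- out$acceptor - out$donor
  span <- range(ex)
  r <- sam[sam$rname == model$chrom & sam$mapq > mapq_min, , drop = FALSE]
  if (!nrow(r)) return(out)
  # rough span filter before CIGAR walking (read length <= 10 kb assumed)
  r <- r[r$pos - 1 < span[2] + window & r$pos + 1e4 > span[1] - window, ,
         drop = FALSE]
  skipped <- 0L
  for (k in seq_len(nrow(r))) {
    bl <- .cigar_blocks(r$cigar[k], r$pos[k] - 1)
    if (is.null(bl)) { skipped <- skipped + 1L; next }
    for (j in seq_len(n_j)) {
      d <- out$donor[j]; a <- out$acceptor[j]
      if (nrow(bl$gaps) && any(bl$gaps[, 1] == d & bl$gaps[, 2] == a)) {
        left <- sum(pmax(pmin(bl$m[, 2], d) - bl$m[, 1], 0))
        right <- sum(pmax(bl$m[, 2] - pmax(bl$m[, 1], a), 0))
        if (left >= anchor && right >= anchor) out$ee[j] <- out$ee[j] + 1L
      }
      if (abs(bl$start - d) <= window && .m_covers(bl, d - anchor, d + anchor))
        out$ei[j] <- out$ei[j] + 1L
      if (abs(bl$start - a) <= window && .m_covers(bl, a - anchor, a + anchor))
        out$ie[j] <- out$ie[j] + 1L
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Count junction reads over many genes
#' @param sam SAM path or data.frame from [read_sam()].
#' @param models named list of `gene_model` objects.
#' @param ... passed to [count_junctions()].
#' @return row-bound junction count table.
#' @export
count_junctions_all <- function(sam, models, ...) {
  if (is.character(sam)) sam <- read_sam(sam)
  do.call(rbind, c(lapply(models, function(m) count_junctions(sam, m, ...)),
                   make.row.names = FALSE))
}

#' Intron-retention score of a sample
#'
#' `(sum EI + sum IE) / (sum EE)` over eligible junctions of the gene set.
#' Eligibility: at least `min_ee` exon-exon reads and intron length
#' strictly greater than `min_intron` bp; ineligible junctions are excluded
#' from numerator and denominator.
#'
#' @param counts junction count table from [count_junctions()].
#' @param gene_set gene ids to include (default all).
#' @param min_ee minimum EE reads (default 5).
#' @param min_intron minimum intron length, exclusive (default 500).
#' @return the retention ratio, or `NA` (with a warning) when no junction
#'   is eligible.
#' @export
retention_score <- function(counts, gene_set = NULL, min_ee = 5,
                            min_intron = 500) {
  if (!is.null(gene_set)) counts <- counts[counts$gene_id %in% gene_set, ]
  ok <- counts$ee >= min_ee & counts$intron_length > min_intron
  if (!any(ok)) {
    warning("retention_score: no eligible junctions")
    return(NA_real_)
  }
  sum(counts$ei[ok] + counts$ie[ok]) / sum(counts$ee[ok])
}

#' Median split of per-sample scores
#'
#' Samples strictly above the median form the high group; ties at the
#' median go to the low group.  With an even number of distinct scores the
#' split is into equal halves.
#'
#' @param scores named numeric vector (>= 2 samples).
#' @return list with character vectors `high` and `low`, plus `median`.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2)
  if (length(unique(scores)) == 1) stop("degenerate split: all scores identical")
  med <- stats::median(scores)
  list(high = names(scores)[scores > med],
       low = names(scores)[scores <= med],
       median = med)
}
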