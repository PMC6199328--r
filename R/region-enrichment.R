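# any-overlap test of query intervals against a dataset, per chromosome
.overlaps_any <- function(chrom, start, end, dataset) {
  res <- logical(length(start))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    d <- dataset[dataset$chrom == ch, , drop = FALSE]
    if (!nrow(d)) next
    q <- IRanges::IRanges(start[sel] + 1, end[sel])
    s <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
    res[sel] <- IRanges::overlapsAny(q, s)
  }
  res
}

#' Count query regions overlapping a dataset
#'
#' A region counts if it intersects any dataset interval by at least one
#' base.  When `regions` carries a `gene_id` column, multi-interval regions
#' are grouped and each gene counts at most once.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `gene_id`.
#' @param dataset data.frame of intervals (`chrom`, `start`, `end`).
#' @return integer count.
#' @export
observed_overlap <- function(regions, dataset) {
  if (!nrow(regions)) return(0L)
  hit <- .overlaps_any(regions$chrom, regions$start, regions$end, dataset)
  if ("gene_id" %in% names(regions))
    sum(vapply(split(hit, regions$gene_id), any, logical(1)))
  else sum(hit)
}

#' Region table of a gene set
#'
#' @param models named list of `gene_model` objects.
#' @param gene_set gene ids.
#' @param region_kind `"promoter"`, `"exons"` or `"introns"`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (multi-row
#'   per gene for exons/introns).
#' @export
region_table <- function(models, gene_set,
                         region_kind = c("promoter", "exons", "introns")) {
  region_kind <- match.arg(region_kind)
  ms <- models[gene_set]
  if (region_kind == "promoter") {
    # vectorized strand-aware (-1000, +1) windows
    chrom <- vapply(ms, `[[`, "", "chrom")
    strand <- vapply(ms, `[[`, "", "strand")
    tss <- vapply(ms, `[[`, 0, "tss")
    start <- ifelse(strand == "+", pmax(0, tss - 1000), tss)
    end <- ifelse(strand == "+", tss + 1, tss + 1001)
    return(data.frame(gene_id = gene_set, chrom = chrom, start = start,
                      end = end, row.names = NULL, stringsAsFactors = FALSE))
  }
  ivs <- lapply(ms, function(g) {
    ex <- g$exons
    if (region_kind == "exons") ex
    else if (nrow(ex) < 2) ex[0, , drop = FALSE]
    else cbind(ex[-nrow(ex), 2], ex[-1, 1])
  })
  n <- vapply(ivs, nrow, 0L)
  m <- do.call(rbind, ivs)
  data.frame(gene_id = rep(gene_set, n),
             chrom = rep(vapply(ms, `[[`, "", "chrom"), n),
             start = m[, 1], end = m[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Trim/extend a background gene's intervals (genomic order) to a target
# total length: intervals are consumed left to right, the last kept one is
# trimmed to the exact residue, and a deficit extends the final interval's
# 3' (right) end.
.match_length <- function(intervals, target) {
  w <- intervals[, 2] - intervals[, 1]
  tot <- sum(w)
  if (tot >= target) {
    keep <- which(cumsum(w) - w < target)
    m <- intervals[keep, , drop = FALSE]
    excess <- sum(m[, 2] - m[, 1]) - target
    m[nrow(m), 2] <- m[nrow(m), 2] - excess
    m
  } else {
    m <- intervals
    m[nrow(m), 2] <- m[nrow(m), 2] + (target - tot)
    m
  }
}

#' Length-matched random region set
#'
#' For each query gene one background gene is drawn (with replacement
#' across draws) and its region is trimmed or 3'-extended to match the
#' query gene's total region length, anchored at the background region's
#' own start.  This reproduces the query set's region-length distribution
#' exactly in every replicate.
#'
#' @param query_regions region table of the query set ([region_table()]).
#' @param bg_regions region table of the background pool.
#' @param rng_draw optional integer vector of pre-drawn background gene
#'   indices (one per query gene); drawn uniformly when `NULL`.
#' @return data.frame of simulated intervals with `gene_id` of the query
#'   gene they stand in for.
#' @export
matched_random_set <- function(query_regions, bg_regions, rng_draw = NULL) {
  q_split <- split(query_regions, query_regions$gene_id)
  bg_split <- split(bg_regions, bg_regions$gene_id)
  if (!length(bg_split)) stop("matched_random_set: empty background")
  if (is.null(rng_draw))
    rng_draw <- sample.int(length(bg_split), length(q_split), replace = TRUE)
  out <- lapply(seq_along(q_split), function(i) {
    q <- q_split[[i]]
    b <- bg_split[[rng_draw[i]]]
    m <- .match_length(cbind(b$start, b$end), sum(q$end - q$start))
    data.frame(gene_id = names(q_split)[i], chrom = b$chrom[1],
               start = m[, 1], end = m[, 2], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Z-score of an observed overlap against a permutation expectation
#' @param observed observed overlap count.
#' @param expected_mean,expected_sd permutation mean and sd.
#' @return `(observed - expected_mean) / expected_sd` (`NA` if sd is 0).
#' @export
z_score <- function(observed, expected_mean, expected_sd) {
  if (is.na(expected_sd) || expected_sd == 0) return(NA_real_)
  (observed - expected_mean) / expected_sd
}

#' Permutation enrichment of a gene-region set against a dataset
#'
#' The observed overlap of the query genes' regions with the dataset is
#' compared against `n_perm` length-matched random region sets drawn from
#' the background gene pool ([matched_random_set()]); the resulting normal
#' approximation yields a Z-score and a two-sided p-value.
#'
#' @param gene_set query gene ids.
#' @param background background gene id pool.
#' @param models named list of `gene_model` objects.
#' @param dataset interval data.frame (`chrom`, `start`, `end`).
#' @param region_kind `"promoter"`, `"exons"` or `"introns"`.
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param exclude_query drop query genes from the background pool.
#' @param dataset_id label carried into the result.
#' @return one-row data.frame: `gene_set_n`, `region_kind`, `dataset_id`,
#'   `observed`, `expected_mean`, `expected_sd`, `z`, `p`, `n_perm`.
#' @export
enrich <- function(gene_set, background, models, dataset,
                   region_kind = c("promoter", "exons", "introns"),
                   n_perm = 1000, exclude_query = FALSE,
                   dataset_id = "dataset") {
  region_kind <- match.arg(region_kind)
  if (n_perm < 100) stop("enrich: n_perm must be >= 100")
  if (exclude_query) background <- setdiff(background, gene_set)
  if (!length(background)) stop("enrich: empty background")
  qreg <- region_table(models, gene_set, region_kind)
  breg <- region_table(models, background, region_kind)
  obs <- observed_overlap(qreg, dataset)
  single <- !anyDuplicated(qreg$gene_id) && !anyDuplicated(breg$gene_id)
  if (single) {
    # vectorized path: one interval per gene, all replicates at once
    Lq <- qreg$end - qreg$start
    nq <- nrow(qreg); nb <- nrow(breg)
    idx <- sample.int(nb, n_perm * nq, replace = TRUE)
    s <- breg$start[idx]; e <- s + rep(Lq, times = n_perm)
    hit <- .overlaps_any(breg$chrom[idx], s, e, dataset)
    perm <- as.integer(rowSums(matrix(hit, nrow = n_perm, byrow = TRUE)))
  } else {
    perm <- vapply(seq_len(n_perm), function(i) {
      observed_overlap(matched_random_set(qreg, breg), dataset)
    }, numeric(1))
  }
  mu <- mean(perm); sdv <- stats::sd(perm)
  z <- z_score(obs, mu, sdv)
  data.frame(gene_set_n = length(unique(qreg$gene_id)),
             region_kind = region_kind, dataset_id = dataset_id,
             observed = obs, expected_mean = mu, expected_sd = sdv,
             z = z, p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
             n_perm = n_perm, stringsAsFactors = FALSE)
}

#' Difference of enrichment Z-scores between two gene sets
#'
#' @param a,b one-row enrichment results ([enrich()]) for the same dataset
#'   and region kind.
#' @return one-row data.frame with `dataset_id`, `region_kind`, `delta`
#'   (`a$z - b$z`).
#' @export
delta_z <- function(a, b) {
  if (!identical(a$dataset_id, b$dataset_id) ||
      !identical(a$region_kind, b$region_kind))
    stop("delta_z: mismatched dataset or region kind")
  data.frame(dataset_id = a$dataset_id, region_kind = a$region_kind,
             delta = a$z - b$z, stringsAsFactors = FALSE)
}
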