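#' Kaplan-Meier estimate of a patient group
#'
#' Product-limit estimator (via \pkg{survival}) with the at-risk table.
#'
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("km_estimate: empty group")
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Compare survival between two groups
#'
#' Single-covariate Cox proportional-hazards Wald test on the group
#' indicator (the primary reported p), with the log-rank test alongside.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level factor/character of group membership.
#' @return list with `hr` (hazard ratio, second level vs first), `wald_p`,
#'   `logrank_p`, `n`, `n_events`.
#' @export
compare_survival <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("compare_survival: need exactly 2 groups")
  if (min(table(group)) < 2) stop("compare_survival: both groups need >= 2 subjects")
  if (sum(event) < 1) return(list(hr = NA_real_, wald_p = NA_real_,
                                  logrank_p = NA_real_, n = length(time),
                                  n_events = 0))
  s <- survival::Surv(time, event)
  cx <- survival::coxph(s ~ group)
  sm <- summary(cx)
  sd_ <- survival::survdiff(s ~ group)
  list(hr = unname(exp(stats::coef(cx))),
       wald_p = unname(sm$coefficients[1, "Pr(>|z|)"]),
       logrank_p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       n = length(time), n_events = sum(event))
}

#' Tumor-infiltrating-lymphocyte (TIL) score
#'
#' Per-sample mean of `log2(x+1)` expression of the cytolytic marker genes
#' (GZMK and PRF1 by default), median-split into TIL-high / TIL-low (ties
#' at the median go to low).  Missing markers fall back to the available
#' ones with a warning.
#'
#' @param gene_expr gene-level `expr_matrix`.
#' @param markers marker gene ids (default `c("GZMK", "PRF1")`).
#' @return data.frame with `sample_id`, `score`, `group`.
#' @export
til_score <- function(gene_expr, markers = c("GZMK", "PRF1")) {
  have <- intersect(markers, em_features(gene_expr))
  if (!length(have)) stop("til_score: no marker genes present")
  if (length(have) < length(markers))
    warning("til_score: falling back to available marker(s): ",
            paste(have, collapse = ", "))
  score <- rowMeans(log2p1(gene_expr$values[, have, drop = FALSE]))
  sp <- median_split(score)
  data.frame(sample_id = names(score), score = unname(score),
             group = ifelse(names(score) %in% sp$high, "TIL-high", "TIL-low"),
             stringsAsFactors = FALSE)
}

#' Two-factor survival strata
#'
#' Crosses the TEdeff call with a second binary factor (e.g. TIL status or
#' mutational burden) into four strata; computes per-stratum KM estimates
#' and all pairwise Cox Wald comparisons among non-empty strata.
#'
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @param labels named `"TEdeff"`/`"TEprof"` vector.
#' @param second named second binary factor over the same samples.
#' @return list with `strata` (per-sample stratum table), `km` (named list
#'   of KM tables), `pairwise` (data.frame of comparisons).
#' @export
two_factor_strata <- function(clinical, labels, second) {
  ids <- intersect(clinical$sample_id, intersect(names(labels), names(second)))
  cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  stratum <- paste(labels[ids], second[ids], sep = "/")
  tab <- data.frame(sample_id = ids, stratum = stratum,
                    time = cl$time, event = cl$event,
                    stringsAsFactors = FALSE)
  km <- lapply(split(tab, tab$stratum),
               function(d) km_estimate(d$time, d$event))
  lv <- names(which(table(stratum) >= 2))
  pairs <- if (length(lv) >= 2) utils::combn(lv, 2, simplify = FALSE) else list()
  pw <- do.call(rbind, c(lapply(pairs, function(p) {
    d <- tab[tab$stratum %in% p, , drop = FALSE]
    cmp <- tryCatch(compare_survival(d$time, d$event, d$stratum),
                    error = function(e) list(hr = NA, wald_p = NA,
                                             logrank_p = NA, n = nrow(d),
                                             n_events = sum(d$event)))
    data.frame(a = p[1], b = p[2], hr = cmp$hr, wald_p = cmp$wald_p,
               logrank_p = cmp$logrank_p, n = cmp$n,
               stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  list(strata = tab, km = km, pairwise = pw)
}

#' Default therapy vocabulary
#'
#' The editable annotation-to-therapy-class mapping shipped with the
#' package (`inst/extdata/therapy_vocabulary.tsv`): raw clinical drug
#' annotations (with their many spellings) mapped to `immunotherapy`,
#' `checkpoint` or `targeted`.
#'
#' @return data.frame with `annotation`, `therapy_class`.
#' @export
therapy_vocabulary <- function() {
  utils::read.table(system.file("extdata", "therapy_vocabulary.tsv",
                                package = "tedeff"),
                    sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

#' Classify raw drug annotations into therapy classes
#'
#' Case-insensitive exact match (after trimming surrounding whitespace)
#' against the vocabulary; unmatched annotations map to `"other"`.
#'
#' @param annotation character vector of raw drug annotations.
#' @param vocab vocabulary data.frame (default [therapy_vocabulary()]).
#' @return character vector of therapy classes.
#' @export
classify_therapy <- function(annotation, vocab = therapy_vocabulary()) {
  key <- tolower(trimws(annotation))
  i <- match(key, tolower(trimws(vocab$annotation)))
  ifelse(is.na(i), "other", vocab$therapy_class[i])
}
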