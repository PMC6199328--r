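test_that("expressed filter applies a strict 90th-percentile cutoff", {
  v <- cbind(gA = rep(31, 10), gB = rep(30, 10),
             gC = c(rep(0, 9), 1000))
  rownames(v) <- sprintf("S%02d", 1:10)
  kept <- expressed_filter(make_em(v))
  expect_true("gA" %in% kept)      # 90th pct 31 > 30
  expect_false("gB" %in% kept)     # exactly 30: strict
  # linear-interpolation oracle for the mostly-zero gene
  q <- stats::quantile(v[, "gC"], 0.9, names = FALSE)
  expect_equal("gC" %in% kept, q > 30)
  expect_length(expressed_filter(make_em(v[, 0, drop = FALSE])), 0)
})

test_that("per-exon t-statistics vanish on identical groups and negate on label swap", {
  set.seed(5)
  v <- matrix(stats::rlnorm(6 * 4, 4, 0.5), 6, 4)
  v[4:6, ] <- v[1:3, ]      # identical groups
  dimnames(v) <- list(sprintf("S%d", 1:6), sprintf("gA:%02d", 1:4))
  fm <- data.frame(feature_id = colnames(v), exon_index = 1:4)
  em <- expr_matrix(v, stats::setNames(rep("gA", 4), colnames(v)), fm)
  lab <- stats::setNames(rep(c("TEdeff", "TEprof"), each = 3), rownames(v))
  ts <- exon_t_stats(em, lab)
  expect_equal(ts$stat, rep(0, 4))
  v2 <- matrix(stats::rlnorm(6 * 4, 4, 0.5), 6, 4, dimnames = dimnames(v))
  em2 <- expr_matrix(v2, stats::setNames(rep("gA", 4), colnames(v)), fm)
  swapped <- stats::setNames(ifelse(lab == "TEdeff", "TEprof", "TEdeff"),
                             names(lab))
  expect_equal(exon_t_stats(em2, lab)$stat, -exon_t_stats(em2, swapped)$stat)
  # zero-variance exons are flagged with t = 0
  v3 <- v2; v3[, 2] <- 7
  em3 <- expr_matrix(v3, stats::setNames(rep("gA", 4), colnames(v)), fm)
  ts3 <- exon_t_stats(em3, lab)
  expect_true(ts3$zero_var[2]); expect_equal(ts3$stat[2], 0)
})

test_that("bin20 is identity at 20 exons, pairwise means at 40, duplication at 10", {
  x20 <- stats::rnorm(20)
  expect_equal(bin20(x20), x20)
  x40 <- stats::rnorm(40)
  expect_equal(bin20(x40), colMeans(matrix(x40, 2)))
  x10 <- stats::rnorm(10)
  # nearest-position oracle: enumerate all 10 x 20 assignments
  pos <- (1:10 - 0.5) / 10; centers <- (1:20 - 0.5) / 20
  oracle <- x10[apply(abs(outer(pos, centers, "-")), 2, which.min)]
  expect_equal(bin20(x10), oracle)
  expect_equal(bin20(x10), rep(x10, each = 2))
  expect_error(bin20(numeric(0)), "empty")
})

test_that("bin20 preserves the mean under even compression", {
  for (n in c(20, 40, 60, 100)) {
    x <- stats::rnorm(n)
    expect_equal(mean(bin20(x)), mean(x), tolerance = 1e-12)
  }
})

test_that("gene class calls follow the body-loss / terminal-gain rule", {
  mk <- function(bins) {
    m <- matrix(bins, 1, 20, dimnames = list(NULL, sprintf("bin%02d", 1:20)))
    data.frame(gene_id = "g", m, body_mean_t = mean(bins[2:17]),
               terminal_t = bins[20], overall_mean_t = mean(bins))
  }
  expect_equal(call_gene_classes(mk(rep(3, 20)))$gene_class, "II")
  expect_equal(call_gene_classes(mk(c(3, rep(-3, 18), 3)))$gene_class, "I")
  expect_equal(call_gene_classes(mk(rep(0, 20)))$gene_class, "neutral")
})

test_that("planted Class I profile has negative body and positive terminal t", {
  b <- generate_cohort(cohort_config(seed = 12), components = "exons")
  lab <- b$truth$labels
  ts <- exon_t_stats(b$exon_expr, lab)
  prof <- exon_bin_profiles(ts)
  cls1 <- prof[prof$gene_id %in%
                 names(b$truth$gene_class)[b$truth$gene_class == "I"], ]
  expect_true(all(cls1$body_mean_t < 0))
  expect_true(all(cls1$terminal_t > 0))
  called <- call_gene_classes(prof)
  tab <- table(planted = b$truth$gene_class[called$gene_id],
               called = called$gene_class)
  expect_gte(tab["I", "I"] / sum(tab["I", ]), 0.85)
  expect_gte(tab["I", "I"] / sum(tab[, "I"]), 0.85)
})

test_that("5'->3' bin vectors are invariant under strand mirroring of the locus", {
  ex_plus <- cbind(seq(1000, 10000, by = 1000), seq(1200, 10200, by = 1000))
  vals <- stats::rnorm(10)            # value of exon k in transcription order
  m <- 20000                          # mirror coordinate
  ex_minus <- cbind(m - ex_plus[, 2], m - ex_plus[, 1])
  gp <- gene_model("gp", "chr1", "+", ex_plus)
  gm <- gene_model("gm", "chr1", "-", ex_minus)
  # genomic-order exon values: + gene ascending = transcription order; the
  # mirrored - gene stores the same biology reversed in genomic order
  genomic_vals_minus <- rev(vals)
  tx_minus <- genomic_vals_minus[match(
    exons_tx_order(gm)[, 1], gm$exons[, 1])]
  expect_equal(bin20(tx_minus), bin20(vals))
  expect_equal(gm$tss, m - gp$tss - 1)  # mirrored TSS base
})

test_that("class feature contrast recovers planted length differences", {
  b <- generate_cohort(cohort_config(seed = 12), components = "exons")
  cls <- data.frame(gene_id = names(b$truth$gene_class),
                    gene_class = unname(b$truth$gene_class))
  con <- class_feature_contrast(cls, b$models)
  expect_gt(con$summary$median_length[1], con$summary$median_length[2])
  expect_lt(con$length_test$p.value, 0.01)
  # single-exon gene spanning its locus has density 1
  g1 <- gene_model("g1", "chr1", "+", cbind(100, 600))
  expect_equal(g1$mrna_length / g1$genomic_length, 1)
  # identical memberships -> t = 0
  same <- class_feature_contrast(
    data.frame(gene_id = rep(cls$gene_id[1:4], 2),
               gene_class = rep(c("I", "II"), each = 4)), b$models)
  expect_equal(unname(same$length_test$statistic), 0)
})

test_that("methylation meta-profile recovers planted promoter/body pattern and mirrors on swap", {
  b <- generate_cohort(cohort_config(seed = 13), components = "methylation")
  lab <- b$truth$labels
  mp <- methylation_metaprofile(b$methylation$beta, b$methylation$positions, lab)
  expect_lt(mean(mp$t[mp$mid > -0.5 & mp$mid < 0.1], na.rm = TRUE), -2)
  expect_gt(mean(mp$t[mp$mid > 0.3 & mp$mid < 0.75], na.rm = TRUE), 2)
  swapped <- stats::setNames(ifelse(lab == "TEdeff", "TEprof", "TEdeff"),
                             names(lab))
  mp2 <- methylation_metaprofile(b$methylation$beta, b$methylation$positions,
                                 swapped)
  expect_equal(mp2$t, -mp$t)
  # identical group distributions -> flat zero profile
  beta_small <- matrix(stats::runif(30 * 3, 0.2, 0.8), 30, 3)
  beta_small <- cbind(beta_small, beta_small)
  dimnames(beta_small) <- list(sprintf("cg%02d", 1:30), sprintf("S%d", 1:6))
  lab_small <- stats::setNames(rep(c("TEdeff", "TEprof"), each = 3),
                               colnames(beta_small))
  mp3 <- methylation_metaprofile(beta_small, stats::runif(30, -1, 2),
                                 lab_small, breaks = seq(-1, 2, by = 0.5))
  expect_equal(mp3$t[!is.na(mp3$t)],
               rep(0, sum(!is.na(mp3$t))))
})
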