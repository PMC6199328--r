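.uniform_track <- function(depth = 4, chrom = "chrT", lo = 0, hi = 5e4,
                           library_size = 1e6) {
  coverage_track(data.frame(chrom = chrom, start = lo, end = hi,
                            depth = depth), library_size = library_size)
}

test_that("uniform coverage gives a flat metagene profile at d*1e6/L", {
  g <- list(g1 = gene_model("g1", "chrT", "+", cbind(10000, 20000)),
            g2 = gene_model("g2", "chrT", "-", cbind(25000, 36000)))
  tr <- .uniform_track(depth = 4, library_size = 2e6)
  mp <- metagene_profile(tr, g)
  expect_equal(nrow(mp), 40 + 101 + 40)
  expect_equal(mp$mean_depth, rep(4 * 1e6 / 2e6, nrow(mp)))
})

test_that("metagene profiles orient minus-strand genes 5' to 3'", {
  # depth ramp rising toward smaller coordinates over a minus-strand gene
  runs <- data.frame(chrom = "chrT",
                     start = seq(10000, 19000, by = 1000),
                     end = seq(11000, 20000, by = 1000),
                     depth = 10:1)
  tr <- coverage_track(runs, library_size = 1e6)
  g <- list(g = gene_model("g", "chrT", "-", cbind(10000, 20000)))
  mp <- metagene_profile(tr, g, flank = 500)
  body <- mp$mean_depth[mp$position >= 0 & mp$position <= 1]
  expect_gt(stats::cor(seq_along(body), body), 0.95)  # rises toward 3'
})

test_that("a triangular TSS peak puts the profile maximum at the TSS grid point", {
  # symmetric triangle peaking exactly at the TSS base
  tss <- 10000
  pos <- (tss - 500):(tss + 500)
  runs <- data.frame(chrom = "chrT", start = pos, end = pos + 1,
                     depth = 500 - abs(pos - tss))
  tr <- coverage_track(runs, library_size = 1e6)
  g <- list(g = gene_model("g", "chrT", "+", cbind(tss, tss + 10000)))
  mp <- metagene_profile(tr, g, flank = 1000)
  expect_equal(mp$position[which.max(mp$mean_depth)], 0)
})

test_that("metagene profile is invariant to scaling the whole track", {
  g <- list(g = gene_model("g", "chrT", "+", cbind(10000, 20000)))
  runs <- data.frame(chrom = "chrT", start = seq(9000, 21000, by = 500),
                     end = seq(9500, 21500, by = 500),
                     depth = stats::runif(25, 1, 10))
  t1 <- coverage_track(runs)
  runs2 <- runs; runs2$depth <- runs2$depth * 7
  t2 <- coverage_track(runs2)
  # library size estimated from the track area scales identically
  expect_equal(metagene_profile(t2, g)$mean_depth,
               metagene_profile(t1, g)$mean_depth)
})

test_that("traveling ratio is 1 on uniform coverage and 0 when signal is TSS-only", {
  g <- gene_model("g", "chrT", "+", cbind(10000, 20000))
  expect_equal(traveling_ratio(.uniform_track(), g)$tr, 1)
  tssonly <- coverage_track(data.frame(chrom = "chrT", start = 9700,
                                       end = 10301, depth = 8),
                            library_size = 1e6)
  expect_equal(traveling_ratio(tssonly, g)$tr, 0)
  # scale invariance
  t1 <- coverage_track(data.frame(chrom = "chrT",
                                  start = c(9700, 10301),
                                  end = c(10301, 20000),
                                  depth = c(10, 3)))
  t2 <- coverage_track(data.frame(chrom = "chrT",
                                  start = c(9700, 10301),
                                  end = c(10301, 20000),
                                  depth = c(50, 15)))
  expect_equal(traveling_ratio(t1, g)$tr, traveling_ratio(t2, g)$tr)
  # zero TSS occupancy -> NA
  bodyonly <- coverage_track(data.frame(chrom = "chrT", start = 15000,
                                        end = 16000, depth = 5),
                             library_size = 1e6)
  expect_true(is.na(traveling_ratio(bodyonly, g)$tr))
})

test_that("planted traveling-ratio groups order correctly on nearly every gene", {
  b <- generate_cohort(cohort_config(n_samples = 8, n_genes = 40, seed = 16),
                       components = "coverage")
  lab <- b$truth$labels
  td <- names(lab)[lab == "TEdeff"][1]
  tp <- names(lab)[lab == "TEprof"][1]
  tr_td <- traveling_ratio_all(b$coverage[[td]], b$models)$tr
  tr_tp <- traveling_ratio_all(b$coverage[[tp]], b$models)$tr
  expect_gte(mean(tr_td < tr_tp, na.rm = TRUE), 0.95)
})

test_that("bedGraph round-trips through the coverage track container", {
  runs <- data.frame(chrom = "chrT", start = c(100, 500), end = c(300, 900),
                     depth = c(2.5, 4))
  path <- file.path(tempdir(), "t.bedGraph")
  write_bedgraph(coverage_track(runs, library_size = 10), path)
  back <- read_bedgraph(path, library_size = 10)
  expect_equal(back$runs$start, runs$start)
  expect_equal(back$runs$end, runs$end)
  expect_equal(back$runs$depth, runs$depth)
})

test_that("occupancy-expression correlation hits the rank extremes and the null", {
  set.seed(41)
  n <- 1000
  occ <- stats::runif(n, 1, 100)
  trs <- data.frame(gene_id = sprintf("g%04d", 1:n),
                    tss_occupancy = 1, body_occupancy = occ, tr = occ)
  mono <- matrix(occ^2, 1, n,
                 dimnames = list("S1", trs$gene_id))  # monotone transform
  expect_equal(occupancy_expression_correlation(trs, make_em(mono), "S1")$rho, 1)
  indep <- matrix(stats::runif(n), 1, n, dimnames = dimnames(mono))
  expect_lt(abs(occupancy_expression_correlation(trs, make_em(indep),
                                                 "S1")$rho), 0.1)
})

test_that("coupled samples correlate occupancy with expression more than decoupled ones", {
  set.seed(43)
  n <- 300
  occ <- stats::rlnorm(n, 3, 0.5)
  trs <- data.frame(gene_id = sprintf("g%04d", 1:n), tss_occupancy = 1,
                    body_occupancy = occ, tr = occ)
  coupled <- occ * stats::rlnorm(n, 0, 0.2)
  decoupled <- sample(occ) * stats::rlnorm(n, 0, 0.2)
  v <- rbind(parental = coupled, perturbed = decoupled)
  colnames(v) <- trs$gene_id
  em <- make_em(v)
  rho_p <- occupancy_expression_correlation(trs, em, "parental")$rho
  rho_d <- occupancy_expression_correlation(trs, em, "perturbed")$rho
  expect_gt(rho_p, rho_d)
  expect_gt(rho_p, 0.8)
})
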