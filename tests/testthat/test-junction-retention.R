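# toy gene: exons [1000,1200) and [1800,2000) -> donor 1200, acceptor 1800,
# intron length 600 (eligible: > 500)

test_that("junction counts match the brute-force per-read scanner on boundary fixtures", {
  g <- toy_gene()
  reads <- list(
    # spliced, 25/25 anchors
    sam_record(1176, "25M600N25M"),
    # spliced with anchors 7/8/9 on the left exon
    sam_record(1194, "7M600N43M"),
    sam_record(1193, "8M600N42M"),
    sam_record(1192, "9M600N41M"),
    # spliced with anchors 7/8/9 on the right exon
    sam_record(1158, "43M600N7M"),
    sam_record(1159, "42M600N8M"),
    sam_record(1160, "41M600N9M"),
    # MAPQ boundary on a valid spliced read
    sam_record(1176, "25M600N25M", mapq = 19),
    sam_record(1176, "25M600N25M", mapq = 20),
    sam_record(1176, "25M600N25M", mapq = 21),
    # unspliced exon-intron reads straddling the donor (20/30 split)
    sam_record(1181, "50M"),
    sam_record(1181, "50M"),
    # donor straddle with exactly 8/intron-side-8 coverage limits
    sam_record(1193, "50M"),   # 8 exon bases, 42 intron bases
    sam_record(1194, "50M"),   # 7 exon bases: below anchor
    sam_record(1159, "50M"),   # 42 exon, 8 intron
    sam_record(1158, "50M"),   # 43 exon, 7 intron: below anchor
    # intron-exon straddle at the acceptor
    sam_record(1781, "50M"),
    # straddle too far from the boundary (starts 151 bp before donor)
    sam_record(1050, "350M"),
    # soft-clipped and insertion-bearing variants
    sam_record(1176, "5S25M600N25M"),
    sam_record(1176, "12M3I13M600N25M"),
    # deletion interrupting the window around the donor
    sam_record(1181, "15M5D35M"),
    # gap not matching the annotated intron
    sam_record(1176, "25M500N25M"),
    # unsupported op: skipped
    sam_record(1176, "25M600N25M2H")
  )
  sam <- do.call(rbind, reads)
  got <- count_junctions(sam, g)
  want <- oracle_count_junctions(sam, g)
  expect_equal(got$ee, want$ee)
  expect_equal(got$ei, want$ei)
  expect_equal(got$ie, want$ie)
  # frozen expectations: 25/25, left anchors 8/9, right anchors 8/9,
  # MAPQ 21, soft-clipped, insertion-bearing = 8 spliced reads
  expect_equal(got$ee, 8L)
  expect_equal(got$ei, 4L)  # two 20/30 straddles + the two exact-8 limits
  expect_equal(got$ie, 1L)
  expect_equal(attr(got, "skipped"), 1L)
})

test_that("junction counting equals the oracle on randomized toy SAMs", {
  set.seed(21)
  g2 <- gene_model("TG2", "chrT", "-",
                   cbind(c(3000, 4000, 5200), c(3300, 4400, 5500)))
  for (rep in 1:5) {
    n <- 100
    pos <- sample(2800:5600, n, replace = TRUE)
    kind <- sample(3, n, replace = TRUE)
    cigar <- ifelse(kind == 1, "50M",
             ifelse(kind == 2,
                    sprintf("%dM%dN%dM", sample(4:46, n, TRUE),
                            sample(c(600, 700, 800), n, TRUE),
                            sample(4:46, n, TRUE)),
                    sprintf("%dM%dD%dM", sample(5:20, n, TRUE), 5,
                            sample(5:20, n, TRUE))))
    sam <- data.frame(qname = sprintf("r%03d", 1:n), flag = 0L,
                      rname = "chrT", pos = pos,
                      mapq = sample(c(19, 20, 21, 60), n, TRUE),
                      cigar = cigar, stringsAsFactors = FALSE)
    got <- count_junctions(sam, g2)
    want <- oracle_count_junctions(sam, g2)
    expect_equal(got$ee, want$ee)
    expect_equal(got$ei, want$ei)
    expect_equal(got$ie, want$ie)
  }
})

test_that("SAM reading drops headers and unmapped records, flags malformed lines", {
  path <- file.path(tempdir(), "t.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrT\tLN:10000",
               "r1\t0\tchrT\t1176\t60\t25M600N25M\t*\t0\t0\tAAA\tIII",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\tAAA\tIII"), path)
  sam <- read_sam(path)
  expect_equal(nrow(sam), 1)
  expect_equal(sam$cigar, "25M600N25M")
  writeLines(c("r1\t0\tchrT"), path)
  expect_error(read_sam(path), "malformed")
})

test_that("retention score applies eligibility rules and arithmetic", {
  counts <- data.frame(gene_id = c("g1", "g1", "g2"),
                       donor = c(1, 2, 3), acceptor = c(10, 20, 30),
                       ee = c(10L, 4L, 7L), ei = c(1L, 100L, 0L),
                       ie = c(1L, 50L, 0L),
                       intron_length = c(600, 900, 700))
  # junction 2 ineligible (ee < 5) despite huge EI counts
  expect_equal(retention_score(counts), (1 + 1 + 0) / (10 + 7))
  expect_equal(retention_score(counts, gene_set = "g1"), 0.2)
  # all reads spliced -> ratio 0
  spliced <- counts; spliced$ei <- 0L; spliced$ie <- 0L
  expect_equal(retention_score(spliced), 0)
  # short intron excluded
  short_intron <- counts; short_intron$intron_length <- c(500, 900, 400)
  expect_warning(out <- retention_score(short_intron, gene_set = "g1"),
                 "no eligible")
  expect_true(is.na(out))
})

test_that("adding an eligible unspliced read never decreases the retention score", {
  set.seed(9)
  for (i in 1:20) {
    counts <- data.frame(gene_id = "g", donor = 1:3, acceptor = 11:13,
                         ee = sample(5:30, 3), ei = sample(0:5, 3),
                         ie = sample(0:5, 3), intron_length = c(600, 800, 1000))
    before <- retention_score(counts)
    j <- sample(3, 1)
    counts$ei[j] <- counts$ei[j] + 1L
    expect_gte(retention_score(counts), before)
  }
})

test_that("median split halves distinct scores and sends ties to the low group", {
  s4 <- stats::setNames(c(1, 2, 3, 4), paste0("S", 1:4))
  sp <- median_split(s4)
  expect_setequal(sp$high, c("S3", "S4"))
  st <- stats::setNames(c(1, 1, 1, 2), paste0("S", 1:4))
  spt <- median_split(st)
  expect_equal(spt$high, "S4")
  expect_error(median_split(stats::setNames(rep(2, 4), paste0("S", 1:4))),
               "degenerate")
})

test_that("planted retention-rate groups separate in the synthetic cohort", {
  seeds <- 1:3
  sep <- vapply(seeds, function(sd) {
    b <- generate_cohort(cohort_config(n_samples = 12, n_genes = 40, seed = sd),
                         components = "sam")
    class1 <- names(b$truth$gene_class)[b$truth$gene_class == "I"]
    sc <- vapply(names(b$truth$labels), function(s)
      retention_score(count_junctions_all(b$sam[[s]], b$models[class1]),
                      class1), numeric(1))
    lab <- b$truth$labels[names(sc)]
    stats::median(sc[lab == "TEdeff"]) > stats::median(sc[lab == "TEprof"])
  }, logical(1))
  expect_true(all(sep))
})
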