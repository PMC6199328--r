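#!/usr/bin/env Rscript
# Step 3 -- differential exon profiles, Class I/II calls, methylation.
#
# Builds the 5'->3' 20-bin exon t-statistic profiles (TEdeff vs TEprof),
# calls Class I (body loss + terminal gain) and Class II (overexpressed)
# genes, contrasts their genomic lengths and exon densities, and computes
# the transcript-relative methylation meta-profile.  Outputs:
# results/exon_bin_profiles.tsv, results/gene_classes.tsv,
# results/class_contrast.tsv, results/methylation_profile.tsv.

suppressMessages(library(tedeff))

exon_expr <- read_expression_tsv("results/cohort/exon_rpkm.tsv")
gene_expr <- read_expression_tsv("results/cohort/gene_expr.tsv")
models <- read_annotation("results/cohort/annotation.gtf")
calls <- read.table("results/tedeff_calls.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
labels <- stats::setNames(calls$label, calls$sample_id)

expressed <- expressed_filter(gene_expr)
tstats <- exon_t_stats(exon_expr, labels)
tstats <- tstats[tstats$gene_id %in% expressed, ]
profiles <- call_gene_classes(exon_bin_profiles(tstats))
write.table(profiles, "results/exon_bin_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(profiles[, c("gene_id", "gene_class")],
            "results/gene_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

con <- class_feature_contrast(profiles, models)
write.table(con$summary, "results/class_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

beta_tab <- read.table("results/cohort/methylation_beta.tsv", header = TRUE,
                       sep = "\t", check.names = FALSE)
beta <- as.matrix(beta_tab[, -(1:2)])
rownames(beta) <- beta_tab$probe_id
mp <- methylation_metaprofile(beta, beta_tab$rel_pos, labels)
write.table(mp, "results/methylation_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("expressed genes: %d of %d\n", length(expressed),
            length(unique(exon_expr$feature_gene))))
cat(sprintf("gene classes: %d Class I, %d Class II, %d neutral\n",
            sum(profiles$gene_class == "I"),
            sum(profiles$gene_class == "II"),
            sum(profiles$gene_class == "neutral")))
cat(sprintf("Class I vs II genomic length t-test p = %.3g\n",
            con$length_test$p.value))
cat(sprintf("methylation profile: min t %.1f (promoter), max t %.1f (body)\n",
            min(mp$t, na.rm = TRUE), max(mp$t, na.rm = TRUE)))
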