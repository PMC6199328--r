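#!/usr/bin/env Rscript
# Step 1 -- simulate the study cohort.
#
# Generates the default synthetic cohort (60 tumors, 25% TEdeff, 120 genes
# with planted Class I/II structure and AT-gene isoform switching) and
# writes every component in its standard text format under results/cohort/.
# Downstream steps read these files, mimicking a run on real data exports.

suppressMessages(library(tedeff))

out <- "results/cohort"
cfg <- cohort_config(seed = 20260923)
bundle <- generate_cohort(cfg, out_dir = out)

lab <- table(bundle$truth$labels)
cls <- table(bundle$truth$gene_class)
cat(sprintf("cohort written to %s\n", out))
cat(sprintf("samples: %d TEdeff / %d TEprof\n", lab["TEdeff"], lab["TEprof"]))
cat(sprintf("genes: %d Class I, %d Class II, %d neutral; %d AT genes\n",
            cls["I"], cls["II"], cls["neutral"],
            length(bundle$truth$at_genes)))
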