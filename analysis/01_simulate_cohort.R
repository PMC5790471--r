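#!/usr/bin/env Rscript

# Step 1 - simulate the paired cohort.
#
# Generates the default 16-pair primary/liver-metastasis cohort (10
# treatment-naive and 6 post-therapy metastases, 4 pairs with WGD in both
# samples and 5 with metastasis-only WGD) on the scaled 22 x 5 Mb genome,
# together with a 188-gene candidate panel and 24 actionable genes, and
# writes all inputs the downstream steps consume. Raw per-sample profiles go
# under scratch/ (they are regenerable); the ground-truth summary goes to
# results/ for comparison in later steps.

suppressPackageStartupMessages(library(pairedcna))

seed <- 20260101 %% 100000
datadir <- "scratch/simdata"
dir.create("results", showWarnings = FALSE)

message("simulating 16-pair cohort with seed ", seed)
co <- simulate_cohort(seed = seed, outdir = datadir)

message("cohort written to ", datadir, ":")
message("  ", nrow(co$sheet), " pairs, ",
        length(co$profiles), " profiles, ",
        nrow(co$genes), " genes, genome ",
        round(genome_size(co$layout) / 1e6), " Mb")

truth <- read.delim(file.path(datadir, "ground_truth.tsv"))
write.table(truth, "results/01_ground_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("planted per-pair ground truth copied to results/01_ground_truth.tsv")
message(sprintf("  planted CN discordance: mean %.3f (range %.3f-%.3f)",
                mean(truth$cn_discordant_fraction),
                min(truth$cn_discordant_fraction),
                max(truth$cn_discordant_fraction)))
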