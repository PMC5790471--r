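#!/usr/bin/env Rscript

# Step 5 - cohort summary and group comparisons.
#
# Collects per-pair discordance, WGD calls and genome fractions into one
# cohort table and runs two-tailed pooled-variance t-tests between exposure
# groups (treatment-naive vs post-therapy metastasis) and timing groups
# (synchronous vs metachronous), reporting raw p-values.

suppressPackageStartupMessages(library(pairedcna))

datadir <- "scratch/simdata"
lay <- read_chrom_sizes(file.path(datadir, "chrom_sizes.tsv"))
sheet <- read_sample_sheet(file.path(datadir, "sample_sheet.tsv"))
grid <- tile_genome(lay, 10000)

profiles <- list()
for (s in c(rbind(sheet$primary_sample, sheet$met_sample))) {
  profiles[[s]] <- read_profile(
    file.path(datadir, "profiles", paste0(s, ".seg.tsv")), lay)
}
wgd <- lapply(profiles, detect_wgd, layout = lay)
fr <- lapply(profiles, genome_fractions)
disc <- list()
for (i in seq_len(nrow(sheet))) {
  tp <- suppressWarnings(assign_windows(profiles[[sheet$primary_sample[i]]],
                                        grid))
  tm <- suppressWarnings(assign_windows(profiles[[sheet$met_sample[i]]],
                                        grid))
  disc[[sheet$patient_id[i]]] <-
    compare_pair(tp, tm, patient_id = sheet$patient_id[i])
}

tab <- summarize_cohort(sheet, disc, wgd, fr)
write.table(as.data.frame(tab), "results/05_cohort_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(attr(tab, "summary"), "results/05_cohort_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

comparisons <- list(
  compare_groups(tab, "cn_discordant_fraction", "met_exposure"),
  compare_groups(tab, "loh_met_only_fraction", "met_exposure"),
  compare_groups(tab, "loh_primary_only_fraction", "met_exposure"),
  compare_groups(tab, "cn_discordant_fraction", "timing"))
ct <- comparison_table(comparisons)
write.table(ct, "results/05_group_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("cohort tables written to results/05_*.tsv")
message(sprintf("  average CN discordance: %.1f%%",
                100 * mean(tab$cn_discordant_fraction)))
message(sprintf("  average LOH difference: %.1f%%",
                100 * mean(tab$loh_difference_fraction)))
for (cmp in comparisons) {
  message(sprintf("  %s by %s: means %.3f vs %.3f, t = %.2f, p = %.4g%s",
                  cmp$metric, cmp$grouping, cmp$means[1], cmp$means[2],
                  cmp$t, cmp$p_value, if (cmp$significant) " *" else ""))
}
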