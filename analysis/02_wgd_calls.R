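#!/usr/bin/env Rscript

# Step 2 - whole-genome-duplication calls and genome fractions.
#
# For every sample: the WGD decision (>70% of at least half the chromosomes
# at total copy number 3-4 with both parental alleles present), the
# diagnostic genome fraction of (3,4)-biallelic sequence, and the
# genome-altered / LOH fractions that correspond to the per-sample bar
# charts of a cohort report.

suppressPackageStartupMessages(library(pairedcna))

datadir <- "scratch/simdata"
lay <- read_chrom_sizes(file.path(datadir, "chrom_sizes.tsv"))
sheet <- read_sample_sheet(file.path(datadir, "sample_sheet.tsv"))

samples <- c(rbind(sheet$primary_sample, sheet$met_sample))
rows <- lapply(samples, function(s) {
  p <- read_profile(file.path(datadir, "profiles", paste0(s, ".seg.tsv")),
                    lay)
  w <- detect_wgd(p, lay)
  f <- genome_fractions(p)
  data.frame(sample_id = s, is_wgd = w$is_wgd,
             qualifying_chromosomes = w$qualifying_chromosomes,
             genome_fraction_34_biallelic =
               round(w$genome_fraction_34_biallelic, 4),
             altered_fraction = round(f[["altered_fraction"]], 4),
             loh_fraction = round(f[["loh_fraction"]], 4))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/02_wgd_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

met <- tab$sample_id %in% sheet$met_sample
message("WGD calls written to results/02_wgd_calls.tsv")
message("  WGD metastases: ", sum(tab$is_wgd[met]),
        " of ", sum(met), "; WGD primaries: ", sum(tab$is_wgd[!met]),
        " of ", sum(!met))
message(sprintf("  altered genome fraction: %.1f-%.1f%% across samples",
                100 * min(tab$altered_fraction),
                100 * max(tab$altered_fraction)))
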