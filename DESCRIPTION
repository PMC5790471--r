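Package: pairedcna
Title: Paired Primary-Metastasis Allele-Specific Copy-Number Discordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares allele-specific somatic copy-number profiles of paired
    primary colorectal tumors and liver metastases. Provides five-category
    copy-number state classification (homozygous deletion, loss, copy-neutral
    LOH, gain, amplification), whole-genome-duplication calling from the
    fraction of chromosomes at 3-4 copies with both parental alleles present,
    10 kb windowed paired discordance with a +1/+2 whole-genome-duplication
    correction, three-way loss-of-heterozygosity discordance classification,
    gene-panel copy-number status and metastasis-private event tabulation,
    cohort summaries with two-sample t-tests, and a synthetic paired-profile
    generator with planted, independently recomputed ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
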