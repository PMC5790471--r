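gene_row <- function(symbol, chrom, start, end, panel = NA_character_) {
  data.frame(symbol = symbol, chromosome = chrom, start = start, end = end,
             panel = panel, stringsAsFactors = FALSE)
}

two_pair_sheet <- function() {
  data.frame(patient_id = c("P1", "P2"),
             primary_sample = c("P1-T", "P2-T"),
             met_sample = c("P1-M", "P2-M"),
             timing = "synchronous", met_exposure = "naive",
             stringsAsFactors = FALSE)
}

test_that("gene status comes from the largest segment over the footprint", {
  lay <- genome_layout("chr1", 50000)
  genes <- gene_row("G1", "chr1", 10000, 20000)
  # fully inside an amplified segment
  st <- gene_status(mk_profile(seg_row("chr1", 0, 50000, 6, 1), lay, "S"),
                    genes)
  expect_equal(as.character(st$category), "AMP")
  # 7 kb of (2,1) beats 3 kb of (4,2)
  seg <- rbind(seg_row("chr1", 0, 17000, 2, 1),
               seg_row("chr1", 17000, 50000, 4, 2))
  st <- gene_status(mk_profile(seg, lay, "S"), genes)
  expect_equal(as.character(st$category), "NEUTRAL_HET")
  expect_equal(st$seg_start, 0)
  # no overlapping segment -> missing
  st <- gene_status(mk_profile(seg_row("chr1", 30000, 50000, 3, 1), lay, "S"),
                    genes)
  expect_true(is.na(st$total_cn))
  expect_true(is.na(st$category))
})

test_that("a gene coinciding with one window matches the window engine", {
  lay <- genome_layout("chr1", 50000)
  set.seed(411)
  for (rep in 1:8) {
    seg <- rand_segments(lay)
    grid <- tile_genome(lay, 10000)
    track <- assign_windows(mk_profile(seg, lay, "S"), grid)
    genes <- gene_row("G1", "chr1", grid$start[3], grid$end[3])
    st <- gene_status(mk_profile(seg, lay, "S"), genes)
    expect_equal(st$total_cn, track$total_cn[3])
    expect_equal(st$minor_cn, track$minor_cn[3])
  }
})

test_that("metastasis-private events follow their definitions", {
  lay <- genome_layout("chr1", 50000)
  genes <- gene_row("G1", "chr1", 10000, 20000)
  sheet <- two_pair_sheet()[1, ]
  st <- rbind(
    gene_status(mk_profile(seg_row("chr1", 0, 50000, 2, 1), lay, "P1-T"), genes),
    gene_status(mk_profile(seg_row("chr1", 0, 50000, 7, 1), lay, "P1-M"), genes))
  pe <- private_events(sheet, st, genes)
  expect_equal(pe$amp_private_to_met, 1)
  expect_equal(pe$loss_private_to_met, 0)
  expect_equal(pe$amp_private_fmt, "1/1 (100.0 %)")
  # event of the same class in both samples is not private
  st2 <- rbind(
    gene_status(mk_profile(seg_row("chr1", 0, 50000, 3, 1), lay, "P1-T"), genes),
    gene_status(mk_profile(seg_row("chr1", 0, 50000, 5, 2), lay, "P1-M"), genes))
  expect_equal(private_events(sheet, st2, genes)$amp_private_to_met, 0)
  # strict mode: a GAIN no longer counts as amplification
  st3 <- rbind(
    gene_status(mk_profile(seg_row("chr1", 0, 50000, 2, 1), lay, "P1-T"), genes),
    gene_status(mk_profile(seg_row("chr1", 0, 50000, 4, 1), lay, "P1-M"), genes))
  expect_equal(private_events(sheet, st3, genes)$amp_private_to_met, 1)
  expect_equal(private_events(sheet, st3, genes, strict = TRUE)$amp_private_to_met, 0)
  # under the WGD correction a +2 biallelic gain is not a private event
  expect_equal(private_events(sheet, st3, genes,
                              wgd_correction = TRUE)$amp_private_to_met, 0)
})

test_that("per-gene outcomes partition the evaluable pairs", {
  set.seed(412)
  lay <- toy_layout(2, 50000)
  genes <- rbind(gene_row("G1", "chr1", 5000, 15000),
                 gene_row("G2", "chr2", 20000, 30000))
  sheet <- two_pair_sheet()
  statuses <- do.call(rbind, lapply(c("P1-T", "P1-M", "P2-T", "P2-M"),
    function(s) gene_status(mk_profile(rand_segments(lay, gap_prob = 0), lay, s),
                            genes)))
  pe <- private_events(sheet, statuses, genes)
  for (g in genes$symbol) {
    sub <- statuses[statuses$symbol == g, ]
    amp <- setNames(as.character(sub$category) %in% c("GAIN", "AMP"),
                    sub$sample_id)
    both <- sum(amp["P1-M"] & amp["P1-T"], amp["P2-M"] & amp["P2-T"])
    met_only <- sum(amp["P1-M"] & !amp["P1-T"], amp["P2-M"] & !amp["P2-T"])
    prim_only <- sum(!amp["P1-M"] & amp["P1-T"], !amp["P2-M"] & amp["P2-T"])
    none <- sum(!amp["P1-M"] & !amp["P1-T"], !amp["P2-M"] & !amp["P2-T"])
    expect_equal(pe$amp_private_to_met[pe$symbol == g], met_only)
    expect_equal(met_only + both + prim_only + none,
                 pe$n_pairs[pe$symbol == g])
  }
  # invariant under reordering genes and pairs
  pe2 <- private_events(sheet[2:1, ], statuses, genes[2:1, ])
  expect_equal(pe[order(pe$symbol), ]$amp_private_to_met,
               pe2[order(pe2$symbol), ]$amp_private_to_met)
})

test_that("cohort gene concordance requires agreement in every pair", {
  lay <- genome_layout("chr1", 50000)
  genes <- rbind(gene_row("G1", "chr1", 5000, 15000),
                 gene_row("G2", "chr1", 30000, 40000))
  sheet <- two_pair_sheet()[1, ]
  # both genes identical -> fraction 1
  p <- mk_profile(seg_row("chr1", 0, 50000, 2, 1), lay, "P1-T")
  m <- mk_profile(seg_row("chr1", 0, 50000, 2, 1), lay, "P1-M")
  cc <- concordance_rate(sheet, rbind(gene_status(p, genes),
                                      gene_status(m, genes)), genes)
  expect_equal(cc$fraction, 1)
  # one of two genes discordant -> 1/2
  m2 <- mk_profile(rbind(seg_row("chr1", 0, 25000, 2, 1),
                         seg_row("chr1", 25000, 50000, 1, 0)), lay, "P1-M")
  cc2 <- concordance_rate(sheet, rbind(gene_status(p, genes),
                                       gene_status(m2, genes)), genes)
  expect_equal(cc2$n_genes, 2)
  expect_equal(cc2$n_concordant, 1)
  expect_equal(cc2$fraction, 0.5)
})

test_that("pairs with a missing gene status drop out of that gene only", {
  lay <- genome_layout("chr1", 50000)
  genes <- rbind(gene_row("G1", "chr1", 5000, 15000),
                 gene_row("G2", "chr1", 30000, 40000))
  sheet <- two_pair_sheet()[1, ]
  p <- mk_profile(seg_row("chr1", 0, 50000, 2, 1), lay, "P1-T")
  m <- mk_profile(seg_row("chr1", 0, 20000, 7, 2), lay, "P1-M")  # G2 uncovered
  st <- rbind(gene_status(p, genes), gene_status(m, genes))
  pe <- private_events(sheet, st, genes)
  expect_equal(pe$n_pairs, c(1, 0))
  expect_equal(pe$amp_private_fmt[2], "0/0")
  cc <- concordance_rate(sheet, st, genes)
  expect_equal(cc$n_genes, 1)  # G2 has no evaluable pair
})
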