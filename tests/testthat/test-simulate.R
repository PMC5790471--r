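small_cfg <- function(...) {
  simulation_config(layout = default_layout(6, 1e6), ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_pair(small_cfg(seed = 42), "P1")
  b <- simulate_pair(small_cfg(seed = 42), "P1")
  expect_identical(a$primary$segments, b$primary$segments)
  expect_identical(a$met$segments, b$met$segments)
  expect_identical(a$truth$window, b$truth$window)
  c <- simulate_pair(small_cfg(seed = 43), "P1")
  expect_false(identical(a$met$segments, c$met$segments))
})

test_that("emitted profiles always satisfy the segment invariants", {
  set.seed(415)
  cfgs <- list(small_cfg(), small_cfg(wgd_met = TRUE),
               small_cfg(wgd_met = TRUE, wgd_primary = TRUE),
               small_cfg(target_discordance = 0.3),
               small_cfg(target_discordance = 0.15, wgd_met = TRUE),
               small_cfg(trunk_event_rate = 150, branch_event_rates = c(60, 60),
                         event_type_weights = c(loss = .5, gain = .1, amp = .1,
                                                homdel = .15, cn_loh = .15)))
  for (cfg in cfgs) {
    sim <- simulate_pair(cfg, "PX")
    for (pr in list(sim$primary, sim$met)) {
      # re-validation throws on any violated invariant
      expect_silent(validate_segments(pr$segments, cfg$layout))
      expect_true(all(pr$segments$minor_cn <=
                        pr$segments$total_cn - pr$segments$minor_cn))
    }
  }
})

test_that("trunk-only pairs are fully concordant", {
  cfg <- small_cfg(branch_event_rates = c(primary = 0, met = 0), seed = 9)
  sim <- simulate_pair(cfg, "P1")
  expect_equal(sim$truth$window$cn_discordant_fraction, 0)
  expect_equal(sim$truth$window$loh_unchanged_fraction, 1)
  grid <- tile_genome(cfg$layout, cfg$window_size)
  r <- suppressWarnings(compare_pair(assign_windows(sim$primary, grid),
                                     assign_windows(sim$met, grid)))
  expect_equal(r$cn_discordant_fraction, 0)
})

test_that("a metastasis-only doubling is erased by the correction and total without it", {
  cfg <- small_cfg(trunk_event_rate = 0,
                   branch_event_rates = c(primary = 0, met = 0),
                   wgd_met = TRUE, seed = 10)
  sim <- simulate_pair(cfg, "P1")
  grid <- tile_genome(cfg$layout, cfg$window_size)
  tp <- assign_windows(sim$primary, grid)
  tm <- assign_windows(sim$met, grid)
  expect_equal(compare_pair(tp, tm, wgd_correction = TRUE)$cn_discordant_fraction, 0)
  expect_equal(compare_pair(tp, tm, wgd_correction = FALSE)$cn_discordant_fraction, 1)
  expect_equal(sim$truth$window$cn_discordant_fraction, 0)
  expect_equal(sim$truth$window_uncorrected$cn_discordant_fraction, 1)
})

test_that("targeted mode plants exact window-level budgets (snapped blocks)", {
  for (seed in c(21, 22)) {
    cfg <- small_cfg(target_discordance = 0.25, loh_met_fraction = 0.05,
                     loh_primary_fraction = 0.08, seed = seed)
    sim <- simulate_pair(cfg, "P1")
    expect_equal(sim$truth$window$cn_discordant_fraction, 0.25)
    expect_equal(sim$truth$window$loh_met_only_fraction, 0.05)
    expect_equal(sim$truth$window$loh_primary_only_fraction, 0.08)
    # pipeline measurement agrees with the independent truth engine
    grid <- tile_genome(cfg$layout, cfg$window_size)
    r <- compare_pair(assign_windows(sim$primary, grid),
                      assign_windows(sim$met, grid))
    expect_equal(r$cn_discordant_fraction,
                 sim$truth$window$cn_discordant_fraction)
    expect_equal(r$loh_met_only_fraction,
                 sim$truth$window$loh_met_only_fraction)
  }
})

test_that("unsnapped block boundaries stay within one window's weight per breakpoint", {
  cfg <- small_cfg(target_discordance = 0.25, snap_to_windows = FALSE,
                   seed = 23)
  sim <- simulate_pair(cfg, "P1")
  truth <- sim$truth$window$cn_discordant_fraction
  grid <- tile_genome(cfg$layout, cfg$window_size)
  r <- compare_pair(assign_windows(sim$primary, grid),
                    assign_windows(sim$met, grid))
  # both routes measure the same emitted pair: they agree exactly
  expect_equal(r$cn_discordant_fraction, truth)
  # and the planted target is met within the boundary-quantization bound
  n_break <- 2 * nrow(sim$truth$planted_blocks)
  bound <- n_break / sim$truth$window$n_windows_compared
  expect_lt(abs(truth - 0.25), bound)
})

test_that("infeasible planted targets abort with a diagnostic", {
  expect_error(simulate_pair(small_cfg(target_discordance = 0.05,
                                       loh_met_fraction = 0.1,
                                       loh_primary_fraction = 0.1,
                                       wgd_met = TRUE), "P1"),
               "infeasible")
  expect_error(simulate_pair(small_cfg(target_discordance = 0.2,
                                       wgd_primary = TRUE), "P1"),
               "primary-only WGD")
  expect_error(simulate_pair(small_cfg(target_discordance = 0.9,
                                       trunk_fraction = 0.3), "P1"),
               "0.95")
})

test_that("doubled metastasis branches are recovered by the WGD caller", {
  set.seed(416)
  lay <- default_layout()
  hits <- vapply(1:15, function(i) {
    sim <- simulate_pair(simulation_config(layout = lay, wgd_met = TRUE), "P")
    detect_wgd(sim$met, lay)$is_wgd && !detect_wgd(sim$primary, lay)$is_wgd
  }, logical(1))
  expect_equal(mean(hits), 1)
})

test_that("cohort simulation emits valid linked files and honors the design", {
  lay <- default_layout(8, 1e6)
  des <- default_cohort_design()[c(1, 5, 8, 11), ]
  out <- withr::local_tempdir()
  co <- simulate_cohort(design = des, layout = lay, seed = 31, outdir = out,
                        genes = simulate_gene_panel(lay, n_candidate = 20,
                                                    n_actionable = 6,
                                                    n_both = 2,
                                                    gene_length = 3e4))
  expect_setequal(names(co$profiles),
                  c(paste0(des$patient_id, "-T"), paste0(des$patient_id, "-M")))
  expect_equal(nrow(co$sheet), 4)
  # files round-trip through the package readers
  lay2 <- read_chrom_sizes(file.path(out, "chrom_sizes.tsv"))
  expect_equal(as.data.frame(lay2), as.data.frame(lay))
  sheet <- read_sample_sheet(file.path(out, "sample_sheet.tsv"))
  expect_equal(sheet$patient_id, des$patient_id)
  g <- read_gene_annotation(file.path(out, "genes.bed"), lay2)
  expect_equal(nrow(g), nrow(co$genes))
  p <- read_profile(file.path(out, "profiles", "C01-T.seg.tsv"), lay2)
  expect_equal(p$segments, co$profiles[["C01-T"]]$segments)
})

test_that("group assignment mismatches are rejected", {
  des <- default_cohort_design()[1:2, ]
  des$met_exposure <- "sometimes"
  expect_error(simulate_cohort(design = des, layout = default_layout(4, 5e5),
                               seed = 1),
               "met_exposure")
  expect_error(simulate_cohort(design = des[0, ]), "at least one")
})

test_that("gene-level ground truth matches the pipeline's bookkeeping", {
  lay <- default_layout(8, 1e6)
  genes <- local({
    set.seed(417)
    simulate_gene_panel(lay, n_candidate = 30, n_actionable = 8, n_both = 3,
                        gene_length = 4e4)
  })
  des <- default_cohort_design()[c(2, 5, 6, 13), ]
  co <- simulate_cohort(design = des, layout = lay, seed = 32, genes = genes)
  statuses <- suppressWarnings(
    do.call(rbind, lapply(co$profiles, gene_status, genes = genes)))
  pe <- private_events(co$sheet, statuses, genes, wgd_correction = TRUE)
  cc <- concordance_rate(co$sheet, statuses, genes, wgd_correction = TRUE)
  truth_amp <- truth_loss <- truth_conc <- truth_eval <-
    setNames(rep(0L, nrow(genes)), genes$symbol)
  for (pid in names(co$truths)) {
    gt <- co$truths[[pid]]$gene
    truth_amp <- truth_amp + gt$amp_private
    truth_loss <- truth_loss + gt$loss_private
    truth_conc <- truth_conc + !gt$concordant
    truth_eval <- truth_eval + gt$evaluable
  }
  expect_equal(pe$amp_private_to_met, unname(truth_amp))
  expect_equal(pe$loss_private_to_met, unname(truth_loss))
  expect_equal(cc$per_gene$n_discordant_pairs, unname(truth_conc))
  expect_equal(cc$per_gene$n_pairs, unname(truth_eval))
})
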