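lay1 <- genome_layout("chr1", 10000)
grid1 <- tile_genome(lay1, 10000)

one_window_pair <- function(p_state, m_state) {
  tp <- assign_windows(mk_profile(seg_row("chr1", 0, 10000, p_state[1],
                                          p_state[2]), lay1, "T"), grid1)
  tm <- assign_windows(mk_profile(seg_row("chr1", 0, 10000, m_state[1],
                                          m_state[2]), lay1, "M"), grid1)
  list(tp = tp, tm = tm)
}

test_that("identical tracks are fully concordant", {
  lay <- toy_layout(2, 50000)
  set.seed(406)
  p <- mk_profile(rand_segments(lay, gap_prob = 0), lay)
  tr <- assign_windows(p, tile_genome(lay, 10000))
  r <- compare_pair(tr, tr)
  expect_equal(r$cn_discordant_fraction, 0)
  expect_equal(r$loh_unchanged_fraction, 1)
  expect_equal(r$loh_met_only_fraction, 0)
})

test_that("a +2 doubling signature is forgiven only when the correction is on", {
  lay <- toy_layout(2, 50000)
  grid <- tile_genome(lay, 10000)
  tp <- assign_windows(uniform_profile(lay, 2, 1, "T"), grid)
  tm <- assign_windows(uniform_profile(lay, 4, 2, "M"), grid)
  expect_equal(compare_pair(tp, tm, wgd_correction = TRUE)$cn_discordant_fraction, 0)
  expect_equal(compare_pair(tp, tm, wgd_correction = FALSE)$cn_discordant_fraction, 1)
  # the forgiveness is one-directional: a doubled *primary* is not excused
  expect_equal(compare_pair(tm, tp, wgd_correction = TRUE)$cn_discordant_fraction, 1)
})

test_that("single-window rule applications match the stated comparison rules", {
  # diff 0 with unequal LOH: CN-concordant but LOH-discordant
  w <- one_window_pair(c(2, 0), c(2, 1))
  r <- compare_pair(w$tp, w$tm)
  expect_equal(r$cn_discordant_fraction, 0)
  expect_equal(r$windows$loh_class, "het_retained_in_met")
  # diff +3 is discordant
  w <- one_window_pair(c(2, 1), c(5, 2))
  expect_equal(compare_pair(w$tp, w$tm)$cn_discordant_fraction, 1)
  # +1 with LOH change is not forgiven
  w <- one_window_pair(c(2, 1), c(3, 0))
  expect_equal(compare_pair(w$tp, w$tm)$cn_discordant_fraction, 1)
  expect_equal(compare_pair(w$tp, w$tm)$loh_met_only_fraction, 1)
  # +1 without LOH change is forgiven
  w <- one_window_pair(c(2, 1), c(3, 1))
  expect_equal(compare_pair(w$tp, w$tm)$cn_discordant_fraction, 0)
  # LOH acquired in the metastasis
  w <- one_window_pair(c(2, 1), c(2, 0))
  r <- compare_pair(w$tp, w$tm)
  expect_equal(r$loh_met_only_fraction, 1)
  expect_equal(r$cn_discordant_fraction, 0)
})

test_that("windows missing in either sample leave all denominators", {
  lay <- genome_layout("chr1", 40000)
  grid <- tile_genome(lay, 10000)
  tp <- assign_windows(mk_profile(seg_row("chr1", 0, 30000, 2, 1), lay, "T"),
                       grid)
  tm <- assign_windows(mk_profile(seg_row("chr1", 10000, 40000, 5, 1), lay,
                                  "M"), grid)
  r <- compare_pair(tp, tm)
  expect_equal(r$n_windows_compared, 2)
  expect_equal(r$cn_discordant_fraction, 1)
  expect_true(all(is.na(r$windows$cn_label[c(1, 4)])))
})

test_that("LOH class fractions always partition the compared windows", {
  set.seed(407)
  lay <- toy_layout(2, 60000)
  grid <- tile_genome(lay, 10000)
  for (rep in 1:10) {
    tp <- assign_windows(mk_profile(rand_segments(lay), lay, "T"), grid)
    tm <- assign_windows(mk_profile(rand_segments(lay), lay, "M"), grid)
    r <- compare_pair(tp, tm)
    if (r$n_windows_compared == 0) next
    expect_equal(r$loh_unchanged_fraction + r$loh_met_only_fraction +
                   r$loh_primary_only_fraction, 1)
  }
})

test_that("swapping the pair preserves discordance without the correction", {
  set.seed(408)
  lay <- toy_layout(2, 60000)
  grid <- tile_genome(lay, 10000)
  for (rep in 1:8) {
    tp <- assign_windows(mk_profile(rand_segments(lay), lay, "T"), grid)
    tm <- assign_windows(mk_profile(rand_segments(lay), lay, "M"), grid)
    a <- compare_pair(tp, tm, wgd_correction = FALSE)
    b <- compare_pair(tm, tp, wgd_correction = FALSE)
    expect_equal(a$cn_discordant_fraction, b$cn_discordant_fraction)
    # and the met/primary LOH classes swap roles
    expect_equal(a$loh_met_only_fraction, b$loh_primary_only_fraction)
  }
})

test_that("pairs on different grids are rejected", {
  lay <- toy_layout(2, 50000)
  tp <- assign_windows(uniform_profile(lay, 2, 1, "T"),
                       tile_genome(lay, 10000))
  tm <- assign_windows(uniform_profile(lay, 2, 1, "M"),
                       tile_genome(lay, 5000))
  expect_error(compare_pair(tp, tm), "same window grid")
})

test_that("pair discordance matches the per-base oracle on random toys", {
  set.seed(409)
  for (rep in 1:10) {
    lay <- toy_layout(2, sample(c(30000, 45000), 1))
    sp <- rand_segments(lay)
    sm <- rand_segments(lay)
    wsize <- sample(c(4000, 10000), 1)
    grid <- tile_genome(lay, wsize)
    got <- compare_pair(assign_windows(mk_profile(sp, lay, "T"), grid),
                        assign_windows(mk_profile(sm, lay, "M"), grid))
    want <- oracle_compare(oracle_window_states(sp, lay, wsize),
                           oracle_window_states(sm, lay, wsize))
    expect_equal(got$n_windows_compared, want$n)
    expect_equal(got$cn_discordant_fraction, want$cn_discordant_fraction)
    expect_equal(got$loh_met_only_fraction, want$loh_met_only_fraction)
    expect_equal(got$loh_primary_only_fraction, want$loh_primary_only_fraction)
  }
})

test_that("genome fractions follow the diploid-reference definitions", {
  lay <- toy_layout(2, 50000)
  expect_equal(unname(genome_fractions(uniform_profile(lay, 2, 1))), c(0, 0))
  # copy-neutral LOH is not a copy-number change
  expect_equal(unname(genome_fractions(uniform_profile(lay, 2, 0))), c(0, 1))
  lay1 <- genome_layout("chr1", 100000)
  seg <- rbind(seg_row("chr1", 0, 50000, 3, 1),
               seg_row("chr1", 50000, 100000, 2, 1))
  expect_equal(unname(genome_fractions(mk_profile(seg, lay1))), c(0.5, 0))
  # denominators are covered bases
  seg2 <- seg_row("chr1", 0, 20000, 1, 0)
  expect_equal(unname(genome_fractions(mk_profile(seg2, lay1))), c(1, 1))
  empty <- structure(list(sample_id = "S", role = "primary",
                          purity = NA_real_, segments = seg2[0, ]),
                     class = "segmented_profile")
  expect_error(genome_fractions(empty), "no segments")
})

test_that("genome fractions match the per-base oracle on random toys", {
  set.seed(410)
  for (rep in 1:10) {
    lay <- toy_layout(2, 40000)
    seg <- rand_segments(lay)
    expect_equal(unname(genome_fractions(mk_profile(seg, lay))),
                 unname(oracle_genome_fractions(seg, lay)))
  }
})
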