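mk_cohort_inputs <- function(fracs) {
  lay <- toy_layout(2, 50000)
  grid <- tile_genome(lay, 10000)
  n <- length(fracs)
  sheet <- data.frame(patient_id = sprintf("P%d", seq_len(n)),
                      primary_sample = sprintf("P%d-T", seq_len(n)),
                      met_sample = sprintf("P%d-M", seq_len(n)),
                      timing = "synchronous",
                      met_exposure = rep(c("naive", "post_therapy"),
                                         length.out = n),
                      stringsAsFactors = FALSE)
  disc <- list(); wgd <- list(); fr <- list()
  for (i in seq_len(n)) {
    # construct a pair whose discordant fraction is exactly fracs[i]
    k <- round(fracs[i] * 10)   # of 10 windows
    segP <- data.frame(chromosome = rep(lay$chromosome, each = 1),
                       start = 0, end = 50000, total_cn = 2, minor_cn = 1)
    segM <- rbind(
      if (k > 0) seg_row("chr1", 0, k * 5000 * 2, 6, 1) else NULL,
      if (k * 10000 < 100000) {
        smen <- k * 10000
        if (smen < 50000) rbind(seg_row("chr1", smen, 50000, 2, 1),
                                seg_row("chr2", 0, 50000, 2, 1))
        else seg_row("chr2", smen - 50000, 50000, 2, 1)
      } else NULL)
    p <- mk_profile(segP, lay, sheet$primary_sample[i])
    m <- mk_profile(segM, lay, sheet$met_sample[i], role = "metastasis")
    disc[[sheet$patient_id[i]]] <-
      compare_pair(assign_windows(p, grid), assign_windows(m, grid),
                   patient_id = sheet$patient_id[i])
    wgd[[p$sample_id]] <- detect_wgd(p, lay)
    wgd[[m$sample_id]] <- detect_wgd(m, lay)
    fr[[p$sample_id]] <- genome_fractions(p)
    fr[[m$sample_id]] <- genome_fractions(m)
  }
  list(sheet = sheet, disc = disc, wgd = wgd, fr = fr)
}

test_that("the cohort table echoes per-pair inputs and their means", {
  x <- mk_cohort_inputs(c(0.2, 0.4))
  tab <- summarize_cohort(x$sheet, x$disc, x$wgd, x$fr)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$cn_discordant_fraction, c(0.2, 0.4))
  summ <- attr(tab, "summary")
  expect_equal(summ$mean[summ$metric == "cn_discordant_fraction"], 0.3)
})

test_that("incomplete cohorts fail naming the culprit", {
  x <- mk_cohort_inputs(c(0.2, 0.4))
  expect_error(summarize_cohort(x$sheet[0, ], x$disc, x$wgd, x$fr), "empty")
  disc <- x$disc
  disc[["P2"]] <- NULL
  expect_error(summarize_cohort(x$sheet, disc, x$wgd, x$fr), "P2")
  wgd <- x$wgd
  wgd[["P1-M"]] <- NULL
  expect_error(summarize_cohort(x$sheet, x$disc, wgd, x$fr), "P1-M")
})

test_that("two identical groups give t = 0 and p = 1", {
  tab <- data.frame(met_exposure = rep(c("naive", "post_therapy"), each = 3),
                    timing = "synchronous",
                    x = c(1, 2, 3, 1, 2, 3))
  r <- compare_groups(tab, "x", "met_exposure")
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
})

test_that("the pooled-variance statistic matches the closed form exactly", {
  a <- c(0.1, 0.2, 0.3)
  b <- c(0.4, 0.5, 0.6)
  tab <- data.frame(met_exposure = rep(c("naive", "post_therapy"), each = 3),
                    timing = "synchronous", x = c(a, b))
  r <- compare_groups(tab, "x", "met_exposure")
  want <- oracle_pooled_t(a, b)
  expect_equal(r$t, want$t, tolerance = 1e-12)
  expect_equal(r$df, want$df)
  expect_equal(r$p_value, want$p, tolerance = 1e-12)
  # Welch variant differs only in df handling, still two-sided
  rw <- compare_groups(tab, "x", "met_exposure", var_equal = FALSE)
  expect_equal(unname(rw$t), want$t, tolerance = 1e-12)
})

test_that("group order affects only the sign of t", {
  tab <- data.frame(met_exposure = rep(c("naive", "post_therapy"),
                                       times = c(4, 3)),
                    timing = "synchronous",
                    x = c(0.1, 0.3, 0.2, 0.25, 0.5, 0.6, 0.4))
  r1 <- compare_groups(tab, "x", "met_exposure")
  tab2 <- tab
  tab2$met_exposure <- ifelse(tab$met_exposure == "naive", "post_therapy",
                              "naive")
  r2 <- compare_groups(tab2, "x", "met_exposure")
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("groups below n = 2 are rejected", {
  tab <- data.frame(met_exposure = c("naive", "post_therapy", "post_therapy"),
                    timing = "synchronous", x = c(0.1, 0.2, 0.3))
  expect_error(compare_groups(tab, "x", "met_exposure"), "n = 1")
})

test_that("power against a planted shift rises with the effect size", {
  set.seed(413)
  power_at <- function(delta, reps = 150) {
    mean(vapply(seq_len(reps), function(i) {
      tab <- simulate_cohort_metrics(10, 6, 0.22 + delta, 0.22, sd = 0.06)
      compare_groups(tab, "cn_discordant_fraction", "met_exposure")$p_value
    }, numeric(1)) < 0.05)
  }
  p0 <- power_at(0)
  p1 <- power_at(0.06)
  p2 <- power_at(0.12)
  expect_lt(p0, p1)
  expect_lt(p1, p2)
  expect_gt(p2, 0.8)
})

test_that("a planted group difference is detected in direction almost always", {
  set.seed(414)
  hits <- vapply(1:200, function(i) {
    tab <- simulate_cohort_metrics(10, 6, 0.30, 0.15, sd = 0.06)
    r <- compare_groups(tab, "cn_discordant_fraction", "met_exposure")
    unname(r$means["naive"] > r$means["post_therapy"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
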