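# Per-base brute-force oracles for toy genomes (<= ~100 kb): literal integer
# vectors per base, counting rather than interval arithmetic. Deliberately
# naive and independent of the package implementation.

# base-resolution state vectors; list per chromosome with total/minor/seg
# (seg = index of the covering segment row, for tie-breaking)
oracle_base_vectors <- function(segments, layout) {
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chromosome[i]
    L <- layout$length[i]
    tot <- rep(NA_real_, L)
    mnr <- rep(NA_real_, L)
    seg_id <- rep(NA_integer_, L)
    rows <- which(segments$chromosome == ch)
    for (j in rows) {
      idx <- (segments$start[j] + 1):segments$end[j]
      tot[idx] <- segments$total_cn[j]
      mnr[idx] <- segments$minor_cn[j]
      seg_id[idx] <- j
    }
    out[[ch]] <- list(total = tot, minor = mnr, seg = seg_id)
  }
  out
}

# per-window state by counting covered bases per segment; largest count wins,
# ties broken by the segment with the smaller start
oracle_window_states <- function(segments, layout, window_size) {
  bv <- oracle_base_vectors(segments, layout)
  res <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chromosome[i]
    L <- layout$length[i]
    starts <- seq(0, L - 1, by = window_size)
    for (ws in starts) {
      we <- min(ws + window_size, L)
      seg_here <- bv[[ch]]$seg[(ws + 1):we]
      covered <- !is.na(seg_here)
      if (!any(covered)) {
        res[[length(res) + 1]] <- data.frame(chromosome = ch, start = ws,
                                             end = we, total = NA_real_,
                                             minor = NA_real_)
        next
      }
      counts <- table(seg_here[covered])
      cand <- as.integer(names(counts))[counts == max(counts)]
      best <- cand[which.min(segments$start[cand])]
      res[[length(res) + 1]] <- data.frame(chromosome = ch, start = ws,
                                           end = we,
                                           total = segments$total_cn[best],
                                           minor = segments$minor_cn[best])
    }
  }
  do.call(rbind, res)
}

# per-chromosome fraction of bases at total 3-4 with minor >= 1
oracle_wgd_fractions <- function(segments, layout) {
  bv <- oracle_base_vectors(segments, layout)
  vapply(layout$chromosome, function(ch) {
    q <- !is.na(bv[[ch]]$total) & bv[[ch]]$total %in% c(3, 4) &
      bv[[ch]]$minor >= 1
    sum(q) / length(bv[[ch]]$total)
  }, numeric(1))
}

# covered-base altered / LOH fractions
oracle_genome_fractions <- function(segments, layout) {
  bv <- oracle_base_vectors(segments, layout)
  tot <- unlist(lapply(bv, `[[`, "total"))
  mnr <- unlist(lapply(bv, `[[`, "minor"))
  cov <- !is.na(tot)
  c(altered_fraction = sum(tot[cov] != 2) / sum(cov),
    loh_fraction = sum(mnr[cov] == 0 & tot[cov] >= 1) / sum(cov))
}

# paired comparison over oracle window states, restating the rules
oracle_compare <- function(wp, wm, wgd_correction = TRUE) {
  cmp <- !is.na(wp$total) & !is.na(wm$total)
  d <- wm$total[cmp] - wp$total[cmp]
  lp <- wp$minor[cmp] == 0 & wp$total[cmp] >= 1
  lm <- wm$minor[cmp] == 0 & wm$total[cmp] >= 1
  conc <- d == 0 | (wgd_correction & (d == 1 | d == 2) & lp == lm)
  list(n = sum(cmp),
       cn_discordant_fraction = mean(!conc),
       loh_unchanged_fraction = mean(lp == lm),
       loh_met_only_fraction = mean(lm & !lp),
       loh_primary_only_fraction = mean(lp & !lm))
}

# textbook pooled-variance two-sample t statistic and two-sided p
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# random valid toy segment table: non-overlapping segments with gaps
rand_segments <- function(layout, max_segs = 20, gap_prob = 0.3) {
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    L <- layout$length[i]
    n_bp <- sample(2:max(2, min(max_segs, 8)), 1)
    bp <- sort(sample(seq(0, L, by = 100), n_bp))
    bp <- unique(c(0, bp, L))
    for (k in seq_len(length(bp) - 1)) {
      if (bp[k] == bp[k + 1] || runif(1) < gap_prob) next
      t <- sample(0:8, 1)
      m <- if (t == 0) 0 else sample(0:(t %/% 2), 1)
      rows[[length(rows) + 1]] <- data.frame(
        chromosome = layout$chromosome[i], start = bp[k], end = bp[k + 1],
        total_cn = t, minor_cn = m)
    }
  }
  if (!length(rows)) {
    rows[[1]] <- data.frame(chromosome = layout$chromosome[1], start = 0,
                            end = layout$length[1], total_cn = 2,
                            minor_cn = 1)
  }
  do.call(rbind, rows)
}
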