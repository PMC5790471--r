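# Independent ground-truth engine for the simulator.
#
# Recomputes window states, paired discordance, genome fractions and
# gene-level bookkeeping from emitted segment tables using plain interval
# arithmetic (sorted-vector scans via findInterval), deliberately sharing no
# code with the GenomicRanges-based pipeline path. Used by simulate_pair()
# to attach ground truth, and usable as a cross-check in its own right.

# per-window (total, minor) by largest overlap; segments must be sorted and
# non-overlapping per chromosome (guaranteed for emitted profiles)
.truth_states <- function(segments, layout, window_size) {
  res_t <- res_m <- numeric(0)
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chromosome[i]
    len <- layout$length[i]
    n <- ceiling(len / window_size)
    ws <- (seq_len(n) - 1) * window_size
    we <- pmin(ws + window_size, len)
    seg <- segments[segments$chromosome == ch, , drop = FALSE]
    tt <- rep(NA_real_, n)
    mm <- rep(NA_real_, n)
    if (nrow(seg)) {
      seg <- seg[order(seg$start), , drop = FALSE]
      # candidate segments per window: ends > window start, starts < window end
      lo <- findInterval(ws, seg$end) + 1          # first seg with end > ws
      hi <- findInterval(we - 0.5, seg$start)      # last seg with start < we
      for (k in which(hi >= lo)) {
        j <- lo[k]:hi[k]
        ov <- pmin(seg$end[j], we[k]) - pmax(seg$start[j], ws[k])
        best <- j[order(-ov, seg$start[j])][1]
        tt[k] <- seg$total_cn[best]
        mm[k] <- seg$minor_cn[best]
      }
    }
    res_t <- c(res_t, tt)
    res_m <- c(res_m, mm)
  }
  list(total = res_t, minor = res_m)
}

# discordance fractions from two state lists, restating the comparison rules
.truth_compare <- function(sp, sm, wgd_correction = TRUE) {
  cmp <- !is.na(sp$total) & !is.na(sm$total)
  n <- sum(cmp)
  d <- sm$total[cmp] - sp$total[cmp]
  lp <- sp$minor[cmp] == 0 & sp$total[cmp] >= 1
  lm <- sm$minor[cmp] == 0 & sm$total[cmp] >= 1
  same_loh <- lp == lm
  conc <- d == 0 | (wgd_correction & (d == 1 | d == 2) & same_loh)
  list(n_windows_compared = n,
       cn_discordant_fraction = sum(!conc) / n,
       loh_unchanged_fraction = sum(same_loh) / n,
       loh_met_only_fraction = sum(lm & !lp) / n,
       loh_primary_only_fraction = sum(lp & !lm) / n)
}

# covered-genome altered / LOH fractions straight off the segment table
.truth_fractions <- function(segments) {
  w <- segments$end - segments$start
  c(altered_fraction = sum(w[segments$total_cn != 2]) / sum(w),
    loh_fraction = sum(w[segments$minor_cn == 0 & segments$total_cn >= 1]) /
      sum(w))
}

# gene-level states by largest overlap, findInterval route
.truth_gene_states <- function(segments, genes) {
  tt <- rep(NA_real_, nrow(genes))
  mm <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chromosome)) {
    gi <- which(genes$chromosome == ch)
    seg <- segments[segments$chromosome == ch, , drop = FALSE]
    if (!nrow(seg)) next
    seg <- seg[order(seg$start), , drop = FALSE]
    lo <- findInterval(genes$start[gi], seg$end) + 1
    hi <- findInterval(genes$end[gi] - 0.5, seg$start)
    for (k in seq_along(gi)) {
      if (hi[k] < lo[k]) next
      j <- lo[k]:hi[k]
      ov <- pmin(seg$end[j], genes$end[gi[k]]) -
        pmax(seg$start[j], genes$start[gi[k]])
      best <- j[order(-ov, seg$start[j])][1]
      tt[gi[k]] <- seg$total_cn[best]
      mm[gi[k]] <- seg$minor_cn[best]
    }
  }
  list(total = tt, minor = mm)
}

# category labels without classify_state's factor plumbing
.truth_category <- function(t, m) {
  ifelse(is.na(t), NA_character_,
  ifelse(t == 0, "HOMDEL",
  ifelse(t == 1, "LOSS",
  ifelse(t == 2 & m == 0, "CN_LOH",
  ifelse(t == 2, "NEUTRAL_HET",
  ifelse(t <= 5, "GAIN", "AMP"))))))
}

# per-gene pair bookkeeping: concordance and private amp/loss labels
.truth_gene_table <- function(seg_p, seg_m, genes, strict = FALSE,
                              wgd_correction = TRUE) {
  gp <- .truth_gene_states(seg_p, genes)
  gm <- .truth_gene_states(seg_m, genes)
  cat_p <- .truth_category(gp$total, gp$minor)
  cat_m <- .truth_category(gm$total, gm$minor)
  ok <- !is.na(cat_p) & !is.na(cat_m)
  d <- gm$total - gp$total
  loh_p <- gp$minor == 0 & gp$total >= 1
  loh_m <- gm$minor == 0 & gm$total >= 1
  forgiven <- ok & (d == 1 | d == 2) & loh_p == loh_m
  amp_set <- if (strict) "AMP" else c("GAIN", "AMP")
  loss_set <- if (strict) "HOMDEL" else c("LOSS", "HOMDEL")
  data.frame(
    symbol = genes$symbol,
    evaluable = ok,
    concordant = ok & (cat_p == cat_m | (wgd_correction & forgiven)),
    amp_private = ok & cat_m %in% amp_set & !(cat_p %in% amp_set) &
      !(wgd_correction & forgiven),
    loss_private = ok & cat_m %in% loss_set & !(cat_p %in% loss_set),
    stringsAsFactors = FALSE)
}

#' Recompute a simulated pair's ground truth from its emitted profiles
#'
#' Runs the generator's independent measurement path (plain interval
#' arithmetic, no shared code with [assign_windows()]/[compare_pair()]) on a
#' pair of segment tables. Exported mainly so that the full-pipeline tests
#' and the acceptance analysis can cross-check the two routes.
#'
#' @param primary,met [segmented_profile()] objects.
#' @param layout a [genome_layout()].
#' @param window_size window size in bp.
#' @param wgd_correction forgive +1/+2 metastasis diffs without LOH change.
#' @param genes optional gene table for gene-level truth.
#' @return list with `window` (both correction modes), `fractions_primary`,
#'   `fractions_met`, and (when `genes` is given) `gene` per-gene labels.
#' @export
pair_ground_truth <- function(primary, met, layout, window_size = 10000,
                              wgd_correction = TRUE, genes = NULL) {
  sp <- .truth_states(primary$segments, layout, window_size)
  sm <- .truth_states(met$segments, layout, window_size)
  out <- list(
    window = .truth_compare(sp, sm, wgd_correction = wgd_correction),
    window_uncorrected = .truth_compare(sp, sm, wgd_correction = FALSE),
    fractions_primary = .truth_fractions(primary$segments),
    fractions_met = .truth_fractions(met$segments))
  if (!is.null(genes)) {
    out$gene <- .truth_gene_table(primary$segments, met$segments, genes,
                                  wgd_correction = wgd_correction)
  }
  out
}
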