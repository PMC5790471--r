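#' Gene-level copy-number/LOH status by largest segment over the footprint
#'
#' For each gene, the overlapping segment with the largest overlap length
#' (within or spanning the gene footprint; ties broken by leftmost segment
#' start) determines the gene's total/minor copy number, LOH flag and
#' category. Genes with no overlapping segment are reported with missing
#' state. Uses the same largest-overlap engine as [assign_windows()].
#'
#' @param profile a [segmented_profile()].
#' @param genes gene table from [read_gene_annotation()] /
#'   [validate_genes()].
#' @return A `gene_status_table` data frame: one row per gene with
#'   `sample_id`, `symbol`, `chromosome`, `start`, `end`, `panel`,
#'   `total_cn`, `minor_cn`, `loh`, `category`, `seg_start`, `seg_end`.
#' @export
gene_status <- function(profile, genes) {
  stopifnot(inherits(profile, "segmented_profile"))
  genes <- validate_genes(genes)
  seg <- profile$segments
  idx <- .largest_overlap(genes, seg)
  out <- data.frame(sample_id = profile$sample_id,
                    symbol = genes$symbol,
                    chromosome = genes$chromosome,
                    start = genes$start, end = genes$end,
                    panel = genes$panel,
                    total_cn = seg$total_cn[idx],
                    minor_cn = seg$minor_cn[idx],
                    stringsAsFactors = FALSE)
  out$loh <- is_loh(out$total_cn, out$minor_cn)
  out$category <- factor(NA_character_, levels = CN_CATEGORIES)
  hit <- !is.na(idx)
  if (any(hit)) {
    out$category[hit] <- classify_state(out$total_cn[hit], out$minor_cn[hit])
  }
  out$seg_start <- seg$start[idx]
  out$seg_end <- seg$end[idx]
  class(out) <- c("gene_status_table", "data.frame")
  out
}

# join primary/met gene statuses for each pair; returns long data frame with
# one row per (pair, gene) where both samples have a status
.pair_gene_join <- function(pairs, statuses) {
  statuses <- as.data.frame(statuses)
  key <- paste(statuses$sample_id, statuses$symbol, sep = "\r")
  if (anyDuplicated(key)) {
    stop2("gene statuses: duplicated (sample, gene) row(s)")
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- statuses[statuses$sample_id == pairs$primary_sample[i], ]
    m <- statuses[statuses$sample_id == pairs$met_sample[i], ]
    if (nrow(p) == 0L || nrow(m) == 0L) {
      stop2("gene statuses missing for pair %s (%s / %s)",
            pairs$patient_id[i], pairs$primary_sample[i], pairs$met_sample[i])
    }
    j <- match(p$symbol, m$symbol)
    data.frame(patient_id = pairs$patient_id[i], symbol = p$symbol,
               cat_p = as.character(p$category), cat_m = as.character(m$category[j]),
               total_p = p$total_cn, total_m = m$total_cn[j],
               loh_p = p$loh, loh_m = m$loh[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# forgiven under the WGD correction at gene level: +1/+2 total copies in the
# metastasis without a change in LOH status
.gene_forgiven <- function(joined) {
  d <- joined$total_m - joined$total_p
  d %in% c(1, 2) & joined$loh_p == joined$loh_m
}

#' Metastasis-private amplification and loss counts per gene
#'
#' For each gene and pair, an amplification event is a category in
#' `amp_categories` (default gains and amplifications; `strict = TRUE`
#' restricts to `AMP` alone and `HOMDEL` alone) and a loss event a category
#' in `loss_categories`. An event is *private to the metastasis* when it is
#' present in the metastasis and no event of that class affects the paired
#' primary. Pairs in which either sample lacks a status for the gene are
#' excluded from that gene's denominator. With `wgd_correction = TRUE` a
#' metastasis gain of +1/+2 total copies without LOH change is not counted
#' as a private event (mirroring the windowed +1/+2 correction in a cohort
#' where metastases may be genome-doubled).
#'
#' @param pairs pair records ([read_sample_sheet()] rows).
#' @param statuses row-bound [gene_status()] tables covering both samples of
#'   every pair.
#' @param genes the gene table (defines the gene universe and order).
#' @param strict count only `AMP`/`HOMDEL` as events. Default `FALSE`.
#' @param wgd_correction forgive +1/+2 without LOH change. Default `FALSE`
#'   (raw category bookkeeping).
#' @return data frame per gene: `symbol`, `chromosome`, `n_pairs`
#'   (evaluable), `amp_private_to_met`, `loss_private_to_met`, and formatted
#'   `amp_private_fmt` / `loss_private_fmt` (`"k/n (pct %)"`).
#' @export
private_events <- function(pairs, statuses, genes, strict = FALSE,
                           wgd_correction = FALSE) {
  genes <- validate_genes(genes)
  pairs <- validate_sample_sheet(pairs)
  joined <- .pair_gene_join(pairs, statuses)
  amp_set <- if (strict) "AMP" else c("GAIN", "AMP")
  loss_set <- if (strict) "HOMDEL" else c("LOSS", "HOMDEL")
  ok <- !is.na(joined$cat_p) & !is.na(joined$cat_m)
  forgiven <- !is.na(joined$total_p) & !is.na(joined$total_m) &
    .gene_forgiven(joined)
  amp_priv <- ok & joined$cat_m %in% amp_set & !(joined$cat_p %in% amp_set) &
    !(wgd_correction & forgiven)
  loss_priv <- ok & joined$cat_m %in% loss_set & !(joined$cat_p %in% loss_set)
  per_gene <- function(stat) {
    v <- tapply(stat, factor(joined$symbol, levels = genes$symbol), sum)
    as.integer(ifelse(is.na(v), 0L, v))
  }
  n_eval <- per_gene(ok)
  amp_k <- per_gene(amp_priv)
  loss_k <- per_gene(loss_priv)
  fmt <- function(k, n) ifelse(n == 0, "0/0",
                               sprintf("%d/%d (%.1f %%)", k, n, 100 * k / n))
  data.frame(symbol = genes$symbol, chromosome = genes$chromosome,
             n_pairs = n_eval,
             amp_private_to_met = amp_k, loss_private_to_met = loss_k,
             amp_private_fmt = fmt(amp_k, n_eval),
             loss_private_fmt = fmt(loss_k, n_eval),
             stringsAsFactors = FALSE)
}

#' Cohort-level gene concordance
#'
#' A gene is concordant ("shared status") when its category is identical in
#' primary and metastasis within *every* pair in which both samples have a
#' status; genes with no evaluable pair are excluded from the denominator.
#' With `wgd_correction = TRUE` a +1/+2 metastasis gain without LOH change
#' does not break concordance.
#'
#' @inheritParams private_events
#' @return list with `n_genes` (evaluable), `n_concordant`, `fraction` and a
#'   `per_gene` data frame (`symbol`, `n_pairs`, `n_discordant_pairs`,
#'   `concordant`).
#' @export
concordance_rate <- function(pairs, statuses, genes, wgd_correction = FALSE) {
  genes <- validate_genes(genes)
  pairs <- validate_sample_sheet(pairs)
  joined <- .pair_gene_join(pairs, statuses)
  ok <- !is.na(joined$cat_p) & !is.na(joined$cat_m)
  forgiven <- !is.na(joined$total_p) & !is.na(joined$total_m) &
    .gene_forgiven(joined)
  disc <- ok & joined$cat_p != joined$cat_m & !(wgd_correction & forgiven)
  sym <- factor(joined$symbol, levels = genes$symbol)
  n_eval <- as.integer(tapply(ok, sym, sum))
  n_disc <- as.integer(tapply(disc, sym, sum))
  n_eval[is.na(n_eval)] <- 0L
  n_disc[is.na(n_disc)] <- 0L
  per_gene <- data.frame(symbol = genes$symbol, n_pairs = n_eval,
                         n_discordant_pairs = n_disc,
                         concordant = n_eval > 0L & n_disc == 0L,
                         stringsAsFactors = FALSE)
  evaluable <- per_gene$n_pairs > 0L
  list(n_genes = sum(evaluable),
       n_concordant = sum(per_gene$concordant[evaluable]),
       fraction = if (any(evaluable)) {
         sum(per_gene$concordant[evaluable]) / sum(evaluable)
       } else NA_real_,
       per_gene = per_gene)
}
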