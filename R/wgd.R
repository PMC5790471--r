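#' Detect whole-genome duplication in a segmented profile
#'
#' A sample is called whole-genome duplicated when more than 70% of at least
#' half of its chromosomes (inclusive: at least `ceiling(n/2)` of them) sit
#' at total copy number 3 or 4 with both parental alleles present
#' (`minor_cn >= 1`). Per-chromosome fractions use the full chromosome length
#' from the layout as denominator, so bases without a segment count against a
#' WGD call, never towards it. The genome-wide fraction of (3,4)-biallelic
#' sequence is reported as a diagnostic only; the decision is the
#' per-chromosome rule.
#'
#' @param profile a [segmented_profile()] (must contain at least one segment).
#' @param layout a [genome_layout()] covering every chromosome in the profile.
#' @return A `wgd_call` list: `is_wgd`, `per_chromosome_fraction` (named
#'   numeric over all layout chromosomes), `qualifying_chromosomes`,
#'   `n_chromosomes`, `genome_fraction_34_biallelic`, `sample_id`.
#' @examples
#' lay <- default_layout(4, 1e6)
#' seg <- data.frame(chromosome = lay$chromosome, start = 0, end = 1e6,
#'                   total_cn = 4, minor_cn = 2)
#' detect_wgd(segmented_profile("s1", seg, layout = lay), lay)
#' @export
detect_wgd <- function(profile, layout) {
  stopifnot(inherits(profile, "segmented_profile"),
            inherits(layout, "genome_layout"))
  seg <- profile$segments
  if (nrow(seg) == 0L) stop2("detect_wgd: profile %s has no segments",
                             profile$sample_id)
  unknown <- setdiff(unique(seg$chromosome), layout$chromosome)
  if (length(unknown)) {
    stop2("detect_wgd: chromosome(s) absent from layout: %s",
          .preview(unknown))
  }
  qual <- seg$total_cn %in% c(3, 4) & seg$minor_cn >= 1
  w <- (seg$end - seg$start) * qual
  per_chrom <- vapply(seq_len(nrow(layout)), function(i) {
    sum(w[seg$chromosome == layout$chromosome[i]]) / layout$length[i]
  }, numeric(1))
  names(per_chrom) <- layout$chromosome
  n_chrom <- nrow(layout)
  qualifying <- sum(per_chrom > 0.70)
  structure(list(
    sample_id = profile$sample_id,
    is_wgd = qualifying >= ceiling(n_chrom / 2),
    per_chromosome_fraction = per_chrom,
    qualifying_chromosomes = qualifying,
    n_chromosomes = n_chrom,
    genome_fraction_34_biallelic = sum(w) / genome_size(layout)
  ), class = "wgd_call")
}

#' @export
print.wgd_call <- function(x, ...) {
  cat(sprintf("<wgd_call> %s: %s (%d/%d chromosomes >70%% at 3-4 biallelic; genome fraction %.3f)\n",
              x$sample_id, if (x$is_wgd) "WGD" else "no WGD",
              x$qualifying_chromosomes, x$n_chromosomes,
              x$genome_fraction_34_biallelic))
  invisible(x)
}

#' Tabulate WGD calls for a set of samples
#'
#' @param calls list of [detect_wgd()] results.
#' @return data frame with one row per sample.
#' @export
wgd_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    data.frame(sample_id = x$sample_id, is_wgd = x$is_wgd,
               qualifying_chromosomes = x$qualifying_chromosomes,
               n_chromosomes = x$n_chromosomes,
               genome_fraction_34_biallelic = x$genome_fraction_34_biallelic,
               stringsAsFactors = FALSE)
  }))
}
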