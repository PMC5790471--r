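#' Paired copy-number and LOH discordance over shared windows
#'
#' Compares the windowed states of a primary tumor and its liver metastasis.
#' Only windows with a state in *both* samples enter the denominator. Per
#' window, `diff = met_total - primary_total`; the window is copy-number
#' concordant iff `diff == 0`, or - when the whole-genome-duplication
#' correction is on - `diff` is +1 or +2 with *equal* LOH status (a doubled
#' metastasis gains 1-2 copies everywhere without allele selection, which
#' the correction forgives; negative diffs are never forgiven, and a +1/+2
#' gain that also changes LOH status is not forgiven). The LOH comparison is
#' computed independently of the
#' copy-number comparison and classifies each window as `unchanged`
#' (equal LOH status), `loh_in_met` (LOH acquired in the metastasis) or
#' `het_retained_in_met` (LOH in the primary only). A window with `diff == 0`
#' but unequal LOH (e.g. 2,1 vs 2,0) is therefore copy-number concordant yet
#' LOH-discordant.
#'
#' @param primary,met [assign_windows()] tracks on the same grid.
#' @param wgd_correction forgive +1/+2 diffs without LOH change. Default
#'   `TRUE` (applied to all pairs).
#' @param patient_id optional label carried into the result.
#' @return A `pair_discordance` list: `patient_id`, `n_windows_compared`,
#'   `cn_discordant_fraction`, `loh_unchanged_fraction`,
#'   `loh_met_only_fraction`, `loh_primary_only_fraction`, `wgd_correction`,
#'   and `windows` (the grid plus `compared`, `cn_label`, `loh_class`).
#' @export
compare_pair <- function(primary, met, wgd_correction = TRUE,
                         patient_id = NA_character_) {
  stopifnot(inherits(primary, "window_state_track"),
            inherits(met, "window_state_track"))
  if (nrow(primary) != nrow(met) ||
      !identical(primary$chromosome, met$chromosome) ||
      !identical(primary$start, met$start) ||
      !identical(primary$end, met$end)) {
    stop2("compare_pair: the two tracks are not on the same window grid")
  }
  compared <- !is.na(primary$total_cn) & !is.na(met$total_cn)
  n <- sum(compared)
  diff <- met$total_cn - primary$total_cn
  loh_eq <- primary$loh == met$loh
  concord <- diff == 0 | (wgd_correction & diff %in% c(1, 2) & loh_eq)
  cn_label <- ifelse(concord, "concordant", "cn_discordant")
  loh_class <- ifelse(loh_eq, "unchanged",
               ifelse(met$loh & !primary$loh, "loh_in_met",
                      "het_retained_in_met"))
  cn_label[!compared] <- NA_character_
  loh_class[!compared] <- NA_character_
  win <- data.frame(chromosome = primary$chromosome, start = primary$start,
                    end = primary$end, compared = compared,
                    cn_label = cn_label, loh_class = loh_class,
                    stringsAsFactors = FALSE)
  frac <- function(lab, x) if (n == 0) NA_real_ else sum(x == lab, na.rm = TRUE) / n
  structure(list(
    patient_id = patient_id,
    primary_sample = attr(primary, "sample_id"),
    met_sample = attr(met, "sample_id"),
    n_windows_compared = n,
    cn_discordant_fraction = frac("cn_discordant", cn_label),
    loh_unchanged_fraction = frac("unchanged", loh_class),
    loh_met_only_fraction = frac("loh_in_met", loh_class),
    loh_primary_only_fraction = frac("het_retained_in_met", loh_class),
    wgd_correction = wgd_correction,
    windows = win
  ), class = "pair_discordance")
}

#' @export
print.pair_discordance <- function(x, ...) {
  cat(sprintf("<pair_discordance> %s (%s vs %s), correction %s\n",
              x$patient_id, x$primary_sample, x$met_sample,
              if (x$wgd_correction) "on" else "off"))
  cat(sprintf("  %d windows compared; CN discordant %.1f%%; LOH: unchanged %.1f%%, met-only %.1f%%, primary-only %.1f%%\n",
              x$n_windows_compared, 100 * x$cn_discordant_fraction,
              100 * x$loh_unchanged_fraction, 100 * x$loh_met_only_fraction,
              100 * x$loh_primary_only_fraction))
  invisible(x)
}

#' Genome-altered and LOH fractions of one profile
#'
#' `altered_fraction` is the fraction of segment-covered sequence whose total
#' copy number differs from the normal diploid 2 (copy-neutral LOH is *not* a
#' copy-number change and does not count); `loh_fraction` is the covered
#' fraction with the minor allele absent at total copy number >= 1.
#' Denominators are segment-covered bases.
#'
#' @param profile a [segmented_profile()] with at least one segment.
#' @param layout optional [genome_layout()] used only to re-validate.
#' @return named numeric: `altered_fraction`, `loh_fraction`.
#' @export
genome_fractions <- function(profile, layout = NULL) {
  stopifnot(inherits(profile, "segmented_profile"))
  seg <- profile$segments
  if (nrow(seg) == 0L) stop2("genome_fractions: profile %s has no segments",
                             profile$sample_id)
  if (!is.null(layout)) validate_segments(seg, layout)
  w <- seg$end - seg$start
  covered <- sum(w)
  c(altered_fraction = sum(w[seg$total_cn != 2]) / covered,
    loh_fraction = sum(w[is_loh(seg$total_cn, seg$minor_cn)]) / covered)
}
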