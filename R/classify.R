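#' Copy-number state categories
#'
#' The five somatic categories used throughout: homozygous deletion (total
#' copy number 0), loss (1), copy-neutral LOH (2 with minor allele absent),
#' gain (3--5) and amplification (6 and above), plus the diploid-heterozygous
#' baseline `NEUTRAL_HET` (2 with one copy of each parental allele).
#'
#' @format Character vector of category levels, in increasing copy-number
#'   order: `HOMDEL`, `LOSS`, `CN_LOH`, `NEUTRAL_HET`, `GAIN`, `AMP`.
#' @export
CN_CATEGORIES <- c("HOMDEL", "LOSS", "CN_LOH", "NEUTRAL_HET", "GAIN", "AMP")

#' Classify an allele-specific copy-number state
#'
#' Maps a (total, minor) copy-number pair to one of the five somatic
#' categories or the diploid-heterozygous baseline:
#' total 0 is `HOMDEL`; total 1 is `LOSS`; total 2 is `CN_LOH` when the minor
#' allele is absent, otherwise `NEUTRAL_HET`; totals 3--5 are `GAIN`; totals
#' of 6 or more are `AMP`. Totals above 8 did not occur in the category
#' table's source data; they are classified `AMP` with a warning rather than
#' rejected (open-ended top bin).
#'
#' @param total_cn integer vector of total copy numbers (>= 0).
#' @param minor_cn integer vector of minor-allele copy numbers (>= 0, and at
#'   most `total_cn - minor_cn`: the minor allele is the lesser allele).
#' @return factor with levels [CN_CATEGORIES].
#' @examples
#' classify_state(c(0, 2, 2, 7), c(0, 0, 1, 2))
#' @export
classify_state <- function(total_cn, minor_cn) {
  if (length(total_cn) != length(minor_cn)) {
    stop2("classify_state: total_cn and minor_cn lengths differ (%d vs %d)",
          length(total_cn), length(minor_cn))
  }
  t_ok <- !is.na(total_cn) & total_cn == round(total_cn)
  m_ok <- !is.na(minor_cn) & minor_cn == round(minor_cn)
  if (!all(t_ok & m_ok)) {
    stop2("classify_state: copy numbers must be non-missing integers (%s)",
          .preview(paste0("(", total_cn[!(t_ok & m_ok)], ",",
                          minor_cn[!(t_ok & m_ok)], ")")))
  }
  total_cn <- as.integer(total_cn)
  minor_cn <- as.integer(minor_cn)
  bad <- total_cn < 0 | minor_cn < 0 | minor_cn > total_cn - minor_cn
  if (any(bad)) {
    stop2(paste0("classify_state: invalid copy-number pair(s) %s; require ",
                 "total_cn >= 0, minor_cn >= 0 and minor_cn <= total_cn - ",
                 "minor_cn (minor allele is the lesser allele)"),
          .preview(paste0("(", total_cn[bad], ",", minor_cn[bad], ")")))
  }
  if (any(total_cn > 8)) {
    warn2("classify_state: total_cn > 8 encountered (%s); classified as AMP",
          .preview(total_cn[total_cn > 8]))
  }
  out <- ifelse(total_cn == 0L, "HOMDEL",
         ifelse(total_cn == 1L, "LOSS",
         ifelse(total_cn == 2L & minor_cn == 0L, "CN_LOH",
         ifelse(total_cn == 2L, "NEUTRAL_HET",
         ifelse(total_cn <= 5L, "GAIN", "AMP")))))
  factor(out, levels = CN_CATEGORIES)
}

#' Loss-of-heterozygosity flag
#'
#' LOH means one parental allele is entirely absent while DNA remains:
#' `minor_cn == 0` with `total_cn >= 1`. A homozygous deletion (total 0) is
#' not LOH.
#'
#' @inheritParams classify_state
#' @return logical vector.
#' @export
is_loh <- function(total_cn, minor_cn) {
  minor_cn == 0L & total_cn >= 1L
}
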