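#' Materialize per-pair results as a cohort table
#'
#' One row per pair in the sample sheet: discordance fractions, three-way
#' LOH-class fractions, per-sample genome-altered and LOH fractions, and
#' WGD flags. Errors name the first patient with a missing input.
#'
#' @param pairs pair records ([read_sample_sheet()] rows); must be non-empty.
#' @param discordance_results list of [compare_pair()] results named by
#'   `patient_id`.
#' @param wgd_calls list of [detect_wgd()] results named by `sample_id`.
#' @param fractions list of [genome_fractions()] results named by
#'   `sample_id`.
#' @return A `cohort_table` data frame; cohort means and ranges per metric
#'   are attached as `attr(, "summary")`.
#' @export
summarize_cohort <- function(pairs, discordance_results, wgd_calls,
                             fractions) {
  pairs <- validate_sample_sheet(pairs)
  if (nrow(pairs) == 0L) stop2("summarize_cohort: empty pair list")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pid <- pairs$patient_id[i]
    ps <- pairs$primary_sample[i]
    ms <- pairs$met_sample[i]
    d <- discordance_results[[pid]]
    if (is.null(d)) stop2("summarize_cohort: no discordance result for %s", pid)
    need <- function(lst, id, what) {
      x <- lst[[id]]
      if (is.null(x)) stop2("summarize_cohort: no %s for sample %s (patient %s)",
                            what, id, pid)
      x
    }
    wp <- need(wgd_calls, ps, "WGD call")
    wm <- need(wgd_calls, ms, "WGD call")
    fp <- need(fractions, ps, "genome fractions")
    fm <- need(fractions, ms, "genome fractions")
    data.frame(patient_id = pid, timing = pairs$timing[i],
               met_exposure = pairs$met_exposure[i],
               n_windows_compared = d$n_windows_compared,
               cn_discordant_fraction = d$cn_discordant_fraction,
               loh_unchanged_fraction = d$loh_unchanged_fraction,
               loh_met_only_fraction = d$loh_met_only_fraction,
               loh_primary_only_fraction = d$loh_primary_only_fraction,
               loh_difference_fraction = d$loh_met_only_fraction +
                 d$loh_primary_only_fraction,
               altered_fraction_primary = unname(fp["altered_fraction"]),
               altered_fraction_met = unname(fm["altered_fraction"]),
               loh_fraction_primary = unname(fp["loh_fraction"]),
               loh_fraction_met = unname(fm["loh_fraction"]),
               wgd_primary = wp$is_wgd, wgd_met = wm$is_wgd,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  metrics <- c("cn_discordant_fraction", "loh_met_only_fraction",
               "loh_primary_only_fraction", "loh_difference_fraction",
               "altered_fraction_primary", "altered_fraction_met",
               "loh_fraction_primary", "loh_fraction_met")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(metric = m, mean = mean(tab[[m]]), min = min(tab[[m]]),
               max = max(tab[[m]]), stringsAsFactors = FALSE)
  }))
  attr(tab, "summary") <- summ
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Two-sample group comparison of a cohort metric
#'
#' Two-tailed Student's t-test between the two levels of a grouping variable
#' (`met_exposure`: naive vs post-therapy; `timing`: synchronous vs
#' metachronous). The default is the pooled-variance (equal-variance) test,
#' matching the classical "Student's t-test"; `var_equal = FALSE` switches
#' to Welch. Raw p-values are reported (no multiple-testing correction);
#' the significance flag uses p < 0.05.
#'
#' @param table a [summarize_cohort()] table (or any data frame with the
#'   metric and grouping columns).
#' @param metric name of the numeric column to compare.
#' @param grouping `"met_exposure"` or `"timing"`.
#' @param var_equal pooled-variance test. Default `TRUE`.
#' @return A `group_comparison` list: `metric`, `grouping`, `groups`, `n`,
#'   `means`, `t`, `df`, `p_value`, `significant`.
#' @export
compare_groups <- function(table, metric,
                           grouping = c("met_exposure", "timing"),
                           var_equal = TRUE) {
  grouping <- match.arg(grouping)
  if (!metric %in% names(table)) {
    stop2("compare_groups: no column '%s' in the cohort table", metric)
  }
  g <- as.character(table[[grouping]])
  x <- table[[metric]]
  levels <- sort(unique(g))
  if (length(levels) != 2L) {
    stop2("compare_groups: grouping '%s' must have exactly 2 levels, found %d",
          grouping, length(levels))
  }
  n <- vapply(levels, function(l) sum(g == l), integer(1))
  if (any(n < 2L)) {
    stop2("compare_groups: group '%s' has n = %d (< 2)",
          levels[which(n < 2)[1]], min(n))
  }
  ht <- stats::t.test(x[g == levels[1]], x[g == levels[2]],
                      var.equal = var_equal, alternative = "two.sided")
  structure(list(
    metric = metric, grouping = grouping, groups = levels, n = n,
    means = setNames(vapply(levels, function(l) mean(x[g == l]), numeric(1)),
                     levels),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, significant = ht$p.value < 0.05,
    var_equal = var_equal
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s (%s)\n", x$metric, x$grouping,
              if (x$var_equal) "pooled-variance t" else "Welch t"))
  cat(sprintf("  %s: n=%d mean=%.4f | %s: n=%d mean=%.4f\n",
              x$groups[1], x$n[1], x$means[1],
              x$groups[2], x$n[2], x$means[2]))
  cat(sprintf("  t = %.4f, df = %.1f, p = %.4g%s\n", x$t, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Tabulate group comparisons
#'
#' @param comparisons list of [compare_groups()] results.
#' @return one row per comparison.
#' @export
comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(x) {
    data.frame(metric = x$metric, grouping = x$grouping,
               group1 = x$groups[1], group2 = x$groups[2],
               n1 = x$n[1], n2 = x$n[2],
               mean1 = x$means[1], mean2 = x$means[2],
               t = x$t, df = x$df, p_value = x$p_value,
               significant = x$significant, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}
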