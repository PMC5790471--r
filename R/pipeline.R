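# End-to-end orchestration: simulate (or read) a paired cohort, call WGD,
# compute windowed discordance, gene-level status, and cohort statistics,
# writing checksum-stable TSVs plus a manifest.

# TSV with a commented provenance header (version, seed, config hash) so
# reruns with the same config produce byte-identical, diff-able files
.write_stage_tsv <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# pairedcna %s; seed=%s; config=%s",
                     as.character(utils::packageVersion("pairedcna")),
                     meta$seed, meta$config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  path
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full paired-discordance pipeline
#'
#' Stages: obtain profiles (simulate a cohort, or read files), per-sample
#' WGD calls and genome fractions, per-pair 10 kb windowed discordance with
#' the +1/+2 correction, gene-panel status / private events / concordance,
#' and cohort group comparisons. Every output TSV carries a commented header
#' with package version, seed and a config hash; `manifest.tsv` lists all
#' files with md5 checksums, and a rerun with the same config and seed
#' reproduces identical checksums.
#'
#' @param outdir output directory (created if absent).
#' @param seed integer seed for every source of randomness.
#' @param input `NULL` to simulate the default cohort, or a list with paths
#'   `sample_sheet`, `profile_dir` (one `<sample_id>.seg.tsv` per sample),
#'   `chrom_sizes`, `genes`.
#' @param design,layout,genes,hotspot_fraction,jitter_sd passed to
#'   [simulate_cohort()] when simulating (`genes = NULL` simulates the
#'   default 188 + 24 panel).
#' @param window_size window size in bp.
#' @param wgd_correction apply the +1/+2 correction to all pairs.
#' @param gene_strict,gene_wgd_correction passed to [private_events()] /
#'   [concordance_rate()].
#' @param write_windows also write per-window discordance labels (BED-like,
#'   one file per pair; large).
#' @return invisibly, a list with the cohort table, group comparisons, gene
#'   summaries and the manifest data frame.
#' @export
run_pipeline <- function(outdir, seed = 1, input = NULL,
                         design = default_cohort_design(),
                         layout = default_layout(), genes = NULL,
                         window_size = 10000,
                         wgd_correction = TRUE, hotspot_fraction = 0.5,
                         jitter_sd = 0.15, gene_strict = FALSE,
                         gene_wgd_correction = TRUE, write_windows = FALSE) {
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop2("stage %s: %s", name, conditionMessage(e))
    })
  }
  config <- list(seed = seed, input = input, window_size = window_size,
                 wgd_correction = wgd_correction,
                 hotspot_fraction = hotspot_fraction, jitter_sd = jitter_sd,
                 gene_strict = gene_strict,
                 gene_wgd_correction = gene_wgd_correction,
                 design = if (is.null(input)) design else NULL,
                 layout = layout, genes = genes)
  meta <- list(seed = seed, config_hash = .config_hash(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  if (is.null(input)) {
    cohort <- stage("simulate",
                    simulate_cohort(design = design, layout = layout,
                                    window_size = window_size, genes = genes,
                                    hotspot_fraction = hotspot_fraction,
                                    jitter_sd = jitter_sd))
    profiles <- cohort$profiles
    sheet <- cohort$sheet
    genes <- cohort$genes
  } else {
    stage("read_inputs", {
      for (f in c("sample_sheet", "chrom_sizes", "genes")) {
        if (is.null(input[[f]]) || !file.exists(input[[f]])) {
          stop2("missing input file '%s'", f)
        }
      }
      layout <- read_chrom_sizes(input$chrom_sizes)
      sheet <- read_sample_sheet(input$sample_sheet)
      genes <- read_gene_annotation(input$genes, layout)
      profiles <- list()
      for (i in seq_len(nrow(sheet))) {
        for (role in c("primary", "metastasis")) {
          sid <- if (role == "primary") sheet$primary_sample[i] else
            sheet$met_sample[i]
          path <- file.path(input$profile_dir, paste0(sid, ".seg.tsv"))
          if (!file.exists(path)) stop2("profile file not found: %s", path)
          purity <- if (role == "primary") sheet$purity_primary[i] else
            sheet$purity_met[i]
          profiles[[sid]] <- read_profile(path, layout, role = role,
                                          purity = purity)
        }
      }
    })
  }

  wgd_calls <- stage("wgd", lapply(profiles, detect_wgd, layout = layout))
  fractions <- stage("fractions", lapply(profiles, genome_fractions))

  grid <- tile_genome(layout, window_size)
  discordance <- stage("compare", {
    res <- list()
    for (i in seq_len(nrow(sheet))) {
      tp <- assign_windows(profiles[[sheet$primary_sample[i]]], grid)
      tm <- assign_windows(profiles[[sheet$met_sample[i]]], grid)
      res[[sheet$patient_id[i]]] <-
        compare_pair(tp, tm, wgd_correction = wgd_correction,
                     patient_id = sheet$patient_id[i])
    }
    res
  })

  statuses <- stage("genes", {
    do.call(rbind, lapply(profiles, gene_status, genes = genes))
  })
  priv <- stage("genes", private_events(sheet, statuses, genes,
                                        strict = gene_strict,
                                        wgd_correction = gene_wgd_correction))
  conc <- stage("genes", concordance_rate(sheet, statuses, genes,
                                          wgd_correction = gene_wgd_correction))

  tab <- stage("cohort", summarize_cohort(sheet, discordance, wgd_calls,
                                          fractions))
  comparisons <- stage("cohort", list(
    compare_groups(tab, "cn_discordant_fraction", "met_exposure"),
    compare_groups(tab, "loh_met_only_fraction", "met_exposure"),
    compare_groups(tab, "loh_primary_only_fraction", "met_exposure"),
    compare_groups(tab, "cn_discordant_fraction", "timing")))

  files <- character(0)
  emit <- function(df, name) {
    files <<- c(files, .write_stage_tsv(df, file.path(outdir, name), meta))
  }
  stage("write", {
    emit(wgd_table(wgd_calls), "wgd_calls.tsv")
    emit(as.data.frame(tab), "cohort_table.tsv")
    emit(comparison_table(comparisons), "group_comparisons.tsv")
    emit(statuses, "gene_status.tsv")
    emit(priv, "private_events.tsv")
    emit(conc$per_gene, "gene_concordance.tsv")
    emit(data.frame(metric = c("n_genes_evaluable", "n_genes_concordant",
                               "concordant_fraction"),
                    value = c(conc$n_genes, conc$n_concordant,
                              conc$fraction)),
         "gene_concordance_summary.tsv")
    if (write_windows) {
      for (pid in names(discordance)) {
        emit(discordance[[pid]]$windows,
             sprintf("windows_%s.tsv", pid))
      }
    }
  })
  manifest <- stage("manifest", {
    m <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)),
                    stringsAsFactors = FALSE)
    utils::write.table(m, file.path(outdir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    m
  })
  invisible(list(cohort_table = tab, comparisons = comparisons,
                 private_events = priv, concordance = conc,
                 wgd_calls = wgd_calls, discordance = discordance,
                 manifest = manifest, config_hash = meta$config_hash))
}
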