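#' Construct a segmented allele-specific copy-number profile
#'
#' One sample's segmented profile: intervals with constant total and
#' minor-allele copy number, 0-based half-open coordinates. Segments are
#' sorted by (chromosome, start) in layout order and must not overlap within
#' a chromosome. Purity is carried as metadata only; profiles below the 50%
#' cellularity inclusion threshold trigger a warning, not an error.
#'
#' @param sample_id sample identifier.
#' @param segments data frame with columns `chromosome`, `start`, `end`,
#'   `total_cn`, `minor_cn` (start/end 0-based half-open, copy numbers
#'   non-negative integers with `minor_cn <= total_cn - minor_cn`).
#' @param role one of `"primary"`, `"metastasis"`, `"normal"`.
#' @param purity tumor cell fraction in \[0, 1\], or `NA` if unknown.
#' @param layout optional [genome_layout()]; when given, segment chromosomes
#'   must exist in it and segments must lie within chromosome bounds.
#' @return A `segmented_profile` object (list with fields `sample_id`,
#'   `role`, `purity`, `segments`).
#' @export
segmented_profile <- function(sample_id, segments,
                              role = c("primary", "metastasis", "normal"),
                              purity = NA_real_, layout = NULL) {
  role <- match.arg(role)
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id) ||
      !nzchar(sample_id)) {
    stop2("segmented_profile: sample_id must be a non-empty string")
  }
  if (!is.na(purity) && (purity < 0 || purity > 1)) {
    stop2("segmented_profile: purity must be in [0, 1], got %s", purity)
  }
  segments <- validate_segments(segments, layout = layout)
  if (!is.na(purity) && purity < 0.5) {
    warn2("sample %s: purity %.2f is below the 0.5 cellularity threshold",
          sample_id, purity)
  }
  structure(list(sample_id = sample_id, role = role, purity = purity,
                 segments = segments),
            class = "segmented_profile")
}

#' Validate and normalize a segment table
#'
#' Checks the segment invariants (start < end; non-negative integer copy
#' numbers; minor allele is the lesser allele; no overlaps within a
#' chromosome; chromosomes present in the layout and segments within bounds
#' when a layout is given) and returns the table sorted by (chromosome in
#' layout order, start).
#'
#' @inheritParams segmented_profile
#' @return the normalized segment data frame.
#' @export
validate_segments <- function(segments, layout = NULL) {
  need <- c("chromosome", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(need, names(segments))
  if (length(miss)) {
    stop2("segments: missing column(s): %s", paste(miss, collapse = ", "))
  }
  segments <- as.data.frame(segments)[need]
  segments$chromosome <- as.character(segments$chromosome)
  for (col in c("start", "end", "total_cn", "minor_cn")) {
    v <- segments[[col]]
    if (any(is.na(v)) || any(v != round(v))) {
      stop2("segments: column %s must be non-missing integers", col)
    }
    segments[[col]] <- as.numeric(v)
  }
  if (any(segments$start < 0)) stop2("segments: start must be >= 0")
  bad <- segments$start >= segments$end
  if (any(bad)) {
    stop2("segments: start >= end at %s", .preview(which(bad)))
  }
  bad <- segments$total_cn < 0 | segments$minor_cn < 0 |
    segments$minor_cn > segments$total_cn - segments$minor_cn
  if (any(bad)) {
    stop2(paste0("segments: invalid copy-number pair(s) %s (need total >= 0, ",
                 "minor >= 0, minor <= total - minor)"),
          .preview(paste0("(", segments$total_cn[bad], ",",
                          segments$minor_cn[bad], ")")))
  }
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "genome_layout"))
    unknown <- setdiff(unique(segments$chromosome), layout$chromosome)
    if (length(unknown)) {
      stop2("segments: chromosome(s) absent from layout: %s", .preview(unknown))
    }
    maxlen <- layout$length[match(segments$chromosome, layout$chromosome)]
    if (any(segments$end > maxlen)) {
      stop2("segments: segment end beyond chromosome length on %s",
            .preview(segments$chromosome[segments$end > maxlen]))
    }
    chrom_rank <- match(segments$chromosome, layout$chromosome)
  } else {
    chrom_rank <- match(segments$chromosome, unique(segments$chromosome))
  }
  segments <- segments[order(chrom_rank, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  # overlap check on the sorted table
  same <- segments$chromosome[-1] == segments$chromosome[-nrow(segments)]
  if (nrow(segments) > 1) {
    olap <- same & segments$start[-1] < segments$end[-nrow(segments)]
    if (any(olap)) {
      i <- which(olap)[1]
      stop2("segments: overlapping segments on %s near position %d",
            segments$chromosome[i + 1], as.integer(segments$start[i + 1]))
    }
  }
  segments
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat(sprintf("<segmented_profile> %s (%s)%s\n", x$sample_id, x$role,
              if (is.na(x$purity)) "" else sprintf(", purity %.2f", x$purity)))
  cat(sprintf("  %d segment(s) on %d chromosome(s), %.1f Mb covered\n",
              nrow(x$segments), length(unique(x$segments$chromosome)),
              sum(x$segments$end - x$segments$start) / 1e6))
  invisible(x)
}

.profile_header <- c("sample_id", "chromosome", "start", "end",
                     "total_cn", "minor_cn")

#' Read a segmented profile (SEG-like TSV)
#'
#' The dialect is a headered TSV with columns `sample_id`, `chromosome`,
#' `start`, `end`, `total_cn`, `minor_cn`; coordinates 0-based half-open.
#' The file must hold a single sample. Malformed rows are reported with
#' their line number (header is line 1).
#'
#' @param path path to the profile TSV.
#' @param layout a [genome_layout()]; rows on chromosomes absent from the
#'   layout are rejected.
#' @inheritParams segmented_profile
#' @return A [segmented_profile()].
#' @export
read_profile <- function(path, layout,
                         role = c("primary", "metastasis", "normal"),
                         purity = NA_real_) {
  role <- match.arg(role)
  if (!file.exists(path)) stop2("profile file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "numeric", "numeric"))
  if (!identical(names(df), .profile_header)) {
    stop2("%s: expected header '%s', found '%s'", path,
          paste(.profile_header, collapse = "\t"),
          paste(names(df), collapse = "\t"))
  }
  if (nrow(df) == 0L) stop2("%s: no segments", path)
  ids <- unique(df$sample_id)
  if (length(ids) != 1L) {
    stop2("%s: expected one sample per file, found %d (%s)", path,
          length(ids), .preview(ids))
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  unknown <- !(df$chromosome %in% layout$chromosome)
  if (any(unknown)) {
    stop2("%s line %d: unknown chromosome '%s'", path,
          line[unknown][1], df$chromosome[unknown][1])
  }
  bad <- df$start >= df$end
  if (any(bad)) {
    stop2("%s line %d: start >= end", path, line[bad][1])
  }
  for (col in c("start", "end", "total_cn", "minor_cn")) {
    v <- df[[col]]
    if (any(is.na(v) | v != round(v))) {
      stop2("%s line %d: non-integer %s", path,
            line[is.na(v) | v != round(v)][1], col)
    }
  }
  prof <- tryCatch(
    segmented_profile(ids, df[, -1], role = role, purity = purity,
                      layout = layout),
    error = function(e) stop2("%s: %s", path, conditionMessage(e)))
  prof
}

#' Write a segmented profile (SEG-like TSV)
#'
#' Inverse of [read_profile()]; `write_profile(read_profile(f))` reproduces
#' the file body byte for byte (fixed header and column order, 0-based
#' half-open coordinates). Set `one_based = TRUE` to emit 1-based inclusive
#' starts for consumption by 1-based tools; such files are reports, not
#' round-trippable inputs.
#'
#' @param profile a [segmented_profile()].
#' @param path output path.
#' @param one_based emit 1-based inclusive coordinates. Default `FALSE`.
#' @export
write_profile <- function(profile, path, one_based = FALSE) {
  stopifnot(inherits(profile, "segmented_profile"))
  seg <- profile$segments
  out <- data.frame(sample_id = profile$sample_id,
                    chromosome = seg$chromosome,
                    start = as.integer(seg$start + if (one_based) 1L else 0L),
                    end = as.integer(seg$end),
                    total_cn = as.integer(seg$total_cn),
                    minor_cn = as.integer(seg$minor_cn))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene annotation (BED4 + optional panel tag)
#'
#' Headerless BED-like TSV: chromosome, start, end (0-based half-open),
#' gene symbol, and an optional fifth column tagging the panel the gene
#' belongs to (`candidate188`, `actionable24` or `both`). The footprint is
#' expected to run from the transcription start site to the last base of the
#' longest transcript.
#'
#' @param path path to the BED file.
#' @param layout a [genome_layout()]; genes on chromosomes absent from the
#'   layout are rejected.
#' @return data frame with columns `symbol`, `chromosome`, `start`, `end`,
#'   `panel` (an empty file gives a zero-row table).
#' @export
read_gene_annotation <- function(path, layout) {
  if (!file.exists(path)) stop2("gene annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(symbol = character(), chromosome = character(),
                      start = numeric(), end = numeric(), panel = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop2("%s line %d: expected at least 4 tab-separated fields", path,
          which(nf < 4)[1])
  }
  df <- data.frame(
    chromosome = vapply(parts, `[[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2))),
    end = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3))),
    symbol = vapply(parts, `[[`, "", 4),
    panel = vapply(parts, function(p) if (length(p) >= 5) p[[5]] else NA_character_, ""),
    stringsAsFactors = FALSE)
  bad <- is.na(df$start) | is.na(df$end) | df$start != round(df$start) |
    df$end != round(df$end)
  if (any(bad)) stop2("%s line %d: non-integer coordinates", path, which(bad)[1])
  if (any(df$start >= df$end)) {
    stop2("%s line %d: start >= end", path, which(df$start >= df$end)[1])
  }
  validate_genes(df[, c("symbol", "chromosome", "start", "end", "panel")],
                 layout = layout)
}

#' @rdname read_gene_annotation
#' @param genes a gene table as returned by [read_gene_annotation()].
#' @export
validate_genes <- function(genes, layout = NULL) {
  need <- c("symbol", "chromosome", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop2("genes: missing column(s): %s",
                          paste(miss, collapse = ", "))
  genes <- as.data.frame(genes)
  if (is.null(genes$panel)) genes$panel <- NA_character_
  genes <- genes[, c("symbol", "chromosome", "start", "end", "panel")]
  if (anyDuplicated(genes$symbol)) {
    stop2("genes: duplicate symbol(s): %s",
          .preview(genes$symbol[duplicated(genes$symbol)]))
  }
  known_panels <- c("candidate188", "actionable24", "both")
  if (any(!is.na(genes$panel) & !(genes$panel %in% known_panels))) {
    stop2("genes: unknown panel tag(s): %s",
          .preview(stats::na.omit(setdiff(genes$panel, known_panels))))
  }
  if (any(genes$start >= genes$end)) {
    stop2("genes: start >= end for %s",
          .preview(genes$symbol[genes$start >= genes$end]))
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(genes$chromosome), layout$chromosome)
    if (length(unknown)) {
      stop2("genes: chromosome(s) absent from layout: %s", .preview(unknown))
    }
  }
  rownames(genes) <- NULL
  genes
}

#' @rdname read_gene_annotation
#' @export
write_gene_annotation <- function(genes, path) {
  genes <- validate_genes(genes)
  out <- data.frame(genes$chromosome, as.integer(genes$start),
                    as.integer(genes$end), genes$symbol)
  if (!all(is.na(genes$panel))) out$panel <- genes$panel
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

#' Read a paired sample sheet
#'
#' Headered TSV pairing each patient's primary tumor and liver metastasis:
#' `patient_id`, `primary_sample`, `met_sample`, `timing`
#' (`synchronous`/`metachronous`), `met_exposure` (`naive`/`post_therapy`),
#' `purity_primary`, `purity_met`.
#'
#' @param path path to the sample sheet TSV.
#' @return validated data frame of pair records.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop2("sample sheet not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a pair-record data frame.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("patient_id", "primary_sample", "met_sample", "timing",
            "met_exposure")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop2("sample sheet: missing column(s): %s",
                          paste(miss, collapse = ", "))
  sheet <- as.data.frame(sheet)
  if (is.null(sheet$purity_primary)) {
    sheet$purity_primary <- rep(NA_real_, nrow(sheet))
  }
  if (is.null(sheet$purity_met)) sheet$purity_met <- rep(NA_real_, nrow(sheet))
  if (anyDuplicated(sheet$patient_id)) {
    stop2("sample sheet: duplicate patient_id(s): %s",
          .preview(sheet$patient_id[duplicated(sheet$patient_id)]))
  }
  same <- sheet$primary_sample == sheet$met_sample
  if (any(same)) {
    stop2("sample sheet: primary and metastasis sample identical for %s",
          .preview(sheet$patient_id[same]))
  }
  if (any(!sheet$timing %in% c("synchronous", "metachronous"))) {
    stop2("sample sheet: timing must be synchronous/metachronous (%s)",
          .preview(setdiff(sheet$timing, c("synchronous", "metachronous"))))
  }
  if (any(!sheet$met_exposure %in% c("naive", "post_therapy"))) {
    stop2("sample sheet: met_exposure must be naive/post_therapy (%s)",
          .preview(setdiff(sheet$met_exposure, c("naive", "post_therapy"))))
  }
  rownames(sheet) <- NULL
  sheet[, c(need, "purity_primary", "purity_met")]
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
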