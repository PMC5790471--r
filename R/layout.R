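#' Construct a genome layout
#'
#' A genome layout is the ordered set of chromosomes (name and length in base
#' pairs) over which all windowed and per-chromosome computations run. The
#' row order is the canonical sort order used by every downstream output.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param len integer vector of chromosome lengths in bp (strictly positive).
#' @return A `genome_layout` data frame with columns `chromosome`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, len) {
  chrom <- as.character(chrom)
  len <- suppressWarnings(as.numeric(len))
  if (length(chrom) != length(len)) {
    stop2("genome_layout: %d chromosome names but %d lengths",
          length(chrom), length(len))
  }
  if (anyDuplicated(chrom)) {
    stop2("genome_layout: duplicate chromosome name(s): %s",
          .preview(chrom[duplicated(chrom)]))
  }
  bad <- is.na(len) | len <= 0 | len != round(len)
  if (any(bad)) {
    stop2("genome_layout: chromosome length must be a positive integer (%s)",
          .preview(paste0(chrom[bad], "=", len[bad])))
  }
  out <- data.frame(chromosome = chrom, length = as.integer(len),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a two-column chromosome-sizes file
#'
#' Plain headerless TSV: chromosome name, length in bp. Sex chromosomes and
#' the mitochondrial contig are dropped by default because the diploid
#' baseline behind the five-category state table does not hold on male X/Y;
#' set `include_sex = TRUE` to keep them.
#'
#' @param path path to the chrom.sizes file.
#' @param include_sex keep X/Y (and chrX/chrY) rows. Default `FALSE`.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, include_sex = FALSE) {
  if (!file.exists(path)) stop2("chromosome sizes file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chromosome", "length"))
  if (!include_sex) {
    drop <- df$chromosome %in% c("X", "Y", "chrX", "chrY", "MT", "chrM", "M")
    df <- df[!drop, , drop = FALSE]
  }
  genome_layout(df$chromosome, df$length)
}

#' @rdname read_chrom_sizes
#' @param layout a [genome_layout()].
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(data.frame(layout$chromosome, layout$length),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Built-in layouts
#'
#' `default_layout()` is a scaled-down genome of 22 equal autosomes (5 Mb
#' each, 110 Mb total: 11,000 windows of 10 kb) that keeps full-pipeline runs
#' fast while leaving enough windows for stable genome fractions.
#' `hg_autosome_layout()` carries full-size human autosome lengths (hg19-like,
#' ~2.88 Gb, ~288,000 windows of 10 kb) for realism runs.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @return A [genome_layout()].
#' @export
default_layout <- function(n_chrom = 22, chrom_length = 5e6) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(chrom_length, n_chrom))
}

#' @rdname default_layout
#' @export
hg_autosome_layout <- function() {
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566)
  genome_layout(paste0("chr", 1:22), len)
}

#' Total genome size of a layout
#' @param layout a [genome_layout()].
#' @return total length in bp.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(as.numeric(layout$length))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %.1f Mb total\n",
              nrow(x), genome_size(x) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("... and %d more\n", nrow(x) - 8))
  invisible(x)
}
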