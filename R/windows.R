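#' Tile a genome into fixed-size windows
#'
#' Windows are adjacent, non-overlapping and cover each chromosome from 0 to
#' its length; every window has length `window_size` except possibly the last
#' per chromosome, which is retained short (length `length %% window_size`)
#' and weighted equally per window in all fractions (regions are counted,
#' not bases).
#'
#' @param layout a [genome_layout()]. An empty layout gives an empty grid.
#' @param window_size window size in bp (default 10 kb).
#' @return A `window_grid` data frame (`chromosome`, `start`, `end`) with the
#'   window size kept in `attr(, "window_size")`.
#' @examples
#' tile_genome(genome_layout("chr1", 25000), 10000)
#' @export
tile_genome <- function(layout, window_size = 10000) {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(window_size) != 1L || is.na(window_size) || window_size <= 0 ||
      window_size != round(window_size)) {
    stop2("tile_genome: window_size must be a positive integer, got %s",
          paste(window_size, collapse = ","))
  }
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    n <- ceiling(len / window_size)
    start <- (seq_len(n) - 1) * window_size
    data.frame(chromosome = layout$chromosome[i], start = start,
               end = pmin(start + window_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- if (length(pieces)) do.call(rbind, pieces) else {
    data.frame(chromosome = character(), start = numeric(), end = numeric())
  }
  rownames(grid) <- NULL
  attr(grid, "window_size") <- window_size
  class(grid) <- c("window_grid", "data.frame")
  grid
}

# Largest-overlap assignment: for each target interval, the index of the
# segment with the largest overlap length; ties broken by smaller segment
# start, then segment index. Shared by window and gene-level calls.
# targets/segments: data frames with chromosome, start, end (0-based
# half-open). Returns NA for targets with no overlapping segment.
.largest_overlap <- function(targets, segments) {
  idx <- rep(NA_integer_, nrow(targets))
  if (nrow(targets) == 0L || nrow(segments) == 0L) return(idx)
  tg <- GenomicRanges::GRanges(targets$chromosome,
                               IRanges::IRanges(targets$start + 1, targets$end))
  sg <- GenomicRanges::GRanges(segments$chromosome,
                               IRanges::IRanges(segments$start + 1, segments$end))
  h <- GenomicRanges::findOverlaps(tg, sg)
  if (length(h) == 0L) return(idx)
  q <- S4Vectors::queryHits(h)
  s <- S4Vectors::subjectHits(h)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(tg)[q],
                                           IRanges::ranges(sg)[s]))
  o <- order(q, -ov, segments$start[s], s)
  keep <- !duplicated(q[o])
  idx[q[o][keep]] <- s[o][keep]
  idx
}

#' Assign per-window copy-number states by largest overlapping segment
#'
#' Each window carries the state of the segment with the largest overlap
#' length within that window (ties broken by the leftmost segment start).
#' Windows with no overlapping segment are missing (`NA` state) and are
#' excluded from paired comparisons.
#'
#' @param profile a [segmented_profile()].
#' @param grid a [tile_genome()] window grid.
#' @return A `window_state_track`: the grid plus columns `total_cn`,
#'   `minor_cn`, `loh`, `category`, with `attr(, "sample_id")`.
#' @export
assign_windows <- function(profile, grid) {
  stopifnot(inherits(profile, "segmented_profile"),
            inherits(grid, "window_grid"))
  seg <- profile$segments
  idx <- .largest_overlap(grid, seg)
  track <- as.data.frame(grid)
  track$total_cn <- seg$total_cn[idx]
  track$minor_cn <- seg$minor_cn[idx]
  track$loh <- is_loh(track$total_cn, track$minor_cn)
  track$category <- factor(NA_character_, levels = CN_CATEGORIES)
  hit <- !is.na(idx)
  if (any(hit)) {
    track$category[hit] <- classify_state(track$total_cn[hit],
                                          track$minor_cn[hit])
  }
  attr(track, "window_size") <- attr(grid, "window_size")
  attr(track, "sample_id") <- profile$sample_id
  class(track) <- c("window_state_track", "data.frame")
  track
}
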