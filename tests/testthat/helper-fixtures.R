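# small constructors shared across test files

toy_layout <- function(n = 2, len = 30000) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

# profile with a uniform (total, minor) state genome-wide
uniform_profile <- function(layout, total, minor, sample_id = "S1",
                            role = "primary") {
  seg <- data.frame(chromosome = layout$chromosome, start = 0,
                    end = layout$length, total_cn = total, minor_cn = minor)
  segmented_profile(sample_id, seg, role = role, layout = layout)
}

mk_profile <- function(segments, layout, sample_id = "S1",
                       role = "primary") {
  segmented_profile(sample_id, segments, role = role, layout = layout)
}

seg_row <- function(chrom, start, end, total, minor) {
  data.frame(chromosome = chrom, start = start, end = end, total_cn = total,
             minor_cn = minor)
}

# one-window track pair from explicit states, for rule-level tests
track_from_states <- function(states, layout, window_size,
                              sample_id = "S1") {
  seg <- do.call(rbind, states)
  assign_windows(mk_profile(seg, layout, sample_id),
                 tile_genome(layout, window_size))
}
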