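# small in-code fixtures shared across test files

demo_event <- function(event_id = "ev1", event_type = "SE", chrom = "chr1",
                       strand = "+", body_start = 1000, body_end = 1200,
                       upstream_limit = 600, downstream_limit = 1600,
                       psi = 0.5) {
  list(event_id = event_id, event_type = event_type, chrom = chrom,
       strand = strand, body_start = body_start, body_end = body_end,
       upstream_limit = upstream_limit, downstream_limit = downstream_limit,
       psi = psi)
}

write_tmp_track <- function(lines) {
  path <- tempfile(fileext = ".bedgraph")
  writeLines(lines, path)
  path
}

# a track with constant value over [0, n_bp) of chr1
constant_track <- function(value = 0.5, n_bp = 4000, resolution = 20) {
  read_track(write_tmp_track(sprintf("chr1\t0\t%d\t%s", n_bp, value)),
             resolution)
}

# four well-separated shapes at the stated study conditions
four_shapes <- function(noise_sd = 0.1, jitter_bins = 2L) {
  shape_library(noise_sd = noise_sd, jitter_bins = jitter_bins)[
    c("flat_low", "flat_high", "step_up", "step_down")]
}
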