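#' Prototype shape specification for synthetic profiles
#'
#' A shape is a prototype function over the normalized profile coordinate
#' `u` in `[0, 1]` (the untruncated profile runs I/E intron, I/E exon, E/I
#' exon, E/I intron, with block boundaries at 0.25, 0.5 and 0.75) returning
#' a methylation level in `[0, 1]`, plus the noise and length-perturbation
#' parameters used when sampling profiles from it.
#'
#' @param name shape name (used as the true cluster label).
#' @param fn vectorized function `u -> level`.
#' @param noise_sd per-bin Gaussian noise standard deviation (default 0.1).
#' @param jitter_bins maximal total-length jitter in bins, applied
#'   symmetrically (default 2, i.e. lengths vary by -2..+2 bins).
#' @param trunc_prob probability that a sampled profile has one intron side
#'   truncated (default 0).
#' @param trunc_max maximal truncated bins per event (default 3).
#' @return a `shape_spec` object.
#' @export
shape_spec <- function(name, fn, noise_sd = 0.1, jitter_bins = 2L,
                       trunc_prob = 0, trunc_max = 3L) {
  stopifnot(is.function(fn), noise_sd >= 0, jitter_bins >= 0,
            trunc_prob >= 0, trunc_prob <= 1)
  structure(list(name = name, fn = fn, noise_sd = noise_sd,
                 jitter_bins = as.integer(jitter_bins),
                 trunc_prob = trunc_prob, trunc_max = as.integer(trunc_max)),
            class = "shape_spec")
}

#' Library of border-profile shapes
#'
#' Six prototype shapes emulating the recurring methylation patterns at
#' exon-intron borders: uniformly low or high methylation, a methylation
#' step up or down across the exon (high/low exon body versus introns), a
#' dip localized at the two borders, and a monotone ramp.
#'
#' @param noise_sd,jitter_bins,trunc_prob,trunc_max defaults stamped into
#'   every returned spec (see [shape_spec()]).
#' @return named list of `shape_spec` objects.
#' @export
shape_library <- function(noise_sd = 0.1, jitter_bins = 2L, trunc_prob = 0,
                          trunc_max = 3L) {
  mk <- function(name, fn) shape_spec(name, fn, noise_sd, jitter_bins,
                                      trunc_prob, trunc_max)
  exonic <- function(u) u >= 0.25 & u < 0.75
  list(
    flat_low = mk("flat_low", function(u) rep(0.15, length(u))),
    flat_high = mk("flat_high", function(u) rep(0.85, length(u))),
    step_up = mk("step_up", function(u) ifelse(exonic(u), 0.8, 0.2)),
    step_down = mk("step_down", function(u) ifelse(exonic(u), 0.2, 0.8)),
    dip_border = mk("dip_border", function(u)
      0.75 - 0.55 * (exp(-(u - 0.25)^2 / (2 * 0.05^2)) +
                     exp(-(u - 0.75)^2 / (2 * 0.05^2)))),
    ramp = mk("ramp", function(u) 0.1 + 0.8 * u))
}

# sample one profile from a shape: jittered length, noise, optional
# intron-side truncation; returns a meth_profile
sample_profile <- function(shape, event_id, flank_bins = 10L, bin_size = 20L) {
  j <- if (shape$jitter_bins > 0)
    sample(seq.int(-shape$jitter_bins, shape$jitter_bins), 1L) else 0L
  blocks <- c(ie_pre = flank_bins, ie_post = flank_bins,
              ei_pre = flank_bins, ei_post = flank_bins)
  # spread the length jitter over the two outer intron ends
  if (j != 0L) {
    half <- abs(j) %/% 2L
    rest <- abs(j) - half
    blocks["ie_pre"] <- blocks["ie_pre"] + sign(j) * rest
    blocks["ei_post"] <- blocks["ei_post"] + sign(j) * half
  }
  if (shape$trunc_prob > 0 && runif(1) < shape$trunc_prob) {
    t <- sample(shape$trunc_max, 1L)
    side <- sample(c("ie_pre", "ei_post"), 1L)
    blocks[side] <- max(2L, blocks[side] - t)
  }
  L <- sum(blocks)
  u <- (seq_len(L) - 0.5) / L
  v <- shape$fn(u)
  if (shape$noise_sd > 0) v <- v + rnorm(L, 0, shape$noise_sd)
  v <- pmin(pmax(v, 0), 1)
  new_profile(event_id, v, blocks[["ie_pre"]], blocks[["ie_post"]],
              blocks[["ei_pre"]], blocks[["ei_post"]], bin_size)
}

#' Generate labeled synthetic profiles
#'
#' Draws `n_per_shape` profiles from each shape: the prototype sampled at
#' the (jittered) length plus clipped Gaussian noise, with optional
#' truncation of an intron-side block. Pure function of (shapes, seed).
#'
#' @param shapes named list of `shape_spec` objects (e.g. a subset of
#'   [shape_library()]).
#' @param n_per_shape profiles per shape.
#' @param seed RNG seed.
#' @param flank_bins untruncated bins per border side (default 10, i.e.
#'   200 bp at 20 bp bins).
#' @param bin_size bp per bin.
#' @return list with `profiles` (named list of `meth_profile`) and
#'   `labels` (named character vector, event_id -> shape name).
#' @export
make_profiles <- function(shapes, n_per_shape, seed = 1, flank_bins = 10L,
                          bin_size = 20L) {
  stopifnot(length(shapes) >= 1, n_per_shape >= 1)
  with_seed(seed, {
    profiles <- list()
    labels <- character(0)
    k <- 0L
    for (shape in shapes) {
      for (i in seq_len(n_per_shape)) {
        k <- k + 1L
        id <- sprintf("ev%05d", k)
        profiles[[id]] <- sample_profile(shape, id, flank_bins, bin_size)
        labels[id] <- shape$name
      }
    }
    list(profiles = profiles, labels = labels)
  })
}

.dna <- c("A", "C", "G", "T")

#' Generate a synthetic track, event table and border FASTA
#'
#' Writes a consistent set of inputs for the full pipeline: a bedGraph
#' methylation track whose binned values around each event's borders
#' realize the event's shape prototype (plus noise), an AS-event table
#' whose inclusion score psi is positively coupled to the event's mean
#' methylation, and a FASTA of border-region sequences with shape-dependent
#' motif planting for enrichment tests. Events are laid out on the bin grid
#' without border-region overlap; minus-strand events have their profile
#' written reversed onto the genome. Pure function of its arguments and
#' `seed`.
#'
#' @param shapes named list of `shape_spec` objects; events are assigned to
#'   shapes round-robin. (Length jitter and truncation do not apply here:
#'   the genomic layout fixes the region sizes; profile-length variation is
#'   exercised through [make_profiles()].)
#' @param n_events total number of events.
#' @param genome_size chromosome length in bp.
#' @param seed RNG seed.
#' @param out_dir output directory (created if needed).
#' @param flank_bp flank width (default 200); event bodies are `2*flank_bp`
#'   long so the border blocks tile the event exactly.
#' @param bin_size bp per bin (default 20).
#' @param psi_base,psi_coupling,psi_noise inclusion-score model:
#'   `psi = clip(psi_base + psi_coupling * mean_methylation + noise)`.
#' @param planted_motif IUPAC string planted into border sequences.
#' @param motif_rate_in,motif_rate_out planting probability for events of
#'   `motif_shape` versus all other shapes.
#' @param motif_shape shape name receiving `motif_rate_in` (default: first
#'   shape).
#' @return list of file paths: `track`, `events`, `fasta`, `truth`.
#' @export
make_track_and_events <- function(shapes, n_events, genome_size = 2e6,
                                  seed = 1, out_dir = tempfile("synth"),
                                  flank_bp = 200L, bin_size = 20L,
                                  psi_base = 0.1, psi_coupling = 0.6,
                                  psi_noise = 0.1,
                                  planted_motif = "TGCATG",
                                  motif_rate_in = 0.8, motif_rate_out = 0.1,
                                  motif_shape = NULL) {
  stopifnot(length(shapes) >= 1, n_events >= 1)
  stride <- 4L * flank_bp + 2L * flank_bp   # event span + spacer introns
  if (n_events * stride + flank_bp > genome_size)
    stop(sprintf("make_track_and_events: genome of %g bp too small for %d events (need %d bp)",
                 genome_size, n_events, n_events * stride + flank_bp))
  if (is.null(motif_shape)) motif_shape <- shapes[[1]]$name
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(track = file.path(out_dir, "track.bedgraph"),
                events = file.path(out_dir, "events.tsv"),
                fasta = file.path(out_dir, "borders.fasta"),
                truth = file.path(out_dir, "truth.tsv"))
  flank_bins <- flank_bp %/% bin_size

  with_seed(seed, {
    track_lines <- character(0)
    ev_rows <- NULL
    fasta_lines <- character(0)
    truth <- NULL
    for (e in seq_len(n_events)) {
      shape <- shapes[[(e - 1L) %% length(shapes) + 1L]]
      id <- sprintf("ev%05d", e)
      base <- (e - 1L) * stride
      body_start <- base + 2L * flank_bp
      body_end <- body_start + 2L * flank_bp
      strand <- if (runif(1) < 0.5) "-" else "+"
      L <- 4L * flank_bins
      u <- (seq_len(L) - 0.5) / L
      v <- pmin(pmax(shape$fn(u) + rnorm(L, 0, shape$noise_sd), 0), 1)
      genomic <- if (strand == "-") rev(v) else v
      starts <- body_start - flank_bp + (seq_len(L) - 1L) * bin_size
      track_lines <- c(track_lines, sprintf("chrS\t%d\t%d\t%s", starts,
                                            starts + bin_size,
                                            formatC(genomic, format = "g",
                                                    digits = 17)))
      psi <- min(max(psi_base + psi_coupling * mean(v) +
                       rnorm(1, 0, psi_noise), 0), 1)
      ev_rows <- rbind(ev_rows, data.frame(
        event_id = id, event_type = "SE", chrom = "chrS", strand = strand,
        body_start = body_start, body_end = body_end,
        upstream_limit = body_start - 2L * flank_bp,
        downstream_limit = body_end + 2L * flank_bp,
        psi = round(psi, 4),
        fpkm = round(exp(rnorm(1, 2, 1)), 3),
        tss_distance = sample.int(100000L, 1L),
        stringsAsFactors = FALSE))
      for (side in c("IE", "EI")) {
        sq <- paste(sample(.dna, 2L * flank_bp, replace = TRUE), collapse = "")
        rate <- if (shape$name == motif_shape) motif_rate_in else motif_rate_out
        if (runif(1) < rate) {
          pos <- sample.int(2L * flank_bp - nchar(planted_motif), 1L)
          substr(sq, pos, pos + nchar(planted_motif) - 1L) <- planted_motif
        }
        fasta_lines <- c(fasta_lines, sprintf(">%s|%s", id, side), sq)
      }
      truth <- rbind(truth, data.frame(event_id = id, shape = shape$name,
                                       stringsAsFactors = FALSE))
    }
    writeLines(track_lines, paths$track)
    write_report(paths$events, ev_rows)
    writeLines(fasta_lines, paths$fasta)
    write_report(paths$truth, truth)
  })
  paths
}
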