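#' Construct a border-profile object
#'
#' A profile is the concatenation of the two border blocks of one AS event,
#' in transcript orientation: first the I/E block (intron to exon), then the
#' E/I block (exon to intron). Each block carries the number of bins before
#' (`pre`) and after (`post`) its border, so bins can be addressed by signed
#' offset from the border (offset 0 = first bin after the border).
#'
#' @param event_id event identifier.
#' @param values numeric vector, one entry per bin.
#' @param ie_pre,ie_post bins before/after the I/E border (intron/exon side).
#' @param ei_pre,ei_post bins before/after the E/I border (exon/intron side).
#' @param bin_size bp per bin.
#' @return a `meth_profile` object; `border_index` is the 0-based position
#'   in `values` where the E/I block begins (equals `ie_pre + ie_post`).
#' @export
new_profile <- function(event_id, values, ie_pre, ie_post, ei_pre, ei_post,
                        bin_size = 20L) {
  stopifnot(length(values) == ie_pre + ie_post + ei_pre + ei_post,
            ie_pre + ie_post >= 2, ei_pre + ei_post >= 2)
  structure(list(event_id = as.character(event_id),
                 values = as.numeric(values),
                 ie_pre = as.integer(ie_pre), ie_post = as.integer(ie_post),
                 ei_pre = as.integer(ei_pre), ei_post = as.integer(ei_post),
                 border_index = as.integer(ie_pre + ie_post),
                 bin_size = as.integer(bin_size)),
            class = "meth_profile")
}

#' @export
print.meth_profile <- function(x, ...) {
  cat(sprintf("Profile %s: %d bins (I/E %d+%d | E/I %d+%d), %d bp bins\n",
              x$event_id, length(x$values), x$ie_pre, x$ie_post,
              x$ei_pre, x$ei_post, x$bin_size))
  invisible(x)
}

#' Extract the genomic interval of one border region
#'
#' Returns the interval covering up to `flank_bp` on each side of the
#' chosen border of an event. Sides are genomic: `"IE"` is the border at
#' `body_start`, `"EI"` the border at `body_end` (for minus-strand events
#' the transcript-orientation roles are swapped later by [build_profile()],
#' which reverses the values; the genomic interval itself is
#' strand-independent). The outward (intron-side) extension is truncated at
#' `upstream_limit` / `downstream_limit` when the neighboring exon/intron
#' border is closer than `flank_bp`; truncation drops partial bins (floored
#' to whole bins relative to the border).
#'
#' @param event one row of a validated event table (list or 1-row
#'   data.frame).
#' @param side `"IE"` (border at `body_start`) or `"EI"` (at `body_end`).
#' @param flank_bp flank width in bp, a multiple of `bin_size`.
#' @param bin_size bp per bin.
#' @return list with `start`, `end` (0-based half-open genomic interval),
#'   `border` (border coordinate), `pre_bins`, `post_bins` (bins before/
#'   after the border in genomic orientation).
#' @export
extract_border_region <- function(event, side = c("IE", "EI"), flank_bp = 200L,
                                  bin_size = 20L) {
  side <- match.arg(side)
  stopifnot(flank_bp %% bin_size == 0)
  full <- flank_bp %/% bin_size
  if (side == "IE") {
    border <- event$body_start
    avail <- border - event$upstream_limit          # outward room, bp
    pre <- min(full, floor(avail / bin_size))       # intron side, truncated
    post <- full                                    # exon side
  } else {
    border <- event$body_end
    avail <- event$downstream_limit - border
    pre <- full                                     # exon side
    post <- min(full, floor(avail / bin_size))      # intron side, truncated
  }
  if (pre < 1 || post < 1)
    stop(sprintf("extract_border_region: event %s side %s collapses to zero bins",
                 event$event_id, side))
  list(start = border - pre * bin_size, end = border + post * bin_size,
       border = border, pre_bins = as.integer(pre), post_bins = as.integer(post))
}

# read profile bins for a genomic interval as overlap-weighted means of
# track bins (exact copies when the interval is aligned to the track grid)
read_region_values <- function(track, chrom, start, end, bin_size) {
  res <- track$resolution
  nbin <- (end - start) %/% bin_size
  vals <- numeric(nbin)
  for (b in seq_len(nbin)) {
    a0 <- start + (b - 1) * bin_size
    a1 <- a0 + bin_size
    t0 <- floor(a0 / res)
    t1 <- ceiling(a1 / res) - 1
    tv <- track_bins(track, chrom, t0, t1 + 1)
    ov <- pmin(a1, (t0:t1 + 1) * res) - pmax(a0, (t0:t1) * res)
    ok <- !is.na(tv) & ov > 0
    vals[b] <- if (any(ok)) sum(tv[ok] * ov[ok]) / sum(ov[ok]) else NA_real_
  }
  vals
}

# linear interpolation of interior NA runs of length <= max_gap;
# returns NULL if longer runs or edge runs remain
impute_gaps <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    len <- r$lengths[k]
    i0 <- pos[k]; i1 <- i0 + len - 1L
    if (len > max_gap || i0 == 1L || i1 == length(v)) return(NULL)
    left <- v[i0 - 1L]; right <- v[i1 + 1L]
    v[i0:i1] <- left + (right - left) * seq_len(len) / (len + 1)
  }
  v
}

#' Build the combined border profile of one event
#'
#' Reads the two border regions of an event from a binned methylation
#' track, concatenates them in transcript orientation (I/E block first; for
#' minus-strand events the genomic values are reversed so the vector runs
#' 5' to 3'), and linearly interpolates isolated missing bins. Events with
#' a missing run longer than `max_gap`, with missing bins at the profile
#' edges, or with an unusably truncated border region yield `NULL` (use
#' [build_profiles()] to collect drop reasons over a table of events).
#'
#' @param track a `meth_track` from [read_track()].
#' @param event one validated event (list or 1-row data.frame).
#' @param flank_bp flank width in bp (default 200).
#' @param max_gap longest missing-bin run to interpolate (default 2).
#' @param bin_size bp per bin; defaults to the track resolution.
#' @return a `meth_profile`, or `NULL` with attribute-free drop (see
#'   [build_profiles()] for the logged reason).
#' @export
build_profile <- function(track, event, flank_bp = 200L, max_gap = 2L,
                          bin_size = track$resolution) {
  left <- tryCatch(extract_border_region(event, "IE", flank_bp, bin_size),
                   error = function(e) NULL)
  right <- tryCatch(extract_border_region(event, "EI", flank_bp, bin_size),
                    error = function(e) NULL)
  if (is.null(left) || is.null(right)) return(NULL)
  vl <- read_region_values(track, event$chrom, left$start, left$end, bin_size)
  vr <- read_region_values(track, event$chrom, right$start, right$end, bin_size)
  if (identical(event$strand, "-")) {
    values <- c(rev(vr), rev(vl))
    ie <- c(pre = right$post_bins, post = right$pre_bins)
    ei <- c(pre = left$post_bins, post = left$pre_bins)
  } else {
    values <- c(vl, vr)
    ie <- c(pre = left$pre_bins, post = left$post_bins)
    ei <- c(pre = right$pre_bins, post = right$post_bins)
  }
  if (all(is.na(values))) return(NULL)
  values <- impute_gaps(values, max_gap)
  if (is.null(values)) return(NULL)
  new_profile(event$event_id, values, ie[["pre"]], ie[["post"]],
              ei[["pre"]], ei[["post"]], bin_size)
}

#' Build profiles for a table of events
#'
#' @param track a `meth_track`.
#' @param events validated event data.frame (see [read_events()]).
#' @inheritParams build_profile
#' @return list with `profiles` (list of `meth_profile`) and `dropped`
#'   (data.frame of `event_id`, `reason`).
#' @export
build_profiles <- function(track, events, flank_bp = 200L, max_gap = 2L,
                           bin_size = track$resolution) {
  profiles <- list()
  drop_id <- character(0)
  drop_why <- character(0)
  for (i in seq_len(nrow(events))) {
    ev <- as.list(events[i, , drop = FALSE])
    p <- tryCatch(
      build_profile(track, ev, flank_bp, max_gap, bin_size),
      error = function(e) NULL)
    if (is.null(p)) {
      drop_id <- c(drop_id, as.character(ev$event_id))
      drop_why <- c(drop_why, drop_reason(track, ev, flank_bp, max_gap, bin_size))
    } else {
      profiles[[length(profiles) + 1L]] <- p
    }
  }
  names(profiles) <- vapply(profiles, function(p) p$event_id, character(1))
  list(profiles = profiles,
       dropped = data.frame(event_id = drop_id, reason = drop_why,
                            stringsAsFactors = FALSE))
}

# classify why an event yields no profile (for the drop log)
drop_reason <- function(track, ev, flank_bp, max_gap, bin_size) {
  left <- tryCatch(extract_border_region(ev, "IE", flank_bp, bin_size),
                   error = function(e) NULL)
  right <- tryCatch(extract_border_region(ev, "EI", flank_bp, bin_size),
                    error = function(e) NULL)
  if (is.null(left) || is.null(right)) return("border region collapses to zero bins")
  vl <- read_region_values(track, ev$chrom, left$start, left$end, bin_size)
  vr <- read_region_values(track, ev$chrom, right$start, right$end, bin_size)
  if (all(is.na(c(vl, vr)))) return("all bins missing")
  sprintf("missing-bin run longer than max_gap=%d (or at profile edge)", max_gap)
}

#' Quantile-normalize methylation tracks across samples
#'
#' Standard quantile normalization over the genome-wide binned values:
#' each sample's sorted non-missing values are replaced by the
#' across-sample mean of order statistics (ties share the mean of the
#' reference values they span). Missing bins stay missing. Delegates to
#' `limma::normalizeQuantiles`.
#'
#' @param tracks list of `meth_track` objects on the same bin grid
#'   (same resolution, chromosomes, and bin counts), or a numeric matrix
#'   with one column per sample.
#' @return list of normalized `meth_track` objects (or the normalized
#'   matrix when a matrix was given).
#' @export
quantile_normalize <- function(tracks) {
  if (is.matrix(tracks)) {
    stopifnot(ncol(tracks) >= 2)
    return(limma::normalizeQuantiles(tracks, ties = TRUE))
  }
  stopifnot(length(tracks) >= 2)
  res <- tracks[[1]]$resolution
  chroms <- names(tracks[[1]]$chroms)
  lens <- lengths(tracks[[1]]$chroms)
  for (tr in tracks[-1]) {
    if (tr$resolution != res || !identical(names(tr$chroms), chroms) ||
        !identical(lengths(tr$chroms), lens))
      stop("quantile_normalize: tracks are on different bin grids")
  }
  mat <- vapply(tracks, function(tr) unlist(tr$chroms, use.names = FALSE),
                numeric(sum(lens)))
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  lapply(seq_along(tracks), function(s) {
    v <- norm[, s]
    out <- tracks[[s]]
    off <- 0L
    for (ch in chroms) {
      out$chroms[[ch]] <- v[(off + 1L):(off + lens[[ch]])]
      off <- off + lens[[ch]]
    }
    out
  })
}

#' Long-format bin table of a profile set
#'
#' One row per (event, block, signed border offset): offset `-k` is the
#' k-th bin before the block's border, offset `k-1 >= 0` the k-th bin after
#' it. This is the alignment used for bin-wise border tests and median
#' profiles, where truncated profiles contribute only the bins they have.
#'
#' @param profiles list of `meth_profile` objects.
#' @return data.frame with columns `event_id`, `block` ("IE"/"EI"),
#'   `offset`, `value`.
#' @export
profile_bin_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    off <- c(seq.int(-p$ie_pre, p$ie_post - 1L),
             seq.int(-p$ei_pre, p$ei_post - 1L))
    blk <- rep(c("IE", "EI"), c(p$ie_pre + p$ie_post, p$ei_pre + p$ei_post))
    data.frame(event_id = p$event_id, block = blk, offset = off,
               value = p$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write / read a profile set as TSV
#'
#' Columns: `event_id`, the four block extents, `bin_size`, and the
#' comma-joined bin values. Deterministic formatting.
#'
#' @param path TSV file.
#' @param profiles list of `meth_profile` objects.
#' @export
write_profiles <- function(path, profiles) {
  df <- data.frame(
    event_id = vapply(profiles, function(p) p$event_id, character(1)),
    ie_pre = vapply(profiles, function(p) p$ie_pre, integer(1)),
    ie_post = vapply(profiles, function(p) p$ie_post, integer(1)),
    ei_pre = vapply(profiles, function(p) p$ei_pre, integer(1)),
    ei_post = vapply(profiles, function(p) p$ei_post, integer(1)),
    bin_size = vapply(profiles, function(p) p$bin_size, integer(1)),
    values = vapply(profiles, function(p)
      paste(formatC(p$values, format = "g", digits = 12), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  write_report(path, df)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    new_profile(df$event_id[i],
                as.numeric(strsplit(df$values[i], ",")[[1]]),
                df$ie_pre[i], df$ie_post[i], df$ei_pre[i], df$ei_post[i],
                df$bin_size[i])
  })
  names(out) <- df$event_id
  out
}
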