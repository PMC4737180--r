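#' Read a binned methylation track from a bedGraph file
#'
#' Parses a bedGraph-dialect file (four whitespace-separated columns:
#' chrom, start, end, methylation level in `[0,1]`; 0-based half-open
#' coordinates) and digitizes it into fixed-size bins anchored at
#' coordinate 0 of each chromosome. Each bin's value is the mean of the
#' overlapping interval values weighted by overlap length, with the
#' denominator restricted to the covered part of the bin. Bins with no
#' coverage are `NA` (missing), which is distinct from a measured level of
#' zero.
#'
#' @param path bedGraph file.
#' @param resolution bin width in bp (default 20).
#' @return a `meth_track` object: list with `resolution` and `chroms`, a
#'   named list of per-chromosome numeric vectors (bin i covers
#'   `[(i-1)*resolution, i*resolution)`).
#' @export
read_track <- function(path, resolution = 20L) {
  stopifnot(resolution >= 1)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(structure(list(resolution = as.integer(resolution), chroms = list()),
                     class = "meth_track"))
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- idx[which(nf != 4L)[1L]]
    stop(sprintf("read_track: malformed line %d (expected 4 fields, got %d)",
                 bad, nf[which(nf != 4L)[1L]]))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  chrom <- m[, 1L]
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  value <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(value) |
                 start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("read_track: malformed line %d (bad coordinates or value)",
                 idx[bad[1L]]))
  out_of_range <- which(value < 0 | value > 1)
  if (length(out_of_range))
    stop(sprintf("read_track: value %g outside [0,1] at line %d",
                 value[out_of_range[1L]], idx[out_of_range[1L]]))

  res <- as.numeric(resolution)
  chroms <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- start[sel]; e <- end[sel]; v <- value[sel]
    nbin <- as.integer(ceiling(max(e) / res))
    wsum <- numeric(nbin)
    cov <- numeric(nbin)
    for (k in seq_along(s)) {
      b0 <- floor(s[k] / res)            # 0-based first bin
      b1 <- ceiling(e[k] / res) - 1      # 0-based last bin
      for (b in b0:b1) {
        ov <- min(e[k], (b + 1) * res) - max(s[k], b * res)
        if (ov > 0) {
          wsum[b + 1L] <- wsum[b + 1L] + ov * v[k]
          cov[b + 1L] <- cov[b + 1L] + ov
        }
      }
    }
    vals <- rep(NA_real_, nbin)
    covered <- cov > 0
    vals[covered] <- wsum[covered] / cov[covered]
    chroms[[ch]] <- vals
  }
  structure(list(resolution = as.integer(resolution), chroms = chroms),
            class = "meth_track")
}

#' @export
print.meth_track <- function(x, ...) {
  cat(sprintf("Methylation track: %d chromosome(s), %d bp bins\n",
              length(x$chroms), x$resolution))
  for (ch in names(x$chroms)) {
    v <- x$chroms[[ch]]
    cat(sprintf("  %s: %d bins, %.1f%% covered\n", ch, length(v),
                100 * mean(!is.na(v))))
  }
  invisible(x)
}

# track values for genomic bins [from, to) on one chromosome, NA outside
track_bins <- function(track, chrom, bin_from, bin_to) {
  v <- track$chroms[[chrom]]
  if (is.null(v)) return(rep(NA_real_, bin_to - bin_from))
  idx <- seq.int(bin_from + 1L, bin_to)
  out <- rep(NA_real_, length(idx))
  ok <- idx >= 1L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

as_event_row <- function(df) df

.event_required <- c("event_id", "event_type", "chrom", "strand",
                     "body_start", "body_end", "upstream_limit",
                     "downstream_limit")
.event_optional <- c("psi", "fpkm", "tss_distance")

#' Read an alternative-splicing event table
#'
#' Reads a TSV with a header naming the event fields. Mandatory columns:
#' `event_id`, `event_type` (SE or RI), `chrom`, `strand` (+/-),
#' `body_start`, `body_end` (0-based half-open coordinates of the skipped
#' exon or retained intron), `upstream_limit`, `downstream_limit` (nearest
#' neighboring exon/intron borders bounding the flank expansion). Optional:
#' `psi` (inclusion score in `[0,1]`), `fpkm`, `tss_distance`, plus any
#' further numeric property columns, which are retained.
#'
#' Rows violating the invariants (`body_start < body_end`,
#' `upstream_limit <= body_start`, `body_end <= downstream_limit`, `psi` in
#' `[0,1]`, valid type/strand) are rejected and collected in a report
#' rather than aborting the read.
#'
#' @param path TSV file with header.
#' @return list with `events` (validated data.frame) and `rejected`
#'   (data.frame with `event_id`, `line`, `reason`).
#' @export
read_events <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.event_required, names(df))
  if (length(missing_cols))
    stop(sprintf("read_events: missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  for (col in c("body_start", "body_end", "upstream_limit", "downstream_limit"))
    df[[col]] <- as.numeric(df[[col]])

  reasons <- character(nrow(df))
  add_reason <- function(bad, why) {
    hit <- bad & !nzchar(reasons)
    reasons[hit] <<- why
  }
  add_reason(!df$event_type %in% c("SE", "RI"), "event_type not SE or RI")
  add_reason(!df$strand %in% c("+", "-"), "strand not + or -")
  add_reason(!is.finite(df$body_start) | !is.finite(df$body_end) |
               df$body_start >= df$body_end, "body_start >= body_end")
  add_reason(is.finite(df$upstream_limit) & df$upstream_limit > df$body_start,
             "upstream_limit > body_start")
  add_reason(is.finite(df$body_end) & is.finite(df$downstream_limit) &
               df$body_end > df$downstream_limit, "body_end > downstream_limit")
  if ("psi" %in% names(df)) {
    psi <- as.numeric(df$psi)
    add_reason(!is.na(psi) & (psi < 0 | psi > 1), "psi out of range")
    df$psi <- psi
  }
  dup <- duplicated(df$event_id)
  add_reason(dup, "duplicate event_id")

  bad <- nzchar(reasons)
  rejected <- data.frame(event_id = as.character(df$event_id[bad]),
                         line = which(bad) + 1L,  # +1 for the header line
                         reason = reasons[bad],
                         stringsAsFactors = FALSE)
  list(events = df[!bad, , drop = FALSE], rejected = rejected)
}

.iupac_codes <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")

#' Read a splicing-motif list
#'
#' Two-column TSV without header: motif name, IUPAC consensus string.
#'
#' @param path motif file.
#' @return a `motif_set` data.frame with columns `name` and `consensus`.
#' @export
read_motifs <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L)
    stop("read_motifs: expected two tab-separated columns (name, consensus)")
  names(df) <- c("name", "consensus")
  df$consensus <- toupper(df$consensus)
  for (i in seq_len(nrow(df))) {
    chars <- strsplit(df$consensus[i], "")[[1]]
    bad <- setdiff(chars, .iupac_codes)
    if (length(bad))
      stop(sprintf("read_motifs: motif '%s' contains non-IUPAC character(s): %s",
                   df$name[i], paste(bad, collapse = "")))
  }
  class(df) <- c("motif_set", "data.frame")
  df
}

#' Write / read cluster assignments
#'
#' Assignments are a data.frame with columns `event_id`, `row`, `col`
#' (0-based grid position of the final best-matching unit). Writing is
#' deterministic: fixed column order and formatting, so identical inputs
#' give byte-identical files.
#'
#' @param path TSV file.
#' @param assignments assignment data.frame.
#' @export
write_assignments <- function(path, assignments) {
  stopifnot(all(c("event_id", "row", "col") %in% names(assignments)))
  write_report(path, assignments[, c("event_id", "row", "col")])
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("event_id", "row", "col") %in% names(df)))
  df
}

#' Write a tabular report as TSV
#'
#' Generic deterministic TSV writer: header line, tab separation, no
#' quoting of numerics, fixed significant-digit formatting for doubles.
#'
#' @param path output file.
#' @param report a data.frame.
#' @export
write_report <- function(path, report) {
  df <- as.data.frame(report)
  for (col in names(df)) {
    if (is.double(df[[col]]))
      df[[col]] <- formatC(df[[col]], format = "g", digits = 10)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}
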