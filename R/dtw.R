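#' Dynamic time warping distance between two profiles
#'
#' Aligns two real-valued sequences with a monotone, continuous and bounded
#' warping path and returns the path of minimal summed node weight, where the
#' weight of matching element `i` of `s1` with element `j` of `s2` is the
#' squared difference `(s1[i] - s2[j])^2`. The alignment cost is additionally
#' reported normalized by the number of nodes on the optimal path, which
#' makes costs comparable between profile pairs of different lengths.
#'
#' With a finite `band_radius` the admissible nodes are restricted to a
#' corridor around the (length-adjusted) diagonal:
#' `|i*(m-1)/(n-1) - j| <= band_radius` in 0-based indices. The slope
#' adjustment keeps the endpoints admissible for unequal-length sequences; a
#' plain `|i - j|` corridor can make the end node unreachable. If the
#' corridor admits no complete path, an error reports the minimal feasible
#' radius.
#'
#' DTW is symmetric but does not obey the triangle inequality, so it is used
#' here only as a pairwise similarity, never as a metric.
#'
#' @param s1,s2 numeric vectors, length >= 1, all values finite.
#' @param band_radius Sakoe-Chiba band radius in bins, or `NULL` for
#'   unrestricted DTW. A radius `>= max(length(s1), length(s2))` is
#'   equivalent to `NULL`.
#' @return an object of class `dtw_result`: a list with elements
#'   `cost` (sum of squared differences along the optimal path),
#'   `normalized` (`cost` divided by the number of path nodes),
#'   `path` (two-column integer matrix of 1-based index pairs, first row
#'   `(1,1)`, last row `(n,m)`), and `band_radius`.
#' @examples
#' dtw_distance(c(0, 1, 0, 0), c(0, 0, 1, 0))$cost  # 0: warping absorbs shift
#' dtw_distance(c(0, 0, 0), c(1, 1, 1))$normalized  # 1
#' @export
dtw_distance <- function(s1, s2, band_radius = NULL) {
  stopifnot(is.numeric(s1), is.numeric(s2))
  if (length(s1) < 1L || length(s2) < 1L)
    stop("dtw_distance: sequences must have length >= 1")
  if (!all(is.finite(s1)) || !all(is.finite(s2)))
    stop("dtw_distance: sequences must be finite")
  band <- if (is.null(band_radius)) -1 else {
    stopifnot(is.numeric(band_radius), length(band_radius) == 1L, band_radius >= 0)
    as.numeric(band_radius)
  }
  .fsom_state$dtw_calls <- .fsom_state$dtw_calls + 1L
  res <- dtw_cpp(as.numeric(s1), as.numeric(s2), band)
  if (!res$feasible) {
    r <- ceiling(band)
    repeat {
      r <- r + 1L
      if (dtw_band_feasible_cpp(length(s1), length(s2), r)) break
    }
    stop(sprintf(
      "dtw_distance: band radius %g admits no complete warping path for lengths %d vs %d; minimal feasible radius is %d",
      band, length(s1), length(s2), r))
  }
  structure(
    list(cost = res$cost, normalized = res$normalized, path = res$path,
         band_radius = band_radius),
    class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW alignment: cost %.6g, normalized %.6g, %d path nodes, band %s\n",
              x$cost, x$normalized, nrow(x$path),
              if (is.null(x$band_radius)) "none" else format(x$band_radius)))
  invisible(x)
}

#' Pairwise normalized DTW distance matrix
#'
#' @param profiles a list of numeric vectors or of [build_profile()] objects.
#' @param band_radius band radius in bins or `NULL` (see [dtw_distance()]).
#' @return symmetric numeric matrix of normalized DTW costs with zero
#'   diagonal; dimnames taken from profile `event_id`s or list names.
#' @export
dtw_distance_matrix <- function(profiles, band_radius = NULL) {
  vals <- profile_values(profiles)
  n <- length(vals)
  ids <- profile_ids(profiles)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(D)
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      d <- dtw_distance(vals[[a]], vals[[b]], band_radius)$normalized
      D[a, b] <- d
      D[b, a] <- d
    }
  }
  D
}

# accept either bare numeric vectors or meth_profile objects
profile_values <- function(profiles) {
  if (is.numeric(profiles)) profiles <- list(profiles)
  lapply(profiles, function(p) if (inherits(p, "meth_profile")) p$values else as.numeric(p))
}

profile_ids <- function(profiles) {
  ids <- vapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (inherits(p, "meth_profile") && !is.null(p$event_id)) p$event_id
    else if (!is.null(names(profiles)) && nzchar(names(profiles)[i])) names(profiles)[i]
    else sprintf("profile_%d", i)
  }, character(1))
  make.unique(ids)
}

#' Export a pairwise distance matrix as TSV
#'
#' Square matrix with an `event_id` header row and column, written with
#' fixed formatting so identical inputs give byte-identical files.
#'
#' @param path output file path.
#' @param D square numeric matrix with dimnames.
#' @export
write_distance_matrix <- function(path, D) {
  df <- data.frame(event_id = rownames(D), as.data.frame(signif(D, 10)),
                   check.names = FALSE)
  write_report(path, df)
}
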