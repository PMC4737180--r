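# near-square grid factorization of M (rows <= cols, rows the largest
# divisor of M not exceeding sqrt(M))
near_square <- function(M) {
  rows <- max(Filter(function(d) M %% d == 0, seq_len(floor(sqrt(M)))))
  c(rows = rows, cols = M %/% rows)
}

#' Build the mediod set and per-item mediod rankings
#'
#' Step 1 of the light-weight cluster-number selection: train a single
#' flexible SOM with `M` neurons (near-square grid), take the trained
#' prototypes as mediods, record each item's normalized DTW distance to all
#' mediods, and rank the mediods per item by increasing distance (ties
#' broken by mediod index). All subsequent consensus computations reuse
#' these rankings without recomputing any distance.
#'
#' @param profiles list of `meth_profile` objects or numeric vectors.
#' @param M number of mediods; must satisfy `choose(M, k) >= m` for every
#'   `k` in `4..K`.
#' @param seed RNG seed for the SOM run.
#' @param K largest cluster number that will be scanned.
#' @param m number of mediod subsets sampled per `k`.
#' @param epochs,band_radius,... passed to [fsom()].
#' @return a `mediod_ranking` object: list with `mediods` (list of
#'   prototype vectors), `ranking` (n x M integer matrix, row i = mediod
#'   indices ordered by increasing distance to item i), `rank_pos`
#'   (n x M matrix, `rank_pos[i, j]` = rank of mediod j for item i),
#'   `ids` (item ids), `M`, and the trained `grid`.
#' @export
build_mediods <- function(profiles, M, seed = 1, K = 8, m = 50,
                          epochs = 15, band_radius = 5, ...) {
  ks <- 4:K
  bad <- ks[choose(M, ks) < m]
  if (length(bad)) {
    Mmin <- M
    while (any(choose(Mmin, ks) < m)) Mmin <- Mmin + 1L
    stop(sprintf(
      "build_mediods: choose(M, k) >= m violated for k = %s with M = %d, m = %d; minimal adequate M is %d",
      paste(bad, collapse = ","), M, m, Mmin))
  }
  dims <- near_square(M)
  fit <- fsom(profiles, dims[["rows"]], dims[["cols"]], epochs = epochs,
              seed = seed, band_radius = band_radius, ...)
  mediods <- lapply(fit$grid$neurons, function(n) n$w)
  vals <- profile_values(profiles)
  ids <- profile_ids(profiles)
  n <- length(vals)
  D <- matrix(0, n, M)
  for (i in seq_len(n))
    for (j in seq_len(M))
      D[i, j] <- dtw_distance(vals[[i]], mediods[[j]], band_radius)$normalized
  ranking <- t(apply(D, 1L, order))          # ties: stable, by mediod index
  rank_pos <- t(apply(ranking, 1L, order))
  structure(list(mediods = mediods, ranking = ranking, rank_pos = rank_pos,
                 distances = D, ids = ids, M = M, grid = fit$grid),
            class = "mediod_ranking")
}

#' Consensus matrix for one candidate cluster number
#'
#' Step 2 of the light-weight selection: sample `m` distinct `k`-subsets of
#' the mediods (seeded; duplicates rejected), assign every item to its
#' highest-ranked mediod within each subset using the stored rankings (no
#' DTW evaluation), and return the items-by-items matrix of co-assignment
#' fractions.
#'
#' @param rankings a `mediod_ranking` from [build_mediods()].
#' @param k subset size (number of candidate clusters).
#' @param m number of subsets; requires `choose(M, k) >= m`.
#' @param seed RNG seed for the subset sampling.
#' @return symmetric consensus matrix with unit diagonal, entries in
#'   `[0, 1]` and multiples of `1/m`.
#' @export
consensus_for_k <- function(rankings, k, m, seed = 1) {
  stopifnot(inherits(rankings, "mediod_ranking"))
  M <- rankings$M
  if (choose(M, k) < m)
    stop(sprintf("consensus_for_k: only %d distinct %d-subsets of %d mediods exist, need %d",
                 choose(M, k), k, M, m))
  P <- rankings$rank_pos
  n <- nrow(P)
  subsets <- with_seed(seed, sample_distinct_subsets(M, k, m))
  cons <- matrix(0, n, n)
  for (sub in subsets) {
    assigned <- sub[apply(P[, sub, drop = FALSE], 1L, which.min)]
    cons <- cons + outer(assigned, assigned, "==")
  }
  cons <- cons / m
  dimnames(cons) <- list(rankings$ids, rankings$ids)
  cons
}

# m distinct k-subsets of 1..M; enumerates when the subset space is small,
# otherwise samples with rejection of duplicates
sample_distinct_subsets <- function(M, k, m) {
  total <- choose(M, k)
  if (total <= 1e5 && k <= M) {
    all_subs <- utils::combn(M, k, simplify = FALSE)
    return(all_subs[sample(length(all_subs), m)])
  }
  seen <- character(0)
  out <- vector("list", m)
  got <- 0L
  while (got < m) {
    sub <- sort(sample(M, k))
    key <- paste(sub, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    got <- got + 1L
    out[[got]] <- sub
  }
  out
}

#' Area under the consensus-matrix CDF
#'
#' Empirical CDF over the strictly-upper-triangle entries of a consensus
#' matrix; the area is the step-function sum `sum_i (x[i+1]-x[i]) * F(x[i])`
#' over the sorted unique entry values extended to 1. A clean partition
#' (entries near 0 or 1) gives a small or large area depending on the
#' balance of within- and between-cluster pairs; the change of this area
#' with `k` drives the selection of the cluster number.
#'
#' @param consensus square symmetric matrix with entries in `[0, 1]`.
#' @return area in `[0, 1]`.
#' @export
cdf_area <- function(consensus) {
  n <- nrow(consensus)
  if (is.null(n) || n < 2L)
    stop("cdf_area: consensus matrix needs at least 2 items")
  entries <- consensus[upper.tri(consensus)]
  xs <- sort(unique(c(entries, 1)))
  if (length(xs) == 1L) return(0)
  F <- stats::ecdf(entries)
  sum(diff(xs) * F(xs[-length(xs)]))
}

#' Select the cluster number from CDF areas
#'
#' Proportional-increase rule over a contiguous range starting at 4:
#' `delta(4) = A(4)` and `delta(k) = (A(k) - A(k-1)) / A(k-1)` for `k > 4`;
#' the selected `k*` is the largest `k` whose relative increase is at least
#' `delta_min`, falling back to 4 when no `k` beyond 4 qualifies.
#'
#' @param areas named numeric vector of CDF areas; names must be the
#'   contiguous integers `4..K`.
#' @param delta_min minimal relative area increase (default 0.025).
#' @return list with `k_star` and `table` (data.frame `k`, `area`, `delta`).
#' @export
select_k <- function(areas, delta_min = 0.025) {
  ks <- as.integer(names(areas))
  if (length(ks) == 0L || ks[1L] != 4L || !identical(ks, ks[1L]:ks[length(ks)]))
    stop("select_k: areas must cover a contiguous k range starting at 4")
  A <- as.numeric(areas)
  delta <- numeric(length(A))
  delta[1L] <- A[1L]
  if (length(A) > 1L) {
    for (i in 2:length(A)) {
      delta[i] <- if (A[i - 1L] > 0) (A[i] - A[i - 1L]) / A[i - 1L]
                  else if (A[i] > 0) Inf else 0
    }
  }
  qualifies <- delta >= delta_min
  k_star <- if (any(qualifies)) max(ks[qualifies]) else 4L
  list(k_star = as.integer(k_star),
       table = data.frame(k = ks, area = A, delta = delta))
}

#' Light-weight consensus selection of the cluster number
#'
#' Runs the full three-step procedure on a profile set: one `M`-mediod SOM
#' partition with per-item mediod rankings, `m` rank-based reassignments
#' per candidate `k` in `4..K`, consensus matrices and CDF areas, and the
#' proportional-increase selection of `k*`.
#'
#' @inheritParams build_mediods
#' @param delta_min passed to [select_k()].
#' @return list with `k_star`, `table` (k, area, delta), `rankings`, and
#'   `consensus` (list of consensus matrices named by k).
#' @export
select_k_profiles <- function(profiles, K = 8, m = 50, M = 2 * K, seed = 1,
                              epochs = 15, band_radius = 5,
                              delta_min = 0.025, ...) {
  rankings <- build_mediods(profiles, M, seed = seed, K = K, m = m,
                            epochs = epochs, band_radius = band_radius, ...)
  consensus <- list()
  areas <- numeric(0)
  for (k in 4:K) {
    cons <- consensus_for_k(rankings, k, m, seed = seed + k)
    consensus[[as.character(k)]] <- cons
    areas[as.character(k)] <- cdf_area(cons)
  }
  sel <- select_k(areas, delta_min)
  list(k_star = sel$k_star, table = sel$table, rankings = rankings,
       consensus = consensus)
}
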