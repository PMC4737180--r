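#' Initialize a flexible SOM grid
#'
#' Each neuron's prototype (weight vector) is initialized as a copy of a
#' distinct input profile sampled uniformly without replacement; per-element
#' shift accumulators start at zero.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param profiles list of `meth_profile` objects or numeric vectors; at
#'   least `rows * cols` of them.
#' @param seed RNG seed for the prototype sampling.
#' @param alpha0,alphaT initial/final learning rate of the exponential decay
#'   schedule.
#' @param sigma0,sigmaT initial/final neighborhood radius (grid Chebyshev
#'   units); default `sigma0 = max(rows, cols)/2`.
#' @param theta accumulator threshold (>= 1) triggering a local prototype
#'   insertion or deletion; `Inf` disables length adaptation.
#' @param band_radius Sakoe-Chiba band radius (bins) for all DTW
#'   computations during training, or `NULL` for unrestricted DTW.
#' @return a `som_grid` object.
#' @export
init_grid <- function(rows, cols, profiles, seed = NULL,
                      alpha0 = 0.5, alphaT = 0.01,
                      sigma0 = max(rows, cols) / 2, sigmaT = 0.5,
                      theta = 1, band_radius = 5) {
  stopifnot(rows >= 1, cols >= 1, alpha0 > 0, alphaT > 0, sigma0 > 0,
            sigmaT > 0, theta >= 1)
  vals <- profile_values(profiles)
  nn <- rows * cols
  if (length(vals) < nn)
    stop(sprintf("init_grid: need at least %d profiles for a %dx%d grid, got %d",
                 nn, rows, cols, length(vals)))
  pick <- with_seed(seed, sample(length(vals), nn))
  neurons <- vector("list", nn)
  for (r in seq_len(rows) - 1L) {
    for (c in seq_len(cols) - 1L) {
      i <- r * cols + c + 1L  # row-major
      w <- vals[[pick[i]]]
      neurons[[i]] <- list(row = r, col = c, w = w,
                           acc = numeric(length(w)), source = pick[i])
    }
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 neurons = neurons,
                 hyper = list(alpha0 = alpha0, alphaT = alphaT,
                              sigma0 = sigma0, sigmaT = sigmaT,
                              theta = theta, band_radius = band_radius),
                 seed = seed, trained_epochs = 0L),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("Flexible SOM grid %dx%d (%s), prototype lengths %s\n",
              x$rows, x$cols,
              if (x$trained_epochs > 0) sprintf("trained %d epochs", x$trained_epochs)
              else "untrained",
              paste(range(vapply(x$neurons, function(n) length(n$w), integer(1))),
                    collapse = "-")))
  invisible(x)
}

#' Best matching unit for one profile
#'
#' The neuron whose prototype minimizes the length-normalized DTW distance
#' to the input; ties broken by row-major grid order.
#'
#' @param grid a `som_grid`.
#' @param s numeric vector or `meth_profile`.
#' @return list with `index` (row-major, 1-based), `row`, `col` (0-based)
#'   and `dist` (normalized DTW cost).
#' @export
find_bmu <- function(grid, s) {
  v <- profile_values(list(s))[[1]]
  band <- grid$hyper$band_radius
  best <- Inf; best_i <- 1L
  for (i in seq_along(grid$neurons)) {
    d <- dtw_distance(v, grid$neurons[[i]]$w, band)$normalized
    if (d < best) { best <- d; best_i <- i }
  }
  nb <- grid$neurons[[best_i]]
  list(index = best_i, row = nb$row, col = nb$col, dist = best)
}

#' Adjust one neuron toward an input profile
#'
#' Implements the flexible (warp-aware) prototype update. The optimal
#' warping path between the input `s` and the prototype `w` is computed
#' with the grid's band. Non-diagonal path steps update the per-element
#' shift accumulators: a step advancing only the input index (the prototype
#' locally under-long) adds `+alpha` at the held prototype index, a step
#' advancing only the prototype index (locally over-long) adds `-alpha`.
#' When an accumulator reaches `theta` in magnitude, the prototype length
#' changes by one at that index: a positive trigger inserts an element
#' whose value interpolates its new neighbors, a negative trigger merges
#' the element with its successor as their average; accumulators of
#' shifted elements move with them unchanged, the triggering accumulator
#' resets to zero. A deletion that would leave fewer than two elements is
#' suppressed. Finally the element values are moved toward their matched
#' input values by factor `alpha` (elements matched by several input
#' elements use the mean of the matched values, computed on the optimal
#' path against the length-adjusted prototype).
#'
#' @param neuron list with at least `w` (numeric) and `acc` (numeric, same
#'   length).
#' @param s input profile (numeric vector or `meth_profile`).
#' @param alpha learning force in `[0, 1]`.
#' @param theta accumulator threshold (>= 1; `Inf` disables length changes).
#' @param band_radius DTW band radius or `NULL`.
#' @return the updated neuron.
#' @export
adjust_neuron <- function(neuron, s, alpha, theta, band_radius = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, theta >= 1)
  x <- profile_values(list(s))[[1]]
  if (alpha == 0) return(neuron)
  w <- neuron$w
  acc <- neuron$acc

  res <- dtw_distance(x, w, band_radius)
  path <- res$path  # col 1: input index, col 2: prototype index (1-based)

  # accumulate length pressure from non-diagonal steps
  L <- nrow(path)
  if (L > 1L) {
    di <- diff(path[, 1L])
    dj <- diff(path[, 2L])
    shrink <- which(di == 1L & dj == 0L)   # prototype under-long here
    expand <- which(di == 0L & dj == 1L)   # prototype over-long here
    for (l in shrink) acc[path[l, 2L]] <- acc[path[l, 2L]] + alpha
    for (l in expand) acc[path[l + 1L, 2L]] <- acc[path[l + 1L, 2L]] - alpha
  }

  # process triggers left-to-right; later indices shift with the structure
  changed <- FALSE
  pos <- 1L
  while (pos <= length(w)) {
    if (acc[pos] >= theta) {
      newv <- if (pos < length(w)) (w[pos] + w[pos + 1L]) / 2 else w[pos]
      w <- append(w, newv, after = pos)
      acc[pos] <- 0
      acc <- append(acc, 0, after = pos)
      changed <- TRUE
      pos <- pos + 2L
    } else if (acc[pos] <= -theta) {
      if (length(w) <= 2L) { pos <- pos + 1L; next }  # deletion suppressed
      if (pos < length(w)) {
        w[pos] <- (w[pos] + w[pos + 1L]) / 2
        w <- w[-(pos + 1L)]
        acc[pos] <- 0
        acc <- acc[-(pos + 1L)]
      } else {
        w[pos - 1L] <- (w[pos - 1L] + w[pos]) / 2
        w <- w[-pos]
        acc[pos - 1L] <- 0
        acc <- acc[-pos]
      }
      changed <- TRUE
      pos <- pos + 1L
    } else {
      pos <- pos + 1L
    }
  }

  # value update on the (possibly re-aligned) prototype
  if (changed) path <- dtw_distance(x, w, band_radius)$path
  xbar <- tapply(x[path[, 1L]], path[, 2L], mean)
  j <- as.integer(names(xbar))
  w[j] <- w[j] + alpha * (as.numeric(xbar) - w[j])

  neuron$w <- w
  neuron$acc <- acc
  neuron
}

#' Train a flexible SOM
#'
#' Runs `epochs` learning epochs. In epoch `t` (1-based) the learning rate
#' and neighborhood width decay exponentially,
#' `alpha(t) = alpha0 * (alphaT/alpha0)^(t/T)` and likewise `sigma(t)`;
#' profiles are visited in a freshly shuffled order (seeded); for each
#' profile the BMU `U` is located and every neuron within grid Chebyshev
#' distance `r <= ceiling(sigma(t))` of `U` is adjusted with force
#' `alpha(t) * exp(-r^2 / (2 sigma(t)^2))` via [adjust_neuron()]. After the
#' final epoch every profile is assigned to its BMU.
#'
#' @param grid a `som_grid` from [init_grid()].
#' @param profiles list of `meth_profile` objects or numeric vectors.
#' @param epochs number of epochs (>= 1).
#' @param seed RNG seed for the per-epoch visiting order.
#' @return list with `grid` (trained) and `assignments` (data.frame
#'   `event_id`, `row`, `col`).
#' @export
fsom_train <- function(grid, profiles, epochs, seed = NULL) {
  stopifnot(inherits(grid, "som_grid"), epochs >= 1)
  vals <- profile_values(profiles)
  ids <- profile_ids(profiles)
  n <- length(vals)
  hp <- grid$hyper
  with_seed(seed, {
    for (t in seq_len(epochs)) {
      alpha_t <- hp$alpha0 * (hp$alphaT / hp$alpha0)^(t / epochs)
      sigma_t <- hp$sigma0 * (hp$sigmaT / hp$sigma0)^(t / epochs)
      h <- ceiling(sigma_t)
      order_t <- sample(n)
      for (idx in order_t) {
        s <- vals[[idx]]
        bmu <- find_bmu(grid, s)
        for (i in seq_along(grid$neurons)) {
          nb <- grid$neurons[[i]]
          r <- max(abs(nb$row - bmu$row), abs(nb$col - bmu$col))
          if (r > h) next
          force_ <- alpha_t * exp(-r^2 / (2 * sigma_t^2))
          grid$neurons[[i]] <- adjust_neuron(nb, s, force_, hp$theta,
                                             hp$band_radius)
        }
      }
    }
  })
  grid$trained_epochs <- grid$trained_epochs + as.integer(epochs)
  assignments <- assign_profiles(grid, vals, ids)
  list(grid = grid, assignments = assignments)
}

# BMU assignment table for a list of value vectors
assign_profiles <- function(grid, vals, ids) {
  rows <- integer(length(vals)); cols <- integer(length(vals))
  for (k in seq_along(vals)) {
    b <- find_bmu(grid, vals[[k]])
    rows[k] <- b$row; cols[k] <- b$col
  }
  data.frame(event_id = ids, row = rows, col = cols, stringsAsFactors = FALSE)
}

#' One-call flexible SOM typing
#'
#' Convenience wrapper: [init_grid()] with `seed`, then [fsom_train()] with
#' `seed + 1`.
#'
#' @inheritParams init_grid
#' @inheritParams fsom_train
#' @return as [fsom_train()].
#' @export
fsom <- function(profiles, rows, cols, epochs = 30, seed = 1,
                 alpha0 = 0.5, alphaT = 0.01,
                 sigma0 = max(rows, cols) / 2, sigmaT = 0.5,
                 theta = 1, band_radius = 5) {
  grid <- init_grid(rows, cols, profiles, seed = seed, alpha0 = alpha0,
                    alphaT = alphaT, sigma0 = sigma0, sigmaT = sigmaT,
                    theta = theta, band_radius = band_radius)
  fsom_train(grid, profiles, epochs, seed = seed + 1L)
}

#' Persist / load a trained SOM grid as TSV
#'
#' One row per neuron: grid position, comma-joined prototype values and
#' accumulators.
#'
#' @param path TSV file.
#' @param grid a `som_grid`.
#' @export
write_som_grid <- function(path, grid) {
  df <- data.frame(
    row = vapply(grid$neurons, function(n) n$row, integer(1)),
    col = vapply(grid$neurons, function(n) n$col, integer(1)),
    weights = vapply(grid$neurons, function(n)
      paste(formatC(n$w, format = "g", digits = 12), collapse = ","),
      character(1)),
    accumulators = vapply(grid$neurons, function(n)
      paste(formatC(n$acc, format = "g", digits = 12), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  write_report(path, df)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies, `2 I(A;B) / (H(A) + H(B))`, in `[0, 1]`: 1 for identical
#' partitions (up to label renaming), 0 for independent ones. When both
#' labelings consist of a single cluster the partitions are identical and
#' the score is defined as 1.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return NMI score in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("nmi: labelings must have equal length")
  n <- length(labels_a)
  stopifnot(n > 0)
  tab <- table(labels_a, labels_b)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha + hb == 0) return(1)  # both single-cluster: identical partitions
  expected <- outer(pa, pb)
  pos <- pj > 0
  mi <- sum(pj[pos] * log(pj[pos] / expected[pos]))
  val <- 2 * mi / (ha + hb)
  min(max(val, 0), 1)
}
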