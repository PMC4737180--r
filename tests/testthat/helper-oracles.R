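# Independent oracles used to verify the implementation. These deliberately
# avoid the dynamic-programming recurrence and any package internals.

# Brute-force DTW: enumerate every monotone/continuous/bounded warping path
# explicitly (exponential recursion, no memoization) and take the minimal
# summed squared-difference node weight. Tractable for lengths <= 8.
bf_dtw_cost <- function(x, y) {
  n <- length(x); m <- length(y)
  rec <- function(i, j) {
    w <- (x[i] - y[j])^2
    if (i == n && j == m) return(w)
    best <- Inf
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    w + best
  }
  rec(1, 1)
}

# Exact two-sided Mann-Whitney p-value by complete enumeration of all
# group-label arrangements (two-sidedness as distance of U from its mean).
enum_utest_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  mid <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) ustat(vals[idx], vals[-idx]))
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}

# Hypergeometric tails by direct combinatorial summation.
enum_hyper_tail <- function(k, K, N, n, upper = TRUE) {
  xs <- if (upper) k:min(n, K) else 0:k
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Plain (fixed-length, Euclidean) SOM with the same initialization scheme,
# schedules and seeded visiting order as the package's trainer, but with
# classical elementwise updates and squared-Euclidean BMU search. Serves as
# the reference trace that flexible training must reduce to when no length
# adaptation can trigger.
classical_som <- function(values, rows, cols, epochs, seed,
                          alpha0 = 0.5, alphaT = 0.01,
                          sigma0 = max(rows, cols) / 2, sigmaT = 0.5) {
  n <- length(values)
  nn <- rows * cols
  set.seed(seed)
  pick <- sample(n, nn)
  W <- values[pick]
  pos <- cbind(row = rep(seq_len(rows) - 1L, each = cols),
               col = rep(seq_len(cols) - 1L, times = rows))
  set.seed(seed + 1L)
  for (t in seq_len(epochs)) {
    alpha_t <- alpha0 * (alphaT / alpha0)^(t / epochs)
    sigma_t <- sigma0 * (sigmaT / sigma0)^(t / epochs)
    h <- ceiling(sigma_t)
    for (idx in sample(n)) {
      v <- values[[idx]]
      ssd <- vapply(W, function(w) sum((w - v)^2), numeric(1))
      bmu <- which.min(ssd)  # first minimum = row-major tie-break
      r <- pmax(abs(pos[, "row"] - pos[bmu, "row"]),
                abs(pos[, "col"] - pos[bmu, "col"]))
      for (i in which(r <= h)) {
        f <- alpha_t * exp(-r[i]^2 / (2 * sigma_t^2))
        W[[i]] <- W[[i]] + f * (v - W[[i]])
      }
    }
  }
  assign <- vapply(values, function(v)
    which.min(vapply(W, function(w) sum((w - v)^2), numeric(1))), integer(1))
  list(W = W, assignment = assign)
}
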