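test_that("grid initialization samples distinct prototypes deterministically", {
  set.seed(77)
  profs <- lapply(1:100, function(i) runif(8))
  g1 <- init_grid(2, 2, profs, seed = 5)
  g2 <- init_grid(2, 2, profs, seed = 5)
  expect_identical(lapply(g1$neurons, `[[`, "w"), lapply(g2$neurons, `[[`, "w"))
  src <- vapply(g1$neurons, `[[`, integer(1), "source")
  expect_length(unique(src), 4L)
  expect_true(all(vapply(g1$neurons, function(n) all(n$acc == 0), logical(1))))

  # grid as large as the input: a permutation of the inputs
  g <- init_grid(2, 2, profs[1:4], seed = 1)
  expect_setequal(vapply(g$neurons, `[[`, integer(1), "source"), 1:4)
  expect_error(init_grid(3, 3, profs[1:4]), "at least 9")
})

test_that("BMU minimizes normalized DTW with row-major tie-breaking", {
  profs <- lapply(1:6, function(i) rep(i / 10, 10))
  g <- init_grid(2, 3, profs, seed = 2)
  for (i in seq_along(g$neurons)) {
    b <- find_bmu(g, g$neurons[[i]]$w)
    expect_equal(b$dist, 0)
    expect_equal(b$index, i)  # earlier identical prototypes would win ties
  }
  # all prototypes identical -> neuron (0,0)
  g$neurons <- lapply(g$neurons, function(n) { n$w <- rep(0.5, 10); n })
  b <- find_bmu(g, runif(10))
  expect_equal(c(b$row, b$col), c(0, 0))
  # BMU distance is a lower bound over the grid
  s <- runif(10)
  g2 <- init_grid(2, 3, lapply(1:6, function(i) runif(10)), seed = 3)
  b <- find_bmu(g2, s)
  dists <- vapply(g2$neurons, function(n)
    dtw_distance(s, n$w, g2$hyper$band_radius)$normalized, numeric(1))
  expect_equal(b$dist, min(dists))
})

test_that("value updates move matched elements toward the input", {
  # diagonal path, half force
  r <- adjust_neuron(list(w = c(0, 0), acc = c(0, 0)), c(2, 2), 0.5, 1)
  expect_equal(r$w, c(1, 1))
  expect_equal(r$acc, c(0, 0))
  # null learning leaves everything unchanged
  r <- adjust_neuron(list(w = c(0.1, 0.9), acc = c(0.2, 0)), c(0.5, 0.5), 0, 1)
  expect_equal(r$w, c(0.1, 0.9))
  expect_equal(r$acc, c(0.2, 0))
})

test_that("an accumulated shrink trigger inserts an interpolated element", {
  # hand-traced 2-vs-3 case: full force and threshold 1 grow W=(0,2) into S
  r <- adjust_neuron(list(w = c(0, 2), acc = c(0, 0)), c(0, 1, 2), 1, 1)
  expect_equal(r$w, c(0, 1, 2))
  expect_equal(r$acc, c(0, 0, 0))
})

test_that("expansion pressure deletes by merging, bounded at length 2", {
  # S shorter than W: expansion steps accumulate negative pressure
  n <- list(w = c(0, 1, 2), acc = c(0, 0, 0))
  r <- adjust_neuron(n, c(0, 2), 1, 1)
  expect_length(r$w, 2)
  # deletion suppressed when the prototype would drop below 2 elements
  n <- list(w = c(0, 1), acc = c(0, 0))
  r <- adjust_neuron(n, 0.5, 1, 1)
  expect_gte(length(r$w), 2)
})

test_that("prototype length changes by at most one per trigger and stays >= 2", {
  set.seed(12)
  for (rep in 1:30) {
    w <- runif(sample(3:8, 1))
    n <- list(w = w, acc = runif(length(w), -0.9, 0.9))
    s <- runif(sample(2:9, 1))
    alpha <- runif(1)
    r <- adjust_neuron(n, s, alpha, 1)
    expect_gte(length(r$w), 2)
    expect_true(all(r$w >= min(c(w, s)) - 1e-12))
    expect_true(all(r$w <= max(c(w, s)) + 1e-12))
  }
})

test_that("training is deterministic and a 1x1 grid absorbs its input", {
  p <- list(runif(10))
  g <- init_grid(1, 1, p, seed = 1, alpha0 = 1, alphaT = 1, theta = 1e9)
  out <- fsom_train(g, p, 1, seed = 2)
  expect_equal(out$grid$neurons[[1]]$w, p[[1]])

  shapes <- four_shapes()
  mp <- make_profiles(shapes[1:2], 10, seed = 4)
  f1 <- fsom(mp$profiles, 1, 2, epochs = 5, seed = 9)
  f2 <- fsom(mp$profiles, 1, 2, epochs = 5, seed = 9)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(lapply(f1$grid$neurons, `[[`, "w"),
                   lapply(f2$grid$neurons, `[[`, "w"))
})

test_that("two separated families are captured by a 1x2 grid (NMI = 1)", {
  mp <- make_profiles(four_shapes()[c("flat_low", "flat_high")], 20, seed = 6)
  fit <- fsom(mp$profiles, 1, 2, epochs = 10, seed = 3)
  lab <- paste(fit$assignments$row, fit$assignments$col)
  expect_equal(nmi(lab, mp$labels[fit$assignments$event_id]), 1.0)
})

test_that("flexible training with theta = Inf on constant equal-length inputs reduces to the classical SOM trace", {
  set.seed(31)
  levels <- runif(40)
  profs <- lapply(levels, function(l) rep(l, 12))
  seed <- 17
  g <- init_grid(2, 2, profs, seed = seed, theta = Inf, band_radius = NULL)
  fit <- fsom_train(g, profs, epochs = 6, seed = seed + 1L)
  ref <- classical_som(profs, 2, 2, epochs = 6, seed = seed)
  for (i in 1:4)
    expect_equal(fit$grid$neurons[[i]]$w, ref$W[[i]], tolerance = 1e-12)
  got <- as.integer(fit$assignments$row * 2 + fit$assignments$col) + 1L
  expect_identical(got, unname(ref$assignment))
})

test_that("NMI scores agreement in [0,1] with relabeling invariance", {
  expect_identical(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_identical(nmi(c(0, 0, 1, 1), c("b", "b", "a", "a")), 1)
  expect_identical(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_identical(nmi(c(1, 1, 1), c(2, 2, 2)), 1)
  expect_error(nmi(1:3, 1:4), "equal length")
  # cross-check against an independent implementation on random labelings
  set.seed(21)
  for (rep in 1:20) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
                 tolerance = 1e-12)
  }
})
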