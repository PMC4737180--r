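test_that("U statistic and exact two-sided p match complete enumeration", {
  r <- test_property(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)  # 2/20 arrangements as extreme
  expect_equal(r$p, enum_utest_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$direction, "low")

  # identical multisets: maximal overlap
  r <- test_property(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  # all values tied everywhere: p = 1, no direction
  r <- test_property(c(2, 2, 2), c(2, 2, 2, 2))
  expect_equal(r$p, 1)
  expect_true(is.na(r$direction))

  # random small no-tie cases against the enumeration oracle
  set.seed(14)
  for (rep in 1:10) {
    x <- sample(1:100, 4); y <- sample(101:200, 5) / 1.7
    expect_equal(test_property(x, y)$p, enum_utest_p(x, y), tolerance = 1e-12)
  }
  expect_error(test_property(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("null type-I error is near the nominal level", {
  set.seed(2024)
  alpha <- 0.05
  reps <- 1000
  hits <- 0L
  # cluster drawn from (and contained in) the background; containment kept
  # small (20 of 500) so the overlap-induced conservativeness is negligible
  for (r in seq_len(reps)) {
    bg <- rnorm(500)
    cl <- sample(bg, 20)
    if (test_property(cl, bg)$p < alpha) hits <- hits + 1L
  }
  rate <- hits / reps
  expect_lt(abs(rate - alpha), 2 * sqrt(alpha * (1 - alpha) / reps))
})

test_that("bin-wise border flags require a strict same-direction majority", {
  set.seed(88)
  # cluster uniformly higher than background in every bin
  bg <- lapply(1:40, function(i) new_profile(paste0("b", i),
    pmin(pmax(rnorm(40, 0.3, 0.05), 0), 1), 10, 10, 10, 10))
  hi <- lapply(1:15, function(i) new_profile(paste0("h", i),
    pmin(pmax(rnorm(40, 0.8, 0.05), 0), 1), 10, 10, 10, 10))
  res <- binwise_border_test(hi, c(bg, hi))
  expect_equal(res$flag, "high")
  expect_equal(nrow(res$bins), 40)
  expect_true(all(res$bins$q >= res$bins$p))

  # a cluster drawn from the background itself shows no trend
  res <- binwise_border_test(bg[1:10], bg)
  expect_equal(res$flag, "none")
})

test_that("bin-wise flag threshold arithmetic is strict", {
  # the flag requires > frac of tested bins; exactly frac must not flag
  flag_for <- function(n_sig, n_tested, frac = 0.8) {
    if (n_sig / n_tested > frac) "high" else "none"
  }
  expect_equal(flag_for(17, 20), "high")
  expect_equal(flag_for(16, 20), "none")
})

test_that("hypergeometric tails match combinatorial enumeration", {
  he <- motif_enrichment(5, 10, 10, 100)
  expect_equal(he$p_enrich, enum_hyper_tail(5, 10, 100, 10, upper = TRUE),
               tolerance = 1e-12)
  expect_equal(he$p_deplete, enum_hyper_tail(5, 10, 100, 10, upper = FALSE),
               tolerance = 1e-12)
  set.seed(6)
  for (rep in 1:20) {
    N <- sample(20:100, 1); K <- sample(0:N, 1)
    n <- sample(3:N, 1); k <- sample(0:min(n, K), 1)
    he <- motif_enrichment(k, n, K, N)
    expect_equal(he$p_enrich, enum_hyper_tail(k, K, N, n, TRUE), tolerance = 1e-12)
    expect_equal(he$p_deplete, enum_hyper_tail(k, K, N, n, FALSE), tolerance = 1e-12)
  }
  # cluster = background: both tails contain the mode
  he <- motif_enrichment(10, 100, 10, 100)
  expect_gte(he$p_enrich, 0.5)
  expect_gte(he$p_deplete, 0.5)
  # fully degenerate: both tails 1
  he <- motif_enrichment(5, 5, 5, 5)
  expect_equal(c(he$p_enrich, he$p_deplete), c(1, 1))
  expect_error(motif_enrichment(3, 10, 4, 5), "larger than background")
})

test_that("BH adjustment matches hand arithmetic and is monotone", {
  adj <- fdr_adjust(c(0.01, 0.02, 0.04), 0.05)
  expect_equal(adj$qvals, c(0.03, 0.03, 0.04))
  expect_true(all(adj$flags))
  adj <- fdr_adjust(0.2, 0.05)
  expect_equal(adj$qvals, 0.2)
  expect_false(adj$flags)
  expect_length(fdr_adjust(numeric(0))$qvals, 0)
  set.seed(8)
  p <- runif(30)
  q <- fdr_adjust(p)$qvals
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("motif scanning hits either strand and respects reverse complement", {
  motifs <- data.frame(name = c("FOX1", "AMB"), consensus = c("TGCATG", "TGYAWG"))
  class(motifs) <- c("motif_set", "data.frame")
  seqs <- c("e1|IE" = "AAAATGCATGAAAA",      # forward hit
            "e2|IE" = "TTTTCATGCATTTT",      # reverse-complement hit
            "e3|IE" = "AAAAAAAAAAAAAA")      # no hit
  h <- scan_motif_hits(seqs, motifs)
  expect_equal(unname(h[, "FOX1"]), c(TRUE, TRUE, FALSE))
  # scanning the reverse complements preserves all hit calls
  rc <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  h2 <- scan_motif_hits(rc, motifs)
  expect_equal(unname(h2), unname(h))
  # ambiguity codes match their expansions
  expect_true(h["e1|IE", "AMB"])
})

test_that("cluster reports assemble tests with per-family FDR", {
  set.seed(42)
  ev <- data.frame(event_id = sprintf("e%02d", 1:40),
                   event_type = "SE", chrom = "c", strand = "+",
                   body_start = 0, body_end = 1,
                   upstream_limit = 0, downstream_limit = 1,
                   psi = c(runif(20, 0.7, 1), runif(20, 0, 0.3)),
                   fpkm = rlnorm(40))
  asg <- data.frame(event_id = ev$event_id,
                    row = rep(c(0L, 1L), each = 20), col = 0L)
  rep_ <- association_report(asg, ev, properties = c("psi", "fpkm"))
  expect_setequal(unique(rep_$property), c("psi", "fpkm"))
  hi <- rep_[rep_$property == "psi" & rep_$row == 0, ]
  lo <- rep_[rep_$property == "psi" & rep_$row == 1, ]
  expect_true(hi$significant && hi$direction == "high")
  expect_true(lo$significant && lo$direction == "low")
  # direction reported only when significant
  expect_true(all(is.na(rep_$direction[!rep_$significant])))
})
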