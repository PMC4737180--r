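test_that("cluster medians are per-bin medians on the signed-offset grid", {
  profs <- list(
    a = new_profile("a", rep(0, 40), 10, 10, 10, 10),
    b = new_profile("b", rep(1, 40), 10, 10, 10, 10),
    c = new_profile("c", rep(2, 40) / 2, 10, 10, 10, 10),
    d = new_profile("d", rep(0.5, 40), 10, 10, 10, 10),
    e = new_profile("e", rep(0.5, 40), 10, 10, 10, 10))
  asg <- data.frame(event_id = c("a", "b", "c", "d", "e"),
                    row = 0L, col = 0L)
  med <- median_profiles(asg, profs, min_members = 5, sample_id = "s1")
  expect_length(med$medians, 1)
  expect_equal(med$medians[[1]]$values, rep(0.5, 40))
  expect_equal(med$medians[[1]]$event_id, "s1:0:0")

  # identical members reproduce the member profile
  asg2 <- data.frame(event_id = c("d", "e", "d", "e", "d"),
                     row = 0L, col = 0L)
  # small clusters are skipped
  asg3 <- data.frame(event_id = c("a", "b", "c"), row = 1L, col = 1L)
  med3 <- median_profiles(asg3, profs, min_members = 5)
  expect_length(med3$medians, 0)
  expect_equal(med3$skipped$n, 3L)
})

test_that("truncated members contribute only the bins they possess", {
  profs <- list(
    full1 = new_profile("full1", rep(0.2, 40), 10, 10, 10, 10),
    full2 = new_profile("full2", rep(0.2, 40), 10, 10, 10, 10),
    full3 = new_profile("full3", rep(0.2, 40), 10, 10, 10, 10),
    tr1 = new_profile("tr1", rep(0.8, 35), 5, 10, 10, 10),
    tr2 = new_profile("tr2", rep(0.8, 35), 5, 10, 10, 10))
  asg <- data.frame(event_id = names(profs), row = 0L, col = 0L)
  med <- median_profiles(asg, profs, min_members = 5)$medians[[1]]
  # full offset grid retained (10 intron bins on the I/E side)
  expect_equal(med$ie_pre, 10L)
  tab <- profile_bin_table(list(med))
  outer_bins <- tab$value[tab$block == "IE" & tab$offset < -5]
  inner_bins <- tab$value[tab$block == "IE" & tab$offset >= -5 & tab$offset < 0]
  expect_true(all(outer_bins == 0.2))   # only untruncated members there
  expect_true(all(inner_bins == 0.2))   # median of (0.2,0.2,0.2,0.8,0.8)
})

test_that("complete-linkage meta-clustering separates level blocks and orders groups", {
  mk <- function(id, level) {
    p <- new_profile(id, rep(level, 40), 10, 10, 10, 10)
    attr(p, "sample") <- sub(":.*", "", id)
    attr(p, "cluster") <- c(row = 0L, col = 0L)
    p
  }
  meds <- list(`s1:0:0` = mk("s1:0:0", 0.1), `s2:0:0` = mk("s2:0:0", 0.12),
               `s1:0:1` = mk("s1:0:1", 0.9), `s2:0:1` = mk("s2:0:1", 0.88))
  sg <- meta_cluster(meds, 2)
  expect_s3_class(sg, "super_grouping")
  g <- sg$groups
  # the two low-methylation medians pair up and get label I
  expect_equal(g$label[g$id %in% c("s1:0:0", "s2:0:0")], c("I", "I"))
  expect_equal(g$label[g$id %in% c("s1:0:1", "s2:0:1")], c("II", "II"))
  # as many groups as medians -> singletons
  sg4 <- meta_cluster(meds, 4)
  expect_equal(sort(unique(sg4$groups$group)), 1:4)
  expect_error(meta_cluster(meds[1:2], 3), "medians < 3")
  # newick export has all leaves
  path <- tempfile(fileext = ".nwk")
  write_dendrogram(path, sg)
  tree <- ape::read.tree(path)
  # ape sanitizes ":" (Newick syntax) to "-" in leaf labels
  expect_setequal(tree$tip.label, gsub(":", "-", names(meds)))
})

test_that("membership sharing edges and ratio rows behave as fractions", {
  g1 <- data.frame(event_id = sprintf("e%d", 1:100),
                   group = rep(c("I", "IV"), each = 50))
  # identical groupings: diagonal edges only
  sh <- membership_sharing(list(s1 = g1, s2 = g1), min_edge = 0.05)
  expect_true(all(sh$edges$group1 == sh$edges$group2))
  expect_equal(sum(sh$edges$weight), 1)
  rs <- tapply(sh$ratios$ratio, sh$ratios$sample, sum)
  expect_true(all(abs(rs - 1) < 1e-12))

  # disjoint memberships: no I-IV edge survives the cutoff
  g2 <- g1; g2$group <- rep(c("IV", "I"), each = 50)
  sh <- membership_sharing(list(s1 = g1, s2 = g2), min_edge = 0.05)
  expect_false(any(sh$edges$group1 == sh$edges$group2))
  expect_equal(shared_membership_fraction(list(s1 = g1, s2 = g1), "I", "IV"), 0)
  expect_equal(shared_membership_fraction(list(s1 = g1, s2 = g2), "I", "IV"), 1)
  expect_error(membership_sharing(list(s1 = g1)), "length")
})
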