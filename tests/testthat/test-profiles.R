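test_that("border regions truncate at the neighboring border, flooring to bins", {
  ev <- demo_event(body_start = 1000, body_end = 1200,
                   upstream_limit = 850, downstream_limit = 1600)
  # 150 bp available upstream -> floor(150/20) = 7 intron bins + 10 exon bins
  reg <- extract_border_region(ev, "IE", 200, 20)
  expect_equal(reg$pre_bins, 7L)
  expect_equal(reg$post_bins, 10L)
  expect_equal(c(reg$start, reg$end), c(860, 1200))

  # full room -> untruncated
  ev$upstream_limit <- 800
  reg <- extract_border_region(ev, "IE", 200, 20)
  expect_equal(c(reg$pre_bins, reg$post_bins), c(10L, 10L))

  # no room at all -> unusable
  ev$upstream_limit <- 1000
  expect_error(extract_border_region(ev, "IE", 200, 20), "zero bins")
})

test_that("profiles concatenate I/E then E/I and reverse on the minus strand", {
  ev <- demo_event(body_start = 1000, body_end = 1400,
                   upstream_limit = 600, downstream_limit = 1800)
  tr <- constant_track(0.5)
  p <- build_profile(tr, ev)
  expect_s3_class(p, "meth_profile")
  expect_length(p$values, 40)
  expect_true(all(p$values == 0.5))
  expect_equal(p$border_index, 20L)

  # genomically increasing ramp: minus-strand profile is the reversed ramp
  ramp_vals <- seq(0, 1, length.out = 200)
  lines <- sprintf("chr1\t%d\t%d\t%.17g", (0:199) * 20, (1:200) * 20, ramp_vals)
  tr <- read_track(write_tmp_track(lines), 20)
  plus <- build_profile(tr, ev)
  ev$strand <- "-"
  minus <- build_profile(tr, ev)
  expect_identical(minus$values, rev(plus$values))
})

test_that("isolated missing bins are interpolated, long runs drop the event", {
  ev <- demo_event(body_start = 1000, body_end = 1400,
                   upstream_limit = 600, downstream_limit = 1800)
  vals <- (1:200) / 400
  full <- sprintf("chr1\t%d\t%d\t%.17g", (0:199) * 20, (1:200) * 20, vals)
  # remove the bin at [1000,1020): single interior gap on a linear ramp,
  # so interpolation recovers the removed value exactly
  tr <- read_track(write_tmp_track(full[-51]), 20)
  p <- build_profile(tr, ev)
  expect_equal(p$values[11], 51 / 400)

  # a 3-bin run exceeds max_gap = 2 -> dropped
  tr <- read_track(write_tmp_track(full[-(51:53)]), 20)
  expect_null(build_profile(tr, ev))
})

test_that("profile building is deterministic and reports drops", {
  tr <- constant_track(0.3)
  events <- do.call(rbind, lapply(list(
    demo_event("ok1"), demo_event("ok2", strand = "-"),
    demo_event("bad", upstream_limit = 1000)),
    as.data.frame))
  res1 <- build_profiles(tr, events)
  res2 <- build_profiles(tr, events)
  expect_identical(res1$profiles, res2$profiles)
  expect_equal(names(res1$profiles), c("ok1", "ok2"))
  expect_equal(res1$dropped$event_id, "bad")
})

test_that("quantile normalization equalizes sorted values and keeps ranks", {
  mk <- function(vals) {
    lines <- sprintf("chr1\t%d\t%d\t%.17g", (seq_along(vals) - 1) * 20,
                     seq_along(vals) * 20, vals)
    read_track(write_tmp_track(lines), 20)
  }
  # rank-matched order statistics: (1,2,3)/(4,5,6) scaled into [0,1]
  out <- quantile_normalize(list(mk(c(0.1, 0.2, 0.3)), mk(c(0.4, 0.5, 0.6))))
  expect_equal(out[[1]]$chroms$chr1, c(0.25, 0.35, 0.45))
  expect_equal(out[[2]]$chroms$chr1, c(0.25, 0.35, 0.45))

  # identical tracks unchanged; sorted multisets identical afterwards
  set.seed(9)
  v1 <- runif(30); v2 <- runif(30)
  out <- quantile_normalize(list(mk(v1), mk(v1)))
  expect_equal(out[[1]]$chroms$chr1, v1)
  out <- quantile_normalize(list(mk(v1), mk(v2)))
  expect_equal(sort(out[[1]]$chroms$chr1), sort(out[[2]]$chroms$chr1))
  # within-sample rank order preserved
  expect_equal(order(out[[1]]$chroms$chr1), order(v1))
  expect_error(quantile_normalize(list(mk(v1), read_track(
    write_tmp_track("chr2\t0\t20\t0.5"), 20))), "grids")
})

test_that("profile sets round-trip through TSV exactly", {
  mp <- make_profiles(four_shapes(), 3, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_profiles(path, mp$profiles)
  back <- read_profiles(path)
  expect_equal(names(back), names(mp$profiles))
  for (id in names(back)) {
    expect_equal(back[[id]]$values, mp$profiles[[id]]$values, tolerance = 1e-9)
    expect_identical(back[[id]]$border_index, mp$profiles[[id]]$border_index)
  }
})

test_that("bin tables index bins by signed offset from each border", {
  p <- new_profile("e", seq(0.01, 0.4, by = 0.01) / 1, 10, 10, 10, 10)
  tab <- profile_bin_table(list(p))
  expect_equal(nrow(tab), 40)
  expect_equal(tab$offset[1:20], c(-10:-1, 0:9))
  expect_equal(tab$block, rep(c("IE", "EI"), each = 20))
  # truncated profile: fewer intron-side offsets
  pt <- new_profile("t", runif(17), 4, 5, 5, 3)
  tt <- profile_bin_table(list(pt))
  expect_equal(min(tt$offset[tt$block == "IE"]), -4)
  expect_equal(max(tt$offset[tt$block == "EI"]), 2)
})
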