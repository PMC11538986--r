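test_that("day_shift rotates whole days and relabels timestamps", {
  tr <- mk_walk(n_days = 3, seed = 71)
  tr$x <- rep(c(1, 2, 3), each = 96)  # mark the days
  sh <- day_shift(tr, 1)
  expect_equal(unique(sh$x[1:96]), 3)        # slot 1 now holds day 3
  expect_equal(unique(sh$x[97:192]), 1)
  expect_equal(unique(sh$x[193:288]), 2)
  expect_equal(sh$timestamp, tr$timestamp)   # grid unchanged
  expect_error(day_shift(tr, 0), "offset")
  expect_error(day_shift(tr, 3), "offset")   # full rotation = identity
})

test_that("day_shift preserves the (time-of-day, x, y) multiset exactly", {
  set.seed(72)
  tr <- mk_walk(n_days = 5, seed = 72)
  tr <- tr[-sample(nrow(tr), 40), ]  # ragged days survive the rotation
  for (off in c(1, 2, 4)) {
    sh <- day_shift(tr, off)
    key <- function(t) sort(paste(format(t$timestamp, "%H:%M"),
                                  round(t$x, 6), round(t$y, 6)))
    expect_equal(key(sh), key(tr))
  }
})

test_that("a constant metric yields p_low = p_high = 1", {
  a <- mk_walk(n_days = 6, seed = 73)
  b <- mk_walk(n_days = 6, seed = 74, id = "B", gid = "G2")
  const <- structure(function(a, b) 42, metric_name = "const")
  nd <- build_null(a, b, const, n_perm = 5, seed = 1)
  expect_equal(nd$p_low, 1)
  expect_equal(nd$p_high, 1)
  expect_false(nd$significant)
})

test_that("null distributions are reproducible and p-values bounded", {
  a <- mk_walk(n_days = 8, seed = 75)
  b <- mk_walk(n_days = 8, seed = 76, id = "B", gid = "G2")
  n1 <- build_null(a, b, metric_mean_distance(), n_perm = 7, seed = 99)
  n2 <- build_null(a, b, metric_mean_distance(), n_perm = 7, seed = 99)
  expect_identical(n1$null, n2$null)
  expect_gte(n1$p_low, 1 / (n1$n_perm + 1))
  expect_lte(n1$p_low, 1)
  expect_gte(n1$p_low + n1$p_high, 1)
  # offsets are distinct when enough days are available
  expect_equal(length(unique(n1$null)) > 1, TRUE)
})

test_that("offsets fall back to replacement sampling with a warning", {
  a <- mk_walk(n_days = 3, seed = 77)
  b <- mk_walk(n_days = 3, seed = 78, id = "B", gid = "G2")
  expect_warning(build_null(a, b, metric_mean_distance(), n_perm = 10,
                            seed = 1), "replacement")
})

test_that("non-overlapping site use gives a degenerate, non-significant sharing null", {
  # group A always at site S01, group B always at S02, 8 nights
  mk_site_track <- function(site_xy, id, gid, n_days = 8) {
    tr <- mk_walk(n_days = n_days, seed = 1, id = id, gid = gid)
    night <- in_window(tr$timestamp, c("20:00", "04:00"))
    tr$x <- ifelse(night, site_xy[1], tr$x + 10000)
    tr$y <- ifelse(night, site_xy[2], tr$y)
    tr
  }
  a <- mk_site_track(c(0, 0), "A", "G1")
  b <- mk_site_track(c(6000, 0), "B", "G2")
  sites <- tibble::tibble(site_id = c("S01", "S02"), x = c(0, 6000),
                          y = c(0, 0))
  sh <- sharing_null(a, b, sites, n_perm = 7, seed = 3)
  expect_equal(sh$empirical, 0)
  expect_true(all(sh$null == 0))
  expect_false(sh$significant)
})

test_that("site-specific nulls detect next-day attraction at a shared site", {
  sig <- logical(5)
  for (s in 1:5) {
    sim <- simulate_scenario("attraction_after_sharing", seed = s)
    tracks <- lapply(split(sim$fixes, sim$fixes$group_id), function(fx)
      remove_jitter(regularize(fx), night_window = c("17:30", "08:30")))
    nc <- nightly_centroids(sim$fixes)
    cs <- cluster_sites(nc, cut_m = 500)
    fl <- flag_shared_nights(cs$nights)
    top <- names(sort(table(fl$dyads$site_id), decreasing = TRUE))[1]
    ps <- suppressWarnings(
      post_sharing_null(tracks[[1]], tracks[[2]], cs$sites, top,
                        metric = "mean_distance", n_perm = 100,
                        seed = s + 5))
    expect_false(ps$abstained)
    sig[s] <- isTRUE(ps$significant) && ps$empirical < ps$null_lo
  }
  expect_gte(mean(sig), 0.8)
})

test_that("site-specific nulls abstain without permuted sharing instances", {
  a <- mk_walk(n_days = 6, seed = 79)
  b <- mk_walk(n_days = 6, seed = 80, id = "B", gid = "G2")
  b$x <- b$x + 50000  # groups never meet
  sites <- tibble::tibble(site_id = c("S01", "S02"), x = c(0, 50000),
                          y = c(0, 0))
  ps <- post_sharing_null(a, b, sites, "S01", n_perm = 5, seed = 4)
  expect_true(ps$abstained)
  expect_true(is.na(ps$significant))
  expect_match(ps$reason, "instance")
})
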