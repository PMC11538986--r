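test_that("headings and their differences follow the geometry", {
  a <- mk_track(x = seq(0, 500, by = 100), y = rep(0, 6))
  b <- mk_track(x = seq(1000, 1500, by = 100), y = rep(200, 6),
                id = "B", gid = "G2")
  ds <- dyad_series(a, b)
  expect_equal(ds$heading_diff[-1], rep(0, 5))        # both due east
  expect_equal(ds$distance_m[1], sqrt(1000^2 + 200^2))
  b2 <- mk_track(x = seq(1500, 1000, by = -100), y = rep(200, 6),
                 id = "B", gid = "G2")
  expect_equal(dyad_series(a, b2)$heading_diff[-1], rep(180, 5))
  # sub-threshold steps leave the heading undefined
  still <- mk_track(x = rep(0, 6), y = rep(0, 6), id = "B", gid = "G2")
  expect_true(all(is.na(dyad_series(a, still)$heading_b)))
})

test_that("dyad series equals a brute-force per-point recomputation", {
  set.seed(51)
  for (rep in 1:5) {
    a <- mk_walk(n_days = 2, seed = rep, id = "A")
    b <- mk_walk(n_days = 2, seed = rep + 100, id = "B", gid = "G2")
    ds <- dyad_series(a, b)
    for (i in sort(sample(2:96, 8))) {
      expect_equal(ds$distance_m[i],
                   sqrt((a$x[i] - b$x[i])^2 + (a$y[i] - b$y[i])^2))
      ha <- atan2(a$y[i] - a$y[i - 1], a$x[i] - a$x[i - 1]) * 180 / pi
      hb <- atan2(b$y[i] - b$y[i - 1], b$x[i] - b$x[i - 1]) * 180 / pi
      d <- abs(ha - hb) %% 360
      expect_equal(ds$heading_diff[i], min(d, 360 - d))
      expect_equal(ds$step_diff[i],
                   abs(sqrt((a$x[i] - a$x[i - 1])^2 + (a$y[i] - a$y[i - 1])^2) -
                         sqrt((b$x[i] - b$x[i - 1])^2 +
                                (b$y[i] - b$y[i - 1])^2)))
    }
  }
})

test_that("interaction merging follows the 75-min rule", {
  grid <- ts_utc("2014-01-15 08:30:00") + seq(0, 9 * 3600, by = 900)
  w1 <- grid[grid <= ts_utc("2014-01-15 09:30:00")]
  w2 <- grid[grid >= ts_utc("2014-01-15 10:30:00") &
               grid <= ts_utc("2014-01-15 11:00:00")]
  ds <- mk_ds_from_times(c(w1, w2), grid)
  ints <- extract_interactions(ds, radius_m = 600)
  expect_equal(nrow(ints), 1)  # 60-min gap merges
  expect_equal(ints$start, w1[1])
  expect_equal(ints$end, w2[length(w2)])

  w3 <- grid[grid >= ts_utc("2014-01-15 11:00:00") &
               grid <= ts_utc("2014-01-15 11:30:00")]
  ds2 <- mk_ds_from_times(c(w1, w3), grid)
  expect_equal(nrow(extract_interactions(ds2, 600)), 2)  # 90-min gap splits
})

test_that("randomized in/out sequences match the brute-force merge oracle", {
  set.seed(52)
  for (rep in 1:40) {
    n_days <- sample(1:3, 1)
    grid <- ts_utc("2014-01-15 00:00:00") + seq(0, n_days * 86400 - 900,
                                                by = 900)
    grid <- grid[in_window(grid, c("08:30", "17:30"))]
    within <- sort(sample(grid, sample(3:25, 1)))
    ds <- mk_ds_from_times(within, grid)
    ints <- extract_interactions(ds, 600)
    oracle <- merge_oracle(within, 75)
    expect_equal(nrow(ints), length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(ints$start[k], oracle[[k]][1])
      expect_equal(ints$end[k], oracle[[k]][2])
    }
  }
})

test_that("interactions never span a night boundary", {
  grid <- ts_utc("2014-01-15 08:30:00") + seq(0, 2 * 86400, by = 900)
  grid <- grid[in_window(grid, c("08:30", "17:30"))]
  ds <- mk_ds_from_times(grid, grid)  # continuously within radius
  ints <- extract_interactions(ds, 600)
  expect_equal(nrow(ints), 3)  # one per day
  expect_equal(as.Date(ints$start), unique(as.Date(grid)))
})

test_that("preceding-night sharing is read from the dyad table", {
  grid <- ts_utc("2014-01-16 09:00:00") + seq(0, 3600, by = 900)
  ds <- mk_ds_from_times(grid, grid)
  shared <- tibble::tibble(night_date = as.Date("2014-01-15"),
                           site_id = "S01", group_a = "G1", group_b = "G2")
  ints <- extract_interactions(ds, 600, shared_dyads = shared,
                               dyad = c("G2", "G1"))
  expect_true(ints$preceded_by_shared_night)
  ints2 <- extract_interactions(ds, 600, shared_dyads = shared,
                                dyad = c("G1", "G3"))
  expect_false(ints2$preceded_by_shared_night)
})

test_that("within-group threshold matches analytic quantiles", {
  a <- mk_track(x = rep(0, 200), y = rep(0, 200),
                start = "2014-01-15 09:00:00")
  b <- mk_track(x = rep(40, 200), y = rep(0, 200),
                start = "2014-01-15 09:00:00", id = "B")
  expect_equal(within_group_threshold(list(a, b)), 40)

  set.seed(53)
  n <- 1e4
  ts0 <- ts_utc("2014-01-15 09:00:00") + (seq_len(n) - 1) * 60
  keep <- in_window(ts0, c("08:30", "17:30"))
  a2 <- tibble::tibble(individual_id = "A", group_id = "G1",
                       timestamp = ts0, x = 0, y = 0, source = "observed")
  b2 <- a2; b2$individual_id <- "B"; b2$x <- runif(n, 0, 100)
  got <- within_group_threshold(list(a2, b2))
  expect_equal(got, 80, tolerance = 0.03)

  solo <- list(a, mk_track(x = 1:40, y = 1:40, id = "C", gid = "G9"))
  expect_error(within_group_threshold(solo), "fallback")
})

test_that("cohesion requires sustained proximity plus travel", {
  path <- seq(0, 500, by = 100)
  a <- mk_track(x = path, y = rep(0, 6), start = "2014-01-15 09:00:00")
  b <- mk_track(x = path, y = rep(10, 6), start = "2014-01-15 09:00:00",
                id = "B", gid = "G2")
  ds <- dyad_series(a, b)
  int <- tibble::tibble(start = ds$timestamp[1],
                        end = ds$timestamp[nrow(ds)])
  expect_true(classify_cohesion(int, ds, threshold_m = 50,
                                min_travel_m = 100))
  # stationary groups close together: no travel, not cohesive
  a2 <- mk_track(x = rep(0, 6), y = rep(0, 6),
                 start = "2014-01-15 09:00:00")
  b2 <- mk_track(x = rep(10, 6), y = rep(0, 6),
                 start = "2014-01-15 09:00:00", id = "B", gid = "G2")
  ds2 <- dyad_series(a2, b2)
  expect_false(classify_cohesion(int, ds2, 50, 100))
})

test_that("cohesion classifier equals exhaustive run enumeration", {
  cohesion_oracle <- function(ds, thr, travel) {
    n <- nrow(ds)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (all(ds$distance_m[i:j] <= thr)) {
        pa <- sum(sqrt(diff(ds$xa[i:j])^2 + diff(ds$ya[i:j])^2))
        pb <- sum(sqrt(diff(ds$xb[i:j])^2 + diff(ds$yb[i:j])^2))
        if (pa >= travel || pb >= travel) return(TRUE)
      }
    }
    FALSE
  }
  set.seed(54)
  agree <- 0
  for (rep in 1:30) {
    a <- mk_walk(n_days = 1, step_sd = 40, seed = rep)
    b <- mk_walk(n_days = 1, step_sd = 40, seed = rep + 500, id = "B",
                 gid = "G2")
    ds <- dyad_series(a, b)[30:60, ]
    int <- tibble::tibble(start = min(ds$timestamp), end = max(ds$timestamp))
    thr <- stats::quantile(ds$distance_m, 0.3)
    got <- classify_cohesion(int, ds, thr, 300)
    expect_equal(got, cohesion_oracle(ds, thr, 300))
    agree <- agree + got
  }
  expect_gt(agree, 0)  # the cases exercise both outcomes
  expect_lt(agree, 30)
})

test_that("front/behind scores are signed by travel order and antisymmetric", {
  # a ahead of b along shared eastward travel
  a <- mk_track(x = seq(100, 600, by = 100), y = rep(0, 6),
                start = "2014-01-15 09:00:00")
  b <- mk_track(x = seq(0, 500, by = 100), y = rep(0, 6),
                start = "2014-01-15 09:00:00", id = "B", gid = "G2")
  fb <- front_behind_scores(dyad_series(a, b))
  expect_true(all(fb$scores$score > 0))
  # side by side: even
  b2 <- mk_track(x = seq(100, 600, by = 100), y = rep(50, 6),
                 start = "2014-01-15 09:00:00", id = "B", gid = "G2")
  fb2 <- front_behind_scores(dyad_series(a, b2))
  expect_equal(fb2$scores$score, rep(0, 5), tolerance = 1e-9)
  # swapping the dyad negates the scores exactly
  set.seed(55)
  ra <- mk_walk(n_days = 1, seed = 60)
  rb <- mk_walk(n_days = 1, seed = 61, id = "B", gid = "G2")
  s_ab <- front_behind_scores(dyad_series(ra, rb))$scores$score
  s_ba <- front_behind_scores(dyad_series(rb, ra))$scores$score
  expect_equal(s_ab, -s_ba, tolerance = 1e-9)
})
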