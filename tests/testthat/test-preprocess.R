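test_that("fixes already on the grid pass through unchanged", {
  tr <- mk_track(x = c(0, 10, 20), y = c(0, 0, 0))
  out <- regularize(tr, 15)
  expect_equal(out$x, tr$x)
  expect_equal(out$timestamp, tr$timestamp)
  expect_true(all(out$source == "observed"))
  # idempotent
  expect_equal(regularize(out, 15), out)
})

test_that("an interior gap is linearly interpolated and flagged", {
  tr <- mk_track(x = c(0, 100), y = c(0, 0))
  tr$timestamp[2] <- tr$timestamp[2] + 900  # leave one missing slot
  out <- regularize(tr, 15)
  expect_equal(nrow(out), 3)
  expect_equal(out$x[2], 50)
  expect_equal(out$y[2], 0)
  expect_equal(out$source[2], "interpolated")
})

test_that("random deletions up to max_gap match a linear oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    full <- mk_track(x = cumsum(rnorm(n, 0, 30)), y = cumsum(rnorm(n, 0, 30)))
    drop <- sort(sample(2:(n - 1), 12))
    # keep gaps at <= 4 consecutive deletions
    runs <- split(drop, cumsum(c(1, diff(drop) != 1)))
    drop <- unlist(lapply(runs, function(r) r[seq_len(min(4, length(r)))]))
    thin <- full[-drop, ]
    out <- regularize(thin, 15)
    oracle_x <- stats::approx(as.numeric(thin$timestamp), thin$x,
                              xout = as.numeric(full$timestamp))$y
    oracle_y <- stats::approx(as.numeric(thin$timestamp), thin$y,
                              xout = as.numeric(full$timestamp))$y
    expect_equal(out$x, oracle_x, tolerance = 1e-9)
    expect_equal(out$y, oracle_y, tolerance = 1e-9)
  }
})

test_that("gaps longer than max_gap stay missing", {
  tr <- mk_track(x = c(0, 100), y = c(0, 0))
  tr$timestamp[2] <- tr$timestamp[2] + 6 * 900
  out <- regularize(tr, 15, max_gap = 4)
  expect_equal(sum(out$source == "missing"), 6)
  expect_true(all(is.na(out$x[out$source == "missing"])))
})

test_that("out-and-back spikes are replaced by the neighbour midpoint", {
  tr <- mk_track(x = c(0, 10, 10000, 20, 30), y = rep(0, 5))
  out <- correct_anomalies(tr, max_speed_mps = 3)
  expect_equal(out$x[3], 15)
  expect_equal(out$source[3], "corrected")
  # clean track is untouched, and correction is idempotent
  clean <- mk_track(x = seq(0, 400, by = 100), y = rep(0, 5))
  expect_equal(correct_anomalies(clean, 3), clean)
  expect_equal(correct_anomalies(out, 3), out)
})

test_that("injected spikes into simulated tracks are recovered", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    sim <- simulate_gps(sim_config(n_groups = 1,
                                   individuals_per_group = 1, n_days = 5),
                        seed = s)
    tr <- regularize(sim$fixes, 15)
    set.seed(s)
    idx <- sample(which(tr$source == "observed")[-c(1, nrow(tr))], 20)
    idx <- idx[idx > 1 & idx < nrow(tr)]
    idx <- idx[!(idx %in% (idx + 1)) & !(idx %in% (idx - 1))]  # isolated
    tr$x[idx] <- tr$x[idx] + 10000
    out <- correct_anomalies(tr, 3)
    hits <- hits + sum(out$source[idx] == "corrected")
    total <- total + length(idx)
  }
  expect_gte(hits / total, 0.95)
})

test_that("night jitter snaps to the nightly median, daytime untouched", {
  set.seed(5)
  n <- 96
  tr <- mk_track(x = rnorm(n, 500, 3), y = rnorm(n, 800, 3),
                 start = "2014-01-15 00:00:00")
  day_sel <- in_window(tr$timestamp, c("08:30", "17:30"))
  day_x <- tr$x[day_sel]
  out <- remove_jitter(tr, c("20:00", "04:00"), 20)
  night_sel <- in_window(out$timestamp, c("20:00", "04:00"))
  # one snapped value per night date (the 00:00-04:00 block belongs to the
  # previous night, the 20:00-24:00 block to this one)
  expect_lte(length(unique(out$x[night_sel])), 2)
  expect_equal(out$x[day_sel], day_x)
  expect_equal(remove_jitter(out, c("20:00", "04:00"), 20), out)
})

test_that("observed-point provenance never increases along the chain", {
  sim <- simulate_gps(sim_config(n_groups = 1, individuals_per_group = 1,
                                 n_days = 3), seed = 2)
  fx <- sim$fixes[-c(10, 11, 50), ]  # knock out a few fixes
  t1 <- regularize(fx, 15)
  t2 <- correct_anomalies(t1, 3)
  t3 <- remove_jitter(t2, c("20:00", "04:00"), 20)
  n_obs <- function(tr) sum(tr$source == "observed")
  expect_true(n_obs(t2) <= n_obs(t1))
  expect_true(n_obs(t3) <= n_obs(t2))
})

test_that("group tracks follow the longest-duration member", {
  long <- mk_walk(n_days = 4, seed = 1, id = "L")
  short <- mk_walk(n_days = 2, seed = 2, id = "S")
  expect_equal(build_group_track(list(long)), long)
  gt <- build_group_track(list(short, long))
  expect_equal(nrow(gt), nrow(long))
  expect_true(all(gt$individual_id == "L"))
  # short member only contributes where the long one is absent
  short2 <- short
  short2$timestamp <- short2$timestamp + 4 * 86400
  gt2 <- build_group_track(list(short2, long))
  expect_equal(sum(gt2$individual_id == "S"), nrow(short2))
  # the group track never deviates from the chosen member's positions
  m <- match(as.numeric(long$timestamp), as.numeric(gt2$timestamp))
  expect_equal(gt2$x[m], long$x)
})
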