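unit_rows <- function(n, v) matrix(rep(v, each = n), n, 3)

test_that("stable posture is sleep, oscillating posture is wake", {
  # 60 minutes of constant orientation
  b <- mk_bursts(unit_rows(60, c(0, 0, 1)), noise_sd = 0.005)
  st <- classify_minutes(b)
  expect_true(all(st$state == "sleep"))
  # alternating +/-20 degree posture flips every minute
  tilt <- rep(c(0, 20), 30) * pi / 180
  ori <- cbind(sin(tilt), 0, cos(tilt))
  st2 <- classify_minutes(mk_bursts(ori, noise_sd = 0.005))
  expect_true(all(st2$state == "wake"))
  # a dead sensor minute is missing
  b3 <- mk_bursts(unit_rows(10, c(0, 0, 1)), noise_sd = 0)
  b3$ax[5, ] <- 0; b3$ay[5, ] <- 0; b3$az[5, ] <- 0
  st3 <- classify_minutes(b3)
  expect_equal(st3$state[5], "missing")
})

test_that("short stable runs stay wake; the run threshold is respected", {
  # 4-minute stable run below the 5-minute window -> wake
  tilt <- c(rep(0, 4), 40, rep(80, 4), 40, rep(0, 6)) * pi / 180
  ori <- cbind(sin(tilt), 0, cos(tilt))
  st <- classify_minutes(mk_bursts(ori, noise_sd = 0.002), window_min = 5)
  expect_true(all(st$state[1:4] == "wake"))
  expect_true(all(st$state[12:16] == "sleep"))  # 6-minute stable tail
})

test_that("sleep metrics match hand-counted label strings", {
  # 480-min period, all sleep
  st <- mk_states(strrep("s", 480))
  sm <- sleep_metrics(st)
  expect_equal(sm$tst_min, 480)
  expect_equal(sm$efficiency, 1)
  expect_equal(sm$fragmentation, 0)

  # 360 sleep minutes; wake bouts: 50, 30, 20, 9 (counted) and 11 x 1 min
  # (ignored): fragmentation = 4 bouts / 6 h = 0.667
  wake_long <- c(50, 30, 20, 9)
  lab <- paste0(
    strrep("s", 40),
    paste0(vapply(wake_long, function(k) paste0(strrep("w", k),
                                                strrep("s", 25)),
                  character(1)), collapse = ""),
    paste0(rep(paste0("w", strrep("s", 20)), 11), collapse = ""))
  lab <- substr(lab, 1, 480)
  stopifnot(nchar(lab) == 480,
            sum(strsplit(lab, "")[[1]] == "s") == 360)
  sm2 <- sleep_metrics(mk_states(lab))
  expect_equal(sm2$tst_min, 360)
  expect_equal(sm2$efficiency, 0.75)
  expect_equal(sm2$n_wake_bouts, 4)
  expect_equal(sm2$fragmentation, 4 / 6, tolerance = 1e-12)

  # boundary: 1-min wake bouts never counted, exactly-2-min bouts counted
  lab3 <- paste0(strrep("s", 100), "w", strrep("s", 100), "ww",
                 strrep("s", 277))
  sm3 <- sleep_metrics(mk_states(lab3))
  expect_equal(sm3$n_wake_bouts, 1)

  # no sleep: fragmentation is missing, not infinite
  sm4 <- sleep_metrics(mk_states(strrep("w", 480)))
  expect_equal(sm4$tst_min, 0)
  expect_true(is.na(sm4$fragmentation))
})

test_that("missing minutes leave the efficiency denominator", {
  lab <- paste0(strrep("s", 200), strrep("m", 80), strrep("w", 200))
  sm <- sleep_metrics(mk_states(lab))
  expect_equal(sm$efficiency, 200 / 400)
  expect_true(sm$usable)  # 400 >= half of 480
  lab2 <- paste0(strrep("s", 100), strrep("m", 380))
  expect_false(sleep_metrics(mk_states(lab2))$usable)
})

test_that("onset and offset bracket the first and last long sleep runs", {
  # starts 19:00: 40 wake, then sleep until a 06:00 waking
  lab <- paste0(strrep("w", 40), strrep("s", 620), strrep("w", 60))
  st <- mk_states(lab, start = "2014-01-15 19:00:00")
  sm <- sleep_metrics(st)
  expect_equal(sm$onset, ts_utc("2014-01-15 19:40:00"))
  expect_equal(sm$offset, ts_utc("2014-01-16 05:59:00"))
})

test_that("synchronization counts joint-state agreement", {
  a <- mk_states(strrep("s", 480))
  expect_equal(synchronization(a, a), 1)
  b <- mk_states(strrep("w", 480), id = "B")
  expect_equal(synchronization(a, b), 0)
  # symmetry and relabel invariance
  set.seed(91)
  lab <- function() paste(sample(c("s", "w"), 480, replace = TRUE,
                                 prob = c(0.8, 0.2)), collapse = "")
  x <- mk_states(lab()); y <- mk_states(lab(), id = "B")
  expect_equal(synchronization(x, y), synchronization(y, x))
  flip <- function(s) {
    s$state <- c(sleep = "wake", wake = "sleep")[s$state]
    s
  }
  expect_equal(synchronization(flip(x), flip(y)), synchronization(x, y))
  # independent Bernoulli(0.8) sequences agree ~ 0.8^2 + 0.2^2
  scores <- replicate(20, synchronization(mk_states(lab()),
                                          mk_states(lab(), id = "B")))
  expect_equal(mean(scores), 0.68, tolerance = 0.05)
  # no joint coverage -> missing
  z <- mk_states(strrep("m", 480), id = "B")
  expect_true(is.na(synchronization(a, z)))
})

test_that("effect tables join metrics to assignments and drop unusable nights", {
  nights <- tibble::tibble(
    individual_id = rep(c("A", "B"), each = 3),
    night_date = rep(as.Date("2014-01-15") + 0:2, 2),
    site_id = "S01", group_id = rep(c("G1", "G2"), each = 3),
    shared = rep(c(TRUE, FALSE, FALSE), 2))
  sn <- tibble::tibble(
    individual_id = rep(c("A", "B"), each = 3),
    night_date = rep(as.Date("2014-01-15") + 0:2, 2),
    tst_min = c(400, 450, 440, 390, 455, 445),
    efficiency = 0.9, fragmentation = 1.5,
    usable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  eff <- build_effect_table(sn, nights)
  expect_equal(nrow(eff), 5)
  expect_true(all(c("shared", "site_id", "group_id") %in% names(eff)))
  expect_equal(sum(eff$shared), 2)

  con <- summarize_sharing_effects(eff, metrics = "tst_min", n_boot = 50,
                                   seed = 1)
  expect_equal(con$difference,
               mean(c(400, 390)) - mean(c(450, 440, 455)))
  # swapping the flag negates the contrast
  eff2 <- eff; eff2$shared <- !eff2$shared
  con2 <- summarize_sharing_effects(eff2, metrics = "tst_min", n_boot = 50,
                                    seed = 1)
  expect_equal(con2$difference, -con$difference)
})

test_that("total sleep time is monotone in the stability threshold", {
  cfg <- sim_config()
  nights <- tibble::tibble(individual_id = "A", shared = FALSE,
                           night_date = as.Date("2014-01-15") + 0:1)
  labels <- simulate_sleep_labels(nights, cfg, seed = 8)
  bursts <- simulate_accel(labels, cfg, seed = 9)
  tst_at <- function(thr) sum(classify_minutes(bursts,
                                               angle_threshold_deg = thr)$state ==
                                "sleep")
  expect_lte(tst_at(2), tst_at(5))
  expect_lte(tst_at(5), tst_at(10))
})
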