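# Fixture builders shared across tests. Everything is generated in code;
# simulator scenarios provide the larger datasets.

options(nightshare.quiet = TRUE)

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# simple trajectory tibble on a regular 15-min grid
mk_track <- function(x, y, start = "2014-01-15 08:00:00", by_min = 15,
                     id = "A", gid = "G1") {
  tibble::tibble(individual_id = id, group_id = gid,
                 timestamp = ts_utc(start) + (seq_along(x) - 1) * by_min * 60,
                 x = x, y = y, source = "observed")
}

# random-walk track over several days with day-time movement only
mk_walk <- function(n_days = 3, step_sd = 50, seed = 1, id = "A",
                    gid = "G1", start_xy = c(0, 0)) {
  set.seed(seed)
  n <- n_days * 96
  tibble::tibble(
    individual_id = id, group_id = gid,
    timestamp = ts_utc("2014-01-15 00:00:00") + (seq_len(n) - 1) * 900,
    x = start_xy[1] + cumsum(stats::rnorm(n, 0, step_sd)),
    y = start_xy[2] + cumsum(stats::rnorm(n, 0, step_sd)),
    source = "observed")
}

# minute-state tibble from a compact label string (s = sleep, w = wake,
# m = missing), starting at a given clock time
mk_states <- function(labels, start = "2014-01-15 21:00:00", id = "A") {
  lab <- strsplit(labels, "")[[1]]
  state <- c(s = "sleep", w = "wake", m = "missing")[lab]
  tibble::tibble(individual_id = id,
                 timestamp = ts_utc(start) + (seq_along(lab) - 1) * 60,
                 angle = NA_real_, state = unname(state))
}

# accel bursts with one burst per minute at the given unit orientations
mk_bursts <- function(orientations, start = "2014-01-15 21:00:00",
                      id = "A", noise_sd = 0.01, len = 32, seed = 1) {
  set.seed(seed)
  n <- nrow(orientations)
  mk <- function(j) orientations[, j] +
    matrix(stats::rnorm(n * len, 0, noise_sd), n, len)
  accel_bursts(rep(id, n), ts_utc(start) + (seq_len(n) - 1) * 60,
               mk(1), mk(2), mk(3))
}

# analytic cell-integrated isotropic Gaussian UD on an aligned grid
gaussian_ud <- function(mu = c(0, 0), sigma = 1, cell = 0.05, half = 6) {
  x0 <- floor((mu[1] - half * sigma) / cell) * cell
  x1 <- ceiling((mu[1] + half * sigma) / cell) * cell
  y0 <- floor((mu[2] - half * sigma) / cell) * cell
  y1 <- ceiling((mu[2] + half * sigma) / cell) * cell
  xs <- seq(x0 + cell / 2, x1 - cell / 2, by = cell)
  ys <- seq(y0 + cell / 2, y1 - cell / 2, by = cell)
  z <- outer(stats::dnorm(xs, mu[1], sigma), stats::dnorm(ys, mu[2], sigma)) *
    cell^2
  structure(list(x = xs, y = ys, z = z / sum(z), cell = cell, h = sigma),
            class = "ud")
}

# dyad series whose distance is 100 m at the given times, 5000 m elsewhere
mk_ds_from_times <- function(within_times, all_times) {
  ds <- tibble::tibble(timestamp = all_times,
                       xa = 0, ya = 0,
                       xb = ifelse(all_times %in% within_times, 100, 5000),
                       yb = 0)
  ds$distance_m <- abs(ds$xb)
  ds$heading_a <- NA_real_; ds$heading_b <- NA_real_
  ds$heading_diff <- NA_real_
  ds$step_a <- 0; ds$step_b <- 0; ds$step_diff <- 0
  ds
}

# brute-force interval merging oracle: within-times -> list of (start, end)
merge_oracle <- function(times, gap_min = 75) {
  if (!length(times)) return(NULL)
  times <- sort(times)
  day <- as.Date(times, tz = "UTC")
  out <- list()
  cur_start <- times[1]; cur_end <- times[1]
  for (i in seq_along(times)[-1]) {
    gap <- as.numeric(times[i] - cur_end, units = "mins")
    if (gap < gap_min && day[i] == as.Date(cur_end, tz = "UTC")) {
      cur_end <- times[i]
    } else {
      out[[length(out) + 1]] <- c(cur_start, cur_end)
      cur_start <- times[i]; cur_end <- times[i]
    }
  }
  out[[length(out) + 1]] <- c(cur_start, cur_end)
  out
}
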