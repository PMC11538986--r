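# Accelerometry-based sleep analysis: posture-angle minute classification
# (a run-length adaptation of wearable-actigraphy angle algorithms),
# per-night sleep metrics, dyadic synchronization and model-ready tables.

#' Classify minutes as sleep or wake from posture-angle stability
#'
#' Each burst yields a posture angle atan2(mean_az, sqrt(mean_ax^2 +
#' mean_ay^2)); a minute is labelled sleep iff it lies inside a run of at
#' least `window_min` consecutive minutes whose successive absolute angle
#' changes all stay below `angle_threshold_deg`. Minutes without a burst
#' are missing; all-zero (dead-sensor) bursts are missing and logged.
#'
#' @param bursts an [accel_bursts] object
#' @param angle_threshold_deg stability threshold, degrees
#' @param window_min minimum stable run labelled sleep, minutes
#' @return tibble: individual_id, timestamp (minute), angle, state
#'   ("sleep", "wake", "missing")
#' @export
classify_minutes <- function(bursts, angle_threshold_deg = 5,
                             window_min = 5) {
  info <- bursts$info
  mx <- rowMeans(bursts$ax, na.rm = TRUE)
  my <- rowMeans(bursts$ay, na.rm = TRUE)
  mz <- rowMeans(bursts$az, na.rm = TRUE)
  dead <- rowSums(abs(bursts$ax), na.rm = TRUE) +
    rowSums(abs(bursts$ay), na.rm = TRUE) +
    rowSums(abs(bursts$az), na.rm = TRUE) == 0
  if (any(dead)) ns_log("%d dead (all-zero) burst(s) set missing", sum(dead),
                        level = "WARN")
  angle <- atan2(mz, sqrt(mx^2 + my^2)) * 180 / pi
  angle[dead] <- NA

  out <- vector("list", length(unique(info$individual_id)))
  k <- 0
  for (id in unique(info$individual_id)) {
    sel <- which(info$individual_id == id)
    sel <- sel[order(info$timestamp[sel])]
    t0 <- min(info$timestamp[sel]); t1 <- max(info$timestamp[sel])
    grid <- seq(t0, t1, by = 60)
    slot <- match(round(as.numeric(info$timestamp[sel]) / 60),
                  round(as.numeric(grid) / 60))
    a <- rep(NA_real_, length(grid))
    a[slot[!is.na(slot)]] <- angle[sel][!is.na(slot)]
    # segment minutes into maximal runs of stable successive angles;
    # any missing minute or change >= threshold breaks the run
    brk <- c(TRUE, abs(diff(a)) >= angle_threshold_deg | is.na(diff(a)))
    seg <- cumsum(brk)
    seg_len <- ave(seq_along(seg), seg, FUN = length)
    state <- ifelse(is.na(a), "missing",
                    ifelse(seg_len >= window_min, "sleep", "wake"))
    # a present minute adjacent to missing neighbours forms its own segment
    k <- k + 1
    out[[k]] <- tibble::tibble(individual_id = id, timestamp = grid,
                               angle = a, state = state)
  }
  do.call(rbind, out)
}

# maximal runs of a logical vector; returns data.frame(start, end, length)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1, end = ends,
             length = r$lengths)[r$values, , drop = FALSE]
}

#' Per-night sleep metrics
#'
#' Over the fixed sleep period (21:00--05:00 by default): total sleep time
#' (sleep minutes), sleep efficiency (sleep / non-missing minutes),
#' fragmentation (maximal wake bouts of at least `wake_bout_min` minutes
#' per hour of sleep; undefined when no sleep), and sleep onset/offset
#' (start of the first / end of the last sleep run of at least
#' `window_min` minutes inside the search window). Nights whose states
#' cover less than half the sleep period are flagged unusable.
#'
#' @param states minute states from [classify_minutes()]
#' @param sleep_period clock window of the sleep period
#' @param wake_bout_min minimum counted wake-bout duration, minutes
#' @param window_min minimum sleep run for onset/offset, minutes
#' @param search_window clock window bracketing onset/offset search
#' @param min_coverage minimum classified fraction of the sleep period
#' @return tibble: individual_id, night_date, tst_min, efficiency,
#'   fragmentation, n_wake_bouts, onset, offset, usable
#' @export
sleep_metrics <- function(states, sleep_period = c("21:00", "05:00"),
                          wake_bout_min = 2, window_min = 5,
                          search_window = c("19:00", "07:00"),
                          min_coverage = 0.5) {
  w <- parse_hm(sleep_period)
  period_min <- ((w[2] - w[1]) %% 24) * 60
  nd <- night_date_of(states$timestamp)
  key <- paste(states$individual_id, nd)
  out <- vector("list", length(unique(key)))
  k <- 0
  for (kk in unique(key)) {
    sel <- which(key == kk)
    sel <- sel[order(states$timestamp[sel])]
    st_all <- states$state[sel]
    tod <- tod_hours(states$timestamp[sel])
    inp <- in_window(tod, sleep_period)
    st <- st_all[inp]
    tst <- sum(st == "sleep")
    nonmiss <- sum(st != "missing")
    eff <- if (nonmiss > 0) tst / nonmiss else NA_real_
    wake_runs <- runs_of(st == "wake")
    n_bouts <- sum(wake_runs$length >= wake_bout_min)
    frag <- if (tst > 0) n_bouts / (tst / 60) else NA_real_
    ins <- in_window(tod, search_window)
    sleep_runs <- runs_of(st_all == "sleep" & ins)
    long <- sleep_runs[sleep_runs$length >= window_min, , drop = FALSE]
    na_ts <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
    onset <- if (nrow(long)) states$timestamp[sel][long$start[1]] else na_ts
    offset <- if (nrow(long)) states$timestamp[sel][long$end[nrow(long)]] else
      na_ts
    k <- k + 1
    out[[k]] <- tibble::tibble(
      individual_id = states$individual_id[sel][1],
      night_date = nd[sel[1]],
      tst_min = tst, efficiency = eff,
      fragmentation = frag, n_wake_bouts = n_bouts,
      onset = onset, offset = offset,
      usable = nonmiss >= min_coverage * period_min)
  }
  res <- do.call(rbind, out)
  res[order(res$individual_id, res$night_date), ]
}

#' Dyadic sleep/wake synchronization score
#'
#' Fraction of jointly classified minutes of the sleep period on which two
#' individuals are in the same state (both sleeping or both awake).
#'
#' @param states_a,states_b minute states of the two individuals
#' @param sleep_period clock window
#' @return scalar in [0, 1]; NA when there is no joint coverage
#' @export
synchronization <- function(states_a, states_b,
                            sleep_period = c("21:00", "05:00")) {
  i <- match(as.numeric(states_b$timestamp), as.numeric(states_a$timestamp))
  sb <- which(!is.na(i)); sa <- i[sb]
  keep <- states_a$state[sa] != "missing" & states_b$state[sb] != "missing" &
    in_window(states_a$timestamp[sa], sleep_period)
  if (!any(keep)) return(NA_real_)
  mean(states_a$state[sa][keep] == states_b$state[sb][keep])
}

#' Build model-ready sleep effect tables
#'
#' Joins per-night sleep metrics to nightly site assignments, yielding one
#' record per usable individual-night with the sharing flag and
#' group/individual/date/site identifiers, ready for mixed-model fitting.
#'
#' @param sleep_nights output of [sleep_metrics()]
#' @param night_assignments tibble with individual_id, night_date, site_id,
#'   shared (and optionally group_id), e.g. the simulator's
#'   `truth$individual_nights` or flagged pipeline night records
#' @return tibble of individual-night records
#' @export
build_effect_table <- function(sleep_nights, night_assignments) {
  key <- paste(sleep_nights$individual_id, sleep_nights$night_date)
  akey <- paste(night_assignments$individual_id,
                night_assignments$night_date)
  i <- match(key, akey)
  out <- sleep_nights
  out$site_id <- night_assignments$site_id[i]
  out$shared <- night_assignments$shared[i]
  out$group_id <- if ("group_id" %in% names(night_assignments))
    night_assignments$group_id[i] else NA_character_
  out <- out[out$usable & !is.na(out$shared), ]
  out
}

#' Sharing contrasts with individual-level block bootstrap
#'
#' Difference in means (shared minus unshared nights) for each sleep
#' metric, with percentile confidence intervals from resampling
#' individuals as blocks.
#'
#' @param effect_table from [build_effect_table()]
#' @param metrics metric columns to contrast
#' @param n_boot bootstrap replicates
#' @param conf confidence level
#' @param seed RNG seed
#' @return tibble: metric, difference, ci_lo, ci_hi, n_shared, n_unshared
#' @export
summarize_sharing_effects <- function(effect_table,
                                      metrics = c("tst_min", "efficiency",
                                                  "fragmentation"),
                                      n_boot = 1000, conf = 0.95,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  diff_fn <- function(tab, m) {
    mean(tab[[m]][tab$shared], na.rm = TRUE) -
      mean(tab[[m]][!tab$shared], na.rm = TRUE)
  }
  ids <- unique(effect_table$individual_id)
  by_id <- split(seq_len(nrow(effect_table)), effect_table$individual_id)
  boots <- matrix(NA_real_, n_boot, length(metrics))
  for (b in seq_len(n_boot)) {
    take <- unlist(by_id[sample(length(ids), replace = TRUE)],
                   use.names = FALSE)
    tab <- effect_table[take, ]
    if (!any(tab$shared) || all(tab$shared)) next
    boots[b, ] <- vapply(metrics, diff_fn, numeric(1), tab = tab)
  }
  alpha <- (1 - conf) / 2
  tibble::tibble(
    metric = metrics,
    difference = unname(vapply(metrics, diff_fn, numeric(1),
                               tab = effect_table)),
    ci_lo = apply(boots, 2, stats::quantile, probs = alpha, na.rm = TRUE),
    ci_hi = apply(boots, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE),
    n_shared = sum(effect_table$shared),
    n_unshared = sum(!effect_table$shared))
}
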