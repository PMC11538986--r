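# Dyadic intergroup geometry: per-timestamp distance / heading / step
# series, empirical response-radius inference against day-shift nulls,
# interaction extraction with the 75-min merge rule, cohesive-movement
# classification and front/behind scores.

# per-point step length and heading, computed within calendar days so that
# whole-day permutations leave them untouched
track_kinematics <- function(track, min_step_m = 1) {
  n <- nrow(track)
  day <- floor(as.numeric(track$timestamp) / 86400)
  dx <- c(NA, diff(track$x)); dy <- c(NA, diff(track$y))
  newday <- c(TRUE, day[-1] != day[-n])
  dx[newday] <- NA; dy[newday] <- NA
  step <- sqrt(dx^2 + dy^2)
  hd <- heading_deg(dx, dy)
  hd[!is.na(step) & step < min_step_m] <- NA
  list(step = step, heading = hd, day = day)
}

#' Per-timestamp dyadic series for a pair of group tracks
#'
#' Inner-joins the two tracks on their common timestamp grid and computes
#' the Euclidean distance, each group's step length and heading (from the
#' displacement into each fix, atan2 convention: 0 deg = east,
#' counterclockwise; undefined for steps under `min_step_m` and across
#' day boundaries), the circular absolute heading difference folded to
#' [0, 180], and the absolute step-length difference.
#'
#' @param track_a,track_b trajectory tibbles
#' @param min_step_m minimum step for a defined heading, metres
#' @return tibble with timestamp, coordinates of both groups, distance_m,
#'   heading_a/b, heading_diff, step_a/b, step_diff
#' @export
dyad_series <- function(track_a, track_b, min_step_m = 1) {
  ka <- track_kinematics(track_a, min_step_m)
  kb <- track_kinematics(track_b, min_step_m)
  ia <- match(as.numeric(track_b$timestamp), as.numeric(track_a$timestamp))
  sel_b <- which(!is.na(ia)); sel_a <- ia[sel_b]
  if (!length(sel_b)) {
    warning("tracks share no timestamps; empty dyad series")
    return(tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                          xa = numeric(), ya = numeric(), xb = numeric(),
                          yb = numeric(), distance_m = numeric(),
                          heading_a = numeric(), heading_b = numeric(),
                          heading_diff = numeric(), step_a = numeric(),
                          step_b = numeric(), step_diff = numeric()))
  }
  xa <- track_a$x[sel_a]; ya <- track_a$y[sel_a]
  xb <- track_b$x[sel_b]; yb <- track_b$y[sel_b]
  fast_tbl(timestamp = track_a$timestamp[sel_a],
           xa = xa, ya = ya, xb = xb, yb = yb,
           distance_m = sqrt((xa - xb)^2 + (ya - yb)^2),
           heading_a = ka$heading[sel_a], heading_b = kb$heading[sel_b],
           heading_diff = circ_diff_deg(ka$heading[sel_a],
                                        kb$heading[sel_b]),
           step_a = ka$step[sel_a], step_b = kb$step[sel_b],
           step_diff = abs(ka$step[sel_a] - kb$step[sel_b]))
}

# mean of a metric per distance bin; bins are (100(k-1), 100k] etc.
bin_metric <- function(dist, value, bin_m, n_bins) {
  b <- pmax(ceiling(dist / bin_m), 1)
  ok <- !is.na(value) & !is.na(b) & b <= n_bins
  cnt <- tabulate(b[ok], n_bins)
  sm <- numeric(n_bins)
  if (any(ok)) {
    rs <- rowsum(value[ok], b[ok])
    sm[as.integer(rownames(rs))] <- rs
  }
  list(mean = ifelse(cnt > 0, sm / cnt, NA_real_), n = cnt)
}

#' Infer the intergroup response radius from binned coordination
#'
#' Pools all dyad timestamps, bins them by concurrent intergroup distance
#' (`bin_m`-wide bins ascending from zero) and compares the mean
#' coordination metric per bin (default: heading difference) with the
#' same quantity under day-shift permutations of one track per dyad. The
#' response radius is the lower edge of the first evaluated bin whose
#' empirical value lies inside the null band (5th--95th percentiles by
#' default); if the first evaluated bin already lies inside, the radius
#' is 0. Bins with fewer than `min_obs` empirical observations are
#' skipped.
#'
#' @param pairs either a list of `list(a = track, b = track)` dyads or a
#'   single such pair
#' @param metric "heading_diff", "step_diff" or "distance"
#' @param n_perm day-shift permutations
#' @param bin_m distance bin width, metres
#' @param band null band quantiles
#' @param min_obs minimum empirical observations per scored bin
#' @param min_step_m heading step threshold
#' @param seed RNG seed
#' @return object of class `response_radius`: `radius_m`, `table` (per-bin
#'   empirical value, counts, null band, evaluated/inside flags), `metric`
#' @export
infer_response_radius <- function(pairs, metric = c("heading_diff",
                                                    "step_diff", "distance"),
                                  n_perm = 1000, bin_m = 100,
                                  band = c(0.05, 0.95), min_obs = 50,
                                  min_step_m = 1, seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(pairs$a)) pairs <- list(pairs)

  # step-based metrics (heading/step differences) describe the step into
  # each fix; they are binned by the intergroup distance at the step's
  # start, where the behavioural response to the neighbour was decided
  lag1 <- function(v) c(NA_real_, v[-length(v)])
  prep <- lapply(pairs, function(p) {
    ds <- dyad_series(p$a, p$b, min_step_m)
    day <- as.Date(ds$timestamp, tz = "UTC")
    days <- sort(unique(day))
    rows_by_day <- split(seq_len(nrow(ds)), match(day, days))
    val <- switch(metric, heading_diff = ds$heading_diff,
                  step_diff = ds$step_diff, distance = ds$distance_m)
    bin_dist <- if (metric == "distance") ds$distance_m else
      lag1(ds$distance_m)
    list(ds = ds, rows_by_day = rows_by_day, n_days = length(days),
         hb = ds$heading_b, sb = ds$step_b, val = val, bin_dist = bin_dist)
  })

  max_d <- max(vapply(prep, function(p) max(p$ds$distance_m, na.rm = TRUE),
                      numeric(1)))
  n_bins <- ceiling(max_d / bin_m)

  acc_s <- numeric(n_bins); acc_n <- numeric(n_bins)
  for (p in prep) {
    bm <- bin_metric(p$bin_dist, p$val, bin_m, n_bins)
    acc_s <- acc_s + ifelse(bm$n > 0, bm$mean * bm$n, 0)
    acc_n <- acc_n + bm$n
  }
  emp_mean <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)

  null_mat <- matrix(NA_real_, n_perm, n_bins)
  for (r in seq_len(n_perm)) {
    acc_s <- numeric(n_bins); acc_n <- numeric(n_bins)
    for (p in prep) {
      if (p$n_days < 2) next
      off <- sample.int(p$n_days - 1, 1)
      src <- ((seq_len(p$n_days) - 1 - off) %% p$n_days) + 1
      idx <- unlist(p$rows_by_day[src], use.names = FALSE)
      dist <- sqrt((p$ds$xa - p$ds$xb[idx])^2 + (p$ds$ya - p$ds$yb[idx])^2)
      val <- switch(metric,
                    heading_diff = circ_diff_deg(p$ds$heading_a, p$hb[idx]),
                    step_diff = abs(p$ds$step_a - p$sb[idx]),
                    distance = dist)
      bm <- bin_metric(if (metric == "distance") dist else lag1(dist),
                      val, bin_m, n_bins)
      acc_s <- acc_s + ifelse(bm$n > 0, bm$mean * bm$n, 0)
      acc_n <- acc_n + bm$n
    }
    null_mat[r, ] <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)
  }

  lo <- apply(null_mat, 2, stats::quantile, probs = band[1], na.rm = TRUE)
  hi <- apply(null_mat, 2, stats::quantile, probs = band[2], na.rm = TRUE)
  null_cov <- colSums(!is.na(null_mat)) / n_perm
  emp_n <- integer(n_bins)
  for (p in prep) {
    bm <- bin_metric(p$bin_dist, p$val, bin_m, n_bins)
    emp_n <- emp_n + bm$n
  }
  evaluated <- emp_n >= min_obs & !is.na(emp_mean) & null_cov >= 0.5
  if (!any(evaluated)) stop("no distance bin reaches min_obs observations")
  inside <- evaluated & emp_mean >= lo & emp_mean <= hi

  ev_idx <- which(evaluated)
  first_inside <- ev_idx[which(inside[ev_idx])[1]]
  if (is.na(first_inside)) {
    radius <- (max(ev_idx)) * bin_m
    ns_log("no evaluated bin falls inside the null band; radius set to the upper evaluated edge",
           level = "WARN")
  } else if (first_inside == ev_idx[1]) {
    radius <- 0
  } else {
    radius <- (first_inside - 1) * bin_m
  }

  structure(list(
    radius_m = radius, metric = metric, n_perm = n_perm, band = band,
    table = tibble::tibble(bin_lo = (seq_len(n_bins) - 1) * bin_m,
                           bin_hi = seq_len(n_bins) * bin_m,
                           n = emp_n, empirical = emp_mean,
                           null_lo = lo, null_hi = hi,
                           evaluated = evaluated, inside = inside)),
    class = "response_radius")
}

#' @export
print.response_radius <- function(x, ...) {
  cat(sprintf("<response_radius> %s: %.0f m (%d permutations, band %.0f-%.0f%%)\n",
              x$metric, x$radius_m, x$n_perm, 100 * x$band[1], 100 * x$band[2]))
  invisible(x)
}

#' Extract dyadic intergroup interactions
#'
#' Maximal runs of daytime timestamps with intergroup distance at most
#' `radius_m`; runs on the same day separated by less than
#' `merge_gap_min` minutes merge into one interaction, and runs never
#' span a night boundary (continuous overnight proximity counts as one
#' interaction per day). Each interaction is flagged with whether the
#' dyad shared a sleeping site on the preceding night.
#'
#' @param ds dyad series from [dyad_series()]
#' @param radius_m response radius, metres
#' @param day_window daytime clock window
#' @param merge_gap_min merge rule threshold, minutes
#' @param interval_min sampling interval (used for duration accounting)
#' @param shared_dyads optional dyad-night sharing table with columns
#'   night_date, group_a, group_b
#' @param dyad optional `c(group_a, group_b)` naming this dyad
#' @return tibble of interactions: start, end, duration_h, n_fixes,
#'   date, preceded_by_shared_night
#' @export
extract_interactions <- function(ds, radius_m,
                                 day_window = c("08:30", "17:30"),
                                 merge_gap_min = 75, interval_min = 15,
                                 shared_dyads = NULL, dyad = NULL) {
  if (radius_m <= 0) stop("radius_m must be positive")
  sel <- which(in_window(ds$timestamp, day_window) &
                 !is.na(ds$distance_m) & ds$distance_m <= radius_m)
  empty <- tibble::tibble(date = as.Date(character()),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_h = numeric(), n_fixes = integer(),
                          preceded_by_shared_night = logical())
  if (!length(sel)) return(empty)
  ts <- ds$timestamp[sel]
  day <- as.Date(ts, tz = "UTC")
  gap_min <- c(Inf, as.numeric(diff(ts), units = "mins"))
  new_run <- gap_min >= merge_gap_min | c(TRUE, day[-1] != day[-length(day)])
  run <- cumsum(new_run)
  starts <- as.vector(tapply(as.numeric(ts), run, min))
  ends <- as.vector(tapply(as.numeric(ts), run, max))
  out <- tibble::tibble(
    date = as.Date(as.POSIXct(starts, origin = "1970-01-01", tz = "UTC")),
    start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"),
    duration_h = (ends - starts) / 3600 + interval_min / 60,
    n_fixes = as.integer(table(run)))
  out$preceded_by_shared_night <- FALSE
  if (!is.null(shared_dyads) && nrow(shared_dyads) && !is.null(dyad)) {
    g <- sort(dyad)
    sh <- shared_dyads[shared_dyads$group_a == g[1] &
                         shared_dyads$group_b == g[2], ]
    out$preceded_by_shared_night <- (out$date - 1) %in% sh$night_date
  }
  out
}

#' Within-group daytime spread threshold
#'
#' Pools daytime dyadic distances between collared members of the same
#' group and returns the requested quantile; used as the distance
#' criterion for cohesive intergroup movement.
#'
#' @param member_trajectories list of trajectories (possibly several groups)
#' @param quantile_p quantile of the pooled distances
#' @param day_window daytime clock window
#' @return metres
#' @export
within_group_threshold <- function(member_trajectories, quantile_p = 0.8,
                                   day_window = c("08:30", "17:30")) {
  groups <- split(member_trajectories,
                  vapply(member_trajectories, function(tr) tr$group_id[1],
                         character(1)))
  pool <- numeric(0)
  for (g in groups) {
    if (length(g) < 2) next
    for (i in seq_along(g)) for (j in seq_along(g)) {
      if (i >= j) next
      ds <- dyad_series(g[[i]], g[[j]])
      keep <- in_window(ds$timestamp, day_window)
      pool <- c(pool, ds$distance_m[keep])
    }
  }
  pool <- pool[!is.na(pool)]
  if (!length(pool))
    stop("no multi-collar group available; configure a fallback cohesion ",
         "threshold explicitly")
  as.numeric(stats::quantile(pool, quantile_p))
}

#' Classify an interaction as cohesive movement
#'
#' Cohesive iff some contiguous run of timestamps inside the interaction
#' keeps the intergroup distance within `threshold_m` throughout while
#' either group travels at least `min_travel_m` of path length.
#'
#' @param interaction one row of [extract_interactions()] output
#' @param ds the dyad series
#' @param threshold_m within-group spread threshold, metres
#' @param min_travel_m minimum path length, metres
#' @return logical
#' @export
classify_cohesion <- function(interaction, ds, threshold_m,
                              min_travel_m = 100) {
  sel <- which(ds$timestamp >= interaction$start &
                 ds$timestamp <= interaction$end)
  if (length(sel) < 2) return(FALSE)
  ok <- !is.na(ds$distance_m[sel]) & ds$distance_m[sel] <= threshold_m
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k] || runs$lengths[k] < 2) next
    i <- sel[starts[k]:ends[k]]
    path_a <- sum(sqrt(diff(ds$xa[i])^2 + diff(ds$ya[i])^2), na.rm = TRUE)
    path_b <- sum(sqrt(diff(ds$xb[i])^2 + diff(ds$yb[i])^2), na.rm = TRUE)
    if (path_a >= min_travel_m || path_b >= min_travel_m) return(TRUE)
  }
  FALSE
}

#' Front/behind score series for a dyad
#'
#' At each step t the score is the distance of group b to the dyad
#' centroid at t+1 minus the distance of group a to that centroid:
#' positive when the first group is in front with respect to the travel
#' direction, zero when the groups are even.
#'
#' @param ds dyad series
#' @param interaction optional single interaction row restricting the series
#' @return list: `scores` tibble (timestamp, score) and `mean`
#' @export
front_behind_scores <- function(ds, interaction = NULL) {
  if (!is.null(interaction))
    ds <- ds[ds$timestamp >= interaction$start &
               ds$timestamp <= interaction$end, ]
  n <- nrow(ds)
  if (n < 2) return(list(scores = tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"), score = numeric()),
    mean = NA_real_))
  cx <- (ds$xa[-1] + ds$xb[-1]) / 2; cy <- (ds$ya[-1] + ds$yb[-1]) / 2
  i <- seq_len(n - 1)
  score <- sqrt((ds$xb[i] - cx)^2 + (ds$yb[i] - cy)^2) -
    sqrt((ds$xa[i] - cx)^2 + (ds$ya[i] - cy)^2)
  list(scores = tibble::tibble(timestamp = ds$timestamp[i], score = score),
       mean = mean(score, na.rm = TRUE))
}
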