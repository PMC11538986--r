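# Cleaning raw fixes into regular, synchronized trajectories. Every point
# carries a provenance flag: observed | interpolated | corrected | missing.

#' Regularize a fix series onto a common time grid
#'
#' Fixes are snapped to the global grid (multiples of `interval_min` since
#' midnight UTC; nearest wins within half an interval, first kept on ties),
#' gaps of at most `max_gap` grid intervals are linearly interpolated and
#' flagged, and longer gaps are left missing.
#'
#' @param fixes tibble with individual_id, group_id, timestamp, x, y for a
#'   single individual
#' @param interval_min sampling interval, minutes
#' @param max_gap longest interpolated gap, in intervals
#' @return a trajectory tibble on a strict grid with a `source` column
#' @export
regularize <- function(fixes, interval_min = 15, max_gap = 4) {
  if (nrow(fixes) < 2) stop("regularize needs at least 2 fixes")
  if (length(unique(fixes$individual_id)) != 1)
    stop("regularize works on one individual at a time")
  step <- interval_min * 60
  tnum <- as.numeric(fixes$timestamp)
  snap <- round(tnum / step) * step
  keep <- !duplicated(snap)
  fixes <- fixes[keep, ]; snap <- snap[keep]
  grid <- seq(min(snap), max(snap), by = step)
  idx <- match(grid, snap)
  x <- fixes$x[idx]; y <- fixes$y[idx]
  source <- ifelse(is.na(idx), "missing", "observed")
  gap_runs <- rle(is.na(idx))
  pos <- cumsum(c(1, gap_runs$lengths))
  for (k in seq_along(gap_runs$lengths)) {
    if (!gap_runs$values[k]) next
    i0 <- pos[k]; i1 <- pos[k] + gap_runs$lengths[k] - 1
    if (i0 == 1 || i1 == length(grid)) next        # edge gaps stay missing
    if (gap_runs$lengths[k] > max_gap) next
    w <- (grid[i0:i1] - grid[i0 - 1]) / (grid[i1 + 1] - grid[i0 - 1])
    x[i0:i1] <- x[i0 - 1] + w * (x[i1 + 1] - x[i0 - 1])
    y[i0:i1] <- y[i0 - 1] + w * (y[i1 + 1] - y[i0 - 1])
    source[i0:i1] <- "interpolated"
  }
  tibble::tibble(individual_id = fixes$individual_id[1],
                 group_id = fixes$group_id[1],
                 timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
                 x = x, y = y, source = source)
}

#' Correct anomalous GPS spikes
#'
#' A spike is an out-and-back displacement: both legs around a point imply
#' speeds above `max_speed_mps` while the bracketing points sit within one
#' interval's travel of each other. Spikes are replaced by the neighbours'
#' midpoint and flagged `corrected`. A pure speed filter would also delete
#' genuine flight responses; the pattern rule does not.
#'
#' @param traj regularized trajectory
#' @param max_speed_mps sustained-speed threshold, m/s
#' @return trajectory with spikes corrected
#' @export
correct_anomalies <- function(traj, max_speed_mps = 3) {
  n <- nrow(traj)
  if (n < 3) return(traj)
  dt <- as.numeric(diff(traj$timestamp), units = "secs")
  dx <- diff(traj$x); dy <- diff(traj$y)
  leg <- sqrt(dx^2 + dy^2)
  i <- 2:(n - 1)
  span <- sqrt((traj$x[i + 1] - traj$x[i - 1])^2 +
                 (traj$y[i + 1] - traj$y[i - 1])^2)
  lim_in <- max_speed_mps * dt[i - 1]
  lim_out <- max_speed_mps * dt[i]
  spike <- leg[i - 1] > lim_in & leg[i] > lim_out & span < pmin(lim_in, lim_out)
  spike[is.na(spike)] <- FALSE
  if (any(spike)) {
    j <- i[spike]
    traj$x[j] <- (traj$x[j - 1] + traj$x[j + 1]) / 2
    traj$y[j] <- (traj$y[j - 1] + traj$y[j + 1]) / 2
    traj$source[j] <- "corrected"
    ns_log("corrected %d anomalous fix(es)", length(j))
  }
  traj
}

#' Remove local night-time GPS jitter
#'
#' Within the night window, fixes within `jitter_radius_m` of that night's
#' median location snap to the median. Daytime fixes are never altered.
#'
#' @param traj regularized trajectory
#' @param night_window clock window, default 20:00--04:00
#' @param jitter_radius_m snap radius, metres
#' @return trajectory with night jitter removed
#' @export
remove_jitter <- function(traj, night_window = c("20:00", "04:00"),
                          jitter_radius_m = 20) {
  night <- in_window(traj$timestamp, night_window) & !is.na(traj$x)
  if (!any(night)) return(traj)
  nd <- night_date_of(traj$timestamp)
  for (d in unique(nd[night])) {
    sel <- which(night & nd == d)
    mx <- stats::median(traj$x[sel]); my <- stats::median(traj$y[sel])
    close <- sel[sqrt((traj$x[sel] - mx)^2 + (traj$y[sel] - my)^2) <=
                   jitter_radius_m]
    traj$x[close] <- mx; traj$y[close] <- my
  }
  traj
}

#' Build a group-level track from member trajectories
#'
#' At each timestamp exactly one collared member represents the group;
#' where several members have simultaneous data the member with the
#' longest total data duration wins.
#'
#' @param trajectories list of member trajectories (same group)
#' @return a single trajectory tibble; `individual_id` records the
#'   contributing member at each point
#' @export
build_group_track <- function(trajectories) {
  if (!length(trajectories)) stop("no member trajectories supplied")
  if (length(trajectories) == 1) return(trajectories[[1]])
  dur <- vapply(trajectories, function(tr) sum(!is.na(tr$x)), numeric(1))
  ord <- order(dur, decreasing = TRUE)
  out <- NULL
  for (k in ord) {
    tr <- trajectories[[k]]
    tr <- tr[!is.na(tr$x), ]
    if (is.null(out)) out <- tr
    else out <- rbind(out, tr[!(as.numeric(tr$timestamp) %in%
                                  as.numeric(out$timestamp)), ])
  }
  out[order(out$timestamp), ]
}
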