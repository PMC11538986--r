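# Day-shift permutation engine. Circularly rotating one trajectory by whole
# days destroys the temporal concurrency of a dyad while preserving each
# track's space use, daily routine and within-day structure exactly -- the
# core guarantee that the null keeps the relationship between movement
# paths and the resource/physical landscape intact.

#' Circularly shift a trajectory by whole days
#'
#' Whole-day blocks rotate forward by `offset_days`: with a 3-day track and
#' offset 1 the day order (1,2,3) becomes (3,1,2). Within-day structure is
#' untouched; timestamps are relabelled to the new day.
#'
#' @param traj trajectory tibble
#' @param offset_days integer, `1 <= offset < n_days` (a full rotation is
#'   the identity and is disallowed)
#' @return shifted trajectory
#' @export
day_shift <- function(traj, offset_days) {
  tnum <- as.numeric(traj$timestamp)
  dayn <- floor(tnum / 86400)
  days <- sort(unique(dayn))
  D <- length(days)
  if (offset_days < 1 || offset_days >= D)
    stop("offset_days must satisfy 1 <= offset < n_days (", D, ")")
  j <- match(dayn, days)
  new_day <- days[((j - 1 + offset_days) %% D) + 1]
  out <- traj
  new_t <- tnum + (new_day - dayn) * 86400
  out$timestamp <- .POSIXct(new_t, tz = "UTC")
  out[order(new_t), ]
}

new_null_distribution <- function(metric, empirical, nulls,
                                  band = c(0.05, 0.95), extra = list()) {
  nulls <- nulls[!is.na(nulls)]
  n <- length(nulls)
  q <- stats::quantile(nulls, band, names = FALSE)
  structure(c(list(
    metric = metric, empirical = empirical, null = nulls,
    n_perm = n, band = band, null_lo = q[1], null_hi = q[2],
    p_low = (1 + sum(nulls <= empirical)) / (n + 1),
    p_high = (1 + sum(nulls >= empirical)) / (n + 1),
    significant = is.finite(empirical) &&
      (empirical < q[1] || empirical > q[2]),
    abstained = FALSE), extra),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  if (isTRUE(x$abstained)) {
    cat(sprintf("<null_distribution> %s: abstained (%s)\n", x$metric,
                x$reason))
    return(invisible(x))
  }
  cat(sprintf(
    "<null_distribution> %s: empirical %.4g, null band [%.4g, %.4g] (%d perms)\n  p_low = %.4g, p_high = %.4g, %s\n",
    x$metric, x$empirical, x$null_lo, x$null_hi, x$n_perm, x$p_low, x$p_high,
    if (x$significant) "significant at the inter-quantile band" else
      "not significant"))
  invisible(x)
}

# pick which member of the dyad gets shifted: fewer tracking days
# (deterministic; ties go to b)
pick_shifted <- function(track_a, track_b) {
  da <- length(unique(as.Date(track_a$timestamp, tz = "UTC")))
  db <- length(unique(as.Date(track_b$timestamp, tz = "UTC")))
  if (da < db) "a" else "b"
}

draw_offsets <- function(n_days, n_perm) {
  if (n_days - 1 >= n_perm) sample(seq_len(n_days - 1), n_perm)
  else {
    warning("fewer distinct day offsets than permutations; sampling with replacement")
    sample(seq_len(n_days - 1), n_perm, replace = TRUE)
  }
}

#' Day-shift null distribution of a dyadic movement metric
#'
#' Applies `n_perm` random whole-day rotations to one track of the dyad
#' (the one with fewer tracking days), recomputes the metric for each
#' permuted dataset and returns the empirical value with one-sided
#' permutation p-values (add-one corrected) and the inter-quantile
#' significance band.
#'
#' @param track_a,track_b group tracks
#' @param metric_fn function(track_a, track_b) -> scalar; see
#'   [metric_mean_distance()] and friends
#' @param n_perm number of permutations (distinct offsets when possible)
#' @param band significance band quantiles
#' @param seed RNG seed
#' @return a `null_distribution`
#' @export
build_null <- function(track_a, track_b, metric_fn, n_perm = 1000,
                       band = c(0.05, 0.95), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  emp <- metric_fn(track_a, track_b)
  who <- pick_shifted(track_a, track_b)
  shifted_days <- length(unique(as.Date(
    (if (who == "a") track_a else track_b)$timestamp, tz = "UTC")))
  offs <- draw_offsets(shifted_days, n_perm)
  nulls <- vapply(offs, function(o) {
    if (who == "a") metric_fn(day_shift(track_a, o), track_b)
    else metric_fn(track_a, day_shift(track_b, o))
  }, numeric(1))
  new_null_distribution(attr(metric_fn, "metric_name") %||% "metric",
                        emp, nulls, band)
}

#' Dyadic movement metrics for permutation tests
#'
#' Factories returning `function(track_a, track_b) -> scalar`:
#' mean dyadic distance; proportion of time in association (within
#' `radius_m`); and mean intergroup distance, heading difference and
#' step-length difference while within the response radius.
#'
#' @param radius_m response radius, metres
#' @param min_step_m heading step threshold
#' @return a metric function with a `metric_name` attribute
#' @export
metric_mean_distance <- function() {
  structure(function(a, b) mean(dyad_series(a, b)$distance_m, na.rm = TRUE),
            metric_name = "mean_distance")
}

#' @rdname metric_mean_distance
#' @export
metric_association <- function(radius_m) {
  structure(function(a, b) {
    d <- dyad_series(a, b)$distance_m
    mean(d <= radius_m, na.rm = TRUE)
  }, metric_name = sprintf("association_%.0fm", radius_m))
}

#' @rdname metric_mean_distance
#' @export
metric_within_distance <- function(radius_m) {
  structure(function(a, b) {
    d <- dyad_series(a, b)$distance_m
    mean(d[d <= radius_m], na.rm = TRUE)
  }, metric_name = sprintf("within_distance_%.0fm", radius_m))
}

#' @rdname metric_mean_distance
#' @export
metric_heading_diff <- function(radius_m = Inf, min_step_m = 1) {
  structure(function(a, b) {
    ds <- dyad_series(a, b, min_step_m)
    mean(ds$heading_diff[ds$distance_m <= radius_m], na.rm = TRUE)
  }, metric_name = if (is.finite(radius_m))
    sprintf("heading_diff_%.0fm", radius_m) else "heading_diff")
}

#' @rdname metric_mean_distance
#' @export
metric_step_diff <- function(radius_m = Inf, min_step_m = 1) {
  structure(function(a, b) {
    ds <- dyad_series(a, b, min_step_m)
    mean(ds$step_diff[ds$distance_m <= radius_m], na.rm = TRUE)
  }, metric_name = if (is.finite(radius_m))
    sprintf("step_diff_%.0fm", radius_m) else "step_diff")
}

#' Sleeping-site sharing null model
#'
#' Compares the empirical proportion of co-tracked nights on which a dyad
#' shares a sleeping site with the same proportion under day-shift
#' permutations of one track. For every replicate the shifted group's
#' nightly site assignments are re-derived from its shifted coordinates
#' (nightly centroids assigned to the nearest known site).
#'
#' @param track_a,track_b group tracks
#' @param sites site table from [cluster_sites()]
#' @param night_window,min_fixes nightly-centroid parameters
#' @param assign_max_m maximum centroid-to-site assignment distance
#' @param n_perm permutations
#' @param band significance band
#' @param seed RNG seed
#' @return a `null_distribution` of the sharing proportion
#' @export
sharing_null <- function(track_a, track_b, sites,
                         night_window = c("20:00", "04:00"), min_fixes = 8,
                         assign_max_m = 500, n_perm = 1000,
                         band = c(0.05, 0.95), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assign1 <- function(tr) {
    nc <- nightly_centroids(tr, night_window, min_fixes)
    nc <- assign_to_sites(nc, sites, assign_max_m)
    stats::setNames(nc$site_id, as.character(nc$night_date))
  }
  share_prop <- function(sa, sb) {
    common <- intersect(names(sa), names(sb))
    if (!length(common)) return(NA_real_)
    mean(!is.na(sa[common]) & !is.na(sb[common]) & sa[common] == sb[common])
  }
  who <- pick_shifted(track_a, track_b)
  fixed <- assign1(if (who == "a") track_b else track_a)
  moving_track <- if (who == "a") track_a else track_b
  emp <- share_prop(assign1(moving_track), fixed)
  D <- length(unique(as.Date(moving_track$timestamp, tz = "UTC")))
  offs <- draw_offsets(D, n_perm)
  nulls <- vapply(offs, function(o)
    share_prop(assign1(day_shift(moving_track, o)), fixed), numeric(1))
  new_null_distribution("sharing_proportion", emp, nulls, band)
}

#' Site-specific post-sharing movement null model
#'
#' Null distribution of a next-day movement metric conditional on the dyad
#' having shared one specific sleeping site, built by subsetting each
#' day-shift replicate to the days following permuted sharing of that
#' site. The model abstains (no p-value) unless the permuted data contain
#' at least `min_instances` shared-night instances at the site.
#'
#' @param track_a,track_b group tracks
#' @param sites site table
#' @param site_id the sleeping site conditioned on
#' @param metric "mean_distance", "heading_diff" or "step_diff"; the latter
#'   two are restricted to timestamps within `radius_m`
#' @param radius_m response radius for the within-radius metrics
#' @param day_window daytime window over which the next-day metric runs
#' @param night_window,min_fixes,assign_max_m nightly assignment parameters
#' @param min_instances abstention threshold on permuted sharing instances
#' @param n_perm permutations
#' @param band significance band
#' @param seed RNG seed
#' @return a `null_distribution`, possibly abstained
#' @export
post_sharing_null <- function(track_a, track_b, sites, site_id,
                              metric = c("mean_distance", "heading_diff",
                                         "step_diff"),
                              radius_m = 600,
                              day_window = c("08:30", "17:30"),
                              night_window = c("20:00", "04:00"),
                              min_fixes = 8, assign_max_m = 500,
                              min_instances = 20, n_perm = 1000,
                              band = c(0.05, 0.95), seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  who <- pick_shifted(track_a, track_b)
  moving <- if (who == "a") track_a else track_b
  fixed_track <- if (who == "a") track_b else track_a

  assign1 <- function(tr) {
    nc <- nightly_centroids(tr, night_window, min_fixes)
    nc <- assign_to_sites(nc, sites, assign_max_m)
    stats::setNames(nc$site_id, as.character(nc$night_date))
  }
  fixed_sites <- assign1(fixed_track)

  next_day_metric <- function(moving_tr, moving_sites) {
    common <- intersect(names(moving_sites), names(fixed_sites))
    sharing <- common[!is.na(moving_sites[common]) &
                        !is.na(fixed_sites[common]) &
                        moving_sites[common] == site_id &
                        fixed_sites[common] == site_id]
    if (!length(sharing)) return(list(value = NA_real_, n = 0L))
    days_after <- as.Date(sharing) + 1
    ds <- dyad_series(fixed_track, moving_tr)
    keep <- as.Date(ds$timestamp, tz = "UTC") %in% days_after &
      in_window(ds$timestamp, day_window)
    ds <- ds[keep, ]
    v <- switch(metric,
                mean_distance = mean(ds$distance_m, na.rm = TRUE),
                heading_diff = mean(ds$heading_diff[ds$distance_m <= radius_m],
                                    na.rm = TRUE),
                step_diff = mean(ds$step_diff[ds$distance_m <= radius_m],
                                 na.rm = TRUE))
    list(value = v, n = length(sharing))
  }

  emp <- next_day_metric(moving, assign1(moving))
  D <- length(unique(as.Date(moving$timestamp, tz = "UTC")))
  offs <- draw_offsets(D, n_perm)
  nulls <- numeric(n_perm); inst <- integer(n_perm)
  for (r in seq_len(n_perm)) {
    sh <- day_shift(moving, offs[r])
    res <- next_day_metric(sh, assign1(sh))
    nulls[r] <- res$value; inst[r] <- res$n
  }
  total_inst <- sum(inst)
  if (total_inst < min_instances || emp$n == 0) {
    return(structure(list(
      metric = paste0("post_sharing_", metric), site_id = site_id,
      abstained = TRUE, significant = NA,
      reason = sprintf("only %d permuted sharing instance(s) at %s (need %d)%s",
                       total_inst, site_id, min_instances,
                       if (emp$n == 0) "; no empirical sharing" else ""),
      n_instances = total_inst, n_empirical = emp$n),
      class = "null_distribution"))
  }
  out <- new_null_distribution(paste0("post_sharing_", metric), emp$value,
                               nulls, band,
                               extra = list(site_id = site_id,
                                            n_instances = total_inst,
                                            n_empirical = emp$n))
  out
}
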