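# Reproducible validation experiments on simulated data with known ground
# truth. These are the package's calibration/power/recovery studies: each
# runs the relevant pipeline stage on a named scenario across replicate
# seeds and returns per-replicate results plus a summary.

# simulator fixes -> preprocessed group tracks (regularized, night-site
# jitter removed over the full site-occupancy window return->depart)
sim_group_tracks <- function(sim) {
  cfg <- sim$config
  occ <- c(cfg$return_time, cfg$depart_time)
  trajs <- lapply(split(sim$fixes, sim$fixes$individual_id), function(fx)
    remove_jitter(regularize(fx, cfg$sampling_interval_min),
                  night_window = occ))
  groups <- vapply(trajs, function(tr) tr$group_id[1], character(1))
  lapply(split(trajs, groups), build_group_track)
}

#' Type-I calibration of the day-shift attraction test
#'
#' Simulates independent group pairs (scenario "null_independent"),
#' applies the mean-dyadic-distance permutation test to each replicate
#' dataset and reports the rejection rate at the inter-quantile band --
#' nominally the band's tail mass (0.10 for the default 90% band).
#'
#' @param n_datasets replicate datasets
#' @param n_perm permutations per dataset
#' @param n_days simulated days
#' @param seed base seed
#' @return list: `rejection_rate`, logical vector `significant`
#' @export
experiment_type1_calibration <- function(n_datasets = 100, n_perm = 200,
                                         n_days = 120, seed = 1L) {
  seeds <- derive_seeds(seed, 2 * n_datasets)
  significant <- logical(n_datasets)
  for (i in seq_len(n_datasets)) {
    sim <- simulate_scenario("null_independent", seed = seeds[i],
                             n_days = n_days)
    tracks <- sim_group_tracks(sim)
    nd <- build_null(tracks[[1]], tracks[[2]], metric_mean_distance(),
                     n_perm = n_perm, seed = seeds[n_datasets + i])
    significant[i] <- nd$significant
  }
  list(rejection_rate = mean(significant), significant = significant)
}

#' Power of the attraction test under post-sharing coupling
#'
#' Scenario "attraction_after_sharing": sharing events and multi-day
#' movement coupling should push the empirical mean dyadic distance below
#' the null's lower band quantile.
#'
#' @param seeds replicate simulation seeds
#' @param n_perm permutations per replicate
#' @return list: `power` (fraction of replicates with the empirical mean
#'   distance below the lower band), per-replicate detail
#' @export
experiment_attraction_power <- function(seeds = 1:20, n_perm = 200) {
  below <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_scenario("attraction_after_sharing", seed = seeds[i])
    tracks <- sim_group_tracks(sim)
    nd <- build_null(tracks[[1]], tracks[[2]], metric_mean_distance(),
                     n_perm = n_perm, seed = seeds[i] + 7L)
    below[i] <- nd$empirical < nd$null_lo
  }
  list(power = mean(below), below = below)
}

#' Response-radius recovery and false-positive rate
#'
#' Scenario "radius_600" embeds movement coupling strictly inside a true
#' 600 m radius; recovery succeeds when the inferred radius falls within
#' `tol_m`. Scenario "null_independent" carries no coupling; the inferred
#' radius should be 0.
#'
#' @param scenario scenario name
#' @param seeds replicate seeds
#' @param n_perm permutations per replicate
#' @param tol_m recovery tolerance, metres
#' @return list: per-replicate `radius_m`, `recovery_rate` (radius_600) or
#'   `zero_rate` (null)
#' @export
experiment_radius_recovery <- function(scenario = c("radius_600",
                                                    "null_independent"),
                                       seeds = 1:20, n_perm = 200,
                                       tol_m = 100) {
  scenario <- match.arg(scenario)
  radii <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_scenario(scenario, seed = seeds[i])
    tracks <- sim_group_tracks(sim)
    rr <- infer_response_radius(list(a = tracks[[1]], b = tracks[[2]]),
                                n_perm = n_perm, seed = seeds[i] + 13L)
    radii[i] <- rr$radius_m
  }
  out <- list(radius_m = radii)
  if (scenario == "radius_600") {
    true_r <- make_scenario("radius_600")$config$response_radius_m
    out$recovery_rate <- mean(abs(radii - true_r) <= tol_m)
  } else out$zero_rate <- mean(radii == 0)
  out
}

#' Sleeping-site recovery from clustered nightly centroids
#'
#' Default study conditions (24 sites at >= 3 km minimum spacing, four
#' groups): the full chain nightly centroids -> complete-linkage
#' clustering at a 500 m cut should recover every site and assign every
#' individual-night to the correct one.
#'
#' @param seeds replicate seeds
#' @param n_days simulated days per replicate
#' @param cut_m clustering cut height
#' @return list: per-replicate `n_sites`, `accuracy`; plus summary fields
#' @export
experiment_site_recovery <- function(seeds = 1:10, n_days = 90,
                                     cut_m = 500) {
  n_sites_found <- integer(length(seeds))
  accuracy <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- sim_config(n_days = n_days)
    sim <- simulate_gps(cfg, seed = seeds[i])
    nc <- nightly_centroids(sim$fixes)
    cs <- cluster_sites(nc, cut_m = cut_m)
    n_sites_found[i] <- nrow(cs$sites)
    # map recovered sites to true sites by nearest centroid, then score
    # every individual-night assignment against the truth table
    truth_sites <- sim$truth$sites
    d2 <- outer(cs$sites$x, truth_sites$x, "-")^2 +
      outer(cs$sites$y, truth_sites$y, "-")^2
    map <- stats::setNames(truth_sites$site_id[max.col(-d2)],
                           cs$sites$site_id)
    got <- cs$nights
    key <- paste(got$individual_id, got$night_date)
    tr <- sim$truth$individual_nights
    tkey <- paste(tr$individual_id, tr$night_date)
    truth_site <- tr$site_id[match(key, tkey)]
    accuracy[i] <- mean(map[got$site_id] == truth_site, na.rm = TRUE)
  }
  list(n_sites = n_sites_found, accuracy = accuracy,
       all_recovered = all(n_sites_found ==
                             sim_config(n_days = n_days)$n_sites),
       mean_accuracy = mean(accuracy))
}

#' Calibration and power of the sleeping-site sharing null
#'
#' "independent": groups choose sites independently each night, so the
#' sharing test should reject at roughly the band's nominal rate.
#' "forced": every night is shared (p_share = 1), so the empirical sharing
#' proportion should exceed the entire null distribution.
#'
#' @param mode "independent" or "forced"
#' @param seeds replicate seeds
#' @param n_perm permutations
#' @return list: `significant` per replicate, `rate`
#' @export
experiment_sharing_null <- function(mode = c("independent", "forced"),
                                    seeds = 1:20, n_perm = 200) {
  mode <- match.arg(mode)
  significant <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    sim <- if (mode == "independent")
      simulate_scenario("null_independent", seed = seeds[i], n_days = 90)
    else simulate_scenario("attraction_after_sharing", seed = seeds[i],
                           n_days = 90, p_share = 1,
                           attraction_strength = 0)
    tracks <- sim_group_tracks(sim)
    nc <- nightly_centroids(sim$fixes)
    cs <- cluster_sites(nc, cut_m = 500)
    sh <- sharing_null(tracks[[1]], tracks[[2]], cs$sites, n_perm = n_perm,
                       seed = seeds[i] + 23L)
    significant[i] <- isTRUE(sh$significant)
  }
  list(significant = significant, rate = mean(significant))
}

#' Sleep-classifier recovery of known minute labels
#'
#' Simulates labelled nights and their accelerometry at the configured
#' noise levels, classifies minutes from the bursts alone and scores the
#' minute-level accuracy against the ground truth.
#'
#' @param seeds replicate seeds
#' @param n_nights nights per replicate
#' @param noise_mult multiplier on the sleep-state accelerometer noise
#'   (for degradation sweeps)
#' @return list: per-replicate `accuracy`, `mean_accuracy`, `min_accuracy`
#' @export
experiment_sleep_classifier <- function(seeds = 1:20, n_nights = 4,
                                        noise_mult = 1) {
  accuracy <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- sim_config(seed = seeds[i])
    cfg$accel_sd_sleep_g <- cfg$accel_sd_sleep_g * noise_mult
    nights <- tibble::tibble(
      individual_id = "A1",
      night_date = cfg$start_date + seq_len(n_nights) - 1,
      shared = FALSE)
    labels <- simulate_sleep_labels(nights, cfg, seed = seeds[i])
    bursts <- simulate_accel(labels, cfg, seed = seeds[i] + 31L)
    states <- classify_minutes(bursts)
    key <- paste(labels$individual_id, fmt_ts(labels$timestamp))
    skey <- paste(states$individual_id, fmt_ts(states$timestamp))
    pred <- states$state[match(key, skey)]
    ok <- !is.na(pred) & pred != "missing"
    accuracy[i] <- mean(pred[ok] == labels$state[ok])
  }
  list(accuracy = accuracy, mean_accuracy = mean(accuracy),
       min_accuracy = min(accuracy))
}

#' Recovery of sleep-disruption effects of shared nights
#'
#' Scenario "sleep_disruption": shared nights carry a 1.5x wake-bout
#' initiation rate. Per replicate the full chain (labels -> bursts ->
#' classifier -> per-night metrics -> effect table -> block-bootstrap
#' contrasts) is run; reported are the total-sleep-time contrast with its
#' CI and the sign of the fragmentation contrast.
#'
#' @param seeds replicate seeds
#' @param n_boot bootstrap replicates per dataset
#' @return list of per-replicate vectors: `tst_diff`, `tst_ci_lo`,
#'   `tst_ci_hi`, `frag_diff`; plus `tst_negative_rate` (CI entirely below
#'   zero) and `frag_positive_rate`
#' @export
experiment_sleep_effects <- function(seeds = 1:20, n_boot = 400) {
  n <- length(seeds)
  tst_diff <- tst_lo <- tst_hi <- frag_diff <- numeric(n)
  for (i in seq_len(n)) {
    sc <- make_scenario("sleep_disruption")
    sim <- simulate_gps(sc$config, seed = seeds[i])
    labels <- simulate_sleep_labels(sim$truth$individual_nights, sc$config,
                                    seed = seeds[i] + 41L)
    bursts <- simulate_accel(labels, sc$config, seed = seeds[i] + 43L)
    states <- classify_minutes(bursts)
    sn <- sleep_metrics(states)
    eff <- build_effect_table(sn, sim$truth$individual_nights)
    con <- summarize_sharing_effects(eff, n_boot = n_boot,
                                     seed = seeds[i] + 47L)
    tst_diff[i] <- con$difference[con$metric == "tst_min"]
    tst_lo[i] <- con$ci_lo[con$metric == "tst_min"]
    tst_hi[i] <- con$ci_hi[con$metric == "tst_min"]
    frag_diff[i] <- con$difference[con$metric == "fragmentation"]
  }
  list(tst_diff = tst_diff, tst_ci_lo = tst_lo, tst_ci_hi = tst_hi,
       frag_diff = frag_diff,
       tst_negative_rate = mean(tst_hi < 0 & tst_diff < 0),
       frag_positive_rate = mean(frag_diff > 0))
}
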