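# End-to-end orchestration: preprocess -> sites -> home ranges -> response
# radius -> interactions -> permutation nulls -> sleep, each stage writing
# its table to the output directory, with a reproducibility manifest.

#' Run the full night/day analysis pipeline
#'
#' Stages: per-individual preprocessing (regularize, correct anomalies,
#' remove night jitter), group tracks, nightly centroids and sleeping-site
#' clustering with shared-night flags, utilization distributions and
#' home-range overlap/affinity, response-radius inference, interaction
#' extraction with cohesion and front/behind characterization, the
#' attraction/avoidance and sleeping-site-choice permutation null models,
#' and (when accelerometry is supplied) sleep classification, per-night
#' metrics, synchronization and sharing contrasts. Every stage writes a
#' CSV; a JSON manifest is written last. A missing accelerometry input
#' skips the sleep stage with a log entry.
#'
#' @param gps GPS fixes: path to CSV or a fixes tibble
#' @param accel optional accelerometry: path to CSV or [accel_bursts]
#' @param out_dir output directory (created if needed)
#' @param config an [analysis_config()]
#' @param seed seed for all stochastic stages
#' @return invisibly, a list of the stage results
#' @export
run_pipeline <- function(gps, accel = NULL, out_dir, config = analysis_config(),
                         seed = config$rng_seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    ns_log("stage %s", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  fixes <- stage("read_gps",
                 if (is.character(gps)) read_gps(gps) else gps)
  bursts <- stage("read_accel", {
    if (is.character(accel)) {
      if (file.exists(accel)) read_accel(accel) else {
        ns_log("accelerometry file not found; sleep stage will be skipped",
               level = "WARN"); NULL
      }
    } else accel
  })

  trajs <- stage("preprocess", {
    lapply(split(fixes, fixes$individual_id), function(fx) {
      tr <- regularize(fx, config$sampling_interval_min,
                       config$max_gap_intervals)
      tr <- correct_anomalies(tr, config$max_speed_mps)
      remove_jitter(tr, config$night_window, config$jitter_radius_m)
    })
  })
  write_table(do.call(rbind, trajs), file.path(out_dir, "trajectories.csv"))

  group_ids <- vapply(trajs, function(tr) tr$group_id[1], character(1))
  gtracks <- stage("group_tracks", {
    lapply(split(trajs, group_ids), build_group_track)
  })
  write_table(do.call(rbind, gtracks), file.path(out_dir, "group_tracks.csv"))

  site_res <- stage("sites", {
    nc <- do.call(rbind, lapply(gtracks, nightly_centroids,
                                night_window = config$night_window,
                                min_fixes = config$min_night_fixes))
    cs <- cluster_sites(nc, config$cluster_linkage, config$cluster_cut_m)
    fl <- flag_shared_nights(cs$nights)
    list(sites = cs$sites, nights = fl$nights, dyads = fl$dyads)
  })
  write_table(site_res$sites, file.path(out_dir, "sites.csv"))
  write_table(site_res$nights, file.path(out_dir, "night_records.csv"))
  write_table(site_res$dyads, file.path(out_dir, "shared_dyads.csv"))

  hr_res <- stage("home_ranges", {
    uds <- lapply(gtracks, estimate_ud, cell_m = config$ud_cell_m)
    hrs <- lapply(uds, home_range, level = config$ud_level)
    gn <- names(gtracks)
    rows <- list()
    for (i in seq_along(gn)) for (j in seq_along(gn)) {
      if (i >= j) next
      ov <- overlap_proportion(hrs[[i]], hrs[[j]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        group_a = gn[i], group_b = gn[j],
        overlap_a_in_b = ov[["a_in_b"]], overlap_b_in_a = ov[["b_in_a"]],
        bhattacharyya = bhattacharyya_affinity(uds[[i]], uds[[j]]))
    }
    list(areas = tibble::tibble(
      group_id = gn,
      area_km2 = unname(vapply(hrs, function(h) h$area_m2 / 1e6,
                               numeric(1)))),
      overlap = do.call(rbind, rows), uds = uds)
  })
  write_table(hr_res$areas, file.path(out_dir, "home_range_areas.csv"))
  write_table(hr_res$overlap, file.path(out_dir, "home_range_overlap.csv"))
  for (g in names(hr_res$uds))
    write_ud(hr_res$uds[[g]], file.path(out_dir, sprintf("ud_%s.asc", g)))

  gn <- names(gtracks)
  dyad_pairs <- list()
  for (i in seq_along(gn)) for (j in seq_along(gn)) if (i < j)
    dyad_pairs[[length(dyad_pairs) + 1]] <-
    list(a = gtracks[[i]], b = gtracks[[j]], name = c(gn[i], gn[j]))

  rr <- stage("response_radius", {
    infer_response_radius(lapply(dyad_pairs, function(p) p[c("a", "b")]),
                          metric = "heading_diff",
                          n_perm = config$n_permutations,
                          bin_m = config$radius_bin_m,
                          band = config$null_band,
                          min_obs = config$min_bin_obs,
                          min_step_m = config$min_step_m, seed = seed)
  })
  write_table(rr$table, file.path(out_dir, "response_radius_bins.csv"))
  radius <- rr$radius_m

  interactions <- stage("interactions", {
    if (radius <= 0) {
      ns_log("response radius is 0; no interactions extracted", level = "WARN")
      NULL
    } else {
      thr <- tryCatch(within_group_threshold(trajs, config$cohesion_quantile,
                                             config$day_window),
                      error = function(e) {
                        ns_log("%s", conditionMessage(e), level = "WARN")
                        NA_real_
                      })
      rows <- list()
      for (p in dyad_pairs) {
        ds <- dyad_series(p$a, p$b, config$min_step_m)
        ints <- extract_interactions(ds, radius, config$day_window,
                                     config$merge_gap_min,
                                     config$sampling_interval_min,
                                     site_res$dyads, p$name)
        if (!nrow(ints)) next
        ints$group_a <- p$name[1]; ints$group_b <- p$name[2]
        ints$cohesive <- NA
        ints$front_behind <- NA_real_
        for (r in seq_len(nrow(ints))) {
          if (!is.na(thr))
            ints$cohesive[r] <- classify_cohesion(ints[r, ], ds, thr,
                                                  config$cohesion_min_travel_m)
          ints$front_behind[r] <- front_behind_scores(ds, ints[r, ])$mean
        }
        rows[[length(rows) + 1]] <- ints
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    }
  })
  if (!is.null(interactions))
    write_table(interactions, file.path(out_dir, "interactions.csv"))

  nulls <- stage("permutation_tests", {
    rad <- if (radius > 0) radius else config$radius_bin_m * 6
    mfs <- list(metric_mean_distance(), metric_association(rad),
                metric_within_distance(rad),
                metric_heading_diff(rad, config$min_step_m),
                metric_step_diff(rad, config$min_step_m))
    rows <- list()
    sub_seeds <- derive_seeds(seed, length(dyad_pairs) * (length(mfs) + 1))
    si <- 0
    for (p in dyad_pairs) {
      for (mf in mfs) {
        si <- si + 1
        nd <- build_null(p$a, p$b, mf, config$n_permutations,
                         config$null_band, seed = sub_seeds[si])
        rows[[length(rows) + 1]] <- tibble::tibble(
          group_a = p$name[1], group_b = p$name[2], metric = nd$metric,
          empirical = nd$empirical, null_lo = nd$null_lo,
          null_hi = nd$null_hi, p_low = nd$p_low, p_high = nd$p_high,
          significant = nd$significant)
      }
      si <- si + 1
      sh <- sharing_null(p$a, p$b, site_res$sites, config$night_window,
                         config$min_night_fixes, config$cluster_cut_m,
                         config$n_permutations, config$null_band,
                         seed = sub_seeds[si])
      rows[[length(rows) + 1]] <- tibble::tibble(
        group_a = p$name[1], group_b = p$name[2], metric = sh$metric,
        empirical = sh$empirical, null_lo = sh$null_lo, null_hi = sh$null_hi,
        p_low = sh$p_low, p_high = sh$p_high, significant = sh$significant)
    }
    do.call(rbind, rows)
  })
  write_table(nulls, file.path(out_dir, "null_tests.csv"))

  post <- stage("post_sharing_nulls", {
    rad <- if (radius > 0) radius else config$radius_bin_m * 6
    rows <- list()
    sub_seeds <- derive_seeds(seed + 2,
                              max(1, length(dyad_pairs)) * 3 *
                                max(1, nrow(site_res$sites)))
    si <- 0
    for (p in dyad_pairs) {
      g <- sort(p$name)
      shared_here <- site_res$dyads[site_res$dyads$group_a == g[1] &
                                      site_res$dyads$group_b == g[2], ]
      for (sid in unique(shared_here$site_id)) {
        for (m in c("mean_distance", "heading_diff", "step_diff")) {
          si <- si + 1
          ps <- post_sharing_null(p$a, p$b, site_res$sites, sid, metric = m,
                                  radius_m = rad,
                                  day_window = config$day_window,
                                  night_window = config$night_window,
                                  min_fixes = config$min_night_fixes,
                                  assign_max_m = config$cluster_cut_m,
                                  n_perm = config$n_permutations,
                                  band = config$null_band,
                                  seed = sub_seeds[si])
          rows[[length(rows) + 1]] <- tibble::tibble(
            group_a = g[1], group_b = g[2], site_id = sid, metric = m,
            abstained = isTRUE(ps$abstained),
            empirical = if (isTRUE(ps$abstained)) NA_real_ else ps$empirical,
            null_lo = if (isTRUE(ps$abstained)) NA_real_ else ps$null_lo,
            null_hi = if (isTRUE(ps$abstained)) NA_real_ else ps$null_hi,
            p_low = if (isTRUE(ps$abstained)) NA_real_ else ps$p_low,
            significant = if (isTRUE(ps$abstained)) NA else ps$significant)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  if (!is.null(post))
    write_table(post, file.path(out_dir, "post_sharing_tests.csv"))

  sleep_res <- NULL
  if (!is.null(bursts)) {
    sleep_res <- stage("sleep", {
      states <- classify_minutes(bursts, config$angle_threshold_deg,
                                 config$sleep_window_min)
      sn <- sleep_metrics(states, config$sleep_period, config$wake_bout_min,
                          config$sleep_window_min)
      # per-individual nightly assignments from the individual trajectories
      nr <- do.call(rbind, lapply(trajs, nightly_centroids,
                                  night_window = config$night_window,
                                  min_fixes = config$min_night_fixes))
      nr <- assign_to_sites(nr, site_res$sites, config$cluster_cut_m)
      nr <- flag_shared_nights(nr)$nights
      eff <- build_effect_table(sn, nr)
      contrasts <- if (nrow(eff) && any(eff$shared) && any(!eff$shared))
        summarize_sharing_effects(eff, n_boot = 1000,
                                  seed = derive_seeds(seed + 1, 1)) else NULL
      list(states = states, nights = sn, effect = eff, contrasts = contrasts)
    })
    write_table(sleep_res$nights, file.path(out_dir, "sleep_nights.csv"))
    write_table(sleep_res$effect, file.path(out_dir, "sleep_effect_table.csv"))
    if (!is.null(sleep_res$contrasts))
      write_table(sleep_res$contrasts,
                  file.path(out_dir, "sleep_contrasts.csv"))
  } else ns_log("no accelerometry supplied; sleep stage skipped")

  manifest <- list(
    package = "nightshare",
    version = as.character(utils::packageVersion("nightshare")),
    seed = seed,
    config = unclass(config),
    inputs = list(
      gps = if (is.character(gps)) unname(tools::md5sum(gps)) else "in-memory",
      accel = if (is.character(accel) && file.exists(accel))
        unname(tools::md5sum(accel)) else if (is.null(bursts)) "absent"
      else "in-memory"),
    rows = list(fixes = nrow(fixes), nights = nrow(site_res$nights),
                sites = nrow(site_res$sites),
                interactions = if (is.null(interactions)) 0L else
                  nrow(interactions),
                null_tests = nrow(nulls),
                sleep_nights = if (is.null(sleep_res)) 0L else
                  nrow(sleep_res$nights)),
    response_radius_m = radius)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(trajectories = trajs, group_tracks = gtracks,
                 sites = site_res, home_ranges = hr_res,
                 response_radius = rr, interactions = interactions,
                 null_tests = nulls, post_sharing = post,
                 sleep = sleep_res, manifest = manifest))
}

#' Summarize a pipeline run as text and figures
#'
#' Writes `report.txt` (null-model results with empirical value, band and
#' p-values; interaction counts split by preceding-night sharing; sleep
#' contrasts; abstentions listed as such) and schematic figures (binned
#' response-radius profile, null distributions with the empirical value,
#' sleep contrasts) into the run directory.
#'
#' @param out_dir a directory written by [run_pipeline()]
#' @return invisibly, the path of the report file
#' @export
render_report <- function(out_dir) {
  path <- function(f) file.path(out_dir, f)
  con <- file(path("report.txt"), "w")
  on.exit(close(con))
  w <- function(...) cat(sprintf(...), "\n", file = con, sep = "")

  w("nightshare run report")
  w("=====================")
  if (file.exists(path("manifest.json"))) {
    man <- jsonlite::read_json(path("manifest.json"))
    w("seed: %s   response radius: %s m", man$seed, man$response_radius_m)
  }

  if (file.exists(path("null_tests.csv"))) {
    nt <- read_table(path("null_tests.csv"))
    w("\nPermutation null models (dyadic movement and site sharing)")
    for (r in seq_len(nrow(nt)))
      w("  %s-%s %-22s empirical %10.3f  band [%.3f, %.3f]  p_low %.4f p_high %.4f %s",
        nt$group_a[r], nt$group_b[r], nt$metric[r], nt$empirical[r],
        nt$null_lo[r], nt$null_hi[r], nt$p_low[r], nt$p_high[r],
        ifelse(nt$significant[r], "*", ""))
  }

  if (file.exists(path("post_sharing_tests.csv"))) {
    ps <- read_table(path("post_sharing_tests.csv"))
    w("\nSite-specific post-sharing null models")
    for (r in seq_len(nrow(ps))) {
      if (ps$abstained[r])
        w("  %s-%s %s %-14s abstained (too few permuted sharing instances)",
          ps$group_a[r], ps$group_b[r], ps$site_id[r], ps$metric[r])
      else
        w("  %s-%s %s %-14s empirical %10.3f  band [%.3f, %.3f] %s",
          ps$group_a[r], ps$group_b[r], ps$site_id[r], ps$metric[r],
          ps$empirical[r], ps$null_lo[r], ps$null_hi[r],
          ifelse(isTRUE(ps$significant[r]), "*", ""))
    }
  }

  if (file.exists(path("interactions.csv"))) {
    ints <- read_table(path("interactions.csv"))
    w("\nInteractions: %d total; %d on days after a shared night; %d cohesive",
      nrow(ints), sum(ints$preceded_by_shared_night),
      sum(ints$cohesive, na.rm = TRUE))
    w("  mean duration %.2f h (after sharing %.2f h, otherwise %.2f h)",
      mean(ints$duration_h),
      mean(ints$duration_h[ints$preceded_by_shared_night]),
      mean(ints$duration_h[!ints$preceded_by_shared_night]))
  } else w("\nInteractions: none extracted")

  if (file.exists(path("sleep_contrasts.csv"))) {
    sc <- read_table(path("sleep_contrasts.csv"))
    w("\nSleep contrasts (shared - unshared nights)")
    for (r in seq_len(nrow(sc)))
      w("  %-14s %8.3f  [%8.3f, %8.3f]", sc$metric[r], sc$difference[r],
        sc$ci_lo[r], sc$ci_hi[r])
  }

  # figures
  if (file.exists(path("response_radius_bins.csv"))) {
    tb <- read_table(path("response_radius_bins.csv"))
    tb <- tb[tb$evaluated, ]
    if (nrow(tb)) {
      g <- ggplot2::ggplot(tb, ggplot2::aes(x = (bin_lo + bin_hi) / 2)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = null_lo, ymax = null_hi),
                             fill = "grey70", alpha = 0.6) +
        ggplot2::geom_line(ggplot2::aes(y = empirical), colour = "darkorange") +
        ggplot2::labs(x = "intergroup distance (m)",
                      y = "mean heading difference (deg)",
                      title = "Empirical coordination vs null band by distance bin") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(path("fig_response_radius.pdf"), g, width = 7,
                      height = 4)
    }
  }
  if (file.exists(path("null_tests.csv"))) {
    nt <- read_table(path("null_tests.csv"))
    nt$dyad <- paste(nt$group_a, nt$group_b, sep = "-")
    g <- ggplot2::ggplot(nt, ggplot2::aes(x = metric)) +
      ggplot2::geom_linerange(ggplot2::aes(ymin = null_lo, ymax = null_hi),
                              colour = "grey50", linewidth = 2) +
      ggplot2::geom_point(ggplot2::aes(y = empirical), colour = "darkorange",
                          size = 2) +
      ggplot2::facet_wrap(~dyad, scales = "free_y") +
      ggplot2::coord_flip() + ggplot2::theme_minimal() +
      ggplot2::labs(y = "metric value (empirical point vs null band)",
                    x = NULL)
    ggplot2::ggsave(path("fig_null_tests.pdf"), g, width = 8, height = 5)
  }
  invisible(path("report.txt"))
}
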