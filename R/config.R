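#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults follow the conventions of multi-group baboon tracking studies:
#' 15-min GPS fixes, nightly centroids over 20:00--04:00, a fixed sleep
#' period of 21:00--05:00, a daytime window of 08:30--17:30 (median
#' departure/arrival times at sleeping sites), a 75-min gap rule for
#' merging interactions, a 100 m minimum travel and the 80% quantile of
#' within-group daytime spread for cohesive movement, 1000 day-shift
#' permutations with a 90% inter-quantile significance band, and 100 m
#' distance bins for response-radius inference.
#'
#' @param sampling_interval_min GPS sampling interval, minutes.
#' @param night_window clock window used for nightly centroids.
#' @param sleep_period clock window over which sleep metrics are computed.
#' @param day_window daytime window for interactions and cohesion.
#' @param merge_gap_min interactions closer than this many minutes merge.
#' @param cohesion_min_travel_m minimum travel for cohesive movement, m.
#' @param cohesion_quantile quantile of within-group daytime distances used
#'   as the cohesion distance threshold.
#' @param n_permutations day-shift permutations per null model.
#' @param null_band lower/upper quantiles of the null significance band.
#' @param radius_bin_m distance bin width for response-radius inference, m.
#' @param min_bin_obs minimum observations for a distance bin to be scored.
#' @param ud_level utilization-distribution mass defining the home range.
#' @param ud_cell_m home-range grid cell size, m.
#' @param wake_bout_min minimum wake-bout length counted by fragmentation.
#' @param angle_threshold_deg posture-angle change below which successive
#'   minutes count as stable (sleep classifier), degrees.
#' @param sleep_window_min minimum run of stable minutes labelled sleep.
#' @param cluster_cut_m tree cut height for sleeping-site clustering, m.
#' @param cluster_linkage hclust linkage for sleeping-site clustering.
#' @param min_night_fixes minimum night fixes for a usable nightly centroid.
#' @param max_gap_intervals longest gap (in sampling intervals) that is
#'   linearly interpolated during regularization.
#' @param max_speed_mps sustained speed marking an anomalous GPS spike, m/s.
#' @param jitter_radius_m night fixes within this distance of the nightly
#'   median are snapped to it, m.
#' @param min_step_m steps shorter than this leave the heading undefined, m.
#' @param rng_seed default seed for stochastic stages.
#' @return a validated list of class `analysis_config`
#' @export
analysis_config <- function(sampling_interval_min = 15,
                            night_window = c("20:00", "04:00"),
                            sleep_period = c("21:00", "05:00"),
                            day_window = c("08:30", "17:30"),
                            merge_gap_min = 75,
                            cohesion_min_travel_m = 100,
                            cohesion_quantile = 0.80,
                            n_permutations = 1000,
                            null_band = c(0.05, 0.95),
                            radius_bin_m = 100,
                            min_bin_obs = 50,
                            ud_level = 0.95,
                            ud_cell_m = 50,
                            wake_bout_min = 2,
                            angle_threshold_deg = 5,
                            sleep_window_min = 5,
                            cluster_cut_m = 500,
                            cluster_linkage = "complete",
                            min_night_fixes = 8,
                            max_gap_intervals = 4,
                            max_speed_mps = 3,
                            jitter_radius_m = 20,
                            min_step_m = 1,
                            rng_seed = 1L) {
  cfg <- list(sampling_interval_min = sampling_interval_min,
              night_window = night_window, sleep_period = sleep_period,
              day_window = day_window, merge_gap_min = merge_gap_min,
              cohesion_min_travel_m = cohesion_min_travel_m,
              cohesion_quantile = cohesion_quantile,
              n_permutations = n_permutations, null_band = null_band,
              radius_bin_m = radius_bin_m, min_bin_obs = min_bin_obs,
              ud_level = ud_level, ud_cell_m = ud_cell_m,
              wake_bout_min = wake_bout_min,
              angle_threshold_deg = angle_threshold_deg,
              sleep_window_min = sleep_window_min,
              cluster_cut_m = cluster_cut_m,
              cluster_linkage = cluster_linkage,
              min_night_fixes = min_night_fixes,
              max_gap_intervals = max_gap_intervals,
              max_speed_mps = max_speed_mps,
              jitter_radius_m = jitter_radius_m,
              min_step_m = min_step_m,
              rng_seed = as.integer(rng_seed))
  pos <- c("sampling_interval_min", "merge_gap_min", "cohesion_min_travel_m",
           "n_permutations", "radius_bin_m", "min_bin_obs", "ud_cell_m",
           "wake_bout_min", "angle_threshold_deg", "sleep_window_min",
           "cluster_cut_m", "min_night_fixes", "max_gap_intervals",
           "max_speed_mps", "jitter_radius_m")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || cfg[[p]] <= 0)
      stop("config value '", p, "' must be a single positive number")
  }
  if (cfg$cohesion_quantile <= 0 || cfg$cohesion_quantile > 1)
    stop("cohesion_quantile must lie in (0, 1]")
  if (cfg$ud_level <= 0 || cfg$ud_level > 1)
    stop("ud_level must lie in (0, 1]")
  if (length(cfg$null_band) != 2 || any(cfg$null_band <= 0) ||
      any(cfg$null_band >= 1) || diff(cfg$null_band) <= 0)
    stop("null_band must be increasing quantiles inside (0, 1)")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}

#' Write / read a configuration as a flat key=value text file
#'
#' Vector-valued entries are comma-joined. `read_config()` overlays the
#' file on the package defaults, so partial files are accepted.
#'
#' @param config an `analysis_config`
#' @param path file path
#' @return `read_config` returns an `analysis_config`
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    paste0(nm, "=", paste(config[[nm]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  defaults <- analysis_config()
  args <- list()
  for (p in kv) {
    key <- trimws(p[1])
    if (!key %in% names(defaults)) {
      ns_log("ignoring unknown config key '%s'", key, level = "WARN")
      next
    }
    val <- strsplit(trimws(paste(p[-1], collapse = "=")), ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (all(!is.na(num))) num else val
  }
  do.call(analysis_config, args)
}
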