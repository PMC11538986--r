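# Sleeping sites: nightly centroids -> hierarchical agglomerative
# clustering -> per-night site assignment and shared-night flags.

#' Nightly centroids of an individual's GPS fixes
#'
#' One record per night with at least `min_fixes` usable fixes inside the
#' night window (default 20:00--04:00); the centroid is the arithmetic
#' mean of the available fixes and the night is dated by the evening on
#' which it starts.
#'
#' @param traj trajectory tibble (one or more individuals)
#' @param night_window clock window
#' @param min_fixes minimum usable fixes per night
#' @return tibble: individual_id, group_id, night_date, x, y, n_fixes
#' @export
nightly_centroids <- function(traj, night_window = c("20:00", "04:00"),
                              min_fixes = 8) {
  sel <- in_window(traj$timestamp, night_window) & !is.na(traj$x)
  if (!any(sel)) return(tibble::tibble(
    individual_id = character(), group_id = character(),
    night_date = as.Date(character()), x = numeric(), y = numeric(),
    n_fixes = integer()))
  tr <- traj[sel, ]
  nd <- night_date_of(tr$timestamp)
  key <- paste(tr$individual_id, nd)
  ag <- rowsum(cbind(x = tr$x, y = tr$y, n = 1), key)
  first <- !duplicated(key)
  lk <- stats::setNames(seq_len(sum(first)), key[first])
  ord <- match(rownames(ag), key[first])
  out <- tibble::tibble(individual_id = tr$individual_id[first][ord],
                        group_id = tr$group_id[first][ord],
                        night_date = nd[first][ord],
                        x = ag[, "x"] / ag[, "n"],
                        y = ag[, "y"] / ag[, "n"],
                        n_fixes = as.integer(ag[, "n"]))
  skipped <- sum(out$n_fixes < min_fixes)
  if (skipped) ns_log("skipped %d sparse night(s) (< %d fixes)", skipped,
                      min_fixes)
  out <- out[out$n_fixes >= min_fixes, ]
  out[order(out$individual_id, out$night_date), ]
}

#' Cluster nightly centroids into sleeping sites
#'
#' Hierarchical agglomerative clustering (complete linkage by default,
#' which bounds the within-site diameter) on Euclidean distances between
#' nightly centroids; the tree is cut at height `cut_m`. Site labels are
#' ordered by site centroid coordinates, so the result is invariant to
#' input order.
#'
#' @param night_records output of [nightly_centroids()]
#' @param linkage hclust linkage criterion
#' @param cut_m tree cut height, metres
#' @return list: `sites` (site_id, x, y, n_nights, n_groups) and `nights`
#'   (the input records with a `site_id` column)
#' @export
cluster_sites <- function(night_records, linkage = "complete", cut_m = 500) {
  if (cut_m <= 0) stop("cut_m must be positive")
  n <- nrow(night_records)
  if (n < 2) stop("need at least 2 night records to cluster")
  hc <- stats::hclust(stats::dist(cbind(night_records$x, night_records$y)),
                      method = linkage)
  cl <- stats::cutree(hc, h = cut_m)
  cx <- tapply(night_records$x, cl, mean)
  cy <- tapply(night_records$y, cl, mean)
  ord <- order(cx, cy)
  relabel <- stats::setNames(seq_along(ord), names(cx)[ord])
  site_idx <- relabel[as.character(cl)]
  night_records$site_id <- sprintf("S%02d", site_idx)
  sites <- tibble::tibble(
    site_id = sprintf("S%02d", seq_along(ord)),
    x = as.numeric(cx[ord]), y = as.numeric(cy[ord]),
    n_nights = as.integer(table(site_idx)[as.character(seq_along(ord))]),
    n_groups = vapply(seq_along(ord), function(s)
      length(unique(night_records$group_id[site_idx == s])), integer(1)))
  list(sites = sites, nights = night_records)
}

#' Assign nightly centroids to existing sites
#'
#' Nearest-site assignment used when re-deriving site use from permuted
#' trajectories: each centroid maps to the closest site centroid within
#' `max_dist_m` (NA beyond it).
#'
#' @param night_records tibble with x, y columns
#' @param sites site table from [cluster_sites()]
#' @param max_dist_m maximum assignment distance
#' @return the records with a `site_id` column
#' @export
assign_to_sites <- function(night_records, sites, max_dist_m = 500) {
  if (!nrow(night_records)) {
    night_records$site_id <- character(0)
    return(night_records)
  }
  d2 <- outer(night_records$x, sites$x, "-")^2 +
    outer(night_records$y, sites$y, "-")^2
  j <- max.col(-d2)
  dmin <- sqrt(d2[cbind(seq_len(nrow(night_records)), j)])
  night_records$site_id <- ifelse(dmin <= max_dist_m, sites$site_id[j],
                                  NA_character_)
  night_records
}

#' Flag shared nights and build the dyad-night sharing table
#'
#' A night is shared when two or more distinct groups are assigned to the
#' same site on the same night date.
#'
#' @param assigned_nights night records carrying `site_id` (and `group_id`)
#' @return list: `nights` (records with a `shared` flag) and `dyads`
#'   (night_date, site_id, group_a, group_b with group_a < group_b)
#' @export
flag_shared_nights <- function(assigned_nights) {
  nr <- assigned_nights
  key <- paste(nr$night_date, nr$site_id)
  ngroups <- tapply(nr$group_id, key, function(g) length(unique(g)))
  nr$shared <- !is.na(nr$site_id) & as.vector(ngroups[key]) >= 2
  dyads <- list()
  for (k in names(ngroups)[ngroups >= 2]) {
    sel <- nr[key == k & !is.na(nr$site_id), ]
    gs <- sort(unique(sel$group_id))
    for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j)
      dyads[[length(dyads) + 1]] <- data.frame(
        night_date = sel$night_date[1], site_id = sel$site_id[1],
        group_a = gs[i], group_b = gs[j])
  }
  dyads <- if (length(dyads)) tibble::as_tibble(do.call(rbind, dyads)) else
    tibble::tibble(night_date = as.Date(character()), site_id = character(),
                   group_a = character(), group_b = character())
  list(nights = nr, dyads = dyads)
}
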