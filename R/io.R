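# Readers and writers for the pipeline's CSV dialects. All analysis runs in
# planar metres; lon/lat inputs are projected on read with a local
# tangent-plane projection centred on the data.

#' Read Movebank-style GPS fixes
#'
#' Expects columns `individual_id`, `group_id`, `timestamp` and either
#' projected `x`, `y` (metres) or geographic `lon`, `lat` (degrees).
#' Unknown columns are ignored. Fixes are sorted by individual and
#' timestamp and duplicates on (individual, timestamp) collapse to the
#' first occurrence.
#'
#' @param path CSV file path.
#' @param projection optional `c(lon0, lat0)` origin for the local
#'   projection; defaults to the median fix location.
#' @return tibble of fixes with columns individual_id, group_id,
#'   timestamp (POSIXct, UTC-stored local clock), x, y. The projection
#'   origin, when used, is attached as attribute `"projection_origin"`.
#' @export
read_gps <- function(path, projection = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "group_id", "timestamp")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("GPS file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  has_xy <- all(c("x", "y") %in% names(df))
  has_ll <- all(c("lon", "lat") %in% names(df))
  if (!has_xy && !has_ll)
    stop("GPS file is missing required column(s): x,y or lon,lat")

  ts <- suppressWarnings(parse_ts(df$timestamp))
  bad <- which(is.na(ts) & !is.na(df$timestamp) & nzchar(df$timestamp))
  if (length(bad))
    stop("unparseable timestamp(s) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")

  if (has_xy) {
    x <- as.numeric(df$x); y <- as.numeric(df$y)
    origin <- NULL
  } else {
    pr <- project_lonlat(as.numeric(df$lon), as.numeric(df$lat), projection)
    x <- pr$x; y <- pr$y; origin <- pr$origin
  }
  out <- tibble::tibble(individual_id = as.character(df$individual_id),
                        group_id = as.character(df$group_id),
                        timestamp = ts, x = x, y = y)
  out <- out[order(out$individual_id, out$timestamp), ]
  dup <- duplicated(out[c("individual_id", "timestamp")])
  if (any(dup))
    ns_log("dropped %d duplicate fix(es) on (individual, timestamp)", sum(dup))
  out <- out[!dup, ]
  if (!is.null(origin)) attr(out, "projection_origin") <- origin
  out
}

#' Write GPS fixes
#' @param fixes tibble as returned by [read_gps()] or [simulate_gps()]
#' @param path output CSV path
#' @export
write_gps <- function(fixes, path) {
  df <- as.data.frame(fixes)
  df$timestamp <- fmt_ts(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tri-axial accelerometer bursts
#'
#' Container for one-burst-per-minute tri-axial accelerometry: a metadata
#' table plus three aligned sample matrices (rows = bursts). Units are g;
#' the nominal burst geometry is ~3 s of samples at 10.54 Hz per axis.
#'
#' @param individual_id,timestamp per-burst metadata vectors
#' @param ax,ay,az numeric matrices, one row per burst
#' @param hz sample rate metadata
#' @return object of class `accel_bursts`
#' @export
accel_bursts <- function(individual_id, timestamp, ax, ay, az, hz = 10.54) {
  ax <- as.matrix(ax); ay <- as.matrix(ay); az <- as.matrix(az)
  n <- length(individual_id)
  stopifnot(length(timestamp) == n, nrow(ax) == n,
            all(dim(ax) == dim(ay)), all(dim(ay) == dim(az)))
  structure(list(info = tibble::tibble(individual_id = as.character(individual_id),
                                       timestamp = as.POSIXct(timestamp, tz = "UTC")),
                 ax = ax, ay = ay, az = az, hz = hz),
            class = "accel_bursts")
}

#' @export
print.accel_bursts <- function(x, ...) {
  cat(sprintf("<accel_bursts> %d bursts x %d samples, %d individual(s), %.2f Hz\n",
              nrow(x$info), ncol(x$ax),
              length(unique(x$info$individual_id)), x$hz))
  invisible(x)
}

#' @export
length.accel_bursts <- function(x) nrow(x$info)

#' Read accelerometer bursts from long-format CSV
#'
#' Expects columns `individual_id`, `timestamp`, `sample_idx`, `ax`,
#' `ay`, `az`: one row per sample, one burst per (individual, timestamp).
#' Bursts whose axes have unequal numbers of usable (non-missing) samples
#' are rejected; the rejection count is logged.
#'
#' @param path CSV file path
#' @param hz sample-rate metadata stored on the result
#' @return an [accel_bursts] object
#' @export
read_accel <- function(path, hz = 10.54) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "timestamp", "sample_idx", "ax", "ay", "az")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("accelerometry file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ts <- suppressWarnings(parse_ts(df$timestamp))
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp(s) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(df$individual_id, fmt_ts(ts))
  ord <- order(key, df$sample_idx)
  df <- df[ord, ]
  key <- key[ord]

  ok_counts <- function(v) tapply(!is.na(v), key, sum)
  ca <- ok_counts(df$ax); cb <- ok_counts(df$ay); cc <- ok_counts(df$az)
  bad_burst <- names(ca)[ca != cb | cb != cc]
  if (length(bad_burst))
    ns_log("rejected %d burst(s) with axis-length mismatch", length(bad_burst),
           level = "WARN")
  keep <- !(key %in% bad_burst)
  df <- df[keep, ]; key <- key[keep]
  if (!nrow(df)) stop("no usable bursts in ", path)

  splits <- split(seq_len(nrow(df)), key)
  ids <- unname(vapply(splits, function(i) df$individual_id[i[1]],
                       character(1)))
  tss <- unname(vapply(splits, function(i)
    as.numeric(parse_ts(df$timestamp[i[1]])), numeric(1)))
  len <- max(lengths(splits))
  grab <- function(col) unname(t(vapply(splits, function(i) {
    v <- df[[col]][i]; length(v) <- len; v
  }, numeric(len))))
  out <- accel_bursts(ids, as.POSIXct(tss, origin = "1970-01-01", tz = "UTC"),
                      grab("ax"), grab("ay"), grab("az"), hz = hz)
  ord <- order(out$info$individual_id, out$info$timestamp)
  out$info <- out$info[ord, ]
  out$ax <- out$ax[ord, , drop = FALSE]
  out$ay <- out$ay[ord, , drop = FALSE]
  out$az <- out$az[ord, , drop = FALSE]
  out
}

#' Write accelerometer bursts to long-format CSV
#' @param bursts an [accel_bursts] object
#' @param path output CSV path
#' @export
write_accel <- function(bursts, path) {
  n <- nrow(bursts$info); len <- ncol(bursts$ax)
  df <- data.frame(individual_id = rep(bursts$info$individual_id, each = len),
                   timestamp = rep(fmt_ts(bursts$info$timestamp), each = len),
                   sample_idx = rep(seq_len(len), times = n),
                   ax = as.vector(t(bursts$ax)),
                   ay = as.vector(t(bursts$ay)),
                   az = as.vector(t(bursts$az)))
  df <- df[!is.na(df$ax) | !is.na(df$ay) | !is.na(df$az), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read intermediate tables with stable formatting
#'
#' Columns keep their order; POSIXct columns are written as ISO-8601 UTC
#' and Date columns as `YYYY-MM-DD`, so that `read_table()` restores the
#' records field-by-field. Timestamp-like columns are recognized by name
#' (`timestamp`, `start`, `end`, `onset`, `offset`) and date-like columns
#' by the suffix `date`.
#'
#' @param x data frame
#' @param path CSV path
#' @return `read_table` returns a tibble
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- fmt_ts(df[[nm]])
    if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts_cols <- intersect(c("timestamp", "start", "end", "onset", "offset"), names(df))
  for (nm in ts_cols) df[[nm]] <- parse_ts(df[[nm]])
  for (nm in grep("date$", names(df), value = TRUE)) df[[nm]] <- as.Date(df[[nm]])
  tibble::as_tibble(df)
}
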