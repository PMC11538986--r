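# Small shared helpers: clock-time windows, circular angles, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an "HH:MM" string to decimal hours
#' @param x character like "08:30"
#' @return numeric hours in [0, 24)
#' @keywords internal
parse_hm <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(q) as.numeric(q[1]) + as.numeric(q[2]) / 60, numeric(1))
}

# decimal hour-of-day of a POSIXct (UTC-stored local clock time)
tod_hours <- function(ts) {
  (as.numeric(ts) %% 86400) / 3600
}

#' Test whether clock times fall inside a daily window
#'
#' Windows that wrap midnight (e.g. 20:00--04:00) are treated as
#' `[start, end)`; non-wrapping windows (e.g. 08:30--17:30) are closed.
#'
#' @param tod numeric decimal hours, or POSIXct
#' @param window length-2 window, "HH:MM" strings or decimal hours
#' @return logical vector
#' @export
in_window <- function(tod, window) {
  if (inherits(tod, "POSIXct")) tod <- tod_hours(tod)
  w <- parse_hm(window)
  if (w[1] <= w[2]) tod >= w[1] & tod <= w[2] else tod >= w[1] | tod < w[2]
}

# date a night belongs to: evening hours keep their date, small hours
# roll back to the previous date (split at noon)
night_date_of <- function(ts) {
  tnum <- as.numeric(ts)
  as.Date(floor(tnum / 86400) - ((tnum %% 86400) / 3600 < 12),
          origin = "1970-01-01")
}

# lightweight tibble constructor for hot paths (columns must be equal length)
fast_tbl <- function(...) {
  l <- list(...)
  structure(l, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(length(l[[1]])))
}

# absolute circular difference of two heading vectors, folded to [0, 180]
circ_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# heading of displacement (dx, dy): degrees, 0 = east, counterclockwise
heading_deg <- function(dx, dy) atan2(dy, dx) * 180 / pi

fmt_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  y <- gsub("T", " ", as.character(x), fixed = TRUE)
  y <- sub("Z$", "", y)
  out <- .POSIXct(rep(NA_real_, length(y)), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(y[idx], fmt, tz = "UTC"))
  }
  out
}

#' Lightweight stderr logger
#'
#' Messages go to stderr; set `options(nightshare.log_file = path)` to also
#' append them to a file, and `options(nightshare.quiet = TRUE)` to silence
#' stderr output.
#'
#' @param fmt sprintf-style format
#' @param ... substitutions
#' @param level one of "INFO", "WARN", "ERROR"
#' @return invisibly, the formatted line
#' @export
ns_log <- function(fmt, ..., level = "INFO") {
  line <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  if (!isTRUE(getOption("nightshare.quiet"))) message(line)
  lf <- getOption("nightshare.log_file")
  if (!is.null(lf)) cat(line, "\n", file = lf, append = TRUE, sep = "")
  invisible(line)
}

# local tangent-plane (equirectangular) projection; adequate at the
# tens-of-km scale of a single study landscape
project_lonlat <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(stats::median(lon), stats::median(lat))
  r <- 6378137
  x <- r * cos(origin[2] * pi / 180) * (lon - origin[1]) * pi / 180
  y <- r * (lat - origin[2]) * pi / 180
  list(x = x, y = y, origin = origin)
}

# deterministic sub-seeds below 2^31 derived from a base seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
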