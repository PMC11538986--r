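# Utilization distributions on cell-aligned grids. Grids are anchored to
# multiples of the cell size, so UDs and home ranges of different groups
# share a common cell lattice and intersect exactly.

href_bandwidth <- function(x, y) {
  n <- length(x)
  sqrt(0.5 * (stats::var(x) + stats::var(y))) * n^(-1 / 6)
}

#' Estimate a utilization distribution by kernel density
#'
#' Gaussian-kernel UD on a regular grid padded at least three bandwidths
#' beyond the data extent; the result holds cell-integrated probability
#' mass normalized to 1. The default bandwidth is the bivariate-normal
#' reference ("href") rule.
#'
#' @param track trajectory tibble (x, y used; missing points dropped)
#' @param bandwidth kernel standard deviation in metres; default href
#' @param cell_m grid cell size, metres
#' @param pad_bw padding beyond the data extent, in bandwidths
#' @return object of class `ud`: cell-centre coordinate vectors `x`, `y`,
#'   mass matrix `z` (rows follow `x`), `cell`, `h`
#' @export
estimate_ud <- function(track, bandwidth = NULL, cell_m = 50, pad_bw = 3) {
  ok <- !is.na(track$x) & !is.na(track$y)
  x <- track$x[ok]; y <- track$y[ok]
  if (length(x) < 30) stop("need at least 30 locations for a UD")
  h <- bandwidth %||% href_bandwidth(x, y)
  if (!is.finite(h) || h <= 0)
    stop("degenerate locations (all identical?); supply a minimum bandwidth")
  pad <- pad_bw * h
  x0 <- floor((min(x) - pad) / cell_m) * cell_m
  x1 <- ceiling((max(x) + pad) / cell_m) * cell_m
  y0 <- floor((min(y) - pad) / cell_m) * cell_m
  y1 <- ceiling((max(y) + pad) / cell_m) * cell_m
  nx <- round((x1 - x0) / cell_m); ny <- round((y1 - y0) / cell_m)
  # MASS::kde2d uses a kernel sd of h/4
  kd <- MASS::kde2d(x, y, h = 4 * h, n = c(nx, ny),
                    lims = c(x0 + cell_m / 2, x1 - cell_m / 2,
                             y0 + cell_m / 2, y1 - cell_m / 2))
  z <- kd$z * cell_m^2
  z <- z / sum(z)
  structure(list(x = kd$x, y = kd$y, z = z, cell = cell_m, h = h),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("<ud> %d x %d cells of %.0f m, bandwidth %.1f m\n",
              length(x$x), length(x$y), x$cell, x$h))
  invisible(x)
}

# integer lattice keys of a ud's cells (global, cell-aligned)
ud_keys <- function(ud) {
  ix <- round(ud$x / ud$cell - 0.5)
  iy <- round(ud$y / ud$cell - 0.5)
  list(ix = rep(ix, times = length(iy)), iy = rep(iy, each = length(ix)),
       mass = as.vector(ud$z))
}

#' Home range as the highest-density cell set
#'
#' The smallest set of highest-density cells whose cumulative mass reaches
#' `level`; the area is the cell count times the cell area.
#'
#' @param ud a [estimate_ud()] result
#' @param level probability mass to enclose
#' @return object of class `home_range`: tibble `cells` (cell centres and
#'   lattice keys), `area_m2`, `level`, `cell`
#' @export
home_range <- function(ud, level = 0.95) {
  k <- ud_keys(ud)
  ord <- order(k$mass, decreasing = TRUE)
  cs <- cumsum(k$mass[ord])
  ncell <- which(cs >= level - 1e-12)[1]
  sel <- ord[seq_len(ncell)]
  sel <- sel[k$mass[sel] > 0]
  structure(list(cells = tibble::tibble(
    ix = k$ix[sel], iy = k$iy[sel],
    x = (k$ix[sel] + 0.5) * ud$cell, y = (k$iy[sel] + 0.5) * ud$cell,
    mass = k$mass[sel]),
    area_m2 = length(sel) * ud$cell^2, level = level, cell = ud$cell),
    class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("<home_range> %.0f%% level, %.2f km2 (%d cells of %.0f m)\n",
              100 * x$level, x$area_m2 / 1e6, nrow(x$cells), x$cell))
  invisible(x)
}

#' Directed home-range overlap proportions
#'
#' @param hr_a,hr_b [home_range()] objects on the same cell size
#' @return named vector: `a_in_b` = shared area / area of a, and `b_in_a`
#' @export
overlap_proportion <- function(hr_a, hr_b) {
  if (hr_a$cell != hr_b$cell)
    stop("home ranges must share a cell size for overlap")
  ka <- paste(hr_a$cells$ix, hr_a$cells$iy)
  kb <- paste(hr_b$cells$ix, hr_b$cells$iy)
  inter <- length(intersect(ka, kb))
  c(a_in_b = inter / length(ka), b_in_a = inter / length(kb))
}

#' Bhattacharyya's affinity between two utilization distributions
#'
#' BA = sum over cells of sqrt(p_a * p_b), in [0, 1]; 1 for identical
#' distributions, 0 for disjoint supports. UDs with different cell sizes
#' are regridded (coarse cells subdivided with uniform mass) with a
#' warning; the cell-size ratio must be an integer.
#'
#' @param ud_a,ud_b [estimate_ud()] results (cell-aligned grids)
#' @return scalar affinity
#' @export
bhattacharyya_affinity <- function(ud_a, ud_b) {
  ka <- ud_keys(ud_a); kb <- ud_keys(ud_b)
  if (ud_a$cell != ud_b$cell) {
    warning("UD grids differ in cell size; regridding to the finer grid")
    if (ud_a$cell > ud_b$cell) ka <- subdivide_keys(ka, ud_a$cell, ud_b$cell)
    else kb <- subdivide_keys(kb, ud_b$cell, ud_a$cell)
  }
  a <- stats::setNames(ka$mass, paste(ka$ix, ka$iy))
  b <- stats::setNames(kb$mass, paste(kb$ix, kb$iy))
  common <- intersect(names(a)[a > 0], names(b)[b > 0])
  sum(sqrt(a[common] * b[common]))
}

#' Write / read a utilization distribution as an ESRI-ASCII-style grid
#'
#' Plain-text raster: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of cell mass from
#' the northern edge down.
#'
#' @param ud a [estimate_ud()] result
#' @param path output path
#' @return `read_ud` returns a `ud` object
#' @export
write_ud <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nx <- length(ud$x); ny <- length(ud$y)
  cat(sprintf("ncols %d\nnrows %d\nxllcorner %.6f\nyllcorner %.6f\ncellsize %.6f\nNODATA_value -9999\n",
              nx, ny, min(ud$x) - ud$cell / 2, min(ud$y) - ud$cell / 2,
              ud$cell), file = con)
  for (j in ny:1)
    cat(paste(format(ud$z[, j], digits = 10, scientific = TRUE),
              collapse = " "), "\n", file = con, sep = "")
  invisible(path)
}

#' @rdname write_ud
#' @export
read_ud <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  val <- stats::setNames(as.numeric(vapply(hdr, `[`, character(1), 2)),
                         tolower(vapply(hdr, `[`, character(1), 1)))
  nx <- val[["ncols"]]; ny <- val[["nrows"]]; cell <- val[["cellsize"]]
  z <- matrix(NA_real_, nx, ny)
  for (r in seq_len(ny))
    z[, ny - r + 1] <- as.numeric(strsplit(trimws(lines[6 + r]),
                                           "\\s+")[[1]])
  structure(list(x = val[["xllcorner"]] + cell * (seq_len(nx) - 0.5),
                 y = val[["yllcorner"]] + cell * (seq_len(ny) - 0.5),
                 z = z, cell = cell, h = NA_real_), class = "ud")
}

subdivide_keys <- function(k, cell_from, cell_to) {
  r <- cell_from / cell_to
  if (abs(r - round(r)) > 1e-9)
    stop("cell sizes are not integer multiples; re-estimate on a common grid")
  r <- round(r)
  off <- expand.grid(dx = 0:(r - 1), dy = 0:(r - 1))
  n <- length(k$ix)
  list(ix = rep(k$ix * r, times = nrow(off)) + rep(off$dx, each = n),
       iy = rep(k$iy * r, times = nrow(off)) + rep(off$dy, each = n),
       mass = rep(k$mass / r^2, times = nrow(off)))
}
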