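#' Voxel geometry of an SBF-SEM stack
#'
#' Physical calibration of a serial block-face stack: lateral pixel sizes and
#' slice (cutting) thickness, plus the voxel grid shape. Defaults follow the
#' common SBF-SEM acquisition used for intercalated-disc imaging: 3.5 nm
#' lateral pixels and 50 nm sections.
#'
#' The physical-coordinate convention used throughout the package maps the
#' pixel at (row r, column c, slice k), all 0-based, to
#' (x = c * dx_nm, y = r * dy_nm, z = k * dz_nm).
#'
#' @param n_rows,n_cols,n_slices voxel counts (all >= 1)
#' @param dx_nm,dy_nm lateral pixel size in nm
#' @param dz_nm slice thickness in nm
#' @return an object of class `voxel_geometry`
#' @export
voxel_geometry <- function(n_rows, n_cols, n_slices,
                           dx_nm = 3.5, dy_nm = 3.5, dz_nm = 50) {
  stopifnot(dx_nm > 0, dy_nm > 0, dz_nm > 0,
            n_rows >= 1, n_cols >= 1, n_slices >= 1)
  structure(list(dx_nm = dx_nm, dy_nm = dy_nm, dz_nm = dz_nm,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_slices = as.integer(n_slices)),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %d slices x %d rows x %d cols, %g x %g x %g nm\n",
              x$n_slices, x$n_rows, x$n_cols, x$dx_nm, x$dy_nm, x$dz_nm))
  invisible(x)
}

#' Physical lateral extent of a stack, nm
#' @param geometry a [voxel_geometry()]
#' @return named vector c(x_nm, y_nm, z_nm), extent from first to last voxel center
#' @export
stack_extent_nm <- function(geometry) {
  c(x_nm = (geometry$n_cols - 1) * geometry$dx_nm,
    y_nm = (geometry$n_rows - 1) * geometry$dy_nm,
    z_nm = (geometry$n_slices - 1) * geometry$dz_nm)
}

#' Length of a polyline
#' @param xy two-column matrix of vertices (nm)
#' @return total segment length (nm)
#' @export
polyline_length <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Cumulative arc length along a polyline (starts at 0)
#' @param xy two-column matrix of vertices
#' @return numeric vector, one entry per vertex
#' @export
cumulative_arc <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) return(rep(0, nrow(xy)))
  c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
}

#' Signed polygon area by the shoelace formula
#'
#' Positive for counter-clockwise vertex order in a y-up frame; use
#' [polygon_area()] for the absolute area.
#' @param xy two-column matrix of polygon vertices (closing edge implicit)
#' @return signed area (nm^2)
#' @export
shoelace_area <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' Absolute polygon area
#' @inheritParams shoelace_area
#' @export
polygon_area <- function(xy) abs(shoelace_area(xy))

#' Rasterized polygon area (grid-counting cross-check)
#'
#' Counts grid-cell centers inside the polygon (even-odd rule) at a given
#' sampling step. Intended as an independent cross-check of the analytic
#' shoelace area; converges to it as `step_nm` shrinks.
#' @param xy polygon vertices (nm)
#' @param step_nm grid spacing (nm)
#' @return estimated area (nm^2)
#' @export
rasterized_polygon_area <- function(xy, step_nm = 1) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) return(0)
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  gx <- seq(xr[1] + step_nm / 2, xr[2], by = step_nm)
  gy <- seq(yr[1] + step_nm / 2, yr[2], by = step_nm)
  if (!length(gx) || !length(gy)) return(0)
  inside <- 0L
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xj <- x[c(n, 1:(n - 1))]; yj <- y[c(n, 1:(n - 1))]
  for (py in gy) {
    # crossing-number test vectorized over one scanline
    crosses <- ((y > py) != (yj > py))
    if (!any(crosses)) next
    xint <- x[crosses] + (py - y[crosses]) / (yj[crosses] - y[crosses]) *
      (xj[crosses] - x[crosses])
    cnt <- vapply(gx, function(px) sum(xint > px) %% 2L, integer(1))
    inside <- inside + sum(cnt == 1L)
  }
  inside * step_nm^2
}

#' Resample a polyline at (approximately) uniform arc steps
#' @param xy two-column vertex matrix
#' @param step_nm target arc spacing
#' @return matrix of resampled points with attribute `"arc"` holding the arc
#'   positions of the samples
#' @export
resample_polyline <- function(xy, step_nm = 1) {
  xy <- as.matrix(xy)
  s <- cumulative_arc(xy)
  total <- s[length(s)]
  if (total <= 0) {
    out <- xy[1, , drop = FALSE]
    attr(out, "arc") <- 0
    return(out)
  }
  sq <- unique(c(seq(0, total, by = step_nm), total))
  out <- cbind(stats::approx(s, xy[, 1], xout = sq)$y,
               stats::approx(s, xy[, 2], xout = sq)$y)
  attr(out, "arc") <- sq
  out
}

#' Test whether a polygon is simple (no self-intersections)
#'
#' Brute-force segment pair check; adequate for the small contour sizes
#' produced by plaque reconstruction.
#' @param xy polygon vertices
#' @return logical
#' @export
polygon_is_simple <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  seg_a <- xy
  seg_b <- xy[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (shared endpoint)
      if (j == i + 1 || (i == 1 && j == n)) next
      p1 <- seg_a[i, ]; p2 <- seg_b[i, ]; p3 <- seg_a[j, ]; p4 <- seg_b[j, ]
      d1 <- cross2(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
      d2 <- cross2(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
      d3 <- cross2(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
      d4 <- cross2(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}
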