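#' Cluster bead detections into plaques
#'
#' Single-linkage connected components of the detections under 3D physical
#' distance, with z taken as slice * dz. Components with fewer than
#' `min_beads` members are discarded.
#'
#' @param detections data.frame with columns slice, x_nm, y_nm (e.g. from
#'   [detect_beads()])
#' @param dz_nm slice thickness used to scale z distances
#' @param link_distance_nm linkage threshold (must exceed the bead spacing)
#' @param min_beads minimum cluster size retained
#' @return list of data.frames, one per cluster, each with an added
#'   `plaque_id` column ("P01", "P02", ... in order of first detection)
#' @export
cluster_plaques <- function(detections, dz_nm = 50,
                            link_distance_nm = 150, min_beads = 6) {
  n <- nrow(detections)
  if (!n) return(list())
  coords <- cbind(detections$x_nm, detections$y_nm, detections$slice * dz_nm)
  comp <- .link_components(coords, link_distance_nm)
  keep <- as.integer(names(which(table(comp) >= min_beads)))
  keep <- keep[order(vapply(keep, function(cc) min(which(comp == cc)), integer(1)))]
  out <- list()
  for (i in seq_along(keep)) {
    d <- detections[comp == keep[i], , drop = FALSE]
    d$plaque_id <- sprintf("P%02d", i)
    out[[i]] <- d
  }
  out
}

# union-find single linkage with cell binning; O(n * neighbours)
.link_components <- function(coords, link) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cell <- floor(coords / link)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cell_map <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  link2 <- link^2
  for (i in seq_len(n)) {
    for (o in seq_len(nrow(offs))) {
      k <- paste(cell[i, 1] + offs[o, 1], cell[i, 2] + offs[o, 2],
                 cell[i, 3] + offs[o, 3])
      js <- cell_map[[k]]
      js <- js[js > i]
      if (!length(js)) next
      d2 <- (coords[js, 1] - coords[i, 1])^2 + (coords[js, 2] - coords[i, 2])^2 +
        (coords[js, 3] - coords[i, 3])^2
      for (j in js[d2 <= link2]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# project points onto a polyline: arc position, signed perpendicular offset
# (positive on the side the normal points to), index of nearest segment
.project_points <- function(pts, poly) {
  poly <- as.matrix(poly)
  arc <- cumulative_arc(poly)
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), .Machine$double.eps)
  s_out <- numeric(nrow(pts)); off <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ap_x <- pts[i, 1] - a[, 1]; ap_y <- pts[i, 2] - a[, 2]
    t <- pmin(pmax((ap_x * ab[, 1] + ap_y * ab[, 2]) / len2, 0), 1)
    dx <- ap_x - t * ab[, 1]; dy <- ap_y - t * ab[, 2]
    d2 <- dx^2 + dy^2
    j <- which.min(d2)
    s_out[i] <- arc[j] + t[j] * sqrt(len2[j])
    cross <- ab[j, 1] * ap_y[j] - ab[j, 2] * ap_x[j]
    off[i] <- sign(cross) * sqrt(d2[j])
  }
  data.frame(s_nm = s_out, offset_nm = off)
}

# order beads along the plaque: principal-axis projection, replaced by the
# MST diameter-path ordering when projection ordering self-overlaps (the
# U-shaped plaque case)
.order_beads <- function(xy) {
  n <- nrow(xy)
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  ord_pca <- order(pc$x[, 1])
  len_pca <- polyline_length(xy[ord_pca, , drop = FALSE])
  ord_mst <- .mst_path_order(xy)
  len_mst <- polyline_length(xy[ord_mst, , drop = FALSE])
  # a genuine fold of the projection ordering (arc self-overlap) roughly
  # doubles the ordered-path length; below that, projection ordering is
  # kept because the MST diameter path of a wide double string can run up
  # one side and back down the other, which would fold the arc coordinate
  if (len_pca <= 1.6 * len_mst) ord_pca else ord_mst
}

# ordering from the diameter path of the Euclidean MST over a kNN graph;
# points off the path are ranked by projection onto the path polyline
.mst_path_order <- function(xy) {
  n <- nrow(xy)
  k <- min(8L, n - 1L)
  d2 <- as.matrix(stats::dist(xy))
  edges <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    edges <- c(edges, rbind(i, nb))
    w <- c(w, d2[i, nb])
  }
  gr <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::E(gr)$weight <- w
  mst <- igraph::mst(gr)
  path <- as.integer(igraph::get_diameter(mst))
  if (length(path) < 2) return(seq_len(n))
  proj <- .project_points(xy, xy[path, , drop = FALSE])
  order(proj$s_nm)
}

#' Fit the per-slice plaque midline from its beads
#'
#' Orders the beads along their principal axis (switching to an MST
#' diameter-path ordering when the projection ordering self-overlaps, as in
#' strongly curved plaques), takes a moving-average curve through the
#' ordered cloud, and then refines it toward the true bisector of the two
#' strings: beads are split by the sign of their perpendicular offset and
#' the midline is moved to the mean of the two sides' interpolated offset
#' profiles. The result is resampled at ~1 nm and arc-parameterized.
#'
#' @param beads_xy n x 2 matrix of bead centroids in one slice (nm)
#' @return midline matrix with attribute `"arc"`, or NULL (with a warning)
#'   when fewer than 4 beads are supplied
#' @export
fit_midline <- function(beads_xy) {
  beads_xy <- as.matrix(beads_xy)
  n <- nrow(beads_xy)
  if (n < 4) {
    warning("fewer than 4 beads in slice; profile skipped")
    return(NULL)
  }
  ord <- .order_beads(beads_xy)
  pts <- beads_xy[ord, , drop = FALSE]
  w <- min(9L, if (n %% 2 == 0) n - 1L else n)
  sm <- cbind(stats::filter(pts[, 1], rep(1 / w, w), sides = 2),
              stats::filter(pts[, 2], rep(1 / w, w), sides = 2))
  sm <- sm[!is.na(sm[, 1]), , drop = FALSE]
  if (nrow(sm) < 2) sm <- pts[c(1, n), , drop = FALSE]
  mid <- resample_polyline(.extend_ends(sm), 1)
  # bisector refinement: midline <- (side A offset + side B offset) / 2
  for (iter in 1:2) {
    proj <- .project_points(beads_xy, mid)
    up <- proj$offset_nm >= 0
    if (sum(up) < 2 || sum(!up) < 2) break
    arc <- attr(mid, "arc")
    fa <- .side_offset_fun(proj$s_nm[up], proj$offset_nm[up])
    fb <- .side_offset_fun(proj$s_nm[!up], proj$offset_nm[!up])
    corr <- (fa(arc) + fb(arc)) / 2
    nrm <- .midline_normals(mid)
    mid <- resample_polyline(mid + corr * nrm, 1)
  }
  mid
}

# extend a polyline beyond both ends along the local end tangents, so that
# beads near the plaque termini project perpendicularly onto the curve
# rather than radially onto its endpoint (the moving-average curve is
# shorter than the bead cloud by half a window at each end)
.extend_ends <- function(poly, ext_nm = 200) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 2) return(poly)
  i0 <- min(n, 6L)
  t0 <- poly[1, ] - poly[i0, ]
  t1 <- poly[n, ] - poly[n - i0 + 1L, ]
  l0 <- sqrt(sum(t0^2)); l1 <- sqrt(sum(t1^2))
  if (l0 == 0 || l1 == 0) return(poly)
  rbind(poly[1, ] + t0 / l0 * ext_nm, poly, poly[n, ] + t1 / l1 * ext_nm)
}

# piecewise-linear offset profile of one side, constant beyond its ends
.side_offset_fun <- function(s, off) {
  if (length(s) == 1) return(function(q) rep(off, length(q)))
  o <- order(s)
  s <- s[o]; off <- off[o]
  s <- s + seq_along(s) * 1e-9          # guard exact ties
  function(q) stats::approx(s, off, xout = q, rule = 2)$y
}

#' Assign beads to the two membrane sides of a plaque slice
#'
#' The sign of the perpendicular offset from the midline determines the
#' side (positive offset = side "A" under the midline's orientation); the
#' arc position is the projection onto the midline. Beads closer than 2 nm
#' to the midline are assigned by majority vote of their 3 nearest
#' neighbours and flagged ambiguous.
#'
#' @param beads_xy n x 2 matrix of bead centroids (nm)
#' @param midline arc-parameterized midline from [fit_midline()]
#' @return data.frame with side ("A"/"B"), s_nm, offset_nm, ambiguous
#' @export
assign_sides <- function(beads_xy, midline) {
  beads_xy <- as.matrix(beads_xy)
  proj <- .project_points(beads_xy, midline)
  side <- ifelse(proj$offset_nm >= 0, "A", "B")
  amb <- abs(proj$offset_nm) < 2
  if (any(amb) && nrow(beads_xy) > 3) {
    d2 <- as.matrix(stats::dist(beads_xy))
    for (i in which(amb)) {
      nb <- order(d2[i, ])[2:4]
      vote <- side[nb[!amb[nb]]]
      if (length(vote)) side[i] <- names(sort(table(vote), decreasing = TRUE))[1]
    }
  }
  data.frame(side = side, s_nm = proj$s_nm, offset_nm = proj$offset_nm,
             ambiguous = amb)
}

#' Polyline through one side's beads in arc order
#'
#' No smoothing is applied: the polyline joins the bead centroids ordered by
#' arc position. A side with a single bead contributes no polyline (the
#' slice remains analyzable as hemiplaque evidence).
#'
#' @param beads_xy bead centroids of one side (nm)
#' @param s_nm their arc positions along the plaque midline
#' @return matrix of polyline vertices with attribute `"arc"` holding the
#'   beads' arc positions, or NULL for fewer than 2 beads
#' @export
fit_side_polyline <- function(beads_xy, s_nm) {
  beads_xy <- as.matrix(beads_xy)
  if (nrow(beads_xy) < 2) return(NULL)
  o <- order(s_nm)
  out <- beads_xy[o, , drop = FALSE]
  attr(out, "arc") <- s_nm[o]
  out
}

#' Close the intercellular-space polygon between the two side polylines
#'
#' Both sides are trimmed to their common arc-interval overlap (vertices
#' outside it dropped, endpoints interpolated exactly at the interval
#' bounds); the polygon is side A in ascending arc order, a straight end
#' cap, side B reversed, and the closing cap. Area is the absolute shoelace
#' area. A self-intersecting polygon is repaired by shrinking the arc
#' interval until simple and flagged.
#'
#' @param side_a,side_b side polylines from [fit_side_polyline()]
#' @return list with `polygon` (vertex matrix), `area_nm2`, `s_lo`, `s_hi`
#'   (the common arc interval), `repaired` flag; or NULL when the sides do
#'   not overlap in arc
#' @export
segment_inner_space <- function(side_a, side_b) {
  if (is.null(side_a) || is.null(side_b)) return(NULL)
  sa <- attr(side_a, "arc"); sb <- attr(side_b, "arc")
  lo <- max(min(sa), min(sb)); hi <- min(max(sa), max(sb))
  if (hi <= lo) return(NULL)
  repaired <- FALSE
  for (try in 0:10) {
    pa <- .trim_side(side_a, sa, lo, hi)
    pb <- .trim_side(side_b, sb, lo, hi)
    poly <- rbind(pa, pb[rev(seq_len(nrow(pb))), , drop = FALSE])
    if (nrow(poly) >= 3 && polygon_is_simple(poly)) {
      return(list(polygon = poly, area_nm2 = polygon_area(poly),
                  s_lo = lo, s_hi = hi, repaired = repaired))
    }
    shrink <- (hi - lo) * 0.05
    lo <- lo + shrink; hi <- hi - shrink
    repaired <- TRUE
    if (hi <= lo) break
  }
  NULL
}

# vertices of one side inside [lo, hi], with interpolated exact endpoints
.trim_side <- function(side, s, lo, hi) {
  keep <- s > lo & s < hi
  fx <- stats::approx(s, side[, 1], xout = c(lo, hi), rule = 2)$y
  fy <- stats::approx(s, side[, 2], xout = c(lo, hi), rule = 2)$y
  rbind(c(fx[1], fy[1]),
        side[keep, , drop = FALSE],
        c(fx[2], fy[2]))
}

#' Reconstruct all plaques of a stack from bead detections
#'
#' Orchestrates clustering, per-slice midline fitting, side assignment,
#' side polylines and inner-space segmentation. Slice midlines of one
#' plaque are oriented consistently (each slice's midline is reversed when
#' its end-to-end chord opposes the previous slice's), which propagates the
#' A/B side labelling through the stack.
#'
#' @param detections data.frame from [detect_beads()]
#' @param geometry the stack's [voxel_geometry()] (supplies dz)
#' @param link_distance_nm,min_beads clustering parameters
#' @return object of class `plaque_reconstruction`: list of plaques, each
#'   with `plaque_id`, `detections`, and `slices` (per analyzable slice:
#'   midline, bead assignment table, side polylines, inner-space segment)
#' @export
reconstruct_plaques <- function(detections, geometry,
                                link_distance_nm = 150, min_beads = 6) {
  clusters <- cluster_plaques(detections, dz_nm = geometry$dz_nm,
                              link_distance_nm = link_distance_nm,
                              min_beads = min_beads)
  plaques <- lapply(clusters, function(cl) {
    slices <- sort(unique(cl$slice))
    out <- list()
    prev_chord <- NULL
    for (k in slices) {
      bk <- cl[cl$slice == k, , drop = FALSE]
      if (nrow(bk) < 4) {
        warning(sprintf("plaque %s slice %d: fewer than 4 beads; profile skipped",
                        cl$plaque_id[1], k))
        next
      }
      xy <- cbind(bk$x_nm, bk$y_nm)
      mid <- fit_midline(xy)
      if (is.null(mid)) next
      chord <- mid[nrow(mid), ] - mid[1, ]
      if (!is.null(prev_chord) && sum(chord * prev_chord) < 0) {
        mid <- resample_polyline(mid[rev(seq_len(nrow(mid))), , drop = FALSE], 1)
        chord <- -chord
      }
      prev_chord <- chord
      asg <- assign_sides(xy, mid)
      asg$x_nm <- bk$x_nm; asg$y_nm <- bk$y_nm
      pa <- fit_side_polyline(xy[asg$side == "A", , drop = FALSE],
                              asg$s_nm[asg$side == "A"])
      pb <- fit_side_polyline(xy[asg$side == "B", , drop = FALSE],
                              asg$s_nm[asg$side == "B"])
      seg <- segment_inner_space(pa, pb)
      out[[as.character(k)]] <- list(slice = k, midline = mid, beads = asg,
                                     side_A = pa, side_B = pb, segment = seg)
    }
    list(plaque_id = cl$plaque_id[1], detections = cl, slices = out)
  })
  structure(list(plaques = plaques, geometry = geometry),
            class = "plaque_reconstruction")
}

#' @export
print.plaque_reconstruction <- function(x, ...) {
  cat(sprintf("plaque_reconstruction: %d plaque(s)\n", length(x$plaques)))
  for (p in x$plaques) {
    cat(sprintf("  %s: %d detections, %d analyzable slices\n",
                p$plaque_id, nrow(p$detections), length(p$slices)))
  }
  invisible(x)
}
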