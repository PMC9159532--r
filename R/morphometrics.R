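#' Per-plane metrics of one reconstructed plaque slice
#'
#' Length is the midline arc length over the trimmed common overlap of the
#' two side polylines; area is the inner-space polygon area; area per
#' length is their ratio (units reduce to nm, the mean inter-membrane gap).
#'
#' @param slice_entry one slice element of a [reconstruct_plaques()] plaque
#' @return one-row data.frame (slice, length_nm, area_nm2,
#'   area_per_length_nm, max_width_nm) or NULL when the slice has no
#'   inner-space segment or a zero-length overlap
#' @export
plane_metrics <- function(slice_entry) {
  seg <- slice_entry$segment
  if (is.null(seg)) return(NULL)
  len <- seg$s_hi - seg$s_lo
  if (len <= 0) return(NULL)
  data.frame(slice = slice_entry$slice,
             length_nm = len,
             area_nm2 = seg$area_nm2,
             area_per_length_nm = seg$area_nm2 / len,
             max_width_nm = .plane_max_width(slice_entry))
}

# maximal inter-polyline perpendicular width, sampled at <= 5 nm arc steps
# over the common overlap; widths are differences of the two sides' signed
# perpendicular offsets from the shared midline
.plane_max_width <- function(slice_entry, step_nm = 5) {
  seg <- slice_entry$segment
  b <- slice_entry$beads
  a_ok <- b$side == "A"; b_ok <- b$side == "B"
  if (sum(a_ok) < 2 || sum(b_ok) < 2 || is.null(seg)) return(NA_real_)
  sq <- seq(seg$s_lo, seg$s_hi, by = step_nm)
  oa <- stats::approx(b$s_nm[a_ok], b$offset_nm[a_ok], xout = sq, rule = 2)$y
  ob <- stats::approx(b$s_nm[b_ok], b$offset_nm[b_ok], xout = sq, rule = 2)$y
  max(abs(oa - ob))
}

#' Pair opposing beads across the two sides of a plaque slice
#'
#' Mutual-nearest matching on arc position: an A bead and a B bead are
#' paired when each is the other's nearest opposite-side bead by arc
#' distance, their arc positions differ by at most `pairing_arc_tol_nm`,
#' and their Euclidean separation is at most `max_gap_nm`. Remaining beads
#' are unpaired; unpaired beads are the structural evidence of orphan
#' (undocked) connexin label.
#'
#' @param beads bead assignment table of one slice (side, s_nm, x_nm, y_nm)
#' @param pairing_arc_tol_nm arc tolerance; default 0.6 x the median
#'   within-side bead spacing of the slice (scale-free)
#' @param max_gap_nm maximum physical separation of a pair
#' @return list with `pairs` (data.frame of A row, B row indices into
#'   `beads`), `unpaired` (data.frame side, row, s_nm), `arc_tol_nm`
#' @export
pair_beads <- function(beads, pairing_arc_tol_nm = NULL, max_gap_nm = 120) {
  ia <- which(beads$side == "A"); ib <- which(beads$side == "B")
  if (is.null(pairing_arc_tol_nm)) {
    sp <- .median_spacing(beads)
    pairing_arc_tol_nm <- if (is.na(sp)) 30 else 0.6 * sp
  }
  pairs <- NULL
  if (length(ia) && length(ib)) {
    ds <- abs(outer(beads$s_nm[ia], beads$s_nm[ib], `-`))
    near_a <- apply(ds, 1, which.min)   # for each A, nearest B
    near_b <- apply(ds, 2, which.min)   # for each B, nearest A
    keep <- which(near_b[near_a] == seq_along(ia))
    if (length(keep)) {
      a <- ia[keep]; b <- ib[near_a[keep]]
      dmat_s <- ds[cbind(keep, near_a[keep])]
      eu <- sqrt((beads$x_nm[a] - beads$x_nm[b])^2 +
                   (beads$y_nm[a] - beads$y_nm[b])^2)
      ok <- dmat_s <= pairing_arc_tol_nm & eu <= max_gap_nm
      if (any(ok)) pairs <- data.frame(a = a[ok], b = b[ok])
    }
  }
  paired_rows <- if (is.null(pairs)) integer(0) else c(pairs$a, pairs$b)
  un <- setdiff(c(ia, ib), paired_rows)
  unpaired <- data.frame(side = beads$side[un], row = un, s_nm = beads$s_nm[un])
  list(pairs = pairs, unpaired = unpaired[order(unpaired$s_nm), , drop = FALSE],
       arc_tol_nm = pairing_arc_tol_nm)
}

# median within-side nearest-neighbour arc spacing of a slice
.median_spacing <- function(beads) {
  sp <- c()
  for (sd_ in c("A", "B")) {
    s <- sort(beads$s_nm[beads$side == sd_])
    if (length(s) > 1) sp <- c(sp, diff(s))
  }
  if (!length(sp)) NA_real_ else stats::median(sp)
}

#' Call hemiplaque segments from per-slice pairings
#'
#' Within each slice, maximal runs of consecutive unpaired beads on one
#' side (consecutive in that side's arc order) with at least
#' `min_run_beads` beads and an arc span of at least `min_run_length_nm`
#' become hemiplaque segments. The segment length is the run's arc span
#' extended by half the local bead spacing at each end.
#'
#' @param beads bead table of the slice
#' @param pairing a [pair_beads()] result for the slice
#' @param min_run_beads minimum beads per run (default 3)
#' @param min_run_length_nm minimum arc span (default 100)
#' @return data.frame (side, s_start_nm, length_nm, n_beads), possibly empty
#' @export
call_hemiplaques <- function(beads, pairing, min_run_beads = 3,
                             min_run_length_nm = 100) {
  spacing <- .median_spacing(beads)
  if (is.na(spacing)) spacing <- 50
  out <- list()
  unpaired_rows <- pairing$unpaired$row
  for (sd_ in c("A", "B")) {
    rows <- which(beads$side == sd_)
    rows <- rows[order(beads$s_nm[rows])]
    if (!length(rows)) next
    is_un <- rows %in% unpaired_rows
    r <- rle(is_un)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run_beads)) {
      run <- rows[starts[j]:ends[j]]
      span <- beads$s_nm[run[length(run)]] - beads$s_nm[run[1]]
      if (span < min_run_length_nm) next
      out[[length(out) + 1L]] <- data.frame(
        side = sd_, s_start_nm = beads$s_nm[run[1]] - spacing / 2,
        length_nm = span + spacing, n_beads = length(run))
    }
  }
  if (!length(out)) {
    return(data.frame(side = character(0), s_start_nm = numeric(0),
                      length_nm = numeric(0), n_beads = integer(0)))
  }
  do.call(rbind, out)
}

#' Morphometrics of a reconstructed stack
#'
#' Computes the per-plane rows (length, area, area per length) and
#' per-plaque summaries (unweighted mean area per length over planes,
#' maximal width over all planes, total plaque length as the sum of
#' per-plane lengths, hemiplaque segments and totals, hemiplaque fraction
#' as 100 x summed hemiplaque length / summed plaque length) for every
#' plaque of a [reconstruct_plaques()] result.
#'
#' @param reconstruction a `plaque_reconstruction`
#' @param pairing_arc_tol_nm,max_gap_nm see [pair_beads()]
#' @param min_run_beads,min_run_length_nm see [call_hemiplaques()]
#' @return object of class `morphometrics_record`: list with data.frames
#'   `per_plane`, `per_plaque`, and `hemiplaque_segments`
#' @export
measure_plaques <- function(reconstruction,
                            pairing_arc_tol_nm = NULL, max_gap_nm = 120,
                            min_run_beads = 3, min_run_length_nm = 100) {
  stopifnot(inherits(reconstruction, "plaque_reconstruction"))
  per_plane <- list(); per_plaque <- list(); segments <- list()
  for (p in reconstruction$plaques) {
    rows <- list(); segs <- list()
    for (sl in p$slices) {
      pm <- plane_metrics(sl)
      pr <- pair_beads(sl$beads, pairing_arc_tol_nm, max_gap_nm)
      hp <- call_hemiplaques(sl$beads, pr, min_run_beads, min_run_length_nm)
      if (!is.null(pm)) {
        pm$plaque_id <- p$plaque_id
        rows[[length(rows) + 1L]] <- pm
      }
      if (nrow(hp)) {
        hp$slice <- sl$slice; hp$plaque_id <- p$plaque_id
        segs[[length(segs) + 1L]] <- hp
      }
    }
    if (!length(rows)) next
    rows <- do.call(rbind, rows)
    segs <- if (length(segs)) do.call(rbind, segs) else NULL
    total_len <- sum(rows$length_nm)
    hemi_len <- if (is.null(segs)) 0 else sum(segs$length_nm)
    hemi_len <- min(hemi_len, total_len)
    per_plane[[length(per_plane) + 1L]] <- rows
    per_plaque[[length(per_plaque) + 1L]] <- data.frame(
      plaque_id = p$plaque_id,
      avg_area_per_length_nm = mean(rows$area_per_length_nm),
      max_width_nm = max(rows$max_width_nm, na.rm = TRUE),
      total_plaque_length_nm = total_len,
      n_planes = nrow(rows),
      total_hemiplaque_length_nm = hemi_len,
      hemiplaque_fraction_pct = 100 * hemi_len / total_len,
      has_hemiplaque = hemi_len > 0)
    if (!is.null(segs)) segments[[length(segments) + 1L]] <- segs
  }
  structure(list(
    per_plane = if (length(per_plane)) do.call(rbind, per_plane) else NULL,
    per_plaque = if (length(per_plaque)) do.call(rbind, per_plaque) else NULL,
    hemiplaque_segments = if (length(segments)) do.call(rbind, segments) else NULL),
    class = "morphometrics_record")
}

#' Group-level hemiplaque statistics
#'
#' Per (genotype, ventricle) group: percentage of plaques containing at
#' least one hemiplaque, pooled hemiplaque length, and pooled length
#' fraction (100 x summed hemiplaque length / summed plaque length).
#'
#' @param per_plaque per-plaque table carrying `genotype` and `ventricle`
#'   columns (and the morphometric fields)
#' @param by grouping columns
#' @return data.frame, one row per group
#' @export
cohort_hemiplaque_stats <- function(per_plaque, by = c("genotype", "ventricle")) {
  stopifnot(all(by %in% names(per_plaque)))
  if (!nrow(per_plaque)) stop("empty group: no plaques in the table")
  key <- interaction(per_plaque[by], drop = TRUE, sep = ":")
  groups <- split(per_plaque, key)
  if (any(!vapply(groups, nrow, integer(1)))) {
    stop(sprintf("empty group: %s",
                 names(groups)[!vapply(groups, nrow, integer(1))][1]))
  }
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    lab <- d[1, by, drop = FALSE]
    cbind(lab, data.frame(
      n_plaques = nrow(d),
      pct_with_hemiplaque = 100 * mean(d$has_hemiplaque),
      total_hemiplaque_length_nm = sum(d$total_hemiplaque_length_nm),
      pooled_length_fraction_pct = 100 * sum(d$total_hemiplaque_length_nm) /
        sum(d$total_plaque_length_nm)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
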