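#' Generative description of one gap-junction plaque
#'
#' A plaque is modelled as a smooth planar ribbon (the intercalated-disc
#' midline) spanning consecutive 50 nm sections. The two connexin bead
#' strings lie at perpendicular offsets of +/- gap(s, z)/2 from the midline,
#' where the gap profile is a baseline inter-string distance plus Gaussian
#' bulges (local widenings of the intercellular space). Orphan runs delete
#' the beads of one side over an arc interval, producing a hemiplaque: a
#' single strand of label lacking opposing partners.
#'
#' @param control_points k x 2 matrix of midline control points (nm, stack
#'   x/y frame); a natural cubic spline is drawn through them
#' @param slice_start first slice index the plaque spans (0-based)
#' @param n_slices number of consecutive slices spanned
#' @param gap_baseline_nm baseline inter-string distance (nm), > 0
#' @param bulges data.frame with columns `center_nm`, `amplitude_nm`,
#'   `width_nm` (Gaussian s.d. along arc) and optional `amp_start_frac`,
#'   `amp_end_frac`: amplitude multipliers at the first and last spanned
#'   slice, linearly interpolated in between (default both 1, i.e. the bulge
#'   spans all sections at full amplitude)
#' @param bead_spacing_nm mean inter-bead spacing along a string
#' @param bead_spacing_jitter_nm s.d. of spacing jitter (truncated at
#'   +/- 2 s.d. so bead order along the arc is preserved)
#' @param bead_diameter_range_nm (lo, hi) of the uniform silver-enhanced
#'   particle diameter, default 10-20 nm
#' @param side_registration "paired" (default): opposing beads represent the
#'   two connexons of docked channels and share arc positions up to a small
#'   registration jitter; "independent": each side is its own renewal
#'   stream (the sides then drift out of arc register)
#' @param bead_registration_jitter_nm s.d. of the per-side arc offset in
#'   "paired" mode (truncated at +/- 2 s.d.)
#' @param orphan_runs data.frame with columns `side` ("A"/"B"), `start_nm`,
#'   `length_nm`: arc intervals whose beads on the named side are removed
#' @param bead_contrast intensity drop of a bead below background, as a
#'   fraction of the dynamic range
#' @param membrane_on_orphan keep the faint membrane trace over orphan
#'   intervals of the deleted side (default FALSE: membrane also absent)
#' @param seed optional per-plaque RNG seed; if NULL the generator's global
#'   stream is used
#' @param plaque_id optional identifier
#' @return object of class `plaque_spec`
#' @export
plaque_spec <- function(control_points,
                        slice_start = 0L,
                        n_slices = 5L,
                        gap_baseline_nm = 20,
                        bulges = NULL,
                        bead_spacing_nm = 50,
                        bead_spacing_jitter_nm = 8,
                        bead_diameter_range_nm = c(10, 20),
                        orphan_runs = NULL,
                        side_registration = c("paired", "independent"),
                        bead_registration_jitter_nm = 5,
                        bead_contrast = 0.55,
                        membrane_on_orphan = FALSE,
                        seed = NULL,
                        plaque_id = NULL) {
  side_registration <- match.arg(side_registration)
  control_points <- as.matrix(control_points)
  stopifnot(ncol(control_points) == 2, nrow(control_points) >= 2,
            gap_baseline_nm > 0, bead_spacing_nm > 0,
            bead_spacing_jitter_nm >= 0, n_slices >= 1, slice_start >= 0,
            length(bead_diameter_range_nm) == 2,
            bead_diameter_range_nm[1] > 0,
            bead_diameter_range_nm[1] < bead_diameter_range_nm[2])
  if (!is.null(bulges)) {
    bulges <- as.data.frame(bulges)
    stopifnot(all(c("center_nm", "amplitude_nm", "width_nm") %in% names(bulges)))
    if (is.null(bulges$amp_start_frac)) bulges$amp_start_frac <- 1
    if (is.null(bulges$amp_end_frac)) bulges$amp_end_frac <- 1
    stopifnot(all(bulges$width_nm > 0))
  }
  if (!is.null(orphan_runs)) {
    orphan_runs <- as.data.frame(orphan_runs)
    stopifnot(all(c("side", "start_nm", "length_nm") %in% names(orphan_runs)),
              all(orphan_runs$side %in% c("A", "B")),
              all(orphan_runs$length_nm > 0), all(orphan_runs$start_nm >= 0))
  }
  structure(list(control_points = control_points,
                 slice_start = as.integer(slice_start),
                 n_slices = as.integer(n_slices),
                 gap_baseline_nm = gap_baseline_nm,
                 bulges = bulges,
                 bead_spacing_nm = bead_spacing_nm,
                 bead_spacing_jitter_nm = bead_spacing_jitter_nm,
                 bead_diameter_range_nm = bead_diameter_range_nm,
                 orphan_runs = orphan_runs,
                 side_registration = side_registration,
                 bead_registration_jitter_nm = bead_registration_jitter_nm,
                 bead_contrast = bead_contrast,
                 membrane_on_orphan = isTRUE(membrane_on_orphan),
                 seed = seed,
                 plaque_id = plaque_id),
            class = "plaque_spec")
}

#' Arc-parameterized midline of a plaque spec
#'
#' Natural cubic spline through the control points, parameterized by chord
#' length and resampled at ~1 nm arc steps.
#' @param spec a [plaque_spec()]
#' @param step_nm resampling step
#' @return matrix of midline points with attribute `"arc"`
#' @export
spec_midline <- function(spec, step_nm = 1) {
  cp <- spec$control_points
  if (nrow(cp) == 2) {
    dense <- resample_polyline(cp, step_nm)
    return(dense)
  }
  t0 <- cumulative_arc(cp)
  fx <- stats::splinefun(t0, cp[, 1], method = "natural")
  fy <- stats::splinefun(t0, cp[, 2], method = "natural")
  tq <- seq(0, max(t0), length.out = max(64L, 4L * ceiling(max(t0) / step_nm)))
  dense <- cbind(fx(tq), fy(tq))
  resample_polyline(dense, step_nm)
}

# slice-dependent bulge multiplier: linear in z across the spanned sections
.bulge_zmult <- function(spec, slice, start_frac, end_frac) {
  if (spec$n_slices == 1) return(start_frac)
  f <- (slice - spec$slice_start) / (spec$n_slices - 1)
  start_frac + f * (end_frac - start_frac)
}

#' Gap profile of a plaque: inter-string distance at arc position and slice
#' @param spec a [plaque_spec()]
#' @param s_nm arc positions (nm)
#' @param slice absolute slice index (0-based); must lie in the spanned range
#' @return gap widths (nm), same length as `s_nm`
#' @export
gap_profile <- function(spec, s_nm, slice) {
  g <- rep(spec$gap_baseline_nm, length(s_nm))
  if (!is.null(spec$bulges) && nrow(spec$bulges)) {
    for (i in seq_len(nrow(spec$bulges))) {
      b <- spec$bulges[i, ]
      zm <- .bulge_zmult(spec, slice, b$amp_start_frac, b$amp_end_frac)
      g <- g + b$amplitude_nm * zm * exp(-(s_nm - b$center_nm)^2 / (2 * b$width_nm^2))
    }
  }
  g
}

# unit normals of an arc-sampled midline (rotate tangent by +90 deg)
.midline_normals <- function(mid) {
  n <- nrow(mid)
  tang <- rbind(mid[2, ] - mid[1, ],
                (mid[3:n, , drop = FALSE] - mid[1:(n - 2), , drop = FALSE]) / 2,
                mid[n, ] - mid[n - 1, ])
  len <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(len, .Machine$double.eps)
  cbind(-tang[, 2], tang[, 1])
}

# truncated-normal spacing jitter, |e| <= 2 sd, preserves bead order
.trunc_jitter <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  e <- stats::rnorm(n, 0, sd)
  pmin(pmax(e, -2 * sd), 2 * sd)
}

.in_orphan <- function(spec, side, s) {
  runs <- spec$orphan_runs
  if (is.null(runs) || !nrow(runs)) return(rep(FALSE, length(s)))
  hit <- rep(FALSE, length(s))
  for (i in seq_len(nrow(runs))) {
    if (runs$side[i] != side) next
    hit <- hit | (s >= runs$start_nm[i] & s <= runs$start_nm[i] + runs$length_nm[i])
  }
  hit
}

# sample bead arc positions and diameters for one side of one slice
.sample_beads_1d <- function(arc_len, spacing, jitter, drange) {
  s <- stats::runif(1, 0, spacing)
  out <- numeric(0)
  while (s <= arc_len) {
    out <- c(out, s)
    s <- s + spacing + .trunc_jitter(1, jitter)
  }
  if (!length(out)) return(data.frame(s_nm = numeric(0), diameter_nm = numeric(0)))
  data.frame(s_nm = out,
             diameter_nm = stats::runif(length(out), drange[1], drange[2]))
}

#' Generate a synthetic SBF-SEM stack of gap-junction plaques
#'
#' Renders dark silver-enhanced nanogold beads as inverted Gaussian spots
#' (full width ~ particle diameter) arranged as two strings at +/- gap/2
#' around each plaque midline, plus faint dark membrane traces at 30% of the
#' bead contrast, a low-frequency background texture, and additive Gaussian
#' noise. Beads are single-slice objects (diameters never exceed the 50 nm
#' section thickness). Returns the rendered stack together with the exact
#' generative ground truth.
#'
#' @param specs list of [plaque_spec()] objects (may be empty)
#' @param geometry a [voxel_geometry()]
#' @param noise_sd additive Gaussian noise s.d. (fraction of dynamic range),
#'   must be > 0
#' @param background_texture_scale_nm correlation length of the smooth
#'   background mottle (nm)
#' @param seed integer RNG seed; the whole stack is a deterministic function
#'   of (specs, geometry, noise_sd, texture scale, seed)
#' @param background_level mean background intensity (fraction of range)
#' @param texture_amplitude s.d. of the background mottle
#' @param bit_depth 8 or 16
#' @return list with elements `stack` (class `em_stack`: `intensities` array
#'   of dim rows x cols x slices, values in [0, 1] quantized to `bit_depth`;
#'   `geometry`; `bit_depth`) and `truth` (class `ground_truth`: per-plaque
#'   spec, midline, bead table, and the stack geometry)
#' @export
generate_stack <- function(specs, geometry,
                           noise_sd = 0.04,
                           background_texture_scale_nm = 200,
                           seed = 1L,
                           background_level = 0.75,
                           texture_amplitude = 0.05,
                           bit_depth = 8L) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  ext <- stack_extent_nm(geometry)
  # validate extents before consuming randomness
  specs <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    stopifnot(inherits(sp, "plaque_spec"))
    if (is.null(sp$plaque_id)) sp$plaque_id <- sprintf("plaque_%02d", i)
    mid <- spec_midline(sp)
    max_half_gap <- max(vapply(sp$slice_start + seq_len(sp$n_slices) - 1L,
                               function(k) max(gap_profile(sp, attr(mid, "arc"), k)),
                               numeric(1))) / 2
    pad <- max_half_gap + max(sp$bead_diameter_range_nm)
    if (min(mid[, 1]) - pad < 0 || max(mid[, 1]) + pad > ext["x_nm"] ||
        min(mid[, 2]) - pad < 0 || max(mid[, 2]) + pad > ext["y_nm"] ||
        sp$slice_start + sp$n_slices > geometry$n_slices) {
      stop(sprintf("plaque '%s' exceeds the stack extent", sp$plaque_id))
    }
    sp
  })

  set.seed(as.integer(seed))
  nr <- geometry$n_rows; nc <- geometry$n_cols; ns <- geometry$n_slices
  truth_plaques <- .build_truth(specs)

  # render: background mottle + membranes + beads, slice by slice
  tex_px <- max(2, background_texture_scale_nm / geometry$dx_nm)
  arr <- array(0, dim = c(nr, nc, ns))
  for (k in seq_len(ns) - 1L) {
    bg <- background_level + texture_amplitude * .smooth_field(nr, nc, tex_px)
    dark <- matrix(0, nr, nc)
    for (tp in truth_plaques) {
      sp <- tp$spec
      if (k < sp$slice_start || k >= sp$slice_start + sp$n_slices) next
      dark <- .render_membranes(dark, tp, k, geometry)
      bk <- tp$beads[tp$beads$slice == k, , drop = FALSE]
      if (nrow(bk)) dark <- .render_beads(dark, bk, sp$bead_contrast, geometry)
    }
    img <- bg - dark + stats::rnorm(nr * nc, 0, noise_sd)
    arr[, , k + 1L] <- pmin(pmax(img, 0), 1)
  }
  maxv <- 2^bit_depth - 1
  arr <- round(arr * maxv) / maxv

  stack <- structure(list(intensities = arr, geometry = geometry,
                          bit_depth = as.integer(bit_depth)),
                     class = "em_stack")
  truth <- structure(list(geometry = geometry, plaques = truth_plaques),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

# sample bead tables for validated specs; assumes the RNG is already seeded
.build_truth <- function(specs, beads = TRUE) {
  out <- lapply(specs, function(sp) {
    if (!is.null(sp$seed)) set.seed(as.integer(sp$seed))
    mid <- spec_midline(sp)
    arc <- attr(mid, "arc")
    nrm <- .midline_normals(mid)
    tab <- list()
    if (beads) {
      paired <- is.null(sp$side_registration) || sp$side_registration == "paired"
      for (k in sp$slice_start + seq_len(sp$n_slices) - 1L) {
        base <- if (paired) {
          .sample_beads_1d(max(arc), sp$bead_spacing_nm,
                           sp$bead_spacing_jitter_nm,
                           sp$bead_diameter_range_nm)
        } else NULL
        for (side in c("A", "B")) {
          b1 <- if (paired) {
            b2 <- base
            if (nrow(b2)) {
              jit <- sp$bead_registration_jitter_nm %||% 5
              b2$s_nm <- pmin(pmax(b2$s_nm + .trunc_jitter(nrow(b2), jit), 0),
                              max(arc))
              b2$diameter_nm <- stats::runif(nrow(b2),
                                             sp$bead_diameter_range_nm[1],
                                             sp$bead_diameter_range_nm[2])
            }
            b2
          } else {
            .sample_beads_1d(max(arc), sp$bead_spacing_nm,
                             sp$bead_spacing_jitter_nm,
                             sp$bead_diameter_range_nm)
          }
          if (!nrow(b1)) next
          b1 <- b1[!.in_orphan(sp, side, b1$s_nm), , drop = FALSE]
          if (!nrow(b1)) next
          idx <- pmin(pmax(round(b1$s_nm) + 1L, 1L), nrow(mid))
          sgn <- if (side == "A") 1 else -1
          g <- gap_profile(sp, b1$s_nm, k)
          ctr <- mid[idx, , drop = FALSE] + sgn * (g / 2) * nrm[idx, , drop = FALSE]
          tab[[length(tab) + 1L]] <- data.frame(
            plaque_id = sp$plaque_id, side = side, slice = k,
            s_nm = b1$s_nm, x_nm = ctr[, 1], y_nm = ctr[, 2],
            diameter_nm = b1$diameter_nm, stringsAsFactors = FALSE)
        }
      }
    }
    tab <- if (length(tab)) do.call(rbind, tab) else
      data.frame(plaque_id = character(0), side = character(0),
                 slice = integer(0), s_nm = numeric(0), x_nm = numeric(0),
                 y_nm = numeric(0), diameter_nm = numeric(0))
    list(spec = sp, midline = mid, beads = tab)
  })
  names(out) <- vapply(specs, `[[`, character(1), "plaque_id")
  out
}

#' Ground truth without rendering
#'
#' Builds the generative ground truth (midlines and bead tables) for a set
#' of plaque specs without rasterizing an image stack. Useful for oracle
#' computations and large simulated cohorts where only [truth_metrics()]
#' values are needed.
#' @inheritParams generate_stack
#' @param beads sample the bead tables (set FALSE when only gap-profile
#'   metrics are needed)
#' @return a `ground_truth` object
#' @export
truth_from_specs <- function(specs, geometry, seed = 1L, beads = TRUE) {
  specs <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    stopifnot(inherits(sp, "plaque_spec"))
    if (is.null(sp$plaque_id)) sp$plaque_id <- sprintf("plaque_%02d", i)
    sp
  })
  set.seed(as.integer(seed))
  structure(list(geometry = geometry, plaques = .build_truth(specs, beads = beads)),
            class = "ground_truth")
}

# smooth random field: coarse iid normals, bilinear upsampled, unit-ish s.d.
.smooth_field <- function(nr, nc, scale_px) {
  gr <- max(2L, ceiling(nr / scale_px) + 1L)
  gc <- max(2L, ceiling(nc / scale_px) + 1L)
  coarse <- matrix(stats::rnorm(gr * gc), gr, gc)
  ri <- seq(1, gr, length.out = nr)
  ci <- seq(1, gc, length.out = nc)
  r0 <- pmin(floor(ri), gr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), gc - 1L); fc <- ci - c0
  a <- coarse[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- coarse[cbind(rep(r0 + 1L, nc), rep(c0, each = nr))]
  d <- coarse[cbind(rep(r0, nc), rep(c0 + 1L, each = nr))]
  e <- coarse[cbind(rep(r0 + 1L, nc), rep(c0 + 1L, each = nr))]
  frv <- rep(fr, nc); fcv <- rep(fc, each = nr)
  matrix(a * (1 - frv) * (1 - fcv) + b * frv * (1 - fcv) +
           d * (1 - frv) * fcv + e * frv * fcv, nr, nc)
}

# stamp an inverted-Gaussian spot field, combined with pmax so overlapping
# stamps do not double the darkness
.stamp_spots <- function(dark, xs_px, ys_px, sigmas_px, amps) {
  nr <- nrow(dark); nc <- ncol(dark)
  for (i in seq_along(xs_px)) {
    s <- sigmas_px[i]
    r <- ceiling(3 * s)
    cx <- xs_px[i]; cy <- ys_px[i]
    c0 <- max(1L, floor(cx) - r + 1L); c1 <- min(nc, floor(cx) + r + 1L)
    r0 <- max(1L, floor(cy) - r + 1L); r1 <- min(nr, floor(cy) + r + 1L)
    if (c0 > c1 || r0 > r1) next
    dxv <- (c0:c1) - 1 - cx
    dyv <- (r0:r1) - 1 - cy
    g <- amps[i] * exp(-(outer(dyv^2, dxv^2, `+`)) / (2 * s^2))
    dark[r0:r1, c0:c1] <- pmax(dark[r0:r1, c0:c1], g)
  }
  dark
}

.render_beads <- function(dark, beads, contrast, geometry) {
  # FWHM ~ diameter  =>  sigma = d / (2 sqrt(2 ln 2))
  sig_px <- beads$diameter_nm / 2.3548 / geometry$dx_nm
  .stamp_spots(dark, beads$x_nm / geometry$dx_nm, beads$y_nm / geometry$dy_nm,
               sig_px, rep(contrast, nrow(beads)))
}

.render_membranes <- function(dark, tp, slice, geometry) {
  sp <- tp$spec
  mid <- tp$midline
  arc <- attr(mid, "arc")
  nrm <- .midline_normals(mid)
  step <- max(1L, round(geometry$dx_nm))          # ~1 px sampling along arc
  idx <- seq(1L, nrow(mid), by = step)
  amp <- 0.3 * sp$bead_contrast
  sig <- 1.2                                       # px, thin membrane trace
  g <- gap_profile(sp, arc[idx], slice)
  for (side in c("A", "B")) {
    sgn <- if (side == "A") 1 else -1
    keep <- rep(TRUE, length(idx))
    if (!sp$membrane_on_orphan) keep <- !.in_orphan(sp, side, arc[idx])
    if (!any(keep)) next
    pts <- mid[idx[keep], , drop = FALSE] +
      sgn * (g[keep] / 2) * nrm[idx[keep], , drop = FALSE]
    dark <- .stamp_spots(dark, pts[, 1] / geometry$dx_nm,
                         pts[, 2] / geometry$dy_nm,
                         rep(sig, nrow(pts)), rep(amp, nrow(pts)))
  }
  dark
}

#' Oracle morphometrics computed directly from generative ground truth
#'
#' Evaluates every metric of the morphometrics module analytically from the
#' generative midline and gap profile, with no image processing: per-plane
#' length (midline arc length), area (integral of the gap profile along the
#' arc), area per length, maximal width (supremum of the gap profile over
#' arc and slices), and hemiplaque intervals (the requested orphan runs,
#' clipped to the plaque extent and merged). Total hemiplaque length is the
#' arc-length union of the runs; the hemiplaque fraction is that union
#' divided by the plaque arc length (x 100).
#'
#' @param truth a `ground_truth` object from [generate_stack()]
#' @return list with data.frames `per_plane` (plaque_id, slice, length_nm,
#'   area_nm2, area_per_length_nm) and `per_plaque` (plaque_id,
#'   avg_area_per_length_nm, max_width_nm, total_plaque_length_nm, n_planes,
#'   total_hemiplaque_length_nm, hemiplaque_fraction_pct, has_hemiplaque)
#' @export
truth_metrics <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!length(truth$plaques)) stop("ground truth contains no plaques")
  per_plane <- list(); per_plaque <- list()
  for (tp in truth$plaques) {
    sp <- tp$spec
    arc <- attr(tp$midline, "arc")
    L <- max(arc)
    slices <- sp$slice_start + seq_len(sp$n_slices) - 1L
    areas <- vapply(slices, function(k) {
      g <- gap_profile(sp, arc, k)
      sum((g[-1] + g[-length(g)]) / 2 * diff(arc))   # trapezoid
    }, numeric(1))
    maxw <- max(vapply(slices, function(k) max(gap_profile(sp, arc, k)),
                       numeric(1)))
    runs <- .clipped_runs(sp, L)
    hemi <- if (nrow(runs)) sum(runs$length_nm) else 0
    per_plane[[length(per_plane) + 1L]] <- data.frame(
      plaque_id = sp$plaque_id, slice = slices, length_nm = L,
      area_nm2 = areas, area_per_length_nm = areas / L,
      stringsAsFactors = FALSE)
    per_plaque[[length(per_plaque) + 1L]] <- data.frame(
      plaque_id = sp$plaque_id,
      avg_area_per_length_nm = mean(areas / L),
      max_width_nm = maxw,
      total_plaque_length_nm = L * length(slices),
      n_planes = length(slices),
      total_hemiplaque_length_nm = hemi,
      hemiplaque_fraction_pct = 100 * hemi / L,
      has_hemiplaque = hemi > 0,
      stringsAsFactors = FALSE)
  }
  list(per_plane = do.call(rbind, per_plane),
       per_plaque = do.call(rbind, per_plaque))
}

# orphan runs clipped to [0, L] and merged over both sides (arc union)
.clipped_runs <- function(spec, L) {
  runs <- spec$orphan_runs
  if (is.null(runs) || !nrow(runs)) {
    return(data.frame(side = character(0), start_nm = numeric(0),
                      length_nm = numeric(0)))
  }
  a <- pmax(runs$start_nm, 0)
  b <- pmin(runs$start_nm + runs$length_nm, L)
  keep <- b > a
  if (!any(keep)) {
    return(data.frame(side = character(0), start_nm = numeric(0),
                      length_nm = numeric(0)))
  }
  iv <- data.frame(side = runs$side[keep], a = a[keep], b = b[keep])
  iv <- iv[order(iv$a), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv$a[i] <= merged$b[last]) {
        merged$b[last] <- max(merged$b[last], iv$b[i])
      } else merged <- rbind(merged, iv[i, ])
    }
  }
  data.frame(side = merged$side, start_nm = merged$a,
             length_nm = merged$b - merged$a, stringsAsFactors = FALSE)
}

#' Cut a stack into overlapping montage tiles with known offsets
#'
#' Emulates montage acquisition (e.g. a 1 x 3 scan with 15% overlap) by
#' tiling the stack along its longer lateral axis. Adjacent tiles share
#' exactly `round(overlap_frac * tile_extent)` pixels.
#'
#' @param stack an `em_stack`
#' @param n_tiles number of tiles (>= 2)
#' @param overlap_frac fractional overlap in (0, 1)
#' @return list with `tiles` (list of `em_stack`), `offsets_px` (0-based
#'   pixel offsets along the tiled axis), `axis` ("cols" or "rows"),
#'   `tile_px` and `overlap_px`
#' @export
render_tiles <- function(stack, n_tiles, overlap_frac) {
  stopifnot(inherits(stack, "em_stack"), n_tiles >= 2,
            overlap_frac > 0, overlap_frac < 1)
  g <- stack$geometry
  axis <- if (g$n_cols >= g$n_rows) "cols" else "rows"
  total <- if (axis == "cols") g$n_cols else g$n_rows
  # largest tile width whose strided tiling fits in the stack
  w <- floor(total / (n_tiles - (n_tiles - 1) * overlap_frac)) + 2L
  repeat {
    ov <- round(overlap_frac * w)
    span <- w + (n_tiles - 1L) * (w - ov)
    if (span <= total || w <= 2L) break
    w <- w - 1L
  }
  ov <- round(overlap_frac * w)
  if (ov >= w || w < 2L) stop("tile extent smaller than the requested overlap")
  stride <- w - ov
  offsets <- (seq_len(n_tiles) - 1L) * stride
  tiles <- lapply(offsets, function(o) {
    idx <- (o + 1L):(o + w)
    sub <- if (axis == "cols") stack$intensities[, idx, , drop = FALSE]
    else stack$intensities[idx, , , drop = FALSE]
    tg <- voxel_geometry(n_rows = dim(sub)[1], n_cols = dim(sub)[2],
                         n_slices = dim(sub)[3],
                         dx_nm = g$dx_nm, dy_nm = g$dy_nm, dz_nm = g$dz_nm)
    structure(list(intensities = sub, geometry = tg,
                   bit_depth = stack$bit_depth), class = "em_stack")
  })
  list(tiles = tiles, offsets_px = offsets, axis = axis,
       tile_px = w, overlap_px = ov)
}

#' Reassemble montage tiles by pure translation
#'
#' Places each tile at its known offset; later tiles overwrite the shared
#' overlap region (the tiles agree there by construction).
#' @param tiling output of [render_tiles()]
#' @return an `em_stack`
#' @export
stitch_tiles <- function(tiling) {
  tiles <- tiling$tiles
  w <- tiling$tile_px
  last <- tiling$offsets_px[length(tiling$offsets_px)]
  total <- last + w
  g1 <- tiles[[1]]$geometry
  if (tiling$axis == "cols") {
    out <- array(0, dim = c(g1$n_rows, total, g1$n_slices))
    for (i in seq_along(tiles)) {
      o <- tiling$offsets_px[i]
      out[, (o + 1L):(o + w), ] <- tiles[[i]]$intensities
    }
    gg <- voxel_geometry(g1$n_rows, total, g1$n_slices, g1$dx_nm, g1$dy_nm, g1$dz_nm)
  } else {
    out <- array(0, dim = c(total, g1$n_cols, g1$n_slices))
    for (i in seq_along(tiles)) {
      o <- tiling$offsets_px[i]
      out[(o + 1L):(o + w), , ] <- tiles[[i]]$intensities
    }
    gg <- voxel_geometry(total, g1$n_cols, g1$n_slices, g1$dx_nm, g1$dy_nm, g1$dz_nm)
  }
  structure(list(intensities = out, geometry = gg,
                 bit_depth = tiles[[1]]$bit_depth), class = "em_stack")
}

#' @export
print.em_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("em_stack: %d x %d px x %d slices, %d-bit, %.2g x %.2g x %.2g um\n",
              d[1], d[2], d[3], x$bit_depth,
              d[2] * x$geometry$dx_nm / 1e3, d[1] * x$geometry$dy_nm / 1e3,
              d[3] * x$geometry$dz_nm / 1e3))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  nb <- sum(vapply(x$plaques, function(p) nrow(p$beads), integer(1)))
  cat(sprintf("ground_truth: %d plaque(s), %d beads\n", length(x$plaques), nb))
  invisible(x)
}

#' Combined bead table of a ground-truth object
#' @param truth a `ground_truth`
#' @return data.frame (plaque_id, side, slice, s_nm, x_nm, y_nm, diameter_nm)
#' @export
truth_beads <- function(truth) {
  tabs <- lapply(truth$plaques, `[[`, "beads")
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
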