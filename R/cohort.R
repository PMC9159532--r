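#' Sample a random plaque spec of a given morphology class
#'
#' Draws one gap-junction plaque emulating either the control morphology
#' (two parallel, closely packed bead strings at a narrow, roughly constant
#' intercellular gap) or the plakophilin-2 knockout (PKP2cKO-like)
#' morphology (a wider baseline gap with Gaussian bulges of the
#' intercellular space and, in a subset of plaques, orphan runs where one
#' side's beads are absent — hemiplaques). The midline is a gently curving
#' random ribbon. The accompanying geometry is sized so the plaque, its
#' widest bulge and the bead diameters fit with a safety margin.
#'
#' Morphology defaults (chosen once as the simulated study conditions):
#' control gap ~ N(20, 2.5) nm truncated to [14, 28]; KO baseline
#' ~ N(25, 4) nm truncated to [16, 40] with 1-2 bulges of amplitude
#' 45-75 nm (max width approaching ~100 nm) and s.d. 120-250 nm along the
#' arc; KO orphan runs present in ~60% of plaques covering ~20% of the arc.
#'
#' @param genotype "control" or "pkp2cko"
#' @param length_range_nm plaque arc-length range (uniform draw)
#' @param n_slices_range range of sections spanned (uniform integer draw)
#' @param plaque_id identifier
#' @param orphan_prob probability a KO plaque carries orphan runs
#' @param orphan_cover_frac target fraction of arc covered by orphan runs
#'   when present
#' @return list with elements `spec` ([plaque_spec()]) and `geometry`
#'   ([voxel_geometry()]); randomness is drawn from the current RNG stream
#' @export
sample_plaque <- function(genotype = c("control", "pkp2cko"),
                          length_range_nm = c(1200, 2000),
                          n_slices_range = c(5L, 8L),
                          plaque_id = NULL,
                          orphan_prob = 0.6,
                          orphan_cover_frac = 0.2) {
  genotype <- match.arg(genotype)
  L <- stats::runif(1, length_range_nm[1], length_range_nm[2])
  n_slices <- sample(seq(n_slices_range[1], n_slices_range[2]), 1)

  # random gently-curving midline: heading random walk, control points ~300 nm
  n_cp <- max(3L, ceiling(L / 300) + 1L)
  seg <- L / (n_cp - 1)
  heading <- cumsum(c(stats::runif(1, -pi / 12, pi / 12),
                      stats::rnorm(n_cp - 2, 0, pi / 22)))
  cp <- rbind(c(0, 0), apply(cbind(cos(heading), sin(heading)) * seg, 2, cumsum))

  if (genotype == "control") {
    gap <- min(max(stats::rnorm(1, 20, 2.5), 14), 28)
    bulges <- NULL
    orphans <- NULL
  } else {
    gap <- min(max(stats::rnorm(1, 25, 4), 16), 35)
    nb <- sample(1:2, 1)
    bulges <- data.frame(
      center_nm = stats::runif(nb, 0.2 * L, 0.8 * L),
      amplitude_nm = stats::runif(nb, 45, 75),
      width_nm = stats::runif(nb, 120, 250),
      amp_start_frac = stats::runif(nb, 0.6, 1),
      amp_end_frac = stats::runif(nb, 0.6, 1))
    # rescale so the widest point reaches ~70-100 nm (the bulged-KO
    # morphology), keeping overlapping bulges from stacking beyond it
    target <- stats::runif(1, 70, 100)
    s_probe <- seq(0, L, by = 5)
    peak <- 0
    for (f in c(1, 0)) {   # widest over the z endpoints (linear in z)
      gsum <- rep(0, length(s_probe))
      for (j in seq_len(nb)) {
        zf <- bulges$amp_start_frac[j] + f * (bulges$amp_end_frac[j] - bulges$amp_start_frac[j])
        gsum <- gsum + bulges$amplitude_nm[j] * zf *
          exp(-(s_probe - bulges$center_nm[j])^2 / (2 * bulges$width_nm[j]^2))
      }
      peak <- max(peak, max(gsum))
    }
    if (gap + peak > target && peak > 0) {
      bulges$amplitude_nm <- bulges$amplitude_nm * (target - gap) / peak
    }
    orphans <- NULL
    if (stats::runif(1) < orphan_prob) {
      nr <- sample(1:2, 1)
      lens <- rep(orphan_cover_frac * L / nr, nr)
      starts <- sort(stats::runif(nr, 0, L - max(lens)))
      # push apart if overlapping
      if (nr == 2 && starts[2] < starts[1] + lens[1]) {
        starts[2] <- min(starts[1] + lens[1] + 30, L - lens[2])
      }
      orphans <- data.frame(side = sample(c("A", "B"), nr, replace = TRUE),
                            start_nm = starts, length_nm = lens)
    }
  }

  # provisional spec centered later once the bounding pad is known
  sp <- plaque_spec(control_points = cp, slice_start = 0L, n_slices = n_slices,
                    gap_baseline_nm = gap, bulges = bulges,
                    orphan_runs = orphans, plaque_id = plaque_id)
  mid <- spec_midline(sp)
  maxg <- max(vapply(seq_len(n_slices) - 1L,
                     function(k) max(gap_profile(sp, attr(mid, "arc"), k)),
                     numeric(1)))
  pad <- maxg / 2 + max(sp$bead_diameter_range_nm) + 40
  shift <- pad - c(min(mid[, 1]), min(mid[, 2]))
  sp$control_points <- sweep(cp, 2, shift, `+`)
  ext_x <- diff(range(mid[, 1])) + 2 * pad
  ext_y <- diff(range(mid[, 2])) + 2 * pad
  geom <- voxel_geometry(n_rows = ceiling(ext_y / 3.5) + 2L,
                         n_cols = ceiling(ext_x / 3.5) + 2L,
                         n_slices = n_slices)
  list(spec = sp, geometry = geom)
}

#' Sample a two-genotype cohort of plaques
#'
#' Each plaque occupies its own small stack (one plaque per region of
#' interest), stratified over left/right ventricle labels, mirroring how
#' plaques are sampled per-ROI in an SBF-SEM morphometry study.
#'
#' @param n_per_group plaques per genotype
#' @param seed RNG seed
#' @param ... passed to [sample_plaque()]
#' @return data.frame-like list: one element per plaque with fields
#'   `plaque_id`, `genotype`, `ventricle`, `spec`, `geometry`
#' @export
sample_cohort <- function(n_per_group = 20, seed = 1L, ...) {
  set.seed(as.integer(seed))
  out <- list()
  for (gt in c("control", "pkp2cko")) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", gt, i)
      pl <- sample_plaque(genotype = gt, plaque_id = id, ...)
      out[[id]] <- list(plaque_id = id, genotype = gt,
                        ventricle = if (i %% 2 == 0) "LV" else "RV",
                        spec = pl$spec, geometry = pl$geometry)
    }
  }
  out
}

#' Ground-truth per-plaque metrics of a sampled cohort
#'
#' Runs [truth_metrics()] on every plaque of a [sample_cohort()] draw
#' without rendering images; returns one row per plaque with genotype and
#' ventricle labels attached.
#' @param cohort a [sample_cohort()] result
#' @return data.frame of per-plaque oracle metrics
#' @export
cohort_truth_metrics <- function(cohort) {
  rows <- lapply(cohort, function(entry) {
    truth <- truth_from_specs(list(entry$spec), entry$geometry,
                              seed = 1L, beads = FALSE)
    tm <- truth_metrics(truth)$per_plaque
    tm$genotype <- entry$genotype
    tm$ventricle <- entry$ventricle
    tm
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
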