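# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# one straight constant-gap plaque in a small stack
straight_plaque_fixture <- function(gap = 20, n_slices = 4, seed = 42) {
  cached(sprintf("straight_%g_%d_%d", gap, n_slices, seed), function() {
    g <- voxel_geometry(n_rows = 140, n_cols = 700, n_slices = n_slices)
    sp <- plaque_spec(control_points = cbind(c(100, 800, 1500, 2200),
                                             c(230, 250, 270, 250)),
                      n_slices = n_slices, gap_baseline_nm = gap,
                      plaque_id = "p1")
    c(generate_stack(list(sp), g, seed = seed), list(geometry = g, spec = sp))
  })
}

# one control-like and one KO-like plaque, each in its own stack
two_genotype_fixture <- function(seed = 1) {
  cached(sprintf("two_genotype_%d", seed), function() {
    set.seed(seed)
    ctl <- sample_plaque("control", plaque_id = "ctl",
                         length_range_nm = c(1200, 1600),
                         n_slices_range = c(4L, 5L))
    ko <- sample_plaque("pkp2cko", plaque_id = "ko",
                        length_range_nm = c(1200, 1600),
                        n_slices_range = c(4L, 5L))
    list(control = c(generate_stack(list(ctl$spec), ctl$geometry,
                                    seed = seed + 100),
                     list(geometry = ctl$geometry)),
         pkp2cko = c(generate_stack(list(ko$spec), ko$geometry,
                                    seed = seed + 200),
                     list(geometry = ko$geometry)))
  })
}

# minimal ground_truth wrapper around a hand-made bead table
truth_from_bead_table <- function(beads, geometry) {
  plaques <- lapply(split(beads, beads$plaque_id), function(b) {
    list(spec = NULL, midline = NULL, beads = b)
  })
  structure(list(geometry = geometry, plaques = plaques),
            class = "ground_truth")
}

# full image pipeline on one sampled cohort: merged truth + recovered
# per-plaque tables (used by recovery property and acceptance tests)
recover_cohort <- function(seed, n_per_group = 20) {
  cached(sprintf("recover_%d_%d", seed, n_per_group), function()
    .recover_cohort_impl(seed, n_per_group))
}

.recover_cohort_impl <- function(seed, n_per_group) {
  co <- sample_cohort(n_per_group = n_per_group, seed = seed)
  truth_tab <- cohort_truth_metrics(co)
  rows <- list()
  for (i in seq_along(co)) {
    e <- co[[i]]
    r <- generate_stack(list(e$spec), e$geometry, seed = seed * 1000L + i)
    det <- detect_beads(r$stack)
    rec <- suppressWarnings(reconstruct_plaques(det, e$geometry))
    mm <- measure_plaques(rec)
    if (is.null(mm$per_plaque)) next
    row <- mm$per_plaque[1, ]
    row$plaque_id <- e$plaque_id
    rows[[e$plaque_id]] <- row
  }
  merge(truth_tab, do.call(rbind, rows), by = "plaque_id",
        suffixes = c("_truth", "_rec"))
}

# brute-force single-linkage connected components (quadratic reference)
bf_components <- function(coords, link) {
  n <- nrow(coords)
  adj <- as.matrix(stats::dist(coords)) <= link
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# do two labelings describe the same partition?
same_partition <- function(a, b) {
  all(vapply(split(seq_along(a), a), function(s) length(unique(b[s])) == 1, logical(1))) &&
    all(vapply(split(seq_along(b), b), function(s) length(unique(a[s])) == 1, logical(1)))
}
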