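# build a minimal one-slice profile with hand-placed beads on two sides
mk_profile <- function(s, off_a, off_b, slice = 0L) {
  beads <- data.frame(
    side = rep(c("A", "B"), each = length(s)),
    s_nm = c(s, s), offset_nm = c(off_a, off_b),
    x_nm = c(s, s), y_nm = c(off_a, off_b), ambiguous = FALSE)
  pa <- fit_side_polyline(cbind(s, off_a), s)
  pb <- fit_side_polyline(cbind(s, off_b), s)
  list(slice = slice, midline = NULL, beads = beads,
       side_A = pa, side_B = pb, segment = segment_inner_space(pa, pb))
}

test_that("plane metrics reproduce rectangle and trapezoid geometry", {
  s <- seq(0, 1000, by = 100)
  rect <- mk_profile(s, rep(10, length(s)), rep(-10, length(s)))
  pm <- plane_metrics(rect)
  expect_equal(pm$length_nm, 1000)
  expect_equal(pm$area_nm2, 20000, tolerance = 1e-9)
  expect_equal(pm$area_per_length_nm, 20, tolerance = 1e-9)
  expect_equal(pm$max_width_nm, 20, tolerance = 1e-9)
  trap <- mk_profile(s, seq(10, 20, length.out = length(s)),
                     seq(-10, -20, length.out = length(s)))
  pmt <- plane_metrics(trap)
  expect_equal(pmt$area_per_length_nm, 30, tolerance = 1e-6)
  expect_equal(pmt$max_width_nm, 40, tolerance = 1e-6)
})

test_that("perfectly opposed strings pair completely", {
  s <- seq(0, 1000, by = 50)
  pr <- pair_beads(mk_profile(s, rep(10, length(s)), rep(-10, length(s)))$beads)
  expect_equal(nrow(pr$pairs), length(s))
  expect_equal(nrow(pr$unpaired), 0)
})

test_that("deleting one side's beads leaves the survivors unpaired", {
  s <- seq(0, 1000, by = 50)
  beads <- mk_profile(s, rep(10, length(s)), rep(-10, length(s)))$beads
  drop <- beads$side == "A" & beads$s_nm >= 400 & beads$s_nm <= 700
  beads <- beads[!drop, ]
  pr <- pair_beads(beads)
  un_b <- pr$unpaired[pr$unpaired$side == "B", ]
  expect_true(all(un_b$s_nm >= 400 & un_b$s_nm <= 700))
  expect_equal(nrow(un_b), sum(s >= 400 & s <= 700))
})

test_that("mutual-nearest pairing matches exhaustive search on 4 vs 4 beads", {
  # one B bead offset in arc; optimum is the mutual-nearest assignment
  sa <- c(0, 50, 100, 150)
  sb <- c(2, 48, 135, 152)
  beads <- data.frame(side = rep(c("A", "B"), each = 4),
                      s_nm = c(sa, sb), offset_nm = rep(c(10, -10), each = 4),
                      x_nm = c(sa, sb), y_nm = rep(c(10, -10), each = 4),
                      ambiguous = FALSE)
  pr <- pair_beads(beads, pairing_arc_tol_nm = 30, max_gap_nm = 120)
  # brute force: enumerate all injective assignments of A beads to B beads,
  # keep mutual-nearest consistent ones within tolerance, maximize pairs
  best <- 0; best_set <- NULL
  perms <- as.matrix(expand.grid(rep(list(0:4), 4)))
  for (i in seq_len(nrow(perms))) {
    asn <- perms[i, ]
    used <- asn[asn > 0]
    if (anyDuplicated(used)) next
    ok <- TRUE; npair <- 0
    for (j in 1:4) {
      if (asn[j] == 0) next
      if (abs(sa[j] - sb[asn[j]]) > 30) { ok <- FALSE; break }
      # mutual nearest requirement
      if (which.min(abs(sb - sa[j])) != asn[j] ||
          which.min(abs(sa - sb[asn[j]])) != j) { ok <- FALSE; break }
      npair <- npair + 1
    }
    if (ok && npair > best) { best <- npair; best_set <- asn }
  }
  expect_equal(nrow(pr$pairs), best)
  got <- cbind(pr$pairs$a, pr$pairs$b - 4L)
  want <- cbind(which(best_set > 0), best_set[best_set > 0])
  expect_equal(got[order(got[, 1]), ], want[order(want[, 1]), ],
               ignore_attr = TRUE)
})

test_that("hemiplaque calling honours run-size and run-length thresholds", {
  s <- seq(0, 1000, by = 50)
  full <- mk_profile(s, rep(10, length(s)), rep(-10, length(s)))$beads
  pr <- pair_beads(full)
  expect_equal(nrow(call_hemiplaques(full, pr)), 0)
  # 300 nm orphan run (spacing 50): one segment of length 300 +/- 50
  drop <- full$side == "A" & full$s_nm >= 400 & full$s_nm <= 700
  orphaned <- full[!drop, ]
  pro <- pair_beads(orphaned)
  seg <- call_hemiplaques(orphaned, pro)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$side, "B")
  expect_lt(abs(seg$length_nm - 300), 50 + 1e-9)
  # two orphan beads only: below min_run_beads, no segment
  drop2 <- full$side == "A" & full$s_nm >= 400 & full$s_nm <= 450
  pr2 <- pair_beads(full[!drop2, ])
  expect_equal(nrow(call_hemiplaques(full[!drop2, ], pr2)), 0)
})

test_that("pairing and hemiplaque calls are symmetric in the side labels", {
  s <- seq(0, 1000, by = 50)
  beads <- mk_profile(s, rep(10, length(s)), rep(-10, length(s)))$beads
  drop <- beads$side == "A" & beads$s_nm >= 300 & beads$s_nm <= 600
  beads <- beads[!drop, ]
  swapped <- beads
  swapped$side <- ifelse(beads$side == "A", "B", "A")
  seg1 <- call_hemiplaques(beads, pair_beads(beads))
  seg2 <- call_hemiplaques(swapped, pair_beads(swapped))
  expect_equal(nrow(seg1), nrow(seg2))
  expect_equal(sort(seg1$length_nm), sort(seg2$length_nm))
  expect_equal(nrow(pair_beads(beads)$pairs), nrow(pair_beads(swapped)$pairs))
})

test_that("cohort hemiplaque statistics match hand computations", {
  tab <- data.frame(
    genotype = rep("pkp2cko", 10), ventricle = rep("RV", 10),
    has_hemiplaque = c(rep(TRUE, 4), rep(FALSE, 6)),
    total_hemiplaque_length_nm = c(rep(100, 4), rep(0, 6)),
    total_plaque_length_nm = rep(1000, 10))
  st <- cohort_hemiplaque_stats(tab)
  expect_equal(st$pct_with_hemiplaque, 40)
  # pooled fraction on the toy table {(30, 300), (0, 200)} -> 6%
  toy <- data.frame(genotype = "g", ventricle = "v",
                    has_hemiplaque = c(TRUE, FALSE),
                    total_hemiplaque_length_nm = c(30, 0),
                    total_plaque_length_nm = c(300, 200))
  expect_equal(cohort_hemiplaque_stats(toy)$pooled_length_fraction_pct, 6)
  expect_error(cohort_hemiplaque_stats(tab[0, ]))
})

test_that("measured plaques respect internal consistency invariants", {
  fx <- two_genotype_fixture(seed = 1)
  for (gt in names(fx)) {
    det <- detect_beads(fx[[gt]]$stack)
    rec <- suppressWarnings(reconstruct_plaques(det, fx[[gt]]$geometry))
    mm <- measure_plaques(rec)
    pp <- mm$per_plaque
    expect_true(all(pp$total_hemiplaque_length_nm <= pp$total_plaque_length_nm))
    expect_true(all(pp$hemiplaque_fraction_pct >= 0 &
                      pp$hemiplaque_fraction_pct <= 100))
    rows <- mm$per_plane
    expect_equal(rows$area_per_length_nm, rows$area_nm2 / rows$length_nm,
                 tolerance = 1e-12)
  }
})

test_that("per-plane rows track the ground-truth oracle within 10%", {
  fx <- two_genotype_fixture(seed = 1)
  for (gt in names(fx)) {
    det <- detect_beads(fx[[gt]]$stack)
    rec <- suppressWarnings(reconstruct_plaques(det, fx[[gt]]$geometry))
    mm <- measure_plaques(rec)
    tm <- truth_metrics(fx[[gt]]$truth)
    rec_mean <- mean(mm$per_plane$area_per_length_nm)
    tru_mean <- mean(tm$per_plane$area_per_length_nm)
    expect_lt(abs(rec_mean - tru_mean) / tru_mean, 0.1)
  }
})

test_that("cohort recovery and group ordering hold on a full cohort", {
  # cached when the acceptance suite has already computed this cohort
  both <- recover_cohort(seed = 1, n_per_group = 20)
  for (gt in c("control", "pkp2cko")) {
    d <- both[both$genotype == gt, ]
    rel <- function(m) abs(mean(d[[paste0(m, "_rec")]]) /
                             mean(d[[paste0(m, "_truth")]]) - 1)
    expect_lt(rel("avg_area_per_length_nm"), 0.15)
    expect_lt(rel("max_width_nm"), 0.15)
    dh <- abs(mean(d$hemiplaque_fraction_pct_rec) -
                mean(d$hemiplaque_fraction_pct_truth))
    expect_lt(dh, 5)
  }
  # widened-group ordering in truth and in recovered metrics
  ctl <- both$genotype == "control"
  expect_gt(mean(both$avg_area_per_length_nm_truth[!ctl]),
            mean(both$avg_area_per_length_nm_truth[ctl]))
  expect_gt(mean(both$avg_area_per_length_nm_rec[!ctl]),
            mean(both$avg_area_per_length_nm_rec[ctl]))
})
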