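test_that("clustering separates distant plaques and drops small components", {
  # two compact plaques 1 um apart
  set.seed(3)
  mk <- function(x0) data.frame(slice = rep(0:1, each = 10),
                                x_nm = x0 + rep(seq(0, 450, by = 50), 2),
                                y_nm = 100 + rnorm(20, 0, 5))
  det <- rbind(mk(0), mk(1500))
  cl <- cluster_plaques(det, link_distance_nm = 150, min_beads = 6)
  expect_length(cl, 2)
  expect_equal(sort(vapply(cl, nrow, integer(1))), c(20L, 20L))
  # 5 isolated noise detections: below min_beads
  noise <- data.frame(slice = 0L, x_nm = seq(0, 4000, by = 1000),
                      y_nm = seq(0, 4000, by = 1000))
  expect_length(cluster_plaques(noise, min_beads = 6), 0)
})

test_that("clustering agrees with brute-force connected components", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 150
    det <- data.frame(slice = sample(0:3, n, replace = TRUE),
                      x_nm = runif(n, 0, 2500), y_nm = runif(n, 0, 2500))
    link <- 220
    comp_bf <- bf_components(cbind(det$x_nm, det$y_nm, det$slice * 50), link)
    cl <- cluster_plaques(det, dz_nm = 50, link_distance_nm = link, min_beads = 1)
    comp_pkg <- integer(n)
    for (i in seq_along(cl)) comp_pkg[as.integer(rownames(cl[[i]]))] <- i
    expect_true(same_partition(comp_bf, comp_pkg))
  }
})

test_that("midline of two parallel bead strings is their bisector", {
  set.seed(5)
  xs <- seq(0, 1500, by = 50)
  beads <- rbind(cbind(xs + runif(length(xs), -5, 5), 0),
                 cbind(xs + runif(length(xs), -5, 5), 20))
  mid <- fit_midline(beads)
  # evaluate midline y over the interior bead range
  sel <- mid[, 1] > 100 & mid[, 1] < 1400
  expect_lt(max(abs(mid[sel, 2] - 10)), 2)
})

test_that("semicircular plaque midline recovers the generating arc length", {
  g <- voxel_geometry(500, 800, 1)
  R <- 600
  th <- seq(0, pi, length.out = 9)
  cp <- cbind(1400 + R * cos(th), 200 + R * sin(th))
  sp <- plaque_spec(control_points = cp, n_slices = 1, gap_baseline_nm = 20,
                    plaque_id = "arc")
  truth <- truth_from_specs(list(sp), g, seed = 8)
  tb <- truth_beads(truth)
  mid <- fit_midline(cbind(tb$x_nm, tb$y_nm))
  L_true <- max(attr(spec_midline(sp), "arc"))
  # recovered length over the bead span (the fitted curve is end-extended)
  proj <- plaquemorph:::.project_points(cbind(tb$x_nm, tb$y_nm), mid)
  L_rec <- diff(range(proj$s_nm))
  expect_lt(abs(L_rec - L_true) / L_true, 0.05)
})

test_that("profiles with fewer than 4 beads are skipped with a warning", {
  expect_warning(out <- fit_midline(rbind(c(0, 0), c(50, 0), c(100, 0))),
                 "skipped")
  expect_null(out)
})

test_that("side assignment separates the generating strings", {
  set.seed(6)
  xs <- seq(0, 1500, by = 50)
  up <- cbind(xs + runif(length(xs), -5, 5), 20)
  dn <- cbind(xs + runif(length(xs), -5, 5), 0)
  beads <- rbind(up, dn)
  mid <- fit_midline(beads)
  asg <- assign_sides(beads, mid)
  lab_up <- asg$side[seq_len(nrow(up))]
  lab_dn <- asg$side[nrow(up) + seq_len(nrow(dn))]
  expect_length(unique(lab_up), 1)
  expect_length(unique(lab_dn), 1)
  expect_false(lab_up[1] == lab_dn[1])
})

test_that("mirror flip swaps side labels but not downstream metrics", {
  fx <- straight_plaque_fixture()
  det <- detect_beads(fx$stack)
  rec1 <- suppressWarnings(reconstruct_plaques(det, fx$geometry))
  det2 <- det
  det2$y_nm <- max(det$y_nm) + min(det$y_nm) - det$y_nm
  rec2 <- suppressWarnings(reconstruct_plaques(det2, fx$geometry))
  m1 <- measure_plaques(rec1)$per_plaque
  m2 <- measure_plaques(rec2)$per_plaque
  expect_equal(m2$avg_area_per_length_nm, m1$avg_area_per_length_nm,
               tolerance = 1e-6)
  expect_equal(m2$max_width_nm, m1$max_width_nm, tolerance = 1e-6)
  expect_equal(m2$hemiplaque_fraction_pct, m1$hemiplaque_fraction_pct,
               tolerance = 1e-6)
})

test_that("side polylines are arc-ordered and order-invariant", {
  xy <- rbind(c(0, 0), c(100, 0), c(200, 50))
  s <- c(0, 100, 210)
  p <- fit_side_polyline(xy, s)
  expect_equal(polyline_length(p), 100 + sqrt(100^2 + 50^2))
  # collinear: length equals first-to-last distance
  xyc <- rbind(c(0, 0), c(80, 0), c(160, 0))
  expect_equal(polyline_length(fit_side_polyline(xyc, c(0, 80, 160))), 160)
  # permuted input produces the identical polyline
  perm <- c(3, 1, 2)
  p2 <- fit_side_polyline(xy[perm, ], s[perm])
  expect_equal(unclass(p2), unclass(p))
  # single bead contributes no polyline
  expect_null(fit_side_polyline(xy[1, , drop = FALSE], 0))
})

test_that("inner-space polygon area is exact on rectangle and trapezoid", {
  mk_side <- function(xy, s) { attr(xy, "arc") <- s; xy }
  # rectangle: gap 20 nm over 1000 nm overlap
  a <- mk_side(cbind(seq(0, 1000, by = 100), 10), seq(0, 1000, by = 100))
  b <- mk_side(cbind(seq(0, 1000, by = 100), -10), seq(0, 1000, by = 100))
  seg <- segment_inner_space(a, b)
  expect_equal(seg$area_nm2, 20000, tolerance = 1e-9)
  expect_true(polygon_is_simple(seg$polygon))
  # trapezoid: 20 nm at s=0 to 40 nm at s=1000
  at <- mk_side(cbind(c(0, 1000), c(10, 20)), c(0, 1000))
  bt <- mk_side(cbind(c(0, 1000), c(-10, -20)), c(0, 1000))
  expect_equal(segment_inner_space(at, bt)$area_nm2, 30000, tolerance = 1e-9)
  # trimming: sides with partial overlap are capped on the common interval
  ao <- mk_side(cbind(c(0, 500, 1000), 10), c(0, 500, 1000))
  bo <- mk_side(cbind(c(200, 700, 1200), -10), c(200, 700, 1200))
  seg2 <- segment_inner_space(ao, bo)
  expect_equal(c(seg2$s_lo, seg2$s_hi), c(200, 1000))
  expect_equal(seg2$area_nm2, 800 * 20, tolerance = 1e-9)
})

test_that("rigid motions leave lengths, areas and widths unchanged", {
  fx <- straight_plaque_fixture()
  det <- detect_beads(fx$stack)
  rec1 <- suppressWarnings(reconstruct_plaques(det, fx$geometry))
  m1 <- measure_plaques(rec1)$per_plaque
  th <- 0.31
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- as.matrix(det[, c("x_nm", "y_nm")]) %*% Rm
  det2 <- det
  det2$x_nm <- xy[, 1] - min(xy[, 1]) + 50
  det2$y_nm <- xy[, 2] - min(xy[, 2]) + 50
  rec2 <- suppressWarnings(reconstruct_plaques(det2, fx$geometry))
  m2 <- measure_plaques(rec2)$per_plaque
  expect_equal(m2$avg_area_per_length_nm, m1$avg_area_per_length_nm,
               tolerance = 1e-6)
  expect_equal(m2$max_width_nm, m1$max_width_nm, tolerance = 1e-6)
  expect_equal(m2$total_plaque_length_nm, m1$total_plaque_length_nm,
               tolerance = 1e-6)
})
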