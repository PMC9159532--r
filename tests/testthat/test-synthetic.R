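test_that("empty spec list yields a background-only stack and empty truth", {
  g <- voxel_geometry(64, 64, 2)
  r <- generate_stack(list(), g, seed = 3)
  expect_length(r$truth$plaques, 0)
  # background + mottle + noise only: intensities near the background level
  expect_equal(mean(r$stack$intensities), 0.75, tolerance = 0.02)
  expect_equal(dim(r$stack$intensities), c(64, 64, 2))
})

test_that("constant-gap straight plaque has oracle area/length equal to the gap", {
  fx <- straight_plaque_fixture(gap = 20)
  tm <- truth_metrics(fx$truth)
  expect_equal(tm$per_plane$area_per_length_nm, rep(20, 4), tolerance = 1e-9)
  expect_equal(tm$per_plaque$max_width_nm, 20, tolerance = 1e-9)
  expect_equal(tm$per_plaque$total_hemiplaque_length_nm, 0)
  expect_equal(tm$per_plaque$hemiplaque_fraction_pct, 0)
})

test_that("rendered bead diameters stay inside the silver-enhancement band", {
  fx <- straight_plaque_fixture()
  tb <- truth_beads(fx$truth)
  expect_true(all(tb$diameter_nm >= 10 & tb$diameter_nm <= 20))
  # beads are single-slice objects: diameter never exceeds the section
  expect_true(all(tb$diameter_nm <= fx$geometry$dz_nm))
})

test_that("generation is bit-identical for identical seed and inputs", {
  g <- voxel_geometry(100, 300, 2)
  sp <- plaque_spec(control_points = cbind(c(100, 500, 900), c(160, 180, 160)),
                    n_slices = 2, plaque_id = "p1")
  r1 <- generate_stack(list(sp), g, seed = 9)
  r2 <- generate_stack(list(sp), g, seed = 9)
  expect_identical(r1$stack$intensities, r2$stack$intensities)
  expect_identical(truth_beads(r1$truth), truth_beads(r2$truth))
  r3 <- generate_stack(list(sp), g, seed = 10)
  expect_false(identical(r1$stack$intensities, r3$stack$intensities))
})

test_that("out-of-extent plaques and bad noise are rejected with clear errors", {
  g <- voxel_geometry(40, 40, 2)
  sp <- plaque_spec(control_points = cbind(c(0, 2000), c(70, 70)),
                    n_slices = 2, plaque_id = "too_long")
  expect_error(generate_stack(list(sp), g, seed = 1), "too_long")
  g2 <- voxel_geometry(100, 300, 2)
  sp2 <- plaque_spec(control_points = cbind(c(100, 500, 900), c(160, 180, 160)),
                     n_slices = 2)
  expect_error(generate_stack(list(sp2), g2, seed = 1, noise_sd = 0),
               "noise_sd")
})

test_that("truth oracle: bulge maximum, orphan-run length and clipping", {
  g <- voxel_geometry(200, 700, 3)
  mk <- function(...) plaque_spec(
    control_points = cbind(c(100, 800, 1500, 2200), c(330, 350, 370, 350)),
    n_slices = 3, gap_baseline_nm = 20, plaque_id = "p", ...)
  # Gaussian bulge: amplitude 80 on baseline 20 -> max width 100 at center
  tm <- truth_metrics(truth_from_specs(list(mk(
    bulges = data.frame(center_nm = 1000, amplitude_nm = 80, width_nm = 150))),
    g, beads = FALSE))
  expect_equal(tm$per_plaque$max_width_nm, 100, tolerance = 1e-3)
  # one orphan run of 300 nm -> true total hemiplaque length 300 nm
  tm2 <- truth_metrics(truth_from_specs(list(mk(
    orphan_runs = data.frame(side = "A", start_nm = 400, length_nm = 300))),
    g, beads = FALSE))
  expect_equal(tm2$per_plaque$total_hemiplaque_length_nm, 300, tolerance = 1e-9)
  expect_true(tm2$per_plaque$has_hemiplaque)
  # runs beyond the plaque end are clipped to the arc extent
  L <- max(attr(spec_midline(mk()), "arc"))
  tm3 <- truth_metrics(truth_from_specs(list(mk(
    orphan_runs = data.frame(side = "B", start_nm = L - 100, length_nm = 500))),
    g, beads = FALSE))
  expect_equal(tm3$per_plaque$total_hemiplaque_length_nm, 100, tolerance = 1e-6)
})

test_that("orphan runs remove the named side's beads over the interval", {
  g <- voxel_geometry(200, 700, 2)
  sp <- plaque_spec(
    control_points = cbind(c(100, 800, 1500, 2200), c(330, 350, 370, 350)),
    n_slices = 2, gap_baseline_nm = 20, plaque_id = "p",
    orphan_runs = data.frame(side = "A", start_nm = 500, length_nm = 400))
  tb <- truth_beads(truth_from_specs(list(sp), g, seed = 5))
  a_in <- tb$side == "A" & tb$s_nm >= 500 & tb$s_nm <= 900
  b_in <- tb$side == "B" & tb$s_nm >= 550 & tb$s_nm <= 850
  expect_equal(sum(a_in), 0)
  expect_gt(sum(b_in), 0)
})

test_that("montage tiles share the exact overlap and stitch back losslessly", {
  g <- voxel_geometry(6, 400, 2)
  r <- generate_stack(list(), g, seed = 4)
  # n_tiles = 2, overlap 0.5: second tile's first half is the first's second
  t2 <- render_tiles(r$stack, n_tiles = 2, overlap_frac = 0.5)
  w <- t2$tile_px; ov <- t2$overlap_px
  expect_equal(ov, round(0.5 * w))
  expect_identical(t2$tiles[[2]]$intensities[, 1:ov, ],
                   t2$tiles[[1]]$intensities[, (w - ov + 1):w, ])
  # n_tiles = 3: stitched width = sum of extents minus shared overlaps
  t3 <- render_tiles(r$stack, n_tiles = 3, overlap_frac = 0.15)
  stitched <- stitch_tiles(t3)
  expect_equal(stitched$geometry$n_cols,
               3 * t3$tile_px - 2 * t3$overlap_px)
  orig <- r$stack$intensities[, 1:stitched$geometry$n_cols, ]
  expect_identical(stitched$intensities[, , ], orig)
  small <- structure(list(intensities = array(runif(10), dim = c(2, 5, 1)),
                          geometry = voxel_geometry(2, 5, 1),
                          bit_depth = 8L), class = "em_stack")
  expect_error(render_tiles(small, n_tiles = 4, overlap_frac = 0.9),
               "overlap")
})
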