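test_that("a blank noise stack produces essentially no detections", {
  g <- voxel_geometry(300, 300, 3)
  r <- generate_stack(list(), g, seed = 5)
  det <- detect_beads(r$stack)
  # false-positive budget: < 1 per 100 um^2 of imaged area
  area_um2 <- prod(stack_extent_nm(g)[c("x_nm", "y_nm")]) / 1e6 * g$n_slices
  expect_lt(nrow(det), area_um2 / 100 + 1)
})

test_that("a single rendered bead is found within 5 nm with a sane diameter", {
  g <- voxel_geometry(80, 80, 1)
  img <- matrix(0.75, 80, 80)
  x0 <- 140; y0 <- 137   # nm, off the pixel grid
  sig <- 14 / 2.3548
  for (r in 1:80) for (c in 1:80) {
    d2 <- ((c - 1) * 3.5 - x0)^2 + ((r - 1) * 3.5 - y0)^2
    img[r, c] <- img[r, c] - 0.55 * exp(-d2 / (2 * sig^2))
  }
  set.seed(11)
  img <- img + rnorm(length(img), 0, 0.04)
  stack <- structure(list(intensities = array(img, dim = c(80, 80, 1)),
                          geometry = g, bit_depth = 8L), class = "em_stack")
  det <- detect_beads(stack)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x_nm - x0)^2 + (det$y_nm - y0)^2), 5)
  expect_lt(abs(det$diameter_nm - 14) / 14, 0.4)
})

test_that("precision and recall exceed 0.9 on the two-genotype fixture", {
  fx <- two_genotype_fixture(seed = 1)
  for (gt in names(fx)) {
    det <- detect_beads(fx[[gt]]$stack)
    m <- match_to_truth(det, fx[[gt]]$truth, match_radius_nm = 15)
    expect_gte(m$precision, 0.9)
    expect_gte(m$recall, 0.9)
  }
})

test_that("raising the response threshold never increases detections", {
  fx <- straight_plaque_fixture()
  n_prev <- Inf
  for (thr in c(0.08, 0.12, 0.2, 0.35)) {
    n <- nrow(detect_beads(fx$stack, detection_params(response_threshold = thr)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("no two detections in a slice are closer than the NMS radius", {
  fx <- straight_plaque_fixture()
  det <- detect_beads(fx$stack)
  for (k in unique(det$slice)) {
    d <- det[det$slice == k, ]
    if (nrow(d) < 2) next
    expect_gte(min(stats::dist(cbind(d$x_nm, d$y_nm))), 12)
  }
})

test_that("detection is equivariant under whole-pixel translation", {
  fx <- straight_plaque_fixture()
  arr <- fx$stack$intensities
  shift <- 8L
  arr2 <- array(0.75, dim = dim(arr))
  arr2[, (shift + 1):dim(arr)[2], ] <- arr[, 1:(dim(arr)[2] - shift), ]
  stack2 <- structure(list(intensities = arr2, geometry = fx$geometry,
                           bit_depth = 8L), class = "em_stack")
  d1 <- detect_beads(fx$stack)
  d2 <- detect_beads(stack2)
  d1 <- d1[d1$x_nm < (dim(arr)[2] - shift - 5) * 3.5, ]
  expect_equal(nrow(d2), nrow(d1))
  o1 <- order(d1$slice, round(d1$x_nm), round(d1$y_nm))
  o2 <- order(d2$slice, round(d2$x_nm - shift * 3.5), round(d2$y_nm))
  expect_equal(d2$x_nm[o2] - shift * 3.5, d1$x_nm[o1], tolerance = 0.51)
  expect_equal(d2$y_nm[o2], d1$y_nm[o1], tolerance = 0.51)
})

test_that("an unresolvable diameter band is rejected with advice", {
  g <- voxel_geometry(50, 50, 1, dx_nm = 10, dy_nm = 10)
  stack <- structure(list(intensities = array(0.75, dim = c(50, 50, 1)),
                          geometry = g, bit_depth = 8L), class = "em_stack")
  expect_error(detect_beads(stack), "resample")
})

test_that("greedy truth matching follows the one-to-one convention", {
  g <- voxel_geometry(100, 100, 1)
  tb <- data.frame(plaque_id = "p", side = "A", slice = 0L,
                   s_nm = c(0, 50), x_nm = c(100, 150), y_nm = c(100, 100),
                   diameter_nm = 14)
  truth <- truth_from_bead_table(tb, g)
  # identical coordinates: perfect score
  det <- data.frame(slice = 0L, x_nm = tb$x_nm, y_nm = tb$y_nm,
                    diameter_nm = 14, score = 1)
  m <- match_to_truth(det, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  # no detections: recall 0, precision reported as 0 by convention
  m0 <- match_to_truth(det[0, ], truth)
  expect_equal(m0$precision, 0)
  expect_equal(m0$recall, 0)
  # 3 detections vs 2 truth beads, all within radius: recall 1, precision 2/3
  det3 <- data.frame(slice = 0L, x_nm = c(101, 149, 104), y_nm = c(100, 100, 103),
                     diameter_nm = 14, score = 1)
  m3 <- match_to_truth(det3, truth)
  expect_equal(m3$recall, 1)
  expect_equal(m3$precision, 2 / 3)
  expect_equal(nrow(m3$pairs), 2)
})
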