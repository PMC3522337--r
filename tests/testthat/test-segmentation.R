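# circle contour helper
circle_contour <- function(center, radius, n = 100) {
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(center[1] + radius * sin(t), center[2] + radius * cos(t))
}

test_that("seeding finds exactly the body-enclosed air components", {
  expect_identical(seed_contours(tissue_slice()), list())
  # background air only: everything below threshold touches the border
  expect_identical(seed_contours(tissue_slice(hu = -1000)), list())

  ph <- generate_phantom_pair(small_phantom_spec(noise_sd = 0))
  sl <- ph$insp$voxels[24, , ]          # carina slice: two lungs (+ tiny bronchi)
  seeds <- seed_contours(sl, spacing = c(1, 1))
  expect_length(seeds, 2)
  centers <- t(vapply(seeds, colMeans, numeric(2)))
  truth_cols <- sort(c(48.5 - 22, 48.5 + 22))
  expect_equal(sort(centers[, 2]), truth_cols, tolerance = 0.05)
  # each contour encloses its ellipse centroid (rasterized membership)
  for (i in 1:2) {
    ras <- airtrapcad:::rasterize_contour(seeds[[i]], 96, 96)
    expect_true(ras[48, round(centers[i, 2])])
  }
})

test_that("snake honours iteration bounds and contracts on uniform slices", {
  expect_error(snake_params(max_iter = 0), class = "airtrapcad_parameter_error")
  sl <- tissue_slice()
  c0 <- circle_contour(c(32.5, 32.5), 20)
  one <- evolve_snake(sl, c0, snake_params(conv_tol = Inf))
  expect_equal(attr(one, "iterations"), 1L)
  expect_true(all(is.finite(one)))

  # pure elasticity: enclosed area strictly decreases every iteration
  p1 <- snake_params(alpha = 0.5, beta = 0, kappa_ext = 0, max_iter = 1,
                     conv_tol = 0)
  x <- c0
  areas <- airtrapcad:::contour_area_px(x)
  for (i in 1:5) {
    x <- evolve_snake(sl, x, p1)
    areas <- c(areas, airtrapcad:::contour_area_px(x))
  }
  expect_true(all(diff(areas) < 0))
})

test_that("snake converges onto a synthetic disk edge to sub-pixel accuracy", {
  n <- 128
  y <- matrix(seq_len(n) - (n + 1) / 2, n, n)
  x <- matrix(seq_len(n) - (n + 1) / 2, n, n, byrow = TRUE)
  sl <- matrix(0, n, n)
  sl[y^2 + x^2 <= 40^2] <- -850
  c0 <- circle_contour(c((n + 1) / 2, (n + 1) / 2), 48, 120)
  # finer stopping tolerance than the pipeline default: the contour must
  # first drift 8 px across a flat region before the edge captures it
  ev <- evolve_snake(sl, c0, snake_params(max_iter = 3000, conv_tol = 0.005))
  radii <- sqrt((ev[, 1] - (n + 1) / 2)^2 + (ev[, 2] - (n + 1) / 2)^2)
  expect_lt(mean(abs(radii - 40)), 1)
  # energy trace is non-increasing on every iteration
  expect_true(all(diff(attr(ev, "energy")) <= 1e-9))
})

test_that("snake energy is non-increasing on noisy anatomy too", {
  ph <- generate_phantom_pair(small_phantom_spec(s_xy = 0.85, s_z = 0.9))
  sl <- ph$insp$voxels[24, , ]
  for (c0 in seed_contours(sl, spacing = c(1, 1))) {
    ev <- evolve_snake(sl, c0, snake_params())
    expect_true(all(diff(attr(ev, "energy")) <= 1e-9))
  }
})

test_that("a collapsing contour raises a collapse error", {
  sl <- tissue_slice()
  c0 <- circle_contour(c(32.5, 32.5), 5)   # 78 px^2, just above min_area = 50
  expect_error(
    evolve_snake(sl, c0, snake_params(alpha = 2, beta = 0, kappa_ext = 0,
                                      conv_tol = 0)),
    class = "airtrapcad_collapse_error")
})

test_that("segmentation recovers noiseless two-ellipsoid volumes near-perfectly", {
  ph <- generate_phantom_pair(phantom_spec(noise_sd = 0))
  # render the truth mask alone at lung HU: no body, no airway
  vox <- array(0, dim(ph$truth_insp$voxels))
  vox[ph$truth_insp$voxels == 1L] <- -850
  v <- ct_volume(vox, ph$insp$spacing, "inspiration")
  m <- segment_lungs(v, exclude_airway = FALSE)   # no airway in this volume
  expect_gte(dice_coefficient(m, ph$truth_insp), 0.99)
})

test_that("segmentation fails cleanly on air-only volumes and is deterministic", {
  allair <- ct_volume(array(-1000, c(6, 32, 32)), c(3, 1, 1))
  expect_error(segment_lungs(allair), class = "airtrapcad_segmentation_error")

  ph <- generate_phantom_pair(small_phantom_spec(s_xy = 0.9, s_z = 0.9))
  m1 <- segment_lungs(ph$insp)
  m2 <- segment_lungs(ph$insp)
  expect_identical(m1$voxels, m2$voxels)
})

test_that("physical lung area is stable under 2x in-plane resolution", {
  lo <- small_phantom_spec(noise_sd = 0)
  hi <- phantom_spec(n_slices = 48L, n_rows = 192L, n_cols = 192L,
                     spacing = c(3, 0.5, 0.5),
                     body_semi_axes = c(42, 45), lung_semi_axes = c(60, 26, 15),
                     lung_center_x = 22, bifurcation_slice = 24L,
                     trachea_radius = 5, bronchus_radius = 2.5,
                     bronchus_offset = 3.5, bronchus_length_slices = 6L,
                     noise_sd = 0)
  m_lo <- segment_lungs(generate_phantom_pair(lo)$insp)
  m_hi <- segment_lungs(generate_phantom_pair(hi)$insp)
  a_lo <- lung_area(m_lo, 24)
  a_hi <- lung_area(m_hi, 24)
  expect_lt(abs(a_hi - a_lo) / a_lo, 0.02)
})

test_that("per-lung output labels the two sides", {
  ph <- generate_phantom_pair(small_phantom_spec(noise_sd = 0))
  m <- segment_lungs(ph$insp, per_lung = TRUE)
  sl <- m$voxels[24, , ]
  expect_setequal(unique(as.vector(sl)), c(0L, 1L, 2L))
  expect_true(all(which(sl == 1L, arr.ind = TRUE)[, 2] < 48.5))
  expect_true(all(which(sl == 2L, arr.ind = TRUE)[, 2] > 48.5))
})
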