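make_mask <- function(labels, spacing = c(1, 1, 1)) lesion_mask(labels, spacing)

test_that("largest_residue is the identity on a single component", {
  sp <- lesion_spec(center = c(32, 32, 32), semi_axes = c(10, 8, 6))
  m <- generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 64))
  r <- largest_residue(m)
  expect_identical(r$labels, m$labels)
  expect_identical(attr(r, "n_components"), 1L)
})

test_that("largest_residue keeps only the biggest residue and reports the split", {
  labs <- build_sphere_array(c(64, 64, 64), c(24, 32, 32), 10)
  labs <- build_sphere_array(c(64, 64, 64), c(52, 32, 32), 5, base = labs)
  m <- make_mask(labs)
  n_main <- sum(build_sphere_array(c(64, 64, 64), c(24, 32, 32), 10) == 1L)
  n_sat <- sum(labs == 1L) - n_main
  r <- largest_residue(m)
  expect_identical(attr(r, "n_components"), 2L)
  expect_equal(sum(r$labels == 1L), n_main)
  expect_equal(attr(r, "retained_fraction"), n_main / (n_main + n_sat))
})

test_that("equal-volume tie keeps the smaller lexicographic centroid with a warning", {
  labs <- build_sphere_array(c(64, 64, 64), c(20, 32, 32), 6)
  labs <- build_sphere_array(c(64, 64, 64), c(46, 32, 32), 6, base = labs)
  m <- make_mask(labs)
  expect_warning(r <- largest_residue(m), "tie")
  kept <- which(r$labels == 1L, arr.ind = TRUE)
  expect_lt(mean(kept[, 1]), 32)  # the x-low sphere survives
})

test_that("empty tumor raises the no-measurable-lesion error", {
  m <- make_mask(array(0L, dim = c(8, 8, 8)))
  expect_error(largest_residue(m), "no measurable lesion")
  expect_error(extract_d123(m), "no measurable lesion")
})

test_that("W and PW recover the in-plane ellipse axes within voxel error", {
  sp <- lesion_spec(center = c(48.3, 47.6, 24.2), semi_axes = c(20, 10, 8))
  m <- generate_lesion_mask(sp, c(1, 1, 1), c(96, 96, 48))
  wp <- extract_w_pw(largest_residue(m))
  expect_equal(wp$W, 40, tolerance = 1.5 / 40)
  expect_equal(wp$PW, 20, tolerance = 1.5 / 20)
  expect_lte(wp$PW, wp$W)
})

test_that("W avoids a central cavity and matches the exhaustive oracle", {
  sp <- lesion_spec(center = c(32, 32, 32), semi_axes = c(15, 15, 6),
                    cavity = list(center = c(32, 32, 32), radius = 5))
  m <- largest_residue(generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 64)))
  wp <- extract_w_pw(m, exact = TRUE)
  expect_lte(wp$cavity_crossing_fraction, 0.10)
  # endpoints on tumor voxels
  e <- wp$w_endpoints
  expect_true(all(m$labels[cbind(e[, 1], e[, 2], wp$w_slice_index)] == 1L))
  o <- oracle_w(m, tol = 0.10)
  expect_equal(wp$W, o$len, tolerance = 1e-12)
})

test_that("C-shaped residue chord equals the exhaustive oracle", {
  m <- c_shape_mask()
  wp <- extract_w_pw(m, exact = TRUE)
  o <- oracle_w(m)
  expect_equal(wp$W, o$len, tolerance = 1e-12)
})

test_that("W/PW equal the exhaustive boundary-pair oracle on random lobed masks", {
  set.seed(421)
  for (rep in 1:6) {
    m <- random_blob_mask(n_side = 40L, n_slices = 2L, cavity = rep %% 2 == 0)
    if (!any(m$labels == 1L)) next
    m <- suppressWarnings(largest_residue(m))
    wp <- extract_w_pw(m, exact = TRUE)
    o <- oracle_w(m)
    expect_equal(wp$W, o$len, tolerance = 1e-12)
    if (!is.null(wp$w_endpoints)) {
      e <- wp$w_endpoints
      theta <- atan2(e[2, 2] - e[1, 2], e[2, 1] - e[1, 1])
      op <- oracle_pw(m$labels[, , wp$w_slice_index], 1, 1, theta)
      if (!is.null(op)) expect_equal(wp$PW, op$len, tolerance = 1e-12)
    }
  }
})

test_that("a single-voxel lesion degenerates to the voxel diagonal", {
  labs <- array(0L, dim = c(16, 16, 16))
  labs[8, 8, 8] <- 1L
  wp <- extract_w_pw(make_mask(labs, c(0.8, 0.6, 1)))
  expect_equal(wp$W, sqrt(0.8^2 + 0.6^2))
  expect_equal(wp$PW, wp$W)
  expect_true("degenerate" %in% wp$flags)
})

test_that("D1-D3 recover axis-aligned ellipsoid extents and track rotation", {
  sp <- lesion_spec(center = c(32.4, 31.7, 32.1), semi_axes = c(15, 10, 5))
  m <- generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 64))
  d <- extract_d123(m)
  expect_equal(unname(d), c(30, 20, 10), tolerance = 1 / 10)
  # rotate the array 90 degrees about z: D1 and D2 swap, D3 unchanged
  rot <- aperm(m$labels, c(2, 1, 3))
  d_rot <- extract_d123(make_mask(rot))
  expect_equal(unname(d_rot[c(2, 1)]), unname(d[c(1, 2)]))
  expect_equal(d_rot[["D3"]], d[["D3"]])
})

test_that("D1-D3 on a rotated ellipsoid equal a direct coordinate scan", {
  sp <- lesion_spec(center = c(32, 32, 32), semi_axes = c(14, 9, 6),
                    orientation = c(0.7, 0.3, 1.2))
  m <- generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 64))
  d <- extract_d123(m)
  idx <- which(m$labels == 1L, arr.ind = TRUE)
  expect_equal(unname(d),
               unname(apply(idx, 2, function(v) max(v) - min(v) + 1)))
})

test_that("rotating the mask 90 degrees leaves W, PW unchanged", {
  sp <- lesion_spec(center = c(32, 32, 24), semi_axes = c(14, 8, 6),
                    orientation = c(0.5, 0, 0))
  m <- generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 48))
  wp <- extract_w_pw(m)
  wp_rot <- extract_w_pw(make_mask(aperm(m$labels, c(2, 1, 3))))
  expect_equal(wp_rot$W, wp$W, tolerance = 1e-12)
  expect_equal(wp_rot$PW, wp$PW, tolerance = 1e-12)
})

test_that("segmented volume converts voxels, gaps and residues correctly", {
  labs <- array(0L, dim = c(20, 20, 10))
  labs[1:10, 1:10, 1:10] <- 1L  # 1000 voxels
  m <- make_mask(labs)
  expect_equal(segmented_volume(m), 1.000)
  expect_equal(segmented_volume(m, slice_gap = 1), 2.000)
  expect_error(segmented_volume(m, slice_gap = -0.5), "non-negative")
  # additivity over residues: both components count
  labs2 <- build_sphere_array(c(64, 64, 64), c(22, 32, 32), 10)
  labs2 <- build_sphere_array(c(64, 64, 64), c(52, 32, 32), 5, base = labs2)
  m2 <- make_mask(labs2)
  expect_equal(segmented_volume(m2), sum(labs2 == 1L) / 1000)
  # invariance to component order (relabelling cannot change a sum)
  perm <- labs2[, , dim(labs2)[3]:1]
  expect_equal(segmented_volume(make_mask(perm)), segmented_volume(m2))
})

test_that("size estimates honour the measurability boundaries exactly", {
  thr <- threshold_config()
  s <- size_estimates(c(W = 10, PW = 10, D1 = 10, D2 = 10, D3 = 10), 0.5, thr)
  expect_equal(s$size_3d, 0.5)   # exactly the 3D boundary -> measurable
  expect_equal(s$size_2d, 100)   # exactly the 2D boundary -> measurable
  expect_true(s$measurable_1d && s$measurable_2d && s$measurable_3d)
  s2 <- size_estimates(c(W = 9.9, PW = 9.9, D1 = 9.9, D2 = 9.9, D3 = 9.9),
                       0.4, thr)
  expect_false(any(s2$measurable_1d, s2$measurable_2d, s2$measurable_3d))
  s0 <- size_estimates(c(W = 0, PW = 0, D1 = 0, D2 = 0, D3 = 0), 0, thr)
  expect_equal(s0$size_1d + s0$size_2d + s0$size_3d, 0)
  expect_false(any(s0$measurable_1d, s0$measurable_2d, s0$measurable_3d))
})

test_that("the ellipsoid half-product ratio sits in the documented band", {
  # size_3d / geometric ellipsoid volume -> 3/pi as spacing -> 0
  set.seed(33)
  for (axes in list(c(12, 10, 10), c(16, 13, 11))) {
    ctr <- c(48, 48, 48) + runif(3, -0.5, 0.5)
    sp <- lesion_spec(center = ctr, semi_axes = axes)
    m <- generate_lesion_mask(sp, c(1, 1, 1), c(96, 96, 96))
    mm <- measure_mask(m)
    ratio <- mm$size_3d * 1000 / (4 / 3 * pi * prod(axes))
    expect_gte(ratio, 0.90)
    expect_lte(ratio, 1.00)
  }
})
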