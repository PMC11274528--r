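test_that("voxelized sphere volume matches the analytic volume within 2%", {
  sp <- lesion_spec(center = c(31.6, 32.3, 31.9), semi_axes = c(10, 10, 10))
  m <- generate_lesion_mask(sp, spacing = c(1, 1, 1), shape = c(64, 64, 64))
  v_vox <- sum(m$labels == 1L)
  expect_lt(abs(v_vox / (4 / 3 * pi * 10^3) - 1), 0.02)
})

test_that("a central cavity carves a hole and is labelled separately", {
  sp <- lesion_spec(center = c(32, 32, 32), semi_axes = c(12, 12, 12),
                    cavity = list(center = c(32, 32, 32), radius = 6))
  m <- generate_lesion_mask(sp, spacing = c(1, 1, 1), shape = c(64, 64, 64))
  expect_gt(sum(m$labels == 2L), 0)
  # no tumor voxel strictly inside the cavity
  ctr <- m$labels[33, 33, 33]
  expect_identical(ctr, 2L)
  # the tumor shell survives
  expect_gt(sum(m$labels == 1L), 0)
})

test_that("a cavity as large as the lesion can disconnect the residue", {
  sp <- lesion_spec(center = c(32, 32, 32), semi_axes = c(10, 10, 3),
                    cavity = list(center = c(32, 32, 32), radius = 8))
  m <- generate_lesion_mask(sp, spacing = c(1, 1, 1), shape = c(64, 64, 64))
  comp <- label_components(m)
  expect_gte(max(comp), 1L)
})

test_that("mask generation is deterministic for a fixed spec", {
  sp <- lesion_spec(center = c(30, 34, 32), semi_axes = c(11, 9, 8),
                    orientation = c(0.4, 0.2, 1.1),
                    irregularity_amplitude = 0.25, irregularity_seed = 77L)
  m1 <- generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 64))
  m2 <- generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 64))
  expect_identical(m1$labels, m2$labels)
})

test_that("a lesion exceeding the image bounds errors naming the axis", {
  sp <- lesion_spec(center = c(5, 32, 32), semi_axes = c(10, 8, 8))
  expect_error(generate_lesion_mask(sp, c(1, 1, 1), c(64, 64, 64)),
               "x axis")
  sp_z <- lesion_spec(center = c(32, 32, 60), semi_axes = c(8, 8, 10))
  expect_error(generate_lesion_mask(sp_z, c(1, 1, 1), c(64, 64, 64)),
               "z axis")
})

test_that("grow_spec with dt = 0 is the identity", {
  sp <- lesion_spec(center = c(32, 32, 32), semi_axes = c(12, 10, 8),
                    true_vde = 5)
  expect_identical(grow_spec(sp, 0), sp)
  expect_error(grow_spec(sp, -1), "non-negative")
})

test_that("one year at VDE 8 takes a 30 mm sphere to exactly 38 mm MTD", {
  sp <- lesion_spec(center = c(64, 64, 64), semi_axes = c(15, 15, 15),
                    true_vde = 8)
  expect_equal(true_mtd(sp), 30, tolerance = 1e-12)
  g <- grow_spec(sp, 1)
  expect_equal(true_mtd(g), 38, tolerance = 1e-9)
})

test_that("anisotropic growth moves one axis only, same MTD as isotropic", {
  sp <- lesion_spec(center = c(64, 64, 64), semi_axes = c(14, 11, 9),
                    true_vde = 6)
  iso <- grow_spec(sp, 0.5, mode = "isotropic")
  ani <- grow_spec(sp, 0.5, mode = "anisotropic", axis = 2L)
  expect_gt(ani$semi_axes[2], sp$semi_axes[2])
  expect_equal(ani$semi_axes[c(1, 3)], sp$semi_axes[c(1, 3)])
  expect_equal(true_mtd(ani), true_mtd(iso), tolerance = 1e-12)
  # independent scalar root-finder oracle for the one-axis scale factor:
  # (8 * (s*a) * b * c)^(1/3) = target MTD
  target <- true_mtd(sp) + 6 * 0.5
  f <- function(s) (8 * s * prod(sp$semi_axes))^(1 / 3) - target
  s_star <- uniroot(f, c(1, 10), tol = 1e-12)$root
  expect_equal(ani$semi_axes[2] / sp$semi_axes[2], s_star, tolerance = 1e-8)
})

test_that("ground-truth MTD and volume are consistent on analytic specs", {
  sp <- lesion_spec(center = c(64, 64, 64), semi_axes = c(16, 12, 9),
                    true_vde = 4)
  for (dt in c(0, 0.3, 1, 2.5)) {
    g <- grow_spec(sp, dt, mode = "anisotropic", axis = 3L)
    expect_equal(true_mtd(g), mtd_from_volume(true_volume(g)),
                 tolerance = 1e-9)
    expect_equal(true_mtd(g), true_mtd(sp) + 4 * dt, tolerance = 1e-9)
  }
})

test_that("ellipsoid voxelization error shrinks monotonically with spacing", {
  axes <- c(12, 10, 8)
  errs <- vapply(c(2, 1, 0.5), function(s) {
    half_extent <- 63 * s / 2
    sp <- lesion_spec(center = rep(half_extent, 3) + c(0.37, -0.21, 0.13),
                      semi_axes = axes)
    m <- generate_lesion_mask(sp, spacing = rep(s, 3), shape = c(64, 64, 64))
    v_vox <- sum(m$labels == 1L) * s^3
    abs(v_vox / (4 / 3 * pi * prod(axes)) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2], 0.03)  # 1 mm spacing
})

test_that("cohort generation writes the expected files deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 2, scans_per_patient = c(3, 3),
                       seed = 11L)
  res1 <- generate_cohort(cfg, dir1)
  res2 <- generate_cohort(cfg, dir2)
  expect_equal(nrow(res1$manifest), 6L)
  expect_length(list.files(file.path(dir1, "masks")), 6L)
  expect_identical(readLines(res1$manifest_path),
                   readLines(res2$manifest_path))
  # masks byte-identical too (pure function of config + seed)
  m1 <- read_lesion_mask(file.path(dir1, res1$manifest$mask_path[1]))
  m2 <- read_lesion_mask(file.path(dir2, res2$manifest$mask_path[1]))
  expect_identical(m1$labels, m2$labels)
})

test_that("a degenerate vde_range plants the same true VDE everywhere", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 3, scans_per_patient = c(2, 2),
                       vde_range = c(8, 8), seed = 5L)
  res <- generate_cohort(cfg, dir)
  vdes <- vapply(res$ground_truth, function(p) p$true_vde, numeric(1))
  expect_equal(unname(vdes), rep(8, 3))
})

test_that("ground truth stays consistent after voxelization at 1 mm", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 2, scans_per_patient = c(2, 2),
                       cavity_prob = 0, max_satellites = 0,
                       irregularity_range = c(0, 0), seed = 9L)
  res <- generate_cohort(cfg, dir)
  meas <- run_measure(res$manifest_path)
  for (i in seq_len(nrow(meas))) {
    pid <- meas$patient_id[i]
    gt <- res$ground_truth[[pid]]
    sc <- Filter(function(s) s$scan_date == meas$scan_date[i], gt$scans)[[1]]
    expect_lt(abs(meas$mtd_v[i] / sc$true_mtd_mm - 1), 0.03)
    expect_lt(abs(meas$mtd_3d[i] / sc$true_mtd_mm - 1), 0.06)
  }
})
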