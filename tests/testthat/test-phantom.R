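# Synthetic phantom: bundle painting, mirror-symmetric cases, lesion
# operators.

test_that("a straight bundle along +x paints identical tangent peaks", {
  grid <- grid_spec(c(30, 20, 20))
  cl <- rbind(c(2, 10, 10), c(27, 10, 10))
  f <- synth_bundle(orientation_field(grid), bundle_spec(cl, radius = 2))
  np <- n_peaks(f)
  idx <- which(np > 0, arr.ind = TRUE)
  expect_gt(nrow(idx), 100)
  for (r in sample(nrow(idx), 20)) {
    v <- f$peaks[idx[r, 1], idx[r, 2], idx[r, 3], 1, ]
    expect_equal(abs(v), c(1, 0, 0), tolerance = 1e-6)
  }
  expect_true(all(f$anisotropy[np > 0] == 0.8))
})

test_that("arc bundle peaks match the analytic tangent within 5 degrees", {
  grid <- grid_spec(c(40, 40, 40))
  # circular arc of radius 15 about (20, 10, 20) in the x-y plane
  theta <- seq(0.2, pi - 0.2, length.out = 30)
  cl <- cbind(20 + 15 * cos(theta), 20 - 10 + 15 * sin(theta), 20)
  ctr <- c(20, 10, 20)
  f <- synth_bundle(orientation_field(grid), bundle_spec(cl, radius = 2))
  idx <- which(n_peaks(f) > 0, arr.ind = TRUE) - 1
  # stay clear of the arc ends, where the tangent is one-sided
  ang_pos <- atan2(idx[, 2] - 10, idx[, 1] - 20)
  idx <- idx[ang_pos > 0.35 & ang_pos < pi - 0.35, , drop = FALSE]
  for (r in sample(nrow(idx), 30)) {
    p <- drop(voxel_to_world(grid, idx[r, , drop = FALSE]))
    radial <- p - ctr; radial[3] <- 0
    tangent <- c(-radial[2], radial[1], 0)
    tangent <- tangent / sqrt(sum(tangent^2))
    v <- f$peaks[idx[r, 1] + 1, idx[r, 2] + 1, idx[r, 3] + 1, 1, ]
    ang <- acos(min(abs(sum(v * tangent)), 1)) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("overlapping orthogonal bundles give two peaks in shared voxels", {
  grid <- grid_spec(c(24, 24, 24))
  f <- orientation_field(grid)
  f <- synth_bundle(f, bundle_spec(rbind(c(2, 12, 12), c(21, 12, 12)), radius = 2))
  f <- synth_bundle(f, bundle_spec(rbind(c(12, 2, 12), c(12, 21, 12)), radius = 2))
  expect_equal(n_peaks(f)[13, 13, 13], 2)
  v1 <- f$peaks[13, 13, 13, 1, ]; v2 <- f$peaks[13, 13, 13, 2, ]
  expect_lt(abs(sum(v1 * v2)), 0.1)
})

test_that("curvature and bounds violations are rejected", {
  grid <- grid_spec(c(20, 20, 20))
  expect_error(synth_bundle(orientation_field(grid),
                            bundle_spec(rbind(c(5, 10, 10), c(40, 10, 10)),
                                        radius = 2)), "exits the grid")
  hairpin <- rbind(c(4, 10, 10), c(14, 10, 10), c(4, 10.5, 10))
  expect_error(synth_bundle(orientation_field(grid),
                            bundle_spec(hairpin, radius = 1.5)), "60 degrees")
})

test_that("a zero-magnitude lesion leaves the case exactly mirror-symmetric", {
  case <- cached_phantom("infiltrate", 0, 5)
  f <- case$field
  m <- mirror_field(f)
  expect_equal(m$peaks, f$peaks)
  expect_equal(m$anisotropy, f$anisotropy)
  # wm and brain masks also symmetric
  expect_equal(mirror_sagittal(case$wm_mask)$data, case$wm_mask$data)
})

test_that("phantom generation is deterministic given the seed", {
  a <- reference_phantom("infiltrate", magnitude = 0.5, rng_seed = 9)
  b <- reference_phantom("infiltrate", magnitude = 0.5, rng_seed = 9)
  expect_identical(a$field$peaks, b$field$peaks)
  expect_identical(a$field$anisotropy, b$field$anisotropy)
  expect_identical(a$truth, b$truth)
  c2 <- reference_phantom("infiltrate", magnitude = 0.5, rng_seed = 10)
  expect_false(identical(a$field$anisotropy, c2$field$anisotropy))
})

test_that("full infiltration removes every bundle peak inside the lesion", {
  case <- reference_phantom("infiltrate", magnitude = 1, rng_seed = 4)
  inside <- case$lesion_mask$data
  expect_equal(sum(n_peaks(case$field)[inside]), 0)
  expect_true(all(case$field$anisotropy[inside & case$wm_mask$data] < 0.2))
  # zero fraction is the identity
  case0 <- reference_phantom("infiltrate", magnitude = 0, rng_seed = 4)
  expect_equal(sum(case0$truth$healthy_fibers), sum(case0$truth$lesioned_fibers))
})

test_that("infiltration deletes a binomial fraction of crossing fibers", {
  # a fat straight bundle gives ~200 fiber lines through the lesion
  grid <- grid_spec(c(40, 48, 40))
  cl <- rbind(c(30, 3, 20), c(30, 44, 20))
  les <- lesion_spec(c(30, 24, 20), radius = 9, mode = "infiltrate",
                     magnitude = 0.5)
  case <- make_symmetric_case(grid, list(bundle_spec(cl, radius = 8)), les,
                              rng_seed = 22)
  n_cross <- case$field$infiltration$per_bundle[[1]]$n_crossing
  n_del <- case$field$infiltration$per_bundle[[1]]$n_deleted
  expect_gt(n_cross, 150)
  # 99% binomial interval around 0.5
  band <- qbinom(c(0.005, 0.995), n_cross, 0.5)
  expect_gte(n_del, band[1])
  expect_lte(n_del, band[2])
})

test_that("an 8 mm push detours tracked streamlines by at least 6 mm", {
  grid <- grid_spec(c(48, 48, 48))
  cl <- rbind(c(38, 3, 24), c(38, 44, 24))   # 6 mm beside the lesion center
  f0 <- synth_bundle(orientation_field(grid), bundle_spec(cl, radius = 3))
  les0 <- lesion_spec(c(32, 24, 24), radius = 10, mode = "displace", magnitude = 0)
  expect_identical(lesion_displace(f0, les0)$peaks, f0$peaks)

  les <- lesion_spec(c(32, 24, 24), radius = 10, mode = "displace", magnitude = 8)
  f1 <- lesion_displace(f0, les)
  brain <- full_brain(grid)
  s <- propagate(f1, brain, c(38, 5, 24), c(0, 1, 0))
  expect_gt(max(s$points[, 2]) - min(s$points[, 2]), 30)  # spans the lesion
  d_to_center <- sqrt(rowSums(sweep(s$points, 2, c(32, 24, 24))^2))
  # original closest approach is 6 mm; the push must add at least 6 more
  expect_gte(min(d_to_center), 6 + 6)

  # excessive magnitude breaks invertibility
  expect_error(lesion_displace(f0, lesion_spec(c(32, 24, 24), radius = 3,
                                               mode = "displace", magnitude = 8)),
               "invertible")
})

test_that("a far-field push preserves the bundle-carrying voxel count", {
  grid <- grid_spec(c(48, 48, 48))
  cl <- rbind(c(37, 3, 24), c(37, 44, 24))   # 13 mm from the lesion center
  f0 <- synth_bundle(orientation_field(grid), bundle_spec(cl, radius = 3))
  les <- lesion_spec(c(24, 24, 24), radius = 10, mode = "displace", magnitude = 2)
  f1 <- lesion_displace(f0, les)
  n0 <- sum(n_peaks(f0) > 0)
  n1 <- sum(n_peaks(f1) > 0)
  expect_lt(abs(n1 - n0) / n0, 0.1)
})

test_that("phantom cases round-trip through the on-disk directory format", {
  case <- cached_phantom("infiltrate", 0.5, 3)
  dir <- file.path(tempdir(), "phantom_case_rt")
  write_phantom_case(case, dir)
  back <- read_phantom_case(dir)
  expect_equal(back$field$peaks, case$field$peaks, tolerance = 1e-6)
  expect_equal(back$lesion_mask$data, case$lesion_mask$data)
  expect_equal(back$truth$healthy_fibers, case$truth$healthy_fibers)
  expect_equal(back$rng_seed, case$rng_seed)
})
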