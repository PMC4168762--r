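# Mask model and ROI geometry: mirroring, intersection, resampling,
# dilations, spheres, physical volume.

test_that("sagittal mirroring maps indices across the mid-plane and is an involution", {
  grid <- grid_spec(c(64, 64, 64))
  m <- empty_mask(grid)
  m$data[3 + 1, 10 + 1, 10 + 1] <- TRUE
  mm <- mirror_sagittal(m)
  expect_equal(which(mm$data, arr.ind = TRUE) - 1L,
               matrix(c(60L, 10L, 10L), 1, 3), ignore_attr = TRUE)

  # a mask symmetric about the mid-plane is a fixed point
  sym <- empty_mask(grid)
  sym$data[c(31, 34), 5, 5] <- TRUE  # indices 30 and 33 mirror to each other
  expect_equal(mirror_sagittal(sym)$data, sym$data)

  set.seed(42)
  g16 <- grid_spec(c(16, 16, 16))
  for (i in 1:50) {
    m <- random_mask(g16)
    expect_equal(mirror_sagittal(mirror_sagittal(m))$data, m$data)
    expect_equal(sum(mirror_sagittal(m)$data), sum(m$data))
  }
})

test_that("mask intersection is voxelwise AND with algebraic properties", {
  g <- grid_spec(c(16, 16, 16))
  set.seed(7)
  a <- random_mask(g); b <- random_mask(g)
  full <- full_brain(g)
  expect_equal(mask_intersect(a, full)$data, a$data)

  disj_a <- empty_mask(g); disj_a$data[1:3, , ] <- TRUE
  disj_b <- empty_mask(g); disj_b$data[10:12, , ] <- TRUE
  expect_equal(sum(mask_intersect(disj_a, disj_b)$data), 0)

  # brute-force voxel loop oracle
  count <- 0L
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    if (a$data[i, j, k] && b$data[i, j, k]) count <- count + 1L
  }
  expect_equal(sum(mask_intersect(a, b)$data), count)

  # commutative, idempotent
  expect_equal(mask_intersect(a, b)$data, mask_intersect(b, a)$data)
  expect_equal(mask_intersect(a, a)$data, a$data)

  g2 <- grid_spec(c(16, 16, 15))
  expect_error(mask_intersect(a, random_mask(g2)), "incompatible")
})

test_that("conservative resampling shrinks at boundaries and is monotone in threshold", {
  g <- grid_spec(c(20, 20, 20))
  m <- empty_mask(g)
  m$data[5:15, 5:15, 5:15] <- TRUE
  expect_equal(resample_mask(m, g, 0.9)$data, m$data)  # identity transform

  # half-voxel shift: boundary layer interpolates to 0.5 < 0.9 and is dropped
  g_shift <- grid_spec(c(20, 20, 20), affine = {
    A <- diag(4); A[1, 4] <- 0.5; A
  })
  r <- resample_mask(m, g_shift, 0.9)
  expect_lt(sum(r$data), sum(m$data))
  # interior survives
  expect_true(all(r$data[6:13, 6:14, 6:14]))

  set.seed(11)
  for (i in 1:20) {
    m <- random_mask(g, p = 0.4)
    shift <- runif(3, -1, 1)
    gs <- grid_spec(c(20, 20, 20), affine = {
      A <- diag(4); A[1:3, 4] <- shift; A
    })
    n90 <- sum(resample_mask(m, gs, 0.9)$data)
    n50 <- sum(resample_mask(m, gs, 0.5)$data)
    expect_lte(n90, n50)
  }
  expect_error(resample_mask(m, g, 0), "threshold")
})

test_that("mm dilation matches an exhaustive center-distance scan", {
  g <- grid_spec(c(45, 45, 45))
  m <- empty_mask(g)
  m$data[23, 23, 23] <- TRUE
  expect_equal(dilate_mm(m, 0)$data, m$data)

  d20 <- dilate_mm(m, 20)
  # brute-force digital ball
  count <- 0L
  for (i in 0:44) for (j in 0:44) for (k in 0:44) {
    if ((i - 22)^2 + (j - 22)^2 + (k - 22)^2 <= 400 + 1e-9) count <- count + 1L
  }
  expect_equal(sum(d20$data), count)

  # anisotropic voxels measured in world mm
  ga <- grid_spec(c(31, 31, 21), voxel_size = c(1, 1, 1.5))
  ma <- empty_mask(ga)
  ma$data[16, 16, 11] <- TRUE
  da <- dilate_mm(ma, 6)
  idx <- which(da$data, arr.ind = TRUE) - 1
  w <- voxel_to_world(ga, idx)
  ctr <- drop(voxel_to_world(ga, c(15, 15, 10)))
  expect_true(all(sqrt(colSums((t(w) - ctr)^2)) <= 6 + 1e-6))
  expect_equal(sum(da$data), sum(outer(outer(((-15:15))^2, ((-15:15))^2, "+"),
                                       (1.5 * (-10:10))^2, "+") <= 36 + 1e-9))

  set.seed(3)
  for (i in 1:5) {
    m <- random_mask(grid_spec(c(12, 12, 12)), p = 0.05)
    if (!any(m$data)) next
    big <- dilate_mm(m, 5)
    expect_true(all(m$data <= big$data))  # superset
    # world-metric dilation dominates composed digital dilations
    comp <- dilate_mm(dilate_mm(m, 2), 3)
    expect_true(all(comp$data <= dilate_mm(m, 5)$data + 0))
  }
})

test_that("factor dilation reaches the target count with 6-connected steps", {
  g <- grid_spec(c(20, 20, 20))
  cube <- empty_mask(g)
  cube$data[8:12, 8:12, 8:12] <- TRUE
  expect_equal(dilate_to_factor(cube, 1)$data, cube$data)

  out <- dilate_to_factor(cube, 1.2)
  expect_gte(sum(out$data), 150)
  # reference: one 6-connected dilation step computed by brute force
  ref <- cube$data
  step1 <- ref
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (ref[i, j, k]) next
    nb <- FALSE
    if (i > 1) nb <- nb || ref[i - 1, j, k]
    if (i < 20) nb <- nb || ref[i + 1, j, k]
    if (j > 1) nb <- nb || ref[i, j - 1, k]
    if (j < 20) nb <- nb || ref[i, j + 1, k]
    if (k > 1) nb <- nb || ref[i, j, k - 1]
    if (k < 20) nb <- nb || ref[i, j, k + 1]
    step1[i, j, k] <- nb
  }
  expect_lte(sum(out$data), sum(step1))
  expect_equal(out$data, step1)

  set.seed(9)
  for (i in 1:5) {
    m <- random_mask(grid_spec(c(10, 10, 10)), p = 0.1)
    if (!any(m$data)) next
    expect_true(all(m$data <= dilate_to_factor(m, 1.2)$data))
  }
  expect_error(dilate_to_factor(empty_mask(g)), "empty")
})

test_that("sphere targets contain exactly the voxels within the world radius", {
  g <- grid_spec(c(21, 21, 21))
  tiny <- sphere_mask(g, c(10, 10, 10), diameter = 0.5)
  expect_equal(which(tiny$data, arr.ind = TRUE) - 1L,
               matrix(c(10L, 10L, 10L), 1, 3), ignore_attr = TRUE)

  s10 <- sphere_mask(g, c(10, 10, 10), diameter = 10)
  count <- 0L
  for (i in 0:20) for (j in 0:20) for (k in 0:20) {
    if ((i - 10)^2 + (j - 10)^2 + (k - 10)^2 <= 25 + 1e-9) count <- count + 1L
  }
  expect_equal(sum(s10$data), count)

  # shift by whole voxels leaves the count unchanged while interior
  s2 <- sphere_mask(g, c(7, 9, 12), diameter = 10)
  expect_equal(sum(s2$data), sum(s10$data))
  expect_error(sphere_mask(g, c(50, 10, 10)), "outside")
})

test_that("physical mask volume accounts for voxel size", {
  g <- grid_spec(c(20, 20, 20), voxel_size = c(1, 1, 1.5))
  expect_equal(mask_volume_cm3(empty_mask(g)), 0)
  m <- empty_mask(g)
  m$data[1:10, 1:10, 1:10] <- TRUE  # 1000 voxels at 1.5 mm^3
  expect_equal(mask_volume_cm3(m), 1.5)

  set.seed(5)
  r <- random_mask(g)
  expect_equal(mask_volume_cm3(r), sum(r$data) * 1.5 / 1000)
  expect_equal(mask_volume_cm3(mirror_sagittal(r)), mask_volume_cm3(r))
})

test_that("NIfTI round trip preserves data and affine", {
  g <- grid_spec(c(12, 14, 10), voxel_size = c(1, 1, 1.5),
                 affine = rbind(c(1, 0, 0, -5), c(0, 1, 0, -7),
                                c(0, 0, 1.5, -4), c(0, 0, 0, 1)))
  set.seed(21)
  m <- random_mask(g)
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(m, f)
  m2 <- read_mask_nifti(f)
  expect_equal(m2$data, m$data)
  expect_equal(m2$grid$affine, g$affine, tolerance = 1e-6, ignore_attr = TRUE)

  sv <- scalar_volume(g, array(runif(prod(g$shape)), g$shape))
  f2 <- tempfile(fileext = ".nii.gz")
  write_nifti(sv, f2)
  sv2 <- read_scalar_nifti(f2)
  expect_equal(sv2$data, sv$data, tolerance = 1e-6)
})
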