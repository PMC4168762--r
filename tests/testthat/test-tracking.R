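# Deterministic and probabilistic streamline propagation, pruning,
# connection probability, TrackVis I/O.

test_that("a uniform field yields a straight streamline spanning the slab", {
  grid <- grid_spec(c(40, 20, 20))
  brain <- full_brain(grid)
  f <- uniform_field(grid, c(1, 0, 0))
  s <- propagate(f, brain, c(20, 10, 10), c(1, 0, 0))
  expect_setequal(s$termination_reasons, "out_of_brain")
  # spans the 40 mm slab
  expect_gt(max(s$points[, 1]) - min(s$points[, 1]), 37)
  expect_lt(max(abs(s$points[, 2] - 10)), 1e-6)
  expect_lt(max(abs(s$points[, 3] - 10)), 1e-6)
  # consecutive-point spacing equals the step
  d <- sqrt(rowSums(diff(s$points)^2))
  expect_true(all(abs(d - 0.5) < 1e-6))
})

test_that("a bend of more than 60 degrees across a voxel stops tracking", {
  grid <- grid_spec(c(40, 20, 20))
  brain <- full_brain(grid)
  bend_field <- function(angle_deg) {
    pk <- array(0, c(grid$shape, 3, 3))
    anis <- array(0.8, grid$shape)
    a <- angle_deg * pi / 180
    for (c in 1:3) {
      pk[1:20, , , 1, c] <- c(1, 0, 0)[c]
      pk[21:40, , , 1, c] <- c(cos(a), sin(a), 0)[c]
    }
    orientation_field(grid, pk, anis)
  }
  s61 <- propagate(bend_field(61), brain, c(10, 10, 10), c(1, 0, 0),
                   tracking_params())
  expect_true("sharp_turn" %in% s61$termination_reasons)
  # forward half stops at the bend boundary
  expect_lt(max(s61$points[, 1]), 21.5)

  s59 <- propagate(bend_field(59), brain, c(10, 10, 10), c(1, 0, 0))
  expect_false("sharp_turn" %in% s59$termination_reasons)
  expect_gt(max(s59$points[, 1]), 25)
})

test_that("anisotropy below 0.2 stops tracking at that voxel", {
  grid <- grid_spec(c(40, 20, 20))
  brain <- full_brain(grid)
  f <- uniform_field(grid, c(1, 0, 0))
  f$anisotropy[26:40, , ] <- 0.19
  s <- propagate(f, brain, c(10, 10, 10), c(1, 0, 0))
  expect_true("low_anisotropy" %in% s$termination_reasons)
  # terminal point lies in the first low-anisotropy voxel
  end <- s$points[which.max(s$points[, 1]), ]
  expect_true(end[1] >= 24.5 && end[1] <= 26)
})

test_that("endpoints agree with a 10x-finer-step reference integrator on a curved field", {
  grid <- grid_spec(c(40, 40, 20))
  brain <- full_brain(grid)
  theta <- seq(0.15, pi - 0.15, length.out = 40)
  cl <- cbind(20 + 14 * cos(theta), 6 + 14 * sin(theta), 10)
  f <- synth_bundle(orientation_field(grid), bundle_spec(cl, radius = 2.5))
  seeds <- rbind(c(20, 20, 10), c(15, 19, 10), c(25, 18.5, 10))
  for (i in seq_len(nrow(seeds))) {
    sv <- round(seeds[i, ])
    dir0 <- f$peaks[sv[1] + 1, sv[2] + 1, sv[3] + 1, 1, ]
    if (sum(dir0^2) == 0) next
    s <- propagate(f, brain, seeds[i, ], dir0)
    ref_f <- reference_propagate(f, brain, seeds[i, ], dir0, step = 0.05)
    ref_b <- reference_propagate(f, brain, seeds[i, ], -dir0, step = 0.05)
    ends <- rbind(s$points[1, ], s$points[nrow(s$points), ])
    ref_ends <- rbind(ref_b[nrow(ref_b), ], ref_f[nrow(ref_f), ])
    # match ends pairwise (order may differ); within 1 voxel
    d1 <- sqrt(sum((ends[1, ] - ref_ends[1, ])^2)) +
          sqrt(sum((ends[2, ] - ref_ends[2, ])^2))
    d2 <- sqrt(sum((ends[1, ] - ref_ends[2, ])^2)) +
          sqrt(sum((ends[2, ] - ref_ends[1, ])^2))
    expect_lt(min(d1, d2) / 2, 1)
  }
})

test_that("one streamline is launched per seed voxel per peak", {
  grid <- grid_spec(c(24, 24, 24))
  brain <- full_brain(grid)
  f <- orientation_field(grid)
  f <- synth_bundle(f, bundle_spec(rbind(c(2, 12, 12), c(21, 12, 12)), radius = 3))
  f <- synth_bundle(f, bundle_spec(rbind(c(12, 2, 12), c(12, 21, 12)), radius = 3))
  # pick 10 crossing voxels with exactly 2 peaks
  np <- n_peaks(f)
  idx <- which(np == 2, arr.ind = TRUE) - 1
  expect_gte(nrow(idx), 10)
  seed <- empty_mask(grid)
  sel <- idx[1:10, , drop = FALSE]
  seed$data[sel + 1] <- TRUE
  seed$data[cbind(sel[, 1] + 1, sel[, 2] + 1, sel[, 3] + 1)] <- TRUE
  t <- track_from_mask(f, brain, seed, tracking_params(min_length = 0))
  expect_equal(t$provenance$n_launched, 20)

  # seeds without peaks launch nothing
  outside <- empty_mask(grid)
  outside$data[2, 2, 2] <- TRUE
  t0 <- track_from_mask(f, brain, outside, tracking_params())
  expect_equal(n_streamlines(t0), 0)

  # deterministic: identical tractograms on repeat
  t2 <- track_from_mask(f, brain, seed, tracking_params(min_length = 0))
  expect_identical(lapply(t$streamlines, `[[`, "points"),
                   lapply(t2$streamlines, `[[`, "points"))
})

test_that("whole-brain tracking enumerates every (voxel, peak) launch", {
  grid <- grid_spec(c(30, 20, 20))
  brain <- full_brain(grid)
  f <- synth_bundle(orientation_field(grid),
                    bundle_spec(rbind(c(2, 10, 10), c(27, 10, 10)), radius = 2.5))
  t <- track_whole_brain(f, brain, tracking_params(min_length = 0))
  n_launch_expected <- sum(n_peaks(f))
  expect_equal(t$provenance$n_launched, n_launch_expected)
  expect_equal(n_streamlines(t) + t$provenance$n_discarded, n_launch_expected)

  # superset property vs any mask seeding
  seed <- empty_mask(grid)
  seed$data[10:12, 9:11, 9:11] <- TRUE
  tm <- track_from_mask(f, brain, mask_intersect(seed, peak_support_mask(f)),
                        tracking_params(min_length = 0))
  expect_gte(n_streamlines(t), n_streamlines(tm))

  empty <- track_whole_brain(orientation_field(grid), brain, tracking_params())
  expect_equal(n_streamlines(empty), 0)
})

test_that("endpoint pruning keeps exactly the streamlines connecting both ROIs", {
  grid <- grid_spec(c(30, 20, 20))
  brain <- full_brain(grid)
  f <- synth_bundle(orientation_field(grid),
                    bundle_spec(rbind(c(2, 10, 10), c(27, 10, 10)), radius = 2.5))
  t <- track_whole_brain(f, brain, tracking_params())
  roi_a <- sphere_mask(grid, c(2, 10, 10), diameter = 8)
  roi_b <- sphere_mask(grid, c(27, 10, 10), diameter = 8)
  pruned <- prune_by_endpoints(t, roi_a, roi_b)

  # brute-force endpoint test over all streamlines
  expected <- sum(vapply(t$streamlines, function(s) {
    va <- round(drop(world_to_voxel(grid, s$points[1, , drop = FALSE])))
    vb <- round(drop(world_to_voxel(grid, s$points[nrow(s$points), , drop = FALSE])))
    ina <- function(v, m) all(v >= 0) && all(v < grid$shape) &&
      m$data[v[1] + 1, v[2] + 1, v[3] + 1]
    (ina(va, roi_a) && ina(vb, roi_b)) || (ina(va, roi_b) && ina(vb, roi_a))
  }, logical(1)))
  expect_equal(n_streamlines(pruned), expected)
  expect_gt(n_streamlines(pruned), 0)

  # idempotent; empty ROI prunes everything
  expect_equal(n_streamlines(prune_by_endpoints(pruned, roi_a, roi_b)),
               n_streamlines(pruned))
  expect_equal(n_streamlines(prune_by_endpoints(t, roi_a, empty_mask(grid))), 0)
})

test_that("probabilistic tracking converges to deterministic for large kappa", {
  grid <- grid_spec(c(30, 14, 14))
  brain <- full_brain(grid)
  f <- synth_bundle(orientation_field(grid),
                    bundle_spec(rbind(c(2, 7, 7), c(27, 7, 7)), radius = 1.5))
  params_det <- tracking_params(min_length = 0)
  t_det <- track_whole_brain(f, brain, params_det)
  params_stiff <- tracking_params(min_length = 0, kappa = 1e6)
  t_prob <- probabilistic_tracts(f, brain, params_stiff, iterations = 2, rng_seed = 5)
  expect_equal(n_streamlines(t_prob) + t_prob$provenance$n_discarded,
               2 * t_det$provenance$n_launched)

  # endpoints of each probabilistic streamline within 1 voxel of the
  # deterministic endpoints from the same launch
  det_ends <- lapply(t_det$streamlines, function(s)
    rbind(s$points[1, ], s$points[nrow(s$points), ]))
  key <- function(s) paste(s$seed_voxel, collapse = "_")
  det_by_seed <- stats::setNames(det_ends, vapply(t_det$streamlines, key, ""))
  for (s in t_prob$streamlines[seq(1, n_streamlines(t_prob), by = 7)]) {
    ref <- det_by_seed[[key(s)]]
    ends <- rbind(s$points[1, ], s$points[nrow(s$points), ])
    d1 <- max(sqrt(rowSums((ends - ref)^2)))
    d2 <- max(sqrt(rowSums((ends - ref[2:1, ])^2)))
    expect_lt(min(d1, d2), 1)
  }

  # seed reproducibility
  t_a <- probabilistic_tracts(f, brain, tracking_params(kappa = 50),
                              iterations = 3, rng_seed = 11)
  t_b <- probabilistic_tracts(f, brain, tracking_params(kappa = 50),
                              iterations = 3, rng_seed = 11)
  expect_identical(lapply(t_a$streamlines, `[[`, "points"),
                   lapply(t_b$streamlines, `[[`, "points"))
})

test_that("connection probability is the per-voxel streamline visitation fraction", {
  grid <- grid_spec(c(30, 20, 20))
  brain <- full_brain(grid)
  f <- synth_bundle(orientation_field(grid),
                    bundle_spec(rbind(c(2, 10, 10), c(27, 10, 10)), radius = 2.5))
  one <- track_from_mask(f, brain, {
    m <- empty_mask(grid); m$data[15, 11, 11] <- TRUE; m
  }, tracking_params())
  expect_equal(n_streamlines(one), 1)
  m1 <- connection_probability_map(one, grid)
  expect_setequal(unique(as.vector(m1$data)), c(0, 1))

  # two spatially disjoint streamlines -> 0.5 on each path
  f2 <- synth_bundle(f, bundle_spec(rbind(c(2, 10, 16), c(27, 10, 16)), radius = 1))
  seeds <- empty_mask(grid)
  seeds$data[15, 11, 11] <- TRUE
  seeds$data[15, 11, 17] <- TRUE
  two <- track_from_mask(f2, brain, seeds, tracking_params())
  m2 <- connection_probability_map(two, grid)
  expect_setequal(unique(as.vector(m2$data)), c(0, 0.5))

  # random tractogram equals brute-force visitation count / N
  t <- track_whole_brain(f2, brain, tracking_params())
  mt <- connection_probability_map(t, grid)
  counts <- array(0, grid$shape)
  for (s in t$streamlines) {
    vox <- round(world_to_voxel(grid, s$points))
    ok <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
          vox[, 1] < 30 & vox[, 2] < 20 & vox[, 3] < 20
    vox <- vox[ok, , drop = FALSE]
    keys <- unique(vox[, 1] + 30 * (vox[, 2] + 20 * vox[, 3]))
    counts[keys + 1] <- counts[keys + 1] + 1
  }
  expect_equal(mt$data, counts / n_streamlines(t))
  empty <- track_from_mask(f2, brain, empty_mask(grid), tracking_params())
  expect_error(connection_probability_map(empty, grid), "empty")
})

test_that("tractograms round-trip through TrackVis format", {
  grid <- grid_spec(c(30, 20, 20), voxel_size = c(1, 1, 1.5),
                    affine = rbind(c(1, 0, 0, -3), c(0, 1, 0, 2),
                                   c(0, 0, 1.5, 0), c(0, 0, 0, 1)))
  brain <- full_brain(grid)
  f <- synth_bundle(orientation_field(grid),
                    bundle_spec(voxel_to_world(grid, rbind(c(2, 10, 10), c(27, 10, 10))),
                                radius = 2.5))
  t <- track_whole_brain(f, brain, tracking_params())
  path <- tempfile(fileext = ".trk")
  write_trk(t, path, grid)
  back <- read_trk(path)
  expect_equal(length(back$streamlines), n_streamlines(t))
  for (i in seq(1, n_streamlines(t), by = 25)) {
    expect_equal(back$streamlines[[i]]$points, t$streamlines[[i]]$points,
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("tracked streamlines satisfy the stopping rules post hoc", {
  case <- cached_phantom("infiltrate", 0.5, 3)
  res <- cached_case_result("infiltrate", 0.5, 3)
  audit <- audit_streamlines(res$tract_healthy, case$field, case$brain_mask)
  expect_true(all(audit$ok))
})
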