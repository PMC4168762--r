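# Shared fixtures built in code. Phantom cases are cached per session since
# several test files exercise the same reference geometry.

random_mask <- function(grid, p = 0.2) {
  mask_volume(grid, array(stats::runif(prod(grid$shape)) < p, grid$shape))
}

# uniform single-peak field along `dir` inside a box mask
uniform_field <- function(grid, dir = c(1, 0, 0), fa = 0.8, support = NULL) {
  pk <- array(0, c(grid$shape, 3, 3))
  anis <- array(0, grid$shape)
  dir <- dir / sqrt(sum(dir^2))
  sup <- if (is.null(support)) array(TRUE, grid$shape) else support$data
  for (c in 1:3) {
    comp <- array(0, grid$shape)
    comp[sup] <- dir[c]
    pk[, , , 1, c] <- comp
  }
  anis[sup] <- fa
  orientation_field(grid, pk, anis)
}

full_brain <- function(grid) mask_volume(grid, array(TRUE, grid$shape))

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(mode, magnitude, rng_seed) {
  key <- paste(mode, magnitude, rng_seed, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- reference_phantom(mode, magnitude = magnitude,
                                               rng_seed = rng_seed)
  }
  .phantom_cache[[key]]
}

cached_case_result <- function(mode, magnitude, rng_seed) {
  key <- paste("res", mode, magnitude, rng_seed, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    case <- cached_phantom(mode, magnitude, rng_seed)
    .phantom_cache[[key]] <- suppressWarnings(
      run_phantom_case(case, run_config(rng_seed = rng_seed)))
  }
  .phantom_cache[[key]]
}

# independent fine-step reference integrator: same stopping rules, written
# without the compiled path (plain R, one direction at a time)
reference_propagate <- function(field, brain, seed, dir, step = 0.05,
                                fa_min = 0.2, max_turn = 60, max_len = 250) {
  grid <- field$grid
  p <- seed
  d <- dir / sqrt(sum(dir^2))
  entry <- d
  pv <- round(drop(world_to_voxel(grid, matrix(p, ncol = 3))))
  pts <- matrix(p, 1, 3)
  np_arr <- n_peaks(field)
  for (i in seq_len(ceiling(max_len / step))) {
    v <- round(drop(world_to_voxel(grid, matrix(p, ncol = 3))))
    if (any(v < 0) || any(v >= grid$shape)) break
    if (!brain$data[v[1] + 1, v[2] + 1, v[3] + 1]) break
    if (field$anisotropy[v[1] + 1, v[2] + 1, v[3] + 1] < fa_min) break
    nv <- np_arr[v[1] + 1, v[2] + 1, v[3] + 1]
    if (nv == 0) break
    pk <- sapply(seq_len(nv), function(q) field$peaks[v[1] + 1, v[2] + 1, v[3] + 1, q, ])
    pk <- matrix(pk, nrow = 3)
    dots <- drop(d %*% pk)
    best <- which.max(abs(dots))  # ties: lowest peak index
    nd <- pk[, best] * sign(dots[best])
    nd <- nd / sqrt(sum(nd^2))
    if (any(v != pv)) { entry <- d; pv <- v }
    if (sum(nd * entry) < cos(max_turn * pi / 180)) break
    d <- nd
    p <- p + step * d
    pts <- rbind(pts, p)
  }
  pts
}
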