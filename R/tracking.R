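#' Tracking parameters
#'
#' Bundles the deterministic stopping rules and the probabilistic
#' dispersion settings. The stopping criteria are an anisotropy floor of
#' 0.2, a maximum bend of 60 degrees across a voxel, and exit from the
#' brain mask.
#'
#' @param step integration step in mm; default half the smallest voxel
#'   dimension (resolved against the field at run time).
#' @param max_turn maximum bend across a voxel, degrees.
#' @param fa_min anisotropy floor.
#' @param min_length minimum streamline length in mm; shorter streamlines
#'   are discarded (and counted).
#' @param max_length maximum half-streamline length in mm.
#' @param kappa concentration of the axial angular dispersion used by
#'   probabilistic tracking (larger = tighter around the peak).
#' @param iterations probabilistic repetitions per (voxel, peak) launch.
#' @export
tracking_params <- function(step = NULL, max_turn = 60, fa_min = 0.2,
                            min_length = 10, max_length = 250,
                            kappa = 80, iterations = 1000) {
  stopifnot(max_turn > 0, max_turn <= 90, fa_min >= 0, fa_min <= 1,
            min_length >= 0, max_length > 0, kappa > 0, iterations >= 1)
  if (!is.null(step)) stopifnot(step > 0)
  structure(list(step = step, max_turn = max_turn, fa_min = fa_min,
                 min_length = min_length, max_length = max_length,
                 kappa = kappa, iterations = as.integer(iterations)),
            class = "tracking_params")
}

resolve_step <- function(params, grid) {
  if (is.null(params$step)) 0.5 * min(grid$voxel_size) else params$step
}

field_arrays <- function(field, brain) {
  stop_if_grid_mismatch(field$grid, brain$grid)
  grid <- field$grid
  list(peaks = field$peaks,
       fa = field$anisotropy,
       brain = array(as.integer(brain$data), grid$shape),
       dims = grid$shape,
       affine = grid$affine[1:3, , drop = FALSE],
       inv = solve(grid$affine)[1:3, , drop = FALSE])
}

reason_labels <- c("low_anisotropy", "sharp_turn", "out_of_brain", "max_length")

new_streamline <- function(points, seed_voxel, seed_peak, reasons) {
  structure(list(points = points, seed_voxel = seed_voxel, seed_peak = seed_peak,
                 termination_reasons = reason_labels[reasons]),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat("<streamline> ", nrow(x$points), " points, terminated: ",
      paste(x$termination_reasons, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Streamline length in mm
#' @param s a streamline.
#' @export
streamline_length <- function(s) {
  p <- s$points
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Propagate a single streamline
#'
#' Deterministic multi-peak propagation from an arbitrary world-space seed:
#' at each step the voxel's peak with maximal `|dot|` with the incoming
#' direction is followed (sign chosen to keep moving forward), stopping on
#' anisotropy below `fa_min`, a bend of more than `max_turn` degrees across
#' a voxel, or exit from the brain mask. Propagation runs in both
#' directions from the seed and the two halves are concatenated.
#'
#' @param field an [orientation_field()].
#' @param brain brain [mask_volume()].
#' @param seed_point world coordinates (mm).
#' @param initial_dir initial direction (unit vector).
#' @param params a [tracking_params()].
#' @return a `streamline`; a seed voxel with no peak yields a degenerate
#'   single-point streamline with reason `low_anisotropy`.
#' @export
propagate <- function(field, brain, seed_point, initial_dir,
                      params = tracking_params()) {
  fa_ <- field_arrays(field, brain)
  step <- resolve_step(params, field$grid)
  res <- .propagate_cpp(fa_$peaks, fa_$fa, fa_$brain, fa_$dims,
                        fa_$affine, fa_$inv,
                        as.numeric(seed_point), as.numeric(initial_dir),
                        step, params$max_turn, params$fa_min,
                        as.integer(ceiling(params$max_length / step)),
                        TRUE, FALSE, params$kappa, 0L)
  sv <- as.integer(round(drop(world_to_voxel(field$grid, matrix(seed_point, ncol = 3)))))
  new_streamline(res$points, sv, NA_integer_, res$reasons + (res$reasons == 0))
}

new_tractogram <- function(streamlines, params, provenance) {
  structure(list(streamlines = streamlines, params = params,
                 provenance = provenance), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("<tractogram> ", length(x$streamlines), " streamlines (",
      x$provenance$mode, ", seeded from ", x$provenance$seed_mask, ")\n", sep = "")
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param t a `tractogram`.
#' @export
n_streamlines <- function(t) length(t$streamlines)

seed_table <- function(field, seed_mask) {
  np <- n_peaks(field)
  idx <- which(seed_mask$data & np > 0, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0) {
    return(list(seeds = matrix(integer(0), 0, 3), peak = integer(0)))
  }
  counts <- np[cbind(idx[, 1] + 1L, idx[, 2] + 1L, idx[, 3] + 1L)]
  seeds <- idx[rep(seq_len(nrow(idx)), counts), , drop = FALSE]
  peak <- unlist(lapply(counts, seq_len)) - 1L
  list(seeds = seeds, peak = as.integer(peak))
}

#' Track one streamline per (seed voxel, peak) pair
#'
#' Launches the same number of streamlines as the number of peaks in every
#' seed voxel, each from the voxel center along that peak, bidirectionally.
#' Streamlines shorter than `min_length` are discarded and counted in the
#' provenance.
#'
#' @inheritParams propagate
#' @param seed_mask seeding [mask_volume()]; must lie inside the brain mask.
#' @param label provenance label for the seed mask.
#' @return a `tractogram`.
#' @export
track_from_mask <- function(field, brain, seed_mask, params = tracking_params(),
                            label = "mask") {
  stop_if_grid_mismatch(field$grid, seed_mask$grid)
  if (any(seed_mask$data & !brain$data)) {
    stop("seed mask extends outside the brain mask")
  }
  st <- seed_table(field, seed_mask)
  run_deterministic(field, brain, st, params, label)
}

run_deterministic <- function(field, brain, st, params, label) {
  fa_ <- field_arrays(field, brain)
  step <- resolve_step(params, field$grid)
  if (nrow(st$seeds) == 0) {
    return(new_tractogram(list(), params,
                          list(seed_mask = label, mode = "deterministic",
                               n_launched = 0L, n_discarded = 0L)))
  }
  res <- .track_cpp(fa_$peaks, fa_$fa, fa_$brain, fa_$dims, fa_$affine, fa_$inv,
                    st$seeds, st$peak, step, params$max_turn, params$fa_min,
                    params$min_length,
                    as.integer(ceiling(params$max_length / step)),
                    FALSE, params$kappa, 0L)
  keep <- which(res$keep)
  sl <- lapply(keep, function(i) {
    new_streamline(res$streamlines[[i]], st$seeds[i, ], st$peak[i],
                   res$reasons[i, ] + (res$reasons[i, ] == 0))
  })
  new_tractogram(sl, params,
                 list(seed_mask = label, mode = "deterministic",
                      n_launched = nrow(st$seeds), n_discarded = res$n_discarded))
}

#' Whole-brain tracking
#'
#' As [track_from_mask()] with the seed mask equal to the brain mask
#' restricted to voxels carrying at least one peak.
#'
#' @inheritParams track_from_mask
#' @export
track_whole_brain <- function(field, brain, params = tracking_params()) {
  seed <- mask_intersect(brain, peak_support_mask(field))
  track_from_mask(field, brain, seed, params, label = "whole_brain")
}

terminal_voxels <- function(t, grid) {
  if (length(t$streamlines) == 0) {
    return(list(a = matrix(integer(0), 0, 3), b = matrix(integer(0), 0, 3)))
  }
  ends <- vapply(t$streamlines, function(s) {
    c(s$points[1, ], s$points[nrow(s$points), ])
  }, numeric(6))
  a <- round(world_to_voxel(grid, t(ends[1:3, , drop = FALSE])))
  b <- round(world_to_voxel(grid, t(ends[4:6, , drop = FALSE])))
  list(a = a, b = b)
}

in_mask <- function(mask, vox) {
  d <- mask$grid$shape
  ok <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
        vox[, 1] < d[1] & vox[, 2] < d[2] & vox[, 3] < d[3]
  out <- logical(nrow(vox))
  if (any(ok)) {
    lin <- vox[ok, 1] + d[1] * (vox[ok, 2] + d[2] * vox[ok, 3]) + 1
    out[ok] <- mask$data[lin]
  }
  out
}

#' Keep streamlines whose endpoints connect two ROIs
#'
#' Two-ROI analysis: a streamline is retained when one terminal point's
#' voxel lies in `roi_a` and the other terminal point's voxel lies in
#' `roi_b`, in either order.
#'
#' @param t a `tractogram`.
#' @param roi_a,roi_b endpoint [mask_volume()]s on the tracking grid.
#' @export
prune_by_endpoints <- function(t, roi_a, roi_b) {
  stop_if_grid_mismatch(roi_a$grid, roi_b$grid)
  tv <- terminal_voxels(t, roi_a$grid)
  a_in_a <- in_mask(roi_a, tv$a); a_in_b <- in_mask(roi_b, tv$a)
  b_in_a <- in_mask(roi_a, tv$b); b_in_b <- in_mask(roi_b, tv$b)
  keep <- (a_in_a & b_in_b) | (a_in_b & b_in_a)
  out <- t
  out$streamlines <- t$streamlines[keep]
  out$provenance$pruned_by <- "endpoint_rois"
  out
}

#' Probabilistic tracking
#'
#' Repeats every (seed voxel, peak) launch `iterations` times; at each step
#' the direction is drawn from an axial angular distribution (tangent-plane
#' Gaussian with sd `1/sqrt(2*kappa)`, Watson-like) centered on the selected
#' peak. All other rules are identical to deterministic propagation.
#' Intended for small problems; for case-level connection-probability
#' images use [run_case_probabilistic()], which does not materialise the
#' streamlines.
#'
#' @inheritParams track_from_mask
#' @param iterations repetitions per launch (defaults to `params$iterations`).
#' @param rng_seed integer seed; identical seeds give identical output.
#' @export
probabilistic_tracts <- function(field, brain, params = tracking_params(),
                                 iterations = NULL, rng_seed = 1L) {
  if (is.null(iterations)) iterations <- params$iterations
  seed <- mask_intersect(brain, peak_support_mask(field))
  st <- seed_table(field, seed)
  rep_idx <- rep(seq_len(nrow(st$seeds)), each = iterations)
  st <- list(seeds = st$seeds[rep_idx, , drop = FALSE], peak = st$peak[rep_idx])
  fa_ <- field_arrays(field, brain)
  step <- resolve_step(params, field$grid)
  if (nrow(st$seeds) == 0) {
    return(new_tractogram(list(), params,
                          list(seed_mask = "whole_brain", mode = "probabilistic",
                               n_launched = 0L, n_discarded = 0L, rng_seed = rng_seed)))
  }
  res <- .track_cpp(fa_$peaks, fa_$fa, fa_$brain, fa_$dims, fa_$affine, fa_$inv,
                    st$seeds, st$peak, step, params$max_turn, params$fa_min,
                    params$min_length,
                    as.integer(ceiling(params$max_length / step)),
                    TRUE, params$kappa, as.integer(rng_seed))
  keep <- which(res$keep)
  sl <- lapply(keep, function(i) {
    new_streamline(res$streamlines[[i]], st$seeds[i, ], st$peak[i],
                   res$reasons[i, ] + (res$reasons[i, ] == 0))
  })
  new_tractogram(sl, params,
                 list(seed_mask = "whole_brain", mode = "probabilistic",
                      n_launched = nrow(st$seeds), n_discarded = res$n_discarded,
                      rng_seed = rng_seed))
}

#' Connection probability image from a tractogram
#'
#' Per voxel: the number of distinct streamlines entering the voxel divided
#' by the total number of streamlines.
#'
#' @param t a non-empty `tractogram`.
#' @param grid grid of the output image (defaults to any provenance grid
#'   passed explicitly; required).
#' @export
connection_probability_map <- function(t, grid) {
  n <- length(t$streamlines)
  if (n == 0) stop("connection probability is undefined for an empty tractogram")
  counts <- array(0, grid$shape)
  d <- grid$shape
  for (s in t$streamlines) {
    vox <- round(world_to_voxel(grid, s$points))
    ok <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
          vox[, 1] < d[1] & vox[, 2] < d[2] & vox[, 3] < d[3]
    lin <- unique(vox[ok, 1] + d[1] * (vox[ok, 2] + d[2] * vox[ok, 3]) + 1)
    counts[lin] <- counts[lin] + 1
  }
  scalar_volume(grid, counts / n, clip = c(0, 1))
}

#' Voxels visited by any streamline of a tractogram
#' @param t a `tractogram`.
#' @param grid target [grid_spec()].
#' @export
tract_support_mask <- function(t, grid) {
  vis <- array(FALSE, grid$shape)
  d <- grid$shape
  for (s in t$streamlines) {
    vox <- round(world_to_voxel(grid, s$points))
    ok <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
          vox[, 1] < d[1] & vox[, 2] < d[2] & vox[, 3] < d[3]
    lin <- vox[ok, 1] + d[1] * (vox[ok, 2] + d[2] * vox[ok, 3]) + 1
    vis[lin] <- TRUE
  }
  mask_volume(grid, vis)
}

#' Post-hoc audit of the stopping criteria
#'
#' Verifies, from the stored points and the field, that every streamline
#' honours the three stopping rules: anisotropy at or above the floor at
#' all non-terminal voxels, all inter-segment bends within the turn limit,
#' and all non-terminal points inside the brain mask.
#'
#' @param t a `tractogram`.
#' @param field the [orientation_field()] it was tracked on.
#' @param brain the brain [mask_volume()].
#' @return a tibble with one row per streamline: `min_fa_interior`,
#'   `max_turn_deg`, `interior_in_brain`, `ok`.
#' @export
audit_streamlines <- function(t, field, brain) {
  grid <- field$grid
  params <- t$params
  rows <- lapply(t$streamlines, function(s) {
    p <- s$points
    n <- nrow(p)
    interior <- if (n > 2) p[2:(n - 1), , drop = FALSE] else p[0, , drop = FALSE]
    vox <- round(world_to_voxel(grid, interior))
    fa_vals <- if (nrow(vox) > 0) {
      lin <- vox[, 1] + grid$shape[1] * (vox[, 2] + grid$shape[2] * vox[, 3]) + 1
      field$anisotropy[lin]
    } else numeric(0)
    inb <- if (nrow(vox) > 0) all(in_mask(brain, vox)) else TRUE
    turns <- if (n > 2) {
      seg <- diff(p)
      seg <- seg / sqrt(rowSums(seg^2))
      dots <- rowSums(seg[-nrow(seg), , drop = FALSE] * seg[-1, , drop = FALSE])
      acos(pmin(pmax(dots, -1), 1)) * 180 / pi
    } else 0
    tibble::tibble(
      min_fa_interior = if (length(fa_vals)) min(fa_vals) else NA_real_,
      max_turn_deg = max(turns),
      interior_in_brain = inb)
  })
  out <- dplyr::bind_rows(rows)
  fa_min <- t$params$fa_min %||% 0.2
  max_turn <- t$params$max_turn %||% 60
  dplyr::mutate(out,
                ok = (is.na(.data$min_fa_interior) | .data$min_fa_interior >= fa_min) &
                     .data$max_turn_deg <= max_turn + 1e-6 &
                     .data$interior_in_brain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
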