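#' Per-voxel fiber orientation field
#'
#' The substrate for tracking: up to three unit-vector fiber directions per
#' voxel (sign-ambiguous axes) plus an anisotropy scalar in [0, 1]. Peaks
#' are stored as a 5D array `(x, y, z, peak, component)` with zero vectors
#' marking absent peaks; slots are filled in order.
#'
#' @param grid a [grid_spec()].
#' @param peaks numeric array of dim `c(grid$shape, 3, 3)`; every nonzero
#'   peak must have unit norm (tolerance 1e-6).
#' @param anisotropy numeric 3D array (or [scalar_volume()]) in [0, 1].
#' @return an object of class `orientation_field`.
#' @export
orientation_field <- function(grid, peaks = NULL, anisotropy = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(peaks)) peaks <- array(0, c(grid$shape, 3, 3))
  stopifnot(all(dim(peaks) == c(grid$shape, 3, 3)))
  if (is.null(anisotropy)) anisotropy <- array(0, grid$shape)
  if (inherits(anisotropy, "scalar_volume")) anisotropy <- anisotropy$data
  anisotropy <- array(pmin(pmax(as.numeric(anisotropy), 0), 1), grid$shape)
  nrm <- peak_norms(peaks)
  bad <- nrm > 1e-8 & abs(nrm - 1) > 1e-6
  if (any(bad)) stop("orientation_field peaks must be unit vectors (or zero)")
  structure(list(grid = grid, peaks = peaks, anisotropy = anisotropy),
            class = "orientation_field")
}

peak_norms <- function(peaks) {
  sqrt(peaks[, , , , 1]^2 + peaks[, , , , 2]^2 + peaks[, , , , 3]^2)
}

#' Number of peaks per voxel
#' @param field an [orientation_field()].
#' @return integer 3D array.
#' @export
n_peaks <- function(field) {
  nrm <- peak_norms(field$peaks)
  array(rowSums(matrix(nrm > 0.5, ncol = 3)), field$grid$shape)
}

#' @export
print.orientation_field <- function(x, ...) {
  np <- n_peaks(x)
  cat("<orientation_field> ", format(x$grid), "; ", sum(np > 0),
      " voxels with peaks (max ", max(np), "/voxel)\n", sep = "")
  invisible(x)
}

#' Mask of voxels carrying at least one peak
#' @param field an [orientation_field()].
#' @export
peak_support_mask <- function(field) {
  mask_volume(field$grid, n_peaks(field) > 0)
}

#' Mirror an orientation field across the sagittal mid-plane
#'
#' Flips the voxel lattice along the left-right axis and negates the
#' left-right component of every peak vector (reflection acts on directions
#' as well as positions). Requires the affine to be axis-aligned on the
#' left-right axis.
#'
#' @param field an [orientation_field()].
#' @export
mirror_field <- function(field) {
  ax <- field$grid$lr_axis
  A <- field$grid$affine[1:3, 1:3]
  off <- A[, ax]; off[ax] <- 0
  if (max(abs(off)) > 1e-9) {
    stop("mirror_field requires the left-right axis to be axis-aligned in world space")
  }
  pk <- field$peaks
  idx <- lapply(dim(pk), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  pk <- do.call(`[`, c(list(pk), idx, list(drop = FALSE)))
  pk[, , , , ax] <- -pk[, , , , ax]
  fa <- flip_axis(field$anisotropy, ax)
  out <- orientation_field(field$grid, pk, fa)
  out$bundles <- mirror_bundle_meta(field$bundles, field$grid)
  out
}

#' Write / read an orientation field as NIfTI
#'
#' The peak array is serialized as a 5D NIfTI `(x, y, z, peak, component)`
#' and the anisotropy as a companion 3D float volume (`<stem>_fa.nii.gz`).
#'
#' @param field an [orientation_field()].
#' @param stem output path stem; `<stem>_peaks.nii.gz` and
#'   `<stem>_fa.nii.gz` are written.
#' @export
write_field_nifti <- function(field, stem) {
  pimg <- RNifti::asNifti(field$peaks)
  pimg <- RNifti::`sform<-`(pimg, structure(field$grid$affine, code = 2L))
  RNifti::writeNifti(pimg, paste0(stem, "_peaks.nii.gz"))
  write_nifti(scalar_volume(field$grid, field$anisotropy), paste0(stem, "_fa.nii.gz"))
  invisible(stem)
}

#' @rdname write_field_nifti
#' @param lr_axis left-right grid axis (default 1).
#' @export
read_field_nifti <- function(stem, lr_axis = 1L) {
  pimg <- RNifti::readNifti(paste0(stem, "_peaks.nii.gz"))
  grid <- read_grid_from_nifti(pimg, lr_axis)
  fa <- read_scalar_nifti(paste0(stem, "_fa.nii.gz"), lr_axis)
  orientation_field(grid, array(as.numeric(pimg), c(grid$shape, 3, 3)), fa$data)
}

# ---- sampled spherical functions and peak finding -------------------------

#' Sampled spherical function
#'
#' A function on the sphere given by its values at a set of unit direction
#' vectors (typically an icosphere tessellation). Values are antipodally
#' symmetrized on construction, since fiber orientation distributions are
#' axial.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param values length-n non-negative values.
#' @param neighbors optional adjacency list (1-based vertex indices); when
#'   the directions come from [icosphere()] its edge graph is used,
#'   otherwise the 6 nearest neighbors by angle.
#' @export
spherical_function <- function(directions, values, neighbors = NULL) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3, nrow(directions) == length(values))
  if (any(values < 0)) stop("spherical function values must be non-negative")
  nrm <- sqrt(rowSums(directions^2))
  directions <- directions / nrm
  # antipodal symmetrization: average with the value at the nearest
  # antipodal direction
  anti <- vapply(seq_len(nrow(directions)), function(i) {
    which.max(-directions %*% directions[i, ])
  }, integer(1))
  values <- (values + values[anti]) / 2
  if (is.null(neighbors)) neighbors <- knn_directions(directions, 6)
  structure(list(directions = directions, values = values, neighbors = neighbors),
            class = "spherical_function")
}

knn_directions <- function(directions, k) {
  # spatial (not axial) neighbors; antipodal maxima are merged later by the
  # axial separation rule
  dots <- directions %*% t(directions)
  diag(dots) <- -Inf
  lapply(seq_len(nrow(directions)), function(i) {
    order(dots[i, ], decreasing = TRUE)[seq_len(k)]
  })
}

#' Icosphere tessellation of the unit sphere
#'
#' Recursively subdivided icosahedron; `level = 3` gives 642 vertices.
#'
#' @param level number of subdivision rounds.
#' @return list with `vertices` (n x 3 unit vectors) and `neighbors`
#'   (adjacency list from the triangulation edges).
#' @export
icosphere <- function(level = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(midpoint_cache[[key]])) return(midpoint_cache[[key]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      idx <- nv + length(newv)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  nb <- vector("list", nrow(v))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  list(vertices = v, neighbors = lapply(nb, unique))
}

#' Extract principal directions from a sampled spherical function
#'
#' Simplified multi-fiber peak finder: local maxima over the tessellation's
#' neighbor graph are sorted by value and greedily retained if they are at
#' least `min_separation` degrees (axial angle) from every already-retained
#' peak and at least `relative_threshold` times the global maximum. At most
#' `max_peaks` directions are returned, each in the positive-hemisphere sign
#' convention (first nonzero component positive).
#'
#' @param f a [spherical_function()] with at least 60 directions.
#' @param min_separation minimum axial angle between retained peaks (deg).
#' @param relative_threshold fraction of the global maximum below which
#'   local maxima are discarded.
#' @param max_peaks maximum number of directions returned.
#' @return matrix with up to `max_peaks` rows of unit vectors (0 rows for an
#'   isotropic function).
#' @export
find_odf_peaks <- function(f, min_separation = 25, relative_threshold = 0.25,
                           max_peaks = 3) {
  stopifnot(inherits(f, "spherical_function"))
  if (length(f$values) < 60) stop("tessellation too coarse (need >= 60 directions)")
  vmax <- max(f$values)
  if (vmax <= 0) stop("spherical function is identically zero")
  is_max <- vapply(seq_along(f$values), function(i) {
    f$values[i] > max(f$values[f$neighbors[[i]]])
  }, logical(1))
  cand <- which(is_max & f$values >= relative_threshold * vmax)
  cand <- cand[order(f$values[cand], decreasing = TRUE)]
  kept <- matrix(numeric(0), 0, 3)
  cos_sep <- cos(min_separation * pi / 180)
  for (i in cand) {
    u <- refine_peak(f, i)
    if (nrow(kept) > 0 && any(abs(kept %*% u) > cos_sep)) next
    kept <- rbind(kept, hemisphere_sign(u))
    if (nrow(kept) >= max_peaks) break
  }
  unname(kept)
}

# sub-tessellation refinement: fit a quadratic surface (in log values, exact
# for exponential-type lobes) over the maximal vertex and its neighbors in
# tangent-plane coordinates and move to its stationary point
refine_peak <- function(f, i) {
  nb <- c(i, f$neighbors[[i]])
  d0 <- f$directions[i, ]
  dirs <- f$directions[nb, , drop = FALSE]
  signs <- sign(drop(dirs %*% d0))
  signs[signs == 0] <- 1
  dirs <- dirs * signs
  v <- f$values[nb]
  if (length(nb) < 6 || any(v <= 0)) return(d0)
  a1 <- c(1, 0, 0)
  if (abs(sum(a1 * d0)) > 0.9) a1 <- c(0, 1, 0)
  e1 <- a1 - sum(a1 * d0) * d0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d0[2] * e1[3] - d0[3] * e1[2], d0[3] * e1[1] - d0[1] * e1[3],
          d0[1] * e1[2] - d0[2] * e1[1])
  x <- drop(dirs %*% e1); y <- drop(dirs %*% e2)
  X <- cbind(1, x, y, x^2, x * y, y^2)
  fit <- tryCatch(qr.solve(X, log(v)), error = function(e) NULL)
  if (is.null(fit)) return(d0)
  H <- matrix(c(2 * fit[4], fit[5], fit[5], 2 * fit[6]), 2, 2)
  if (any(is.na(H)) || det(H) <= 0 || H[1, 1] >= 0) return(d0)  # not a max
  off <- -solve(H, fit[2:3])
  if (sqrt(sum(off^2)) > max(abs(c(x, y)))) return(d0)  # outside the patch
  u <- d0 + off[1] * e1 + off[2] * e2
  u / sqrt(sum(u^2))
}

# canonical sign: first component whose |value| exceeds tolerance is positive
hemisphere_sign <- function(u, tol = 1e-9) {
  for (c in 1:3) {
    if (abs(u[c]) > tol) {
      if (u[c] < 0) u <- -u
      break
    }
  }
  u
}
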