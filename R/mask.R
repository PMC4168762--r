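#' Binary mask volume
#'
#' Binary 3D region on a [grid_spec()] lattice: lesion masks, white-matter
#' and brain masks, exclusion shells and target spheres are all
#' `mask_volume` objects.
#'
#' @param grid a [grid_spec()].
#' @param data logical (or coercible) 3D array matching `grid$shape`.
#' @return an object of class `mask_volume`.
#' @export
mask_volume <- function(grid, data) {
  stopifnot(inherits(grid, "grid_spec"))
  data <- array(as.logical(data), dim = dim(data))
  if (!identical(dim(data), NULL) && !all(dim(data) == grid$shape)) {
    stop("mask data shape does not match grid shape")
  }
  dim(data) <- grid$shape
  structure(list(grid = grid, data = data), class = "mask_volume")
}

#' Empty mask on a grid
#' @inheritParams mask_volume
#' @export
empty_mask <- function(grid) {
  mask_volume(grid, array(FALSE, grid$shape))
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> ", format(x$grid), ", ", sum(x$data), " voxels set\n", sep = "")
  invisible(x)
}

#' Scalar volume (anisotropy, connection probability)
#'
#' @inheritParams mask_volume
#' @param data numeric 3D array matching `grid$shape`.
#' @param clip optional length-2 range to which values are clipped (e.g.
#'   `c(0, 1)` for anisotropy maps).
#' @export
scalar_volume <- function(grid, data, clip = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  data <- array(as.numeric(data), dim = grid$shape)
  if (!is.null(clip)) data <- pmin(pmax(data, clip[1]), clip[2])
  structure(list(grid = grid, data = data), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", format(x$grid), ", range [",
      paste(format(range(x$data)), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Mirror a mask across the sagittal mid-plane
#'
#' Reflects the mask through the grid mid-plane of the left-right axis:
#' voxel `(i,j,k)` maps to `(Nx-1-i, j, k)`. The volume is assumed to have
#' been aligned so that the inter-hemispheric plane coincides with the grid
#' mid-plane; which axis is left-right is carried by the grid
#' (`grid$lr_axis`). Used to obtain the healthy-hemisphere homolog of a
#' lesion ROI.
#'
#' @param mask a [mask_volume()] (or [scalar_volume()]).
#' @return the mirrored volume on the identical grid.
#' @export
mirror_sagittal <- function(mask) {
  UseMethod("mirror_sagittal")
}

#' @export
mirror_sagittal.mask_volume <- function(mask) {
  mask_volume(mask$grid, flip_axis(mask$data, mask$grid$lr_axis))
}

#' @export
mirror_sagittal.scalar_volume <- function(mask) {
  scalar_volume(mask$grid, flip_axis(mask$data, mask$grid$lr_axis))
}

flip_axis <- function(arr, axis) {
  idx <- lapply(dim(arr), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Voxelwise intersection of two masks
#'
#' @param a,b [mask_volume()] objects on the same grid.
#' @return a [mask_volume()] with the voxelwise logical AND.
#' @export
mask_intersect <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  mask_volume(a$grid, a$data & b$data)
}

#' Voxelwise union of two masks
#' @inheritParams mask_intersect
#' @export
mask_union <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  mask_volume(a$grid, a$data | b$data)
}

#' Resample a mask onto another grid with conservative thresholding
#'
#' Interpolates the mask trilinearly as a 0/1 field at the target grid's
#' voxel centers and keeps voxels whose interpolated value is at least
#' `threshold`. The default 0.9 keeps only voxels almost fully inside the
#' source mask, shrinking it conservatively at boundaries (the behaviour
#' wanted when moving a manually drawn ROI between image spaces).
#'
#' @param mask a [mask_volume()].
#' @param target a [grid_spec()] to resample onto.
#' @param threshold binarisation threshold in (0, 1].
#' @return a [mask_volume()] on `target`.
#' @export
resample_mask <- function(mask, target, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  src <- mask$grid
  xyz <- grid_coords(target)
  vox <- world_to_voxel(src, xyz)
  vals <- trilinear_interp(mask$data + 0, vox)
  mask_volume(target, array(vals >= threshold, target$shape))
}

# trilinear interpolation of a 3D array at 0-based continuous voxel coords;
# outside-the-grid samples read as 0
trilinear_interp <- function(arr, vox) {
  d <- dim(arr)
  f <- floor(vox)
  w <- vox - f
  out <- numeric(nrow(vox))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- f[, 1] + dx; jj <- f[, 2] + dy; kk <- f[, 3] + dz
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
          (if (dy == 1) w[, 2] else 1 - w[, 2]) *
          (if (dz == 1) w[, 3] else 1 - w[, 3])
    ok <- ii >= 0 & jj >= 0 & kk >= 0 & ii < d[1] & jj < d[2] & kk < d[3] & wt > 0
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      out[ok] <- out[ok] + wt[ok] * arr[lin]
    }
  }
  out
}

#' Distance map to a mask (mm)
#'
#' Exact Euclidean distance from every voxel center to the nearest voxel
#' center inside the mask, measured in world mm so anisotropic voxels are
#' respected.
#'
#' @param mask a [mask_volume()].
#' @return a [scalar_volume()] of distances (mm); `Inf`-like large values
#'   where the mask is empty.
#' @export
mask_distance_mm <- function(mask) {
  d <- .edt_cpp(array(as.integer(mask$data), mask$grid$shape),
                mask$grid$shape, mask$grid$voxel_size)
  scalar_volume(mask$grid, d)
}

#' Dilate a mask by a physical distance
#'
#' Morphological dilation in world metric: the output contains every voxel
#' whose center lies within `distance` mm of some input voxel center. Used
#' for the 2 cm peri-lesional exclusion shell.
#'
#' @param mask a [mask_volume()].
#' @param distance dilation distance in mm (>= 0).
#' @return a [mask_volume()]; always a superset of the input.
#' @export
dilate_mm <- function(mask, distance) {
  if (distance < 0) stop("dilation distance must be non-negative")
  if (distance == 0 || !any(mask$data)) return(mask)
  d <- mask_distance_mm(mask)
  mask_volume(mask$grid, d$data <= distance + 1e-9)
}

#' Dilate a mask to a multiple of its voxel count
#'
#' Repeats 1-voxel 6-connected morphological dilation until the voxel count
#' reaches `factor` times the original count, returning the first iterate
#' meeting the bound. This reproduces "grow the ROI to 1.2 times its size"
#' style morphology.
#'
#' @param mask a non-empty [mask_volume()].
#' @param factor target size ratio (>= 1).
#' @export
dilate_to_factor <- function(mask, factor = 1.2) {
  n0 <- sum(mask$data)
  if (n0 == 0) stop("cannot dilate an empty mask to a size factor")
  if (factor < 1) stop("factor must be >= 1")
  target <- factor * n0
  out <- mask$data
  while (sum(out) < target) {
    out <- dilate6(out)
  }
  mask_volume(mask$grid, out)
}

# one 6-connected binary dilation step
dilate6 <- function(arr) {
  d <- dim(arr)
  out <- arr
  # shift along each axis in both directions and OR
  out[-1, , ] <- out[-1, , ] | arr[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | arr[-1, , ]
  out[, -1, ] <- out[, -1, ] | arr[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | arr[, -1, ]
  out[, , -1] <- out[, , -1] | arr[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | arr[, , -1]
  out
}

#' Spherical ROI around a world-space center
#'
#' Marks every voxel whose center lies within `diameter/2` mm of `center`.
#' The 10 mm default matches the wide target ROIs drawn around endpoint
#' cluster centroids.
#'
#' @param grid a [grid_spec()].
#' @param center world coordinates (mm), length 3.
#' @param diameter sphere diameter in mm.
#' @export
sphere_mask <- function(grid, center, diameter = 10) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3)
  vox <- drop(world_to_voxel(grid, matrix(center, ncol = 3)))
  if (any(vox < -0.5) || any(vox > grid$shape - 0.5)) {
    stop("sphere center lies outside the grid")
  }
  xyz <- grid_coords(grid)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 + (xyz[, 3] - center[3])^2
  mask_volume(grid, array(d2 <= (diameter / 2)^2 + 1e-9, grid$shape))
}

#' Physical mask volume in cm^3
#'
#' Voxel count times physical voxel volume. This is how tumor volume is
#' computed from the lesion mask.
#'
#' @param mask a [mask_volume()].
#' @return volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$data) * voxel_volume_mm3(mask$grid) / 1000
}

#' Center of mass of a mask (world mm)
#' @param mask a [mask_volume()].
#' @export
mask_center_of_mass <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stop("empty mask has no center of mass")
  colMeans(voxel_to_world(mask$grid, idx))
}

#' Read / write masks and scalar volumes as NIfTI
#'
#' Masks are written as unsigned 8-bit NIfTI with the grid affine stored in
#' the sform/qform; on read any nonzero value is treated as true. Scalar
#' volumes are written as float32.
#'
#' @param x a [mask_volume()] or [scalar_volume()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_nifti` returns `path` invisibly; the readers return the
#'   reconstructed volume.
#' @export
write_nifti <- function(x, path) {
  datatype <- if (inherits(x, "mask_volume")) "uint8" else "float"
  arr <- if (inherits(x, "mask_volume")) array(as.integer(x$data), x$grid$shape) else x$data
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(x$grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_grid_from_nifti <- function(img, lr_axis = 1L) {
  aff <- unclass(RNifti::xform(img))
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid_spec(dim(img)[1:3], vs, aff, lr_axis = lr_axis)
}

#' @rdname write_nifti
#' @param path file path.
#' @param lr_axis left-right grid axis recorded on the grid (default 1).
#' @export
read_mask_nifti <- function(path, lr_axis = 1L) {
  img <- RNifti::readNifti(path)
  grid <- read_grid_from_nifti(img, lr_axis)
  mask_volume(grid, array(as.array(img) != 0, grid$shape))
}

#' @rdname write_nifti
#' @export
read_scalar_nifti <- function(path, lr_axis = 1L) {
  img <- RNifti::readNifti(path)
  grid <- read_grid_from_nifti(img, lr_axis)
  scalar_volume(grid, array(as.numeric(img), grid$shape))
}
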