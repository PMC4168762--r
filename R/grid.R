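#' Image grid geometry
#'
#' A `grid_spec` describes the sampling lattice shared by all volumes in a
#' case: the array shape in voxels, the physical voxel size in mm, and a 4x4
#' voxel-to-world affine. Voxel indices are 0-based and refer to voxel
#' centers, so the world position of voxel `(i,j,k)` is `affine %*% c(i,j,k,1)`.
#'
#' @param shape integer vector of length 3, array dimensions (voxels).
#' @param voxel_size numeric length 3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0,0,0).
#' @param lr_axis which grid axis runs left-right (used by sagittal
#'   mirroring); default 1.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, voxel_size = c(1, 1, 1), affine = NULL, lr_axis = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(dim(affine) == c(4, 4))
  if (abs(det(affine)) < 1e-12) stop("grid affine is not invertible")
  stopifnot(lr_axis %in% 1:3)
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine,
                 lr_axis = as.integer(lr_axis)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(format(x$voxel_size), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(format(x$voxel_size, trim = TRUE), collapse = "x"), " mm")
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_equal(a, b)) {
    stop("incompatible grids: volumes are not defined on the same lattice",
         call. = FALSE)
  }
}

#' Convert voxel indices to world coordinates
#'
#' @param grid a [grid_spec()].
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind_coords(ijk)
  t(grid$affine[1:3, 1:3] %*% t(ijk) + grid$affine[1:3, 4])
}

#' Convert world coordinates to (continuous) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of 0-based continuous voxel coordinates.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind_coords(xyz)
  inv <- solve(grid$affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  stopifnot(ncol(x) == 3)
  x
}

# world coordinates of every voxel center, in array order (n_voxels x 3)
grid_coords <- function(grid) {
  idx <- as.matrix(expand.grid(i = seq_len(grid$shape[1]) - 1L,
                               j = seq_len(grid$shape[2]) - 1L,
                               k = seq_len(grid$shape[3]) - 1L))
  voxel_to_world(grid, idx)
}

#' Physical volume of one voxel in mm^3
#' @param grid a [grid_spec()].
#' @export
voxel_volume_mm3 <- function(grid) abs(det(grid$affine[1:3, 1:3]))
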