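#' Write a tractogram in TrackVis (.trk) format
#'
#' Streamline points are stored in the TrackVis "voxmm" convention
#' (`(voxel + 0.5) * voxel_size`, corner origin) with the voxel-to-world
#' affine recorded in the version-2 header, and tracking parameters in a
#' JSON sidecar (`<path>.json`).
#'
#' @param t a `tractogram`.
#' @param path output file path (`.trk`).
#' @param grid the tracking [grid_spec()].
#' @export
write_trk <- function(t, path, grid) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(raw(1), con)
  writeBin(as.integer(grid$shape), con, size = 2)
  writeBin(as.numeric(grid$voxel_size), con, size = 4)
  writeBin(numeric(3), con, size = 4)                      # origin
  writeBin(0L, con, size = 2)                              # n_scalars
  writeBin(raw(200), con)                                  # scalar names
  writeBin(0L, con, size = 2)                              # n_properties
  writeBin(raw(200), con)                                  # property names
  writeBin(as.numeric(t(grid$affine)), con, size = 4)      # vox_to_ras, row-major
  writeBin(raw(444), con)                                  # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)               # voxel_order
  writeBin(raw(4), con)                                    # pad2
  writeBin(numeric(6), con, size = 4)                      # image orientation
  writeBin(raw(2), con)                                    # pad1
  writeBin(raw(6), con)                                    # invert/swap flags
  writeBin(length(t$streamlines), con, size = 4)           # n_count
  writeBin(2L, con, size = 4)                              # version
  writeBin(1000L, con, size = 4)                           # hdr_size
  for (s in t$streamlines) {
    vox <- world_to_voxel(grid, s$points)
    pts <- sweep(vox + 0.5, 2, grid$voxel_size, `*`)
    writeBin(nrow(pts), con, size = 4)
    writeBin(as.numeric(t(pts)), con, size = 4)
  }
  sidecar <- list(params = t$params[!vapply(t$params, is.null, logical(1))],
                  provenance = t$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK") stop("not a TrackVis .trk file")
  dim3 <- readBin(con, "integer", 3, size = 2)
  vs <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)
  n_scalars <- readBin(con, "integer", 1, size = 2); readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2); readBin(con, "raw", 200)
  aff <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)
  if (max(abs(aff)) == 0) aff <- diag(c(vs, 1))
  grid <- grid_spec(dim3, vs, aff)
  sl <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    pts <- matrix(readBin(con, "numeric", np * (3 + n_scalars), size = 4),
                  ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4)
    vox <- sweep(pts, 2, vs, `/`) - 0.5
    sl[[i]] <- new_streamline(voxel_to_world(grid, vox), NA_integer_, NA_integer_,
                              c(4L, 4L))
  }
  params <- tracking_params()
  side <- paste0(path, ".json")
  prov <- list(seed_mask = "trk_file", mode = "unknown")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    prov <- meta$provenance
  }
  t <- new_tractogram(sl, params, prov)
  t$grid <- grid
  t
}
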