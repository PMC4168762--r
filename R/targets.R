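#' Collect terminal voxels of a tractogram
#'
#' For each streamline end, walks inward from the terminal point and
#' collects the last `n_last` distinct voxels entered along the path; voxels
#' falling inside the exclusion mask (the 2 cm peri-lesional shell) are
#' dropped and counted. Restricting to terminal voxels outside the shell
#' focuses target generation on long- and medium-range connectivity.
#'
#' @param t a `tractogram`.
#' @param exclusion exclusion [mask_volume()] on the tracking grid.
#' @param n_last number of distinct terminal voxels per end.
#' @return a tibble with columns `i, j, k` (0-based voxel), `streamline`,
#'   `end` (1 or 2); the number of excluded voxels is in
#'   `attr(, "excluded_count")`.
#' @export
collect_endpoints <- function(t, exclusion, n_last = 10) {
  grid <- exclusion$grid
  d <- grid$shape
  rows <- list()
  excluded <- 0L
  for (si in seq_along(t$streamlines)) {
    p <- t$streamlines[[si]]$points
    vox <- round(world_to_voxel(grid, p))
    for (end in 1:2) {
      v <- if (end == 1) vox else vox[rev(seq_len(nrow(vox))), , drop = FALSE]
      inside <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
                v[, 1] < d[1] & v[, 2] < d[2] & v[, 3] < d[3]
      v <- v[inside, , drop = FALSE]
      if (nrow(v) == 0) next
      keys <- v[, 1] + d[1] * (v[, 2] + d[2] * v[, 3])
      dist_vox <- v[!duplicated(keys), , drop = FALSE]
      dist_vox <- dist_vox[seq_len(min(n_last, nrow(dist_vox))), , drop = FALSE]
      excl <- in_mask(exclusion, dist_vox)
      excluded <- excluded + sum(excl)
      dist_vox <- dist_vox[!excl, , drop = FALSE]
      if (nrow(dist_vox) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        i = dist_vox[, 1], j = dist_vox[, 2], k = dist_vox[, 3],
        streamline = si, end = end)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(i = numeric(0), j = numeric(0), k = numeric(0),
                   streamline = integer(0), end = integer(0))
  attr(out, "excluded_count") <- excluded
  attr(out, "grid") <- grid
  out
}

# mean silhouette width for a k-means partition (subsampled for large n)
mean_silhouette <- function(points, cluster, max_n = 2000) {
  n <- nrow(points)
  if (n > max_n) {
    sub <- round(seq(1, n, length.out = max_n))
    points <- points[sub, , drop = FALSE]
    cluster <- cluster[sub]
  }
  if (length(unique(cluster)) < 2) return(NA_real_)
  dd <- as.matrix(stats::dist(points))
  ks <- sort(unique(cluster))
  sil <- vapply(seq_len(nrow(points)), function(i) {
    own <- cluster[i]
    same <- cluster == own
    a <- if (sum(same) > 1) sum(dd[i, same]) / (sum(same) - 1) else 0
    b <- min(vapply(ks[ks != own], function(kk) mean(dd[i, cluster == kk]),
                    numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' Cluster endpoint voxels into candidate target centroids
#'
#' k-means (Lloyd's algorithm, 10 seeded restarts) over the world-space
#' endpoint coordinates for k = 1..`k_max`; k is chosen by the mean
#' silhouette width, falling back to k = 1 when the best silhouette is
#' below 0.5 (no real cluster structure). Centroids are returned most
#' populated first.
#'
#' @param e an endpoint tibble from [collect_endpoints()].
#' @param k_max maximum number of clusters tried.
#' @param rng_seed integer seed controlling restarts.
#' @return a tibble with columns `x, y, z` (centroid, mm), `member_count`,
#'   sorted by `member_count` descending.
#' @export
cluster_endpoints <- function(e, k_max = 4, rng_seed = 1L) {
  if (nrow(e) == 0) stop("cannot cluster an empty endpoint set")
  grid <- attr(e, "grid")
  pts <- voxel_to_world(grid, as.matrix(e[, c("i", "j", "k")]))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  n_unique <- nrow(unique(round(pts, 6)))
  best_k <- 1L; best_sil <- -Inf; best_fit <- NULL
  if (nrow(pts) >= k_max && n_unique >= 2) {
    for (k in 2:min(k_max, n_unique)) {
      # Lloyd restarts can propose empty clusters on duplicated voxel
      # coordinates; those restarts are simply discarded by kmeans
      fit <- suppressWarnings(
        stats::kmeans(pts, centers = k, nstart = 10, iter.max = 100,
                      algorithm = "Lloyd"))
      sil <- mean_silhouette(pts, fit$cluster)
      if (!is.na(sil) && sil > best_sil) {
        best_sil <- sil; best_k <- k; best_fit <- fit
      }
    }
  }
  if (best_k == 1 || best_sil < 0.5) {
    centroids <- matrix(colMeans(pts), 1, 3)
    counts <- nrow(pts)
  } else {
    centroids <- best_fit$centers
    counts <- as.integer(table(best_fit$cluster)[rownames(centroids)])
    ord <- order(counts, decreasing = TRUE)
    centroids <- centroids[ord, , drop = FALSE]
    counts <- counts[ord]
  }
  tibble::tibble(x = centroids[, 1], y = centroids[, 2], z = centroids[, 3],
                 member_count = counts)
}

#' Decide targets from clustered centroids
#'
#' Applies the one-vs-two-target rule: with the seed's center of mass `s`,
#' if the bearings of the two most-populated centroids from `s` subtend at
#' least `opposed_angle` degrees the fibers project to two diametrically
#' opposed areas and both centroids become targets (`opposed_pair`);
#' otherwise only the most-populated centroid is kept (`single_majority`).
#' Each target becomes a sphere ROI of `sphere_diameter` mm, and each
#' sphere is also sagittally mirrored for the contralateral analysis.
#'
#' @param centroids tibble from [cluster_endpoints()].
#' @param seed_mask the seeding [mask_volume()].
#' @param grid the case [grid_spec()].
#' @param opposed_angle opposition threshold in degrees.
#' @param sphere_diameter target sphere diameter in mm.
#' @return an object of class `target_set`: `centroids` (matrix),
#'   `decision`, `spheres`, `mirrored_spheres`.
#' @export
select_targets <- function(centroids, seed_mask, grid, opposed_angle = 120,
                           sphere_diameter = 10) {
  if (nrow(centroids) == 0) stop("no centroids to select targets from")
  s <- mask_center_of_mass(seed_mask)
  cen <- as.matrix(centroids[, c("x", "y", "z")])
  decision <- "single_majority"
  chosen <- cen[1, , drop = FALSE]
  if (nrow(cen) >= 2) {
    v1 <- cen[1, ] - s; v2 <- cen[2, ] - s
    ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
    if (ang >= opposed_angle) {
      decision <- "opposed_pair"
      chosen <- cen[1:2, , drop = FALSE]
    }
  }
  spheres <- lapply(seq_len(nrow(chosen)), function(i) {
    sphere_mask(grid, chosen[i, ], diameter = sphere_diameter)
  })
  mirrored <- lapply(spheres, mirror_sagittal)
  structure(list(centroids = chosen, decision = decision, spheres = spheres,
                 mirrored_spheres = mirrored), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", x$decision, ", ", nrow(x$centroids), " target(s)\n", sep = "")
  invisible(x)
}

#' Serialize a target set to JSON + NIfTI sphere masks
#' @param targets a `target_set`.
#' @param dir output directory.
#' @export
write_target_set <- function(targets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(centroids_mm = targets$centroids,
                            decision = targets$decision),
                       file.path(dir, "targets.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(targets$spheres)) {
    write_nifti(targets$spheres[[i]], file.path(dir, sprintf("target_%d.nii.gz", i)))
    write_nifti(targets$mirrored_spheres[[i]],
                file.path(dir, sprintf("target_%d_mirror.nii.gz", i)))
  }
  invisible(dir)
}
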