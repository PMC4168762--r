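#' Bundle specification for the synthetic phantom
#'
#' A parametric white-matter bundle: a tube of given radius around a smooth
#' centerline, every voxel of which carries a unit peak tangent to the
#' nearest centerline point.
#'
#' @param centerline m x 3 matrix of world control points (mm); interpolated
#'   with a natural cubic spline.
#' @param radius tube radius in mm.
#' @param fa_inside anisotropy assigned inside the bundle; must exceed the
#'   0.2 tracking floor.
#' @param fibers_fraction fraction of bundle voxels carrying a peak.
#' @export
bundle_spec <- function(centerline, radius = 3.5, fa_inside = 0.8,
                        fibers_fraction = 1) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3, nrow(centerline) >= 2)
  stopifnot(radius > 0, fa_inside > 0.2, fa_inside <= 1)
  stopifnot(fibers_fraction > 0, fibers_fraction <= 1)
  structure(list(centerline = centerline, radius = radius,
                 fa_inside = fa_inside, fibers_fraction = fibers_fraction),
            class = "bundle_spec")
}

#' Lesion specification for the synthetic phantom
#'
#' A spherical lesion that either displaces the surrounding bundles
#' (meningioma-like mass effect) or infiltrates them, deleting a fraction of
#' fibers in place (glioma-like invasion).
#'
#' @param center world coordinates of the lesion center (mm).
#' @param radius lesion radius in mm.
#' @param mode `"displace"` or `"infiltrate"`.
#' @param magnitude push distance in mm (displace) or fiber removal
#'   fraction in [0, 1] (infiltrate).
#' @export
lesion_spec <- function(center, radius, mode = c("displace", "infiltrate"),
                        magnitude) {
  mode <- match.arg(mode)
  stopifnot(radius > 0, length(center) == 3)
  if (mode == "infiltrate" && (magnitude < 0 || magnitude > 1)) {
    stop("infiltration removal fraction must be in [0, 1]")
  }
  if (mode == "displace" && magnitude < 0) stop("displacement magnitude must be >= 0")
  structure(list(center = as.numeric(center), radius = radius, mode = mode,
                 magnitude = magnitude), class = "lesion_spec")
}

# sample a centerline every `ds` mm with unit tangents and a
# parallel-transported cross-section frame
densify_centerline <- function(centerline, ds = 0.25) {
  seg <- sqrt(rowSums(diff(centerline)^2))
  s <- c(0, cumsum(seg))
  sout <- seq(0, s[length(s)], by = ds)
  pts <- sapply(1:3, function(c) stats::spline(s, centerline[, c], xout = sout,
                                               method = "natural")$y)
  tangents <- rbind(pts[2, ] - pts[1, ], (pts[-(1:2), ] - pts[1:(nrow(pts) - 2), ]) / 2,
                    pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
  tangents <- tangents / sqrt(rowSums(tangents^2))
  # parallel transport an initial normal along the curve
  n <- nrow(pts)
  n1 <- matrix(0, n, 3); n2 <- matrix(0, n, 3)
  a <- c(1, 0, 0)
  if (abs(sum(a * tangents[1, ])) > 0.9) a <- c(0, 1, 0)
  n1[1, ] <- a - sum(a * tangents[1, ]) * tangents[1, ]
  n1[1, ] <- n1[1, ] / sqrt(sum(n1[1, ]^2))
  n2[1, ] <- cross3(tangents[1, ], n1[1, ])
  for (i in 2:n) {
    v <- n1[i - 1, ] - sum(n1[i - 1, ] * tangents[i, ]) * tangents[i, ]
    n1[i, ] <- v / sqrt(sum(v^2))
    n2[i, ] <- cross3(tangents[i, ], n1[i, ])
  }
  list(points = pts, tangents = tangents, n1 = n1, n2 = n2, s = sout)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Paint a bundle into an orientation field
#'
#' Every voxel whose center lies within `spec$radius` of the centerline gets
#' a unit peak tangent to the nearest centerline point and anisotropy
#' `spec$fa_inside`. Voxels are also labelled with a fiber-line id (the
#' centerline-frame cross-section offset quantised at voxel scale), which the
#' infiltration operator uses to delete whole fibers rather than isolated
#' voxels.
#'
#' @param field an [orientation_field()].
#' @param spec a [bundle_spec()].
#' @return the updated field, with per-bundle metadata in `field$bundles`.
#' @export
synth_bundle <- function(field, spec) {
  grid <- field$grid
  cl <- densify_centerline(spec$centerline)
  vox_cl <- world_to_voxel(grid, cl$points)
  if (any(vox_cl < 0) || any(t(vox_cl) > grid$shape - 1)) {
    stop("bundle centerline exits the grid")
  }
  # curvature guard: tangent rotation over one voxel of arc length must stay
  # well under the 60 deg stopping limit or the healthy bundle untrackable
  step_vox <- max(1L, round(min(grid$voxel_size) / 0.25))
  n <- nrow(cl$points)
  if (n > step_vox) {
    dots <- rowSums(cl$tangents[1:(n - step_vox), ] * cl$tangents[(1 + step_vox):n, ])
    if (any(dots < cos(60 * pi / 180))) {
      stop("bundle centerline bends by more than 60 degrees per voxel")
    }
  }
  # candidate voxels: bounding box of the curve padded by the radius
  pad <- spec$radius + max(grid$voxel_size)
  lo <- floor(world_to_voxel(grid, matrix(apply(cl$points, 2, min) - pad, ncol = 3)))
  hi <- ceiling(world_to_voxel(grid, matrix(apply(cl$points, 2, max) + pad, ncol = 3)))
  lo <- pmax(as.integer(lo), 0L); hi <- pmin(as.integer(hi), grid$shape - 1L)
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  xyz <- voxel_to_world(grid, idx)
  # nearest centerline sample for each candidate voxel
  d2 <- outer(xyz[, 1], cl$points[, 1], `-`)^2 +
        outer(xyz[, 2], cl$points[, 2], `-`)^2 +
        outer(xyz[, 3], cl$points[, 3], `-`)^2
  nearest <- max.col(-d2)
  mind <- sqrt(d2[cbind(seq_len(nrow(idx)), nearest)])
  inside <- mind <= spec$radius
  idx <- idx[inside, , drop = FALSE]
  nearest <- nearest[inside]
  xyz <- xyz[inside, , drop = FALSE]
  if (nrow(idx) == 0) stop("bundle contains no voxels at this radius/grid")

  if (spec$fibers_fraction < 1) {
    keep <- stats::runif(nrow(idx)) < spec$fibers_fraction
    idx <- idx[keep, , drop = FALSE]; nearest <- nearest[keep]
    xyz <- xyz[keep, , drop = FALSE]
  }

  # fiber-line id from the transported cross-section frame
  off <- xyz - cl$points[nearest, , drop = FALSE]
  u <- rowSums(off * cl$n1[nearest, , drop = FALSE])
  v <- rowSums(off * cl$n2[nearest, , drop = FALSE])
  q <- min(grid$voxel_size)
  key <- paste(round(u / q), round(v / q))
  fiber_id <- match(key, unique(key))

  tangent <- cl$tangents[nearest, , drop = FALSE]
  slot <- integer(nrow(idx))
  pk <- field$peaks
  fa <- field$anisotropy
  nvox <- prod(grid$shape)
  lin <- idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3]) + 1
  np_here <- n_peaks(field)[lin]
  if (any(np_here >= 3)) stop("more than 3 overlapping bundles in a voxel")
  slot <- np_here + 1L
  for (c in 1:3) {
    pk[lin + nvox * ((slot - 1L) + 3 * (c - 1L))] <- tangent[, c]
  }
  fa[lin] <- pmax(fa[lin], spec$fa_inside)
  out <- orientation_field(grid, pk, fa)
  out$bundles <- c(field$bundles,
                   list(list(voxels = unname(idx), slot = slot, fiber_id = fiber_id,
                             tangent = tangent, arc_s = cl$s[nearest], spec = spec)))
  out
}

mirror_bundle_meta <- function(bundles, grid) {
  if (is.null(bundles)) return(NULL)
  ax <- grid$lr_axis
  lapply(bundles, function(b) {
    b$voxels[, ax] <- grid$shape[ax] - 1L - b$voxels[, ax]
    b$tangent[, ax] <- -b$tangent[, ax]
    b
  })
}

# forward radial push: y = x + m * g(|x-c|) * (x-c)/|x-c|, with the C1 bump
# g(s) = (1 - (s/(2r))^2)^2 for s < 2r, 0 beyond
push_profile <- function(s, r) {
  R <- 2 * r
  ifelse(s < R, (1 - (s / R)^2)^2, 0)
}

forward_push <- function(q, center, m, r) {
  d <- sweep(q, 2, center)
  s <- sqrt(rowSums(d^2))
  fac <- ifelse(s > 1e-12, m * push_profile(s, r) / s, 0)
  q + d * fac
}

#' Apply a displacing (mass-effect) lesion to an orientation field
#'
#' A smooth invertible radial push of `magnitude` mm, decaying to zero at
#' twice the lesion radius, moves the bundle geometry away from the lesion
#' center; peaks are re-oriented by the local rotation of the deformation
#' (normalised Jacobian action) and the lesion core is emptied (anisotropy
#' 0, no peaks) to model the tumor mass.
#'
#' @param field an [orientation_field()].
#' @param lesion a [lesion_spec()] with `mode = "displace"`.
#' @export
lesion_displace <- function(field, lesion) {
  stopifnot(lesion$mode == "displace")
  m <- lesion$magnitude; r <- lesion$radius
  if (m == 0) return(field)
  # max |g'| = 1.5396/(2r); the push is invertible iff 1 + m g' > 0
  if (m * 1.5396 / (2 * r) >= 0.999) {
    stop("displacement magnitude too large relative to lesion radius (push not invertible)")
  }
  grid <- field$grid
  c0 <- lesion$center
  R <- 2 * r
  pad <- R + max(grid$voxel_size)
  lo <- pmax(as.integer(floor(world_to_voxel(grid, matrix(c0 - pad, ncol = 3)))), 0L)
  hi <- pmin(as.integer(ceiling(world_to_voxel(grid, matrix(c0 + pad, ncol = 3)))),
             grid$shape - 1L)
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  xyz <- voxel_to_world(grid, idx)
  dvec <- sweep(xyz, 2, c0)
  t_ <- sqrt(rowSums(dvec^2))
  sel <- t_ < R
  idx <- idx[sel, , drop = FALSE]; xyz <- xyz[sel, , drop = FALSE]
  dvec <- dvec[sel, , drop = FALSE]; t_ <- t_[sel]

  pk <- field$peaks; fa <- field$anisotropy
  nvox <- prod(grid$shape)
  dest_lin <- idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3]) + 1

  # invert the radial map by bisection: find s with s + m g(s) = t
  has_pre <- t_ >= m   # points with t < m are vacated by the push
  s_lo <- pmax(t_ - m, 0); s_hi <- t_
  for (it in 1:50) {
    s_mid <- (s_lo + s_hi) / 2
    f_mid <- s_mid + m * push_profile(s_mid, r) - t_
    hit_hi <- f_mid > 0
    s_hi[hit_hi] <- s_mid[hit_hi]
    s_lo[!hit_hi] <- s_mid[!hit_hi]
  }
  s_ <- (s_lo + s_hi) / 2
  pre <- xyz
  ok <- has_pre & t_ > 1e-9
  pre[ok, ] <- sweep(dvec[ok, , drop = FALSE] * (s_[ok] / t_[ok]), 2, c0, `+`)

  src_cont <- world_to_voxel(grid, pre)
  src_vox <- round(src_cont)
  src_vox <- pmin(pmax(src_vox, 0), matrix(grid$shape - 1L, nrow(src_vox), 3, byrow = TRUE))
  src_lin <- src_vox[, 1] + grid$shape[1] * (src_vox[, 2] + grid$shape[2] * src_vox[, 3]) + 1

  # finite-difference Jacobian of the forward push at the preimage
  h <- 0.1
  J <- array(0, c(nrow(pre), 3, 3))
  for (a in 1:3) {
    e <- c(0, 0, 0); e[a] <- h
    J[, , a] <- (forward_push(sweep(pre, 2, e, `+`), c0, m, r) -
                 forward_push(sweep(pre, 2, e, `-`), c0, m, r)) / (2 * h)
  }

  # trilinear, axis-aware pullback of the peaks: the nearest voxel's peak
  # fixes the reference axis, the 8 surrounding voxels' matching peaks are
  # sign-aligned and weight-averaged, so the displaced direction field stays
  # smooth enough to track through the compressed peritumoral shell
  fl <- floor(src_cont)
  fw <- src_cont - fl
  cos45 <- cos(45 * pi / 180)
  new_pk <- pk; new_fa <- fa
  for (p in 1:3) {
    vref <- sapply(1:3, function(c) pk[src_lin + nvox * ((p - 1) + 3 * (c - 1))])
    vref <- matrix(vref, ncol = 3)
    acc <- matrix(0, nrow(vref), 3)
    has_ref <- rowSums(vref^2) > 1e-12
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ci <- pmin(pmax(fl[, 1] + dx, 0), grid$shape[1] - 1L)
      cj <- pmin(pmax(fl[, 2] + dy, 0), grid$shape[2] - 1L)
      ck <- pmin(pmax(fl[, 3] + dz, 0), grid$shape[3] - 1L)
      wt <- (if (dx == 1) fw[, 1] else 1 - fw[, 1]) *
            (if (dy == 1) fw[, 2] else 1 - fw[, 2]) *
            (if (dz == 1) fw[, 3] else 1 - fw[, 3])
      clin <- ci + grid$shape[1] * (cj + grid$shape[2] * ck) + 1
      # best-matching peak of this corner voxel against the reference axis
      bestdot <- rep(0, length(clin))
      bestvec <- matrix(0, length(clin), 3)
      for (q in 1:3) {
        vq <- sapply(1:3, function(c) pk[clin + nvox * ((q - 1) + 3 * (c - 1))])
        vq <- matrix(vq, ncol = 3)
        dq <- rowSums(vq * vref)
        better <- abs(dq) > abs(bestdot)
        bestdot[better] <- dq[better]
        bestvec[better, ] <- vq[better, , drop = FALSE]
      }
      use <- abs(bestdot) > cos45
      if (any(use)) {
        acc[use, ] <- acc[use, , drop = FALSE] +
          (wt[use] * sign(bestdot[use])) * bestvec[use, , drop = FALSE]
      }
    }
    nrmacc <- sqrt(rowSums(acc^2))
    vsrc <- vref
    smooth_ok <- has_ref & nrmacc > 1e-9
    vsrc[smooth_ok, ] <- acc[smooth_ok, , drop = FALSE] / nrmacc[smooth_ok]
    vrot <- sapply(1:3, function(rw) {
      J[, rw, 1] * vsrc[, 1] + J[, rw, 2] * vsrc[, 2] + J[, rw, 3] * vsrc[, 3]
    })
    vrot <- matrix(vrot, ncol = 3)
    nrm <- sqrt(rowSums(vrot^2))
    nz <- nrm > 1e-9 & ok & has_ref
    vrot[nz, ] <- vrot[nz, , drop = FALSE] / nrm[nz]
    vrot[!nz, ] <- 0
    for (c in 1:3) new_pk[dest_lin + nvox * ((p - 1) + 3 * (c - 1))] <- vrot[, c]
  }
  fa_interp <- trilinear_interp(fa, src_cont)
  new_fa[dest_lin] <- ifelse(ok, fa_interp, 0)

  # lesion core: tumor mass, no coherent structure
  core <- t_ <= r
  core_lin <- dest_lin[core]
  for (p in 1:3) for (c in 1:3) new_pk[core_lin + nvox * ((p - 1) + 3 * (c - 1))] <- 0
  new_fa[core_lin] <- 0

  out <- orientation_field(grid, new_pk, new_fa)
  out$bundles <- NULL  # voxel-level bundle metadata no longer valid
  out$displacement <- lesion
  out
}

#' Apply an infiltrating lesion to an orientation field
#'
#' Each fiber line crossing the lesion (identified by the bundle metadata
#' laid down by [synth_bundle()]) is independently deleted with probability
#' `lesion$magnitude`. Deletion removes the fiber's peaks only inside the
#' lesion mask; surviving fibers are untouched, so the bundle thins rather
#' than shifts. Voxels left with no peaks get anisotropy drawn below the
#' 0.2 tracking floor. Uses the current RNG stream.
#'
#' @param field an [orientation_field()] with bundle metadata.
#' @param lesion a [lesion_spec()] with `mode = "infiltrate"`.
#' @export
lesion_infiltrate <- function(field, lesion) {
  stopifnot(lesion$mode == "infiltrate")
  f <- lesion$magnitude
  if (f == 0) return(field)
  if (is.null(field$bundles)) {
    stop("lesion_infiltrate needs the fiber-line metadata created by synth_bundle")
  }
  grid <- field$grid
  les <- sphere_mask(grid, lesion$center, diameter = 2 * lesion$radius)
  nvox <- prod(grid$shape)
  pk <- field$peaks; fa <- field$anisotropy
  record <- list()
  for (bi in seq_along(field$bundles)) {
    b <- field$bundles[[bi]]
    lin <- b$voxels[, 1] + grid$shape[1] * (b$voxels[, 2] + grid$shape[2] * b$voxels[, 3]) + 1
    in_lesion <- les$data[lin]
    crossing <- unique(b$fiber_id[in_lesion])
    if (length(crossing) == 0) {
      record[[bi]] <- list(n_crossing = 0L, n_deleted = 0L, deleted = integer(0))
      next
    }
    deleted <- crossing[stats::runif(length(crossing)) < f]
    kill <- in_lesion & b$fiber_id %in% deleted
    if (any(kill)) {
      klin <- lin[kill]; kslot <- b$slot[kill]
      for (c in 1:3) pk[klin + nvox * ((kslot - 1) + 3 * (c - 1))] <- 0
      # compact peak slots so they stay filled in order
      for (vli in unique(klin)) {
        vecs <- sapply(1:3, function(p) sapply(1:3, function(c)
          pk[vli + nvox * ((p - 1) + 3 * (c - 1))]))
        vecs <- t(vecs)  # rows = slots
        keep <- rowSums(vecs^2) > 1e-12
        vecs <- rbind(vecs[keep, , drop = FALSE], matrix(0, 3 - sum(keep), 3))
        for (p in 1:3) for (c in 1:3) {
          pk[vli + nvox * ((p - 1) + 3 * (c - 1))] <- vecs[p, c]
        }
      }
      # anisotropy below the floor where nothing survives
      dead <- unique(klin)
      still <- sapply(dead, function(vli)
        sum(sapply(1:3, function(p) sum(sapply(1:3, function(c)
          pk[vli + nvox * ((p - 1) + 3 * (c - 1))]^2)))) > 1e-12)
      fa[dead[!still]] <- stats::runif(sum(!still), 0, 0.19)
    }
    record[[bi]] <- list(n_crossing = length(crossing), n_deleted = length(deleted),
                         deleted = deleted)
  }
  out <- orientation_field(grid, pk, fa)
  out$bundles <- field$bundles
  out$infiltration <- list(lesion = lesion, per_bundle = record)
  out
}

#' Build a mirror-symmetric two-hemisphere phantom case
#'
#' Bundles (all specified in the affected hemisphere) are painted into the
#' field, mirrored exactly into the other hemisphere so the pre-lesion
#' left/right fields are mirror images, and the lesion operator is then
#' applied only on the affected side. The returned truth records the
#' pre-lesion fiber populations and what the lesion removed or moved.
#'
#' @param grid a [grid_spec()] (the mid-plane of `lr_axis` is the
#'   inter-hemispheric plane).
#' @param bundles list of [bundle_spec()]s, all lying in one hemisphere.
#' @param lesion a [lesion_spec()] centered in the same hemisphere.
#' @param rng_seed integer seed; all phantom randomness flows through it.
#' @return an object of class `phantom_case`: `field`, `brain_mask`,
#'   `wm_mask`, `lesion_mask`, `truth`, `rng_seed`.
#' @export
make_symmetric_case <- function(grid, bundles, lesion, rng_seed = 1L) {
  if (inherits(bundles, "bundle_spec")) bundles <- list(bundles)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)

  ax <- grid$lr_axis
  mid <- (grid$shape[ax] - 1) / 2
  les_vox <- drop(world_to_voxel(grid, matrix(lesion$center, ncol = 3)))
  if (abs(les_vox[ax] - mid) < 1) stop("lesion must not be centered on the mid-plane")
  side <- sign(les_vox[ax] - mid)

  field <- orientation_field(grid)
  for (b in bundles) field <- synth_bundle(field, b)
  for (b in field$bundles) {
    bs <- sign(b$voxels[, ax] - mid)
    if (any(bs != side)) stop("all bundles must lie in the affected hemisphere")
  }
  healthy_fibers <- vapply(field$bundles, function(b) length(unique(b$fiber_id)),
                           integer(1))

  mirrored <- mirror_field(field)
  pk <- field$peaks + mirrored$peaks
  fa <- pmax(field$anisotropy, mirrored$anisotropy)
  full <- orientation_field(grid, pk, fa)
  full$bundles <- c(field$bundles, mirrored$bundles)

  lesion_mask <- sphere_mask(grid, lesion$center, diameter = 2 * lesion$radius)
  wm_mask <- peak_support_mask(full)

  brain <- array(TRUE, grid$shape)
  brain[c(1, grid$shape[1]), , ] <- FALSE
  brain[, c(1, grid$shape[2]), ] <- FALSE
  brain[, , c(1, grid$shape[3])] <- FALSE
  brain_mask <- mask_volume(grid, brain)

  lesioned <- if (lesion$mode == "displace") {
    lesion_displace(full, lesion)
  } else {
    lesion_infiltrate(full, lesion)
  }

  deleted <- if (!is.null(lesioned$infiltration)) {
    # bundles were ordered affected-hemisphere first
    lapply(lesioned$infiltration$per_bundle[seq_along(bundles)], `[[`, "n_deleted")
  } else {
    rep(list(0L), length(bundles))
  }
  truth <- list(
    healthy_fibers = healthy_fibers,
    lesioned_fibers = healthy_fibers - unlist(deleted),
    lesion = lesion,
    affected_side = side
  )
  structure(list(field = lesioned, brain_mask = brain_mask, wm_mask = wm_mask,
                 lesion_mask = lesion_mask, truth = truth, rng_seed = rng_seed),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", format(x$field$grid), "; lesion mode ",
      x$truth$lesion$mode, " (magnitude ", x$truth$lesion$magnitude, "), seed ",
      x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Reference phantom: one arc bundle crossing a spherical lesion
#'
#' The standard desk-scale study case: a 64 mm cube at 1 mm isotropic
#' resolution containing a gently curved bundle that runs the full
#' anteroposterior extent of one hemisphere, with a lesion at (infiltrate)
#' or beside (displace) its midpoint. Both bundle ends lie beyond the 2 cm
#' peri-lesional exclusion shell, so endpoint clustering finds two opposed
#' targets.
#'
#' @param mode lesion mode, `"displace"` or `"infiltrate"`.
#' @param magnitude push mm (displace; default 5) or removal fraction
#'   (infiltrate).
#' @param rng_seed integer seed.
#' @param shape grid shape (default 64^3, 1 mm isotropic).
#' @param voxel_size voxel dimensions in mm.
#' @return a `phantom_case`.
#' @export
reference_phantom <- function(mode = c("infiltrate", "displace"), magnitude = 0.5,
                              rng_seed = 1L, shape = c(64, 64, 64),
                              voxel_size = c(1, 1, 1)) {
  mode <- match.arg(mode)
  grid <- grid_spec(shape, voxel_size)
  ext <- shape * voxel_size
  # bundle plane and apex on voxel centers, with a gentle arc (sag ~ ext/16)
  # so FACT-style stepping stays faithful to the parallel fiber geometry
  x0 <- voxel_to_world(grid, c(round(0.74 * shape[1]), 0, 0))[1]
  ymid <- voxel_to_world(grid, c(0, round(shape[2] / 2), 0))[2]
  z0 <- voxel_to_world(grid, c(0, 0, round(0.53125 * shape[3])))[3]
  z_apex <- voxel_to_world(grid, c(0, 0, round(0.5625 * shape[3])))[3]
  sag <- z_apex - z0
  yspan <- c(0.0625, 0.28, 0.5, 0.72, 0.9375) * ext[2]
  half <- (yspan[5] - yspan[1]) / 2
  zc <- z_apex - sag * ((yspan - ymid) / half)^2
  cl <- cbind(x0, yspan, zc)
  apex <- c(x0, ymid, z_apex)
  if (mode == "infiltrate") {
    # lesion centered on the bundle and wider than it, so every fiber line
    # crosses; the thick bundle gives enough independent fiber lines for the
    # per-fiber deletion statistics to be stable
    bundle <- bundle_spec(cl, radius = 4.5, fa_inside = 0.8)
    lesion <- lesion_spec(apex, radius = 7, mode = "infiltrate",
                          magnitude = magnitude)
  } else {
    # extra-axial mass beside a slimmer bundle: its surface reaches the
    # centerline and the gentle wide push (decay over 2 radii) slides the
    # whole bundle away without transecting it
    if (missing(magnitude)) magnitude <- 3
    bundle <- bundle_spec(cl, radius = 2.5, fa_inside = 0.8)
    lesion <- lesion_spec(apex - c(0, 0, 7.5), radius = 7.5, mode = "displace",
                          magnitude = magnitude)
  }
  make_symmetric_case(grid, list(bundle), lesion, rng_seed = rng_seed)
}

#' Write a phantom case to a directory of NIfTI volumes plus a truth JSON
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_field_nifti(case$field, file.path(dir, "field"))
  write_nifti(case$brain_mask, file.path(dir, "brain.nii.gz"))
  write_nifti(case$wm_mask, file.path(dir, "wm.nii.gz"))
  write_nifti(case$lesion_mask, file.path(dir, "lesion.nii.gz"))
  truth <- case$truth
  truth$lesion <- unclass(truth$lesion)
  jsonlite::write_json(list(truth = truth, rng_seed = case$rng_seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom_case
#' @export
read_phantom_case <- function(dir) {
  field <- read_field_nifti(file.path(dir, "field"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  structure(list(field = field,
                 brain_mask = read_mask_nifti(file.path(dir, "brain.nii.gz")),
                 wm_mask = read_mask_nifti(file.path(dir, "wm.nii.gz")),
                 lesion_mask = read_mask_nifti(file.path(dir, "lesion.nii.gz")),
                 truth = truth$truth, rng_seed = truth$rng_seed),
            class = "phantom_case")
}
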