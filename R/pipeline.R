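#' Run one case end-to-end in both hemispheres
#'
#' The full lesion-mirrored pipeline: mirror the lesion ROI across the
#' sagittal mid-plane, intersect with white matter to form the seed in the
#' healthy hemisphere (resampled with conservative 0.9 thresholding if the
#' ROI lives on a different grid), track tumor-out from the seed, collect
#' terminal voxels beyond the 2 cm exclusion shell, cluster them, apply the
#' one-vs-two-target rule, whole-brain track, and prune per hemisphere:
#' by the two target spheres when targets are diametrically opposed, or by
#' the 1.2x-dilated homolog ROI and the single target otherwise. The
#' affected hemisphere uses the sagittal mirrors of the same ROIs. The
#' outcome is the per-hemisphere tract count and its percentage decrease.
#'
#' @param field an [orientation_field()].
#' @param brain brain [mask_volume()].
#' @param wm white-matter [mask_volume()].
#' @param lesion_mask lesion [mask_volume()] confined to one hemisphere
#'   (may be on a different grid; it is then resampled conservatively).
#' @param config a [run_config()].
#' @param case_id identifier carried into the result.
#' @return an object of class `case_result`; when no reference tracts are
#'   found in the healthy hemisphere the result carries
#'   `status = "uninformative"` and an `NA` percentage decrease.
#' @export
run_case <- function(field, brain, wm, lesion_mask, config = run_config(),
                     case_id = "case") {
  grid <- field$grid
  params <- config_tracking_params(config)

  if (!grids_equal(lesion_mask$grid, grid)) {
    lesion_mask <- resample_mask(lesion_mask, grid, config$resample_threshold)
  }

  homolog <- mirror_sagittal(lesion_mask)
  seed <- mask_intersect(homolog, wm)
  seed <- mask_intersect(seed, brain)
  if (!any(seed$data)) stop("mirrored lesion does not intersect white matter")

  # stage 1: tumor-out tracking from the healthy-hemisphere homolog seed
  t_seed <- track_from_mask(field, brain, seed, params, label = "homolog_seed")

  exclusion <- dilate_mm(homolog, config$exclusion_mm)
  endpoints <- collect_endpoints(t_seed, exclusion, n_last = config$n_last)
  if (nrow(endpoints) == 0) stop("no endpoints survive the exclusion shell")
  centroids <- cluster_endpoints(endpoints, k_max = config$k_max,
                                 rng_seed = config$rng_seed)
  targets <- select_targets(centroids, seed, grid,
                            opposed_angle = config$opposed_angle,
                            sphere_diameter = config$sphere_diam_mm)

  # stage 2: whole-brain two-ROI analysis, both hemispheres
  t_wb <- track_whole_brain(field, brain, params)
  if (targets$decision == "opposed_pair") {
    roi_h <- list(targets$spheres[[1]], targets$spheres[[2]])
    roi_l <- list(targets$mirrored_spheres[[1]], targets$mirrored_spheres[[2]])
  } else {
    dil_homolog <- dilate_to_factor(seed, config$dilation_factor)
    lesion_endpoint <- if (config$affected_endpoint == "lesion") {
      mask_intersect(lesion_mask, brain)
    } else {
      mirror_sagittal(dil_homolog)
    }
    roi_h <- list(dil_homolog, targets$spheres[[1]])
    roi_l <- list(lesion_endpoint, targets$mirrored_spheres[[1]])
  }
  tract_h <- prune_by_endpoints(t_wb, roi_h[[1]], roi_h[[2]])
  tract_l <- prune_by_endpoints(t_wb, roi_l[[1]], roi_l[[2]])

  n_h <- n_streamlines(tract_h)
  n_l <- n_streamlines(tract_l)
  status <- if (n_h == 0) "uninformative" else "ok"
  if (n_h == 0) {
    warning("no reference tracts in the healthy hemisphere; case is uninformative")
  }
  pct <- if (n_h > 0) percent_decrease(n_h, n_l) else NA_real_

  structure(list(
    case_id = case_id,
    decision = targets$decision,
    n_healthy = n_h,
    n_lesioned = n_l,
    pct_decrease = pct,
    tumor_volume_cm3 = mask_volume_cm3(lesion_mask),
    status = status,
    targets = targets,
    tract_healthy = tract_h,
    tract_lesioned = tract_l,
    seed_mask = seed,
    exclusion_mask = exclusion,
    endpoints = endpoints,
    n_seed_launched = t_seed$provenance$n_launched,
    config = config), class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat("<case_result> ", x$case_id, " (", x$decision, ")\n",
      "  tracts healthy/lesioned: ", x$n_healthy, " / ", x$n_lesioned, "\n",
      "  pct decrease: ", ifelse(is.na(x$pct_decrease), "NA",
                                 sprintf("%.2f%%", x$pct_decrease)),
      "   tumor volume: ", sprintf("%.2f cm^3", x$tumor_volume_cm3), "\n", sep = "")
  invisible(x)
}

#' @method tidy case_result
#' @export
tidy.case_result <- function(x, ...) {
  tibble::tibble(case_id = x$case_id, decision = x$decision,
                 n_healthy = x$n_healthy, n_lesioned = x$n_lesioned,
                 pct_decrease = x$pct_decrease,
                 tumor_volume_cm3 = x$tumor_volume_cm3, status = x$status)
}

#' Probabilistic case analysis: connection-probability maps per hemisphere
#'
#' Repeats the case's two-ROI analysis in the probabilistic framework:
#' whole-brain seeding, `config$iterations` repetitions per launch through
#' the axial dispersion model, retention of streamlines connecting the same
#' ROI pair used deterministically, and a per-hemisphere image whose voxels
#' hold the fraction of retained streamlines entering the voxel.
#'
#' @inheritParams run_case
#' @param det_result optionally, the [run_case()] result to reuse ROIs and
#'   targets from; when `NULL` the deterministic stages are run first.
#' @return list with `map_healthy`, `map_lesioned` ([scalar_volume()]s),
#'   `retained_healthy`, `retained_lesioned`, `launched`, and the
#'   deterministic `case`.
#' @export
run_case_probabilistic <- function(field, brain, wm, lesion_mask,
                                   config = run_config(), case_id = "case",
                                   det_result = NULL) {
  if (is.null(det_result)) {
    det_result <- run_case(field, brain, wm, lesion_mask, config, case_id)
  }
  grid <- field$grid
  params <- config_tracking_params(config)
  targets <- det_result$targets
  if (targets$decision == "opposed_pair") {
    roi_h <- list(targets$spheres[[1]], targets$spheres[[2]])
    roi_l <- list(targets$mirrored_spheres[[1]], targets$mirrored_spheres[[2]])
  } else {
    dil_homolog <- dilate_to_factor(det_result$seed_mask, config$dilation_factor)
    roi_h <- list(dil_homolog, targets$spheres[[1]])
    roi_l <- list(mirror_sagittal(dil_homolog), targets$mirrored_spheres[[1]])
  }
  one_side <- function(rois, seed_offset) {
    fa_ <- field_arrays(field, brain)
    step <- resolve_step(params, grid)
    seed <- mask_intersect(brain, peak_support_mask(field))
    st <- seed_table(field, seed)
    res <- .prob_connection_cpp(fa_$peaks, fa_$fa, fa_$brain, fa_$dims,
                                fa_$affine, fa_$inv, st$seeds, st$peak,
                                step, params$max_turn, params$fa_min,
                                params$min_length,
                                as.integer(ceiling(params$max_length / step)),
                                params$kappa, params$iterations,
                                as.integer(config$rng_seed + seed_offset),
                                array(as.integer(rois[[1]]$data), grid$shape),
                                array(as.integer(rois[[2]]$data), grid$shape))
    list(map = scalar_volume(grid, array(res$probability, grid$shape), clip = c(0, 1)),
         retained = res$retained, launched = res$launched)
  }
  h <- one_side(roi_h, 0L)
  l <- one_side(roi_l, 1L)
  list(map_healthy = h$map, map_lesioned = l$map,
       retained_healthy = h$retained, retained_lesioned = l$retained,
       launched = h$launched, case = det_result)
}

#' Tractogram deviation from a reference point
#'
#' Mean over streamlines of the closest-approach distance to a world-space
#' point; used to quantify how far a displaced bundle detours around a
#' lesion relative to its healthy mirror.
#'
#' @param t a `tractogram`.
#' @param point world coordinates (mm).
#' @export
mean_closest_approach <- function(t, point) {
  if (length(t$streamlines) == 0) return(NA_real_)
  mean(vapply(t$streamlines, function(s) {
    sqrt(min(rowSums(sweep(s$points, 2, point)^2)))
  }, numeric(1)))
}

#' Run the full pipeline on a phantom case
#'
#' Convenience wrapper binding [reference_phantom()] (or any
#' `phantom_case`) to [run_case()].
#'
#' @param case a `phantom_case`.
#' @param config a [run_config()].
#' @param case_id identifier.
#' @export
run_phantom_case <- function(case, config = run_config(), case_id = "phantom") {
  run_case(case$field, case$brain_mask, case$wm_mask, case$lesion_mask,
           config, case_id)
}
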