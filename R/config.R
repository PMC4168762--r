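#' Run configuration
#'
#' Aggregates every tunable of the pipeline with its default: tracking
#' stopping rules, endpoint/target generation settings, the ROI dilation
#' factor, the conservative resampling threshold, and the probabilistic
#' settings. Serialized verbatim into every output directory so any
#' artifact can be reproduced.
#'
#' @param step tracking step (mm); `NULL` = half the smallest voxel.
#' @param fa_min anisotropy floor for tracking.
#' @param max_turn maximum bend across a voxel (degrees).
#' @param min_length minimum streamline length (mm).
#' @param n_last terminal voxels collected per streamline end.
#' @param exclusion_mm peri-lesional exclusion dilation (mm).
#' @param sphere_diam_mm target sphere diameter (mm).
#' @param opposed_angle opposition threshold for the two-target rule (deg).
#' @param k_max maximum k tried by endpoint clustering.
#' @param dilation_factor ROI size factor for single-target pruning.
#' @param resample_threshold conservative mask resampling threshold.
#' @param kappa probabilistic axial concentration.
#' @param iterations probabilistic repetitions per launch.
#' @param affected_endpoint for the affected hemisphere, use the mirrored
#'   dilated homolog ROI (`"mirrored_homolog"`, default) or the original
#'   lesion ROI (`"lesion"`) as the lesion-side endpoint.
#' @param rng_seed integer seed for all stochastic stages.
#' @export
run_config <- function(step = NULL, fa_min = 0.2, max_turn = 60, min_length = 10,
                       n_last = 10, exclusion_mm = 20, sphere_diam_mm = 10,
                       opposed_angle = 120, k_max = 4,
                       dilation_factor = 1.2, resample_threshold = 0.9,
                       kappa = 80, iterations = 1000,
                       affected_endpoint = c("mirrored_homolog", "lesion"),
                       rng_seed = 1L) {
  affected_endpoint <- match.arg(affected_endpoint)
  stopifnot(fa_min >= 0, fa_min <= 1, max_turn > 0, max_turn <= 90,
            n_last >= 1, exclusion_mm >= 0, sphere_diam_mm > 0,
            opposed_angle > 0, opposed_angle <= 180, k_max >= 1,
            dilation_factor >= 1, resample_threshold > 0, resample_threshold <= 1,
            kappa > 0, iterations >= 1)
  structure(list(step = step, fa_min = fa_min, max_turn = max_turn,
                 min_length = min_length, n_last = n_last,
                 exclusion_mm = exclusion_mm, sphere_diam_mm = sphere_diam_mm,
                 opposed_angle = opposed_angle, k_max = k_max,
                 dilation_factor = dilation_factor,
                 resample_threshold = resample_threshold,
                 kappa = kappa, iterations = as.integer(iterations),
                 affected_endpoint = affected_endpoint,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

config_tracking_params <- function(config) {
  tracking_params(step = config$step, max_turn = config$max_turn,
                  fa_min = config$fa_min, min_length = config$min_length,
                  kappa = config$kappa, iterations = config$iterations)
}

#' Write / read a run configuration as flat key=value text
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  vals$step <- if (is.null(vals$step)) "auto" else vals$step
  writeLines(paste0(names(vals), "=", unlist(vals)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                          vapply(kv, `[[`, "", 1))
  num <- function(x) if (identical(x, "auto")) NULL else as.numeric(x)
  run_config(step = num(vals$step %||% "auto"),
             fa_min = as.numeric(vals$fa_min %||% 0.2),
             max_turn = as.numeric(vals$max_turn %||% 60),
             min_length = as.numeric(vals$min_length %||% 10),
             n_last = as.numeric(vals$n_last %||% 10),
             exclusion_mm = as.numeric(vals$exclusion_mm %||% 20),
             sphere_diam_mm = as.numeric(vals$sphere_diam_mm %||% 10),
             opposed_angle = as.numeric(vals$opposed_angle %||% 120),
             k_max = as.numeric(vals$k_max %||% 4),
             dilation_factor = as.numeric(vals$dilation_factor %||% 1.2),
             resample_threshold = as.numeric(vals$resample_threshold %||% 0.9),
             kappa = as.numeric(vals$kappa %||% 80),
             iterations = as.numeric(vals$iterations %||% 1000),
             affected_endpoint = vals$affected_endpoint %||% "mirrored_homolog",
             rng_seed = as.integer(vals$rng_seed %||% 1))
}
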