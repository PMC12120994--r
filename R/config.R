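run_config_defaults <- function() {
  list(
    # scene generation
    image_rows = 512L, image_cols = 512L, pixel_size = NULL,
    n_tubes = 25L, length_mean_um = 3, curvature = 8, psf_sigma = 1.3,
    tube_amplitude = 8000, background_level = 2000,
    illumination_gradient = 0.2, read_noise_sd = 200, shot_noise = TRUE,
    n_scenes = 3L,
    # segmentation
    median_radius = 15L, gaussian_sigma = 1, threshold_method = "otsu",
    min_feature_px = 3L, connectivity = 8L, length_metric = "pixel_count",
    # statistics
    bin_width = 1, fit_lo = 0, fit_hi = 0.99,
    # run control
    seed = 1L, verbosity = 1L)
}

#' Build a run configuration
#'
#' Merges user values over the defaults; `pixel_size` has no default and
#' must be supplied. Unknown keys are rejected. The configuration, together
#' with its single top-level `seed` (from which each scene derives its own
#' seed), reproduces a full run exactly.
#'
#' @param ... configuration values (see [load_run_config()] for the keys).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defaults
  cfg[names(user)] <- user
  if (is.null(cfg$pixel_size))
    stop("missing required configuration key: pixel_size", call. = FALSE)
  stopifnot_scalar_pos(cfg$pixel_size, "pixel_size")
  structure(cfg, class = "run_config")
}

#' Load / save a run configuration (YAML)
#'
#' @param path path to a YAML file of configuration keys.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' @rdname load_run_config
#' @param config a `run_config`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

scene_spec_from_config <- function(config, seed) {
  scene_spec(image_shape = c(config$image_rows, config$image_cols),
             pixel_size = config$pixel_size,
             n_tubes = config$n_tubes,
             length_distribution = dist_exponential(config$length_mean_um),
             curvature = config$curvature, psf_sigma = config$psf_sigma,
             tube_amplitude = config$tube_amplitude,
             background_level = config$background_level,
             illumination_gradient = config$illumination_gradient,
             read_noise_sd = config$read_noise_sd,
             shot_noise = config$shot_noise, seed = seed)
}

pipeline_config_from_config <- function(config) {
  pipeline_config(median_radius = config$median_radius,
                  gaussian_sigma = config$gaussian_sigma,
                  threshold_method = config$threshold_method,
                  min_feature_px = config$min_feature_px,
                  connectivity = config$connectivity,
                  length_metric = config$length_metric)
}

run_stage <- function(name, verbosity, expr) {
  if (verbosity > 0) message("[tubequant] stage: ", name)
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Simulate, segment and summarize in one run
#'
#' Generates `n_scenes` synthetic micrographs (each scene acting as one
#' experimental replicate), runs the segmentation pipeline on each, computes
#' the growth statistics, and writes every artifact (config snapshot,
#' micrographs, per-image records/params/overlays, statistics CSVs, and a
#' machine-readable JSON report comparing measured lengths against the
#' generator's ground truth).
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @param out_dir output directory.
#' @return Invisible list of class `run_report`.
#' @export
end_to_end <- function(config, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_run_config(config, file.path(out_dir, "config.yaml"))
  pcfg <- pipeline_config_from_config(config)
  verb <- config$verbosity

  samples <- list(); gts <- list(); thresholds <- numeric(0)
  for (i in seq_len(config$n_scenes)) {
    scene <- run_stage(sprintf("simulate scene %d", i), verb, {
      sp <- scene_spec_from_config(config, derive_seed(config$seed, i))
      render_scene(sp)
    })
    scene$micrograph$image_id <- sprintf("scene%02d", i)
    run_stage(sprintf("write scene %d", i), verb, {
      write_micrograph(scene$micrograph,
                       file.path(out_dir, sprintf("scene%02d.tif", i)))
      write_ground_truth(scene$ground_truth,
                         file.path(out_dir, sprintf("scene%02d_truth.csv", i)))
    })
    seg <- run_stage(sprintf("segment scene %d", i), verb,
                     run_pipeline(scene$micrograph, pcfg, out_dir = out_dir))
    thresholds[i] <- seg$threshold
    gts[[i]] <- scene$ground_truth
    if (nrow(seg$records) > 0)
      samples[[length(samples) + 1]] <-
        length_sample(seg$records$length_um,
                      replicate_id = sprintf("scene%02d", i))
  }

  stats <- if (length(samples) > 0)
    run_stage("statistics", verb,
              write_statistics(samples, file.path(out_dir, "stats"),
                               bin_width = config$bin_width,
                               fit_range = c(config$fit_lo, config$fit_hi)))
  else NULL

  true_lengths <- unlist(lapply(gts, function(g) g$true_length_um))
  measured_mean <- if (is.null(stats)) NA_real_ else stats$summary$grand_mean
  report <- list(
    n_scenes = config$n_scenes,
    n_tubes_true = length(true_lengths),
    n_measured = if (is.null(stats)) 0L else as.integer(stats$summary$n_total),
    thresholds = thresholds,
    true_mean_um = if (length(true_lengths)) mean(true_lengths) else NA_real_,
    nominal_mean_um = config$length_mean_um,
    measured_mean_um = measured_mean,
    measured_error_um = if (is.null(stats)) NA_real_ else stats$summary$error,
    relative_mean_error = if (is.null(stats)) NA_real_ else
      abs(measured_mean - config$length_mean_um) / config$length_mean_um,
    ccdf_slope = if (is.null(stats)) NA_real_ else stats$fit$slope)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d scenes, %d/%d tubes measured\n",
              x$n_scenes, x$n_measured, x$n_tubes_true))
  cat(sprintf("  mean length: measured %.3g +/- %.3g um, ground truth %.3g um, nominal %.3g um\n",
              x$measured_mean_um, x$measured_error_um, x$true_mean_um,
              x$nominal_mean_um))
  cat(sprintf("  relative error vs nominal: %.1f%%; normalized CCDF slope %.3f\n",
              100 * x$relative_mean_error, x$ccdf_slope))
  invisible(x)
}
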