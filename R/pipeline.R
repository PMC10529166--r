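#' End-to-end assessment pipeline and configuration
#'
#' Orchestrates segment -> find marker -> measure area -> classify tissue on a
#' photograph plus a user scribble, producing an [assessment_report()].  A
#' marker that fails geometric validation does not abort the run: the report
#' carries a machine-readable rejection reason and no physical area, matching
#' the capture protocol in which an inclined or occluded marker means the
#' photograph must be retaken.
#'
#' @name pipeline
NULL

default_config_list <- function() {
  list(
    segmentation = list(n_segments = 100L, compactness = 10, max_iter = 10L,
                        sigma = 3, enforce_connectivity = TRUE,
                        merge_threshold = 20,
                        retry_n_segments = c(150L, 200L, 300L)),
    marker = list(hue_low = 200, hue_high = 260, sat_low = 0.35, sat_high = 1,
                  val_low = 0.20, val_high = 1, min_proportionality = 0.8,
                  max_asymmetry = 0.2, min_area_px = 400),
    tissue = list(model_path = NULL, size_small_max = 5, size_medium_max = 20),
    seed = 1L,
    log_level = "info")
}

validate_config <- function(cfg) {
  if (cfg$segmentation$n_segments < 2)
    stop_wm("config error: segmentation.n_segments must be >= 2",
            class = "config_error")
  if (cfg$segmentation$sigma < 0)
    stop_wm("config error: segmentation.sigma must be >= 0", class = "config_error")
  if (cfg$marker$hue_low > cfg$marker$hue_high)
    stop_wm("config error: marker hue range inverted", class = "config_error")
  if (cfg$tissue$size_small_max >= cfg$tissue$size_medium_max)
    stop_wm("config error: tissue size thresholds must increase",
            class = "config_error")
  cfg
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop_wm("config error: unknown key '", full, "'", class = "config_error")
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop_wm("config error: '", full, "' must be a mapping", class = "config_error")
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a pipeline configuration file
#'
#' The configuration is a YAML mapping with sections `segmentation`, `marker`
#' and `tissue` plus top-level `seed` and `log_level`; every key has a
#' default, unknown keys are rejected, and values are validated.  An empty (or
#' missing) file yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config_list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_wm("config file not found: ", path, class = "config_error")
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(validate_config(cfg), class = "pipeline_config")
}

config_superpixel_params <- function(cfg) {
  superpixel_params(n_segments = cfg$segmentation$n_segments,
                    compactness = cfg$segmentation$compactness,
                    max_iter = cfg$segmentation$max_iter,
                    sigma = cfg$segmentation$sigma,
                    enforce_connectivity = cfg$segmentation$enforce_connectivity)
}

config_hsv_range <- function(cfg) {
  hsv_range(hue_deg = c(cfg$marker$hue_low, cfg$marker$hue_high),
            sat = c(cfg$marker$sat_low, cfg$marker$sat_high),
            val = c(cfg$marker$val_low, cfg$marker$val_high))
}

config_marker_qc <- function(cfg) {
  marker_qc(min_proportionality = cfg$marker$min_proportionality,
            max_asymmetry = cfg$marker$max_asymmetry,
            min_area_px = cfg$marker$min_area_px)
}

#' Run the full assessment pipeline
#'
#' @param image an [rgb_image()] or a path readable by [read_image()].
#' @param scr a [scribble()] inside the wound (or an `n x 2` point matrix).
#' @param config a [load_config()] result (default configuration if omitted).
#' @param model optional trained [tissue_model()] (overrides
#'   `config$tissue$model_path`); when neither is given, tissue
#'   classification is skipped.
#' @return an [assessment_report()].  `status` in the provenance is `"ok"` or
#'   `"marker_rejected"`.
#' @export
run_pipeline <- function(image, scr, config = load_config(), model = NULL) {
  if (is.character(image)) image <- read_image(image)
  if (!inherits(scr, "scribble")) scr <- scribble(scr)
  params <- config_superpixel_params(config)
  labels <- compute_superpixels(image, params)
  roi <- merge_from_scribble(labels, image, scr,
                             merge_threshold = config$segmentation$merge_threshold,
                             params = params)
  marker <- find_marker(image, config_hsv_range(config), config_marker_qc(config))
  prov <- list(package_version = as.character(utils::packageVersion("woundmetric")),
               n_segments = params$n_segments, sigma = params$sigma,
               compactness = params$compactness,
               merge_threshold = config$segmentation$merge_threshold,
               seed = config$seed)
  if (is.null(model) && !is.null(config$tissue$model_path))
    model <- load_tissue_model(config$tissue$model_path)
  fractions <- NULL
  if (!is.null(model) && mask_area_px(roi$wound_mask) > 0)
    fractions <- classify_tissue_fractions(model, image, roi$wound_mask)
  if (!marker$valid) {
    prov$status <- "marker_rejected"
    return(assessment_report(area_cm2 = NA_real_, scale_cm2_per_px = NA_real_,
                             marker = marker, tissue_fractions = fractions,
                             provenance = prov))
  }
  area <- measure_area(roi, marker)
  prov$status <- "ok"
  prov$size_category <- as.character(size_category(
    area, c(config$tissue$size_small_max, config$tissue$size_medium_max)))
  assessment_report(area_cm2 = area, scale_cm2_per_px = marker$scale_cm2_per_px,
                    marker = marker, tissue_fractions = fractions,
                    provenance = prov)
}
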