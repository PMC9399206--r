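#' Pipeline configuration
#'
#' Collects every tunable of the scoring pipeline in one validated object:
#' Savitzky-Golay filter settings, velocity-band and distance-zone
#' thresholds, gripper hysteresis, cross-validation layout and the
#' hyperparameter grids of the four regression algorithms.
#'
#' Internal units are millimetres, seconds and radians throughout.
#'
#' @param sg_window Savitzky-Golay window length in samples; odd,
#'   greater than `sg_polyorder`. Default 21.
#' @param sg_polyorder Polynomial order of the local fit. Default 3, the
#'   minimum for a finite third derivative (jerk).
#' @param velocity_thresholds Four strictly ascending speeds (mm/s)
#'   separating the Idle / Low / Middle / High / Very_high bands.
#' @param zone_boundaries Two ascending distances (mm) separating the
#'   Close / Near / Far zones around the target structure.
#' @param gripper_open,gripper_close Hysteresis thresholds (rad) for
#'   counting gripper opening/closing cycles; `gripper_open > gripper_close`.
#' @param adbo_window Half-width (s) of the window around gripper events
#'   used for the ADBO bimanual metric.
#' @param idle_threshold Speed (mm/s) below which a tip counts as idle;
#'   defaults to the first velocity threshold.
#' @param selection_threshold Absolute Spearman correlation above which a
#'   metric is selected for an item (strict inequality). Default 0.4.
#' @param k_outer,k_inner Outer/inner cross-validation fold counts.
#' @param repetitions Number of repetitions of the nested CV.
#' @param seed Master seed for the validation protocol.
#' @param grids Hyperparameter grids, as produced by [default_grids()];
#'   `NULL` defers to the defaults at fit time.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @seealso [read_pipeline_config()], [default_grids()]
#' @export
pipeline_config <- function(sg_window = 21L,
                            sg_polyorder = 3L,
                            velocity_thresholds = c(5, 25, 75, 150),
                            zone_boundaries = c(20, 50),
                            gripper_open = 0.35,
                            gripper_close = 0.15,
                            adbo_window = 0.25,
                            idle_threshold = NULL,
                            selection_threshold = 0.4,
                            k_outer = 10L,
                            k_inner = 10L,
                            repetitions = 100L,
                            seed = 1L,
                            grids = NULL) {
  cfg <- list(
    sg_window = as.integer(sg_window),
    sg_polyorder = as.integer(sg_polyorder),
    velocity_thresholds = as.numeric(velocity_thresholds),
    zone_boundaries = as.numeric(zone_boundaries),
    gripper_open = gripper_open,
    gripper_close = gripper_close,
    adbo_window = adbo_window,
    idle_threshold = if (is.null(idle_threshold)) velocity_thresholds[1] else idle_threshold,
    selection_threshold = selection_threshold,
    k_outer = as.integer(k_outer),
    k_inner = as.integer(k_inner),
    repetitions = as.integer(repetitions),
    seed = as.integer(seed),
    grids = grids
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$sg_window %% 2L != 1L || cfg$sg_window <= cfg$sg_polyorder) {
    stop("configuration error: sg_window must be odd and exceed sg_polyorder",
         call. = FALSE)
  }
  if (length(cfg$velocity_thresholds) != 4L ||
      any(diff(cfg$velocity_thresholds) <= 0)) {
    stop("configuration error: velocity_thresholds must be 4 strictly ascending speeds",
         call. = FALSE)
  }
  if (length(cfg$zone_boundaries) != 2L || any(diff(cfg$zone_boundaries) <= 0)) {
    stop("configuration error: zone_boundaries must be 2 ascending distances",
         call. = FALSE)
  }
  if (cfg$gripper_open <= cfg$gripper_close) {
    stop("configuration error: gripper_open must exceed gripper_close (hysteresis)",
         call. = FALSE)
  }
  if (cfg$k_outer < 2L || cfg$k_inner < 2L) {
    stop("configuration error: k_outer and k_inner must be >= 2", call. = FALSE)
  }
  if (cfg$repetitions < 1L) {
    stop("configuration error: repetitions must be >= 1", call. = FALSE)
  }
  if (cfg$selection_threshold <= 0 || cfg$selection_threshold > 1) {
    stop("configuration error: selection_threshold must be in (0, 1]", call. = FALSE)
  }
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the [pipeline_config()] defaults;
#' everything else keeps its default, so partial files are valid.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("configuration error: unsupported config format '.", ext, "'", call. = FALSE)
  )
  if (!is.list(raw)) stop("configuration error: malformed config file ", path, call. = FALSE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("configuration error: unknown config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}
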