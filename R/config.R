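#' Default run configuration
#'
#' All tunable pipeline parameters with their documented defaults. Blur radii
#' and contour widths are in pixels (the scales the source scripts use),
#' tracking bounds in micrometres, and the osmolarity block carries the
#' isosmotic medium (341 mOsm), the ideal-dissociation osmolarity of the
#' water + 1.26 mM CaCl2 diluent (3 x 1.26 = 3.78 mOsm) and the two dilution
#' presets (mild 80/320 uL, maximal 40/360 uL).
#'
#' @return A nested named list of parameters.
#' @export
default_config <- function() {
  list(
    mode = "all",
    seed = 1L,
    output_dir = "rimquant-out",
    calibration = list(dx = 0.16, dy = 0.16, dz = 1.5, dt = 1),
    guv = list(
      blur_sigma_px = 3,
      contour_width_px = 3,
      norm_percentiles = c(0.001, 0.999),
      min_crop_px = 8,
      measure_on = "raw"
    ),
    nuclei = list(
      blur_sigma_px = 1,
      rolling_ball_radius_px = 50,
      contour_width_px = 3,
      min_volume_vox = 200,
      marker_erode_px = 7,
      refine_keep_fraction = 0.6,
      background_ring_fraction = 0.5
    ),
    tracking = list(
      max_displacement_um = 50,
      min_track_length = 3
    ),
    er = list(
      min_volume_vox = 10,
      marker_erode_px = 0,
      ridge_sigmas_px = c(1, 2),
      perimeter_method = "contour"
    ),
    rate = list(
      window_fraction = 0.3,
      min_r2 = 0.9
    ),
    osmolarity = list(
      iso_mosm = 341,
      diluent_mosm = 3.78,
      presets = list(
        mild = list(v_start_ul = 80, v_diluent_ul = 320),
        maximal = list(v_start_ul = 40, v_diluent_ul = 360)
      )
    ),
    buffers = list(
      # GUV binding buffers: hypoosmotic differential and free calcium
      guv_no_ca = list(delta_mosm = 240, kcl_mm = 113.5, free_ca_um = 0),
      guv_ca = list(delta_mosm = 240, kcl_mm = 106, free_ca_um = 20)
    )
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Every key in the
#' file must exist in the default tree; a misspelled or unknown key raises a
#' validation error naming it. An empty or missing file yields the full
#' default configuration.
#'
#' @param path Optional path to a YAML configuration file.
#' @return The merged configuration list.
#' @examples
#' cfg <- load_config()
#' cfg$nuclei$contour_width_px
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user, prefix = character(0))
}

merge_config <- function(base, user, prefix) {
  if (!is.list(user)) stop("configuration section '", paste(prefix, collapse = "."),
                           "' must be a mapping")
  for (key in names(user)) {
    path <- c(prefix, key)
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", paste(path, collapse = "."))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]], path)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

config_calibration <- function(cfg) {
  do.call(pixel_calibration, cfg$calibration)
}
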