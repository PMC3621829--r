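# Run configuration: one YAML-backed structure tying the module constants
# together so that any run is reproducible from (config file, seed) alone.

run_config_defaults <- function() {
  list(schema = "cytofocus-config-1",
       pixel_size_um = 0.92,
       seed = 1L,
       filters = list(size_min_px = 50, canny_high = 0.07,
                      canny_sigma = 1.41, canny_low_ratio = 0.4,
                      color_min_px = 10, background_level = 230 / 255,
                      bg_margin = 0.05),
       sharpness = list(svm_sigma = 1, max_cells = 200, tile_px = 64,
                        overview_px = 384, min_area_px = 50,
                        max_area_px = 1e6),
       workflow = list(initial_points = 12, point_increment = 12,
                       max_points = 85, min_valid = 6,
                       max_focus_iters = 5, restart_cap = 2,
                       max_scan_rounds = 7, sharpness_threshold = 90,
                       oof_score = 30, oof_regions = 12),
       slide = list(n_cells = 500, z_range_um = 21, dust_density = 2,
                    dust_layer_offset_um = 40, width_px = 4096,
                    height_px = 4096, circle_diameter_um = 2200,
                    noise_sd = 0.005))
}

#' Load a run configuration
#'
#' Reads a YAML file, applies defaults for omitted keys, and rejects
#' unknown keys by name. An empty (or missing-section) file yields the
#' full defaults: 90% sharpness threshold, 12 initial focus points,
#' 0.92 um working pixels.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return a `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("malformed config file: ", conditionMessage(e)))
    if (is.null(user)) user <- list()
    merge_level <- function(base, over, prefix = "") {
      for (nm in names(over)) {
        if (!nm %in% names(base))
          stop("unknown configuration key: ", prefix, nm)
        if (is.list(base[[nm]]) && is.list(over[[nm]])) {
          base[[nm]] <- merge_level(base[[nm]], over[[nm]],
                                    paste0(prefix, nm, "."))
        } else base[[nm]] <- over[[nm]]
      }
      base
    }
    cfg <- merge_level(cfg, user)
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  w <- cfg$workflow
  stopifnot(cfg$pixel_size_um > 0,
            w$sharpness_threshold >= 0, w$sharpness_threshold <= 100,
            w$initial_points >= 1, w$min_valid >= 1,
            w$max_focus_iters >= 1, w$max_scan_rounds >= 1,
            cfg$filters$size_min_px >= 0, cfg$filters$canny_high > 0,
            cfg$slide$n_cells >= 0, cfg$slide$z_range_um >= 0)
  invisible(cfg)
}

#' Save a run configuration as YAML
#'
#' Round-trips losslessly through [load_config()].
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Materialize module configurations from a run configuration
#'
#' @param cfg a `run_config`.
#' @return list with a `filter_config`, a `workflow_config` and the slide
#'   generator arguments.
#' @export
expand_config <- function(cfg) {
  fc <- do.call(filter_config, cfg$filters)
  wf <- workflow_config(
    initial_points = cfg$workflow$initial_points,
    point_increment = cfg$workflow$point_increment,
    max_points = cfg$workflow$max_points,
    min_valid = cfg$workflow$min_valid,
    max_focus_iters = cfg$workflow$max_focus_iters,
    restart_cap = cfg$workflow$restart_cap,
    max_scan_rounds = cfg$workflow$max_scan_rounds,
    sharpness_threshold = cfg$workflow$sharpness_threshold,
    oof_score = cfg$workflow$oof_score,
    oof_regions = cfg$workflow$oof_regions,
    max_cells = cfg$sharpness$max_cells,
    overview_px = cfg$sharpness$overview_px,
    tile_px = cfg$sharpness$tile_px,
    filter = fc, seed = cfg$seed)
  slide_args <- cfg$slide
  slide_args$pixel_size_um <- cfg$pixel_size_um
  slide_args$seed <- cfg$seed
  list(filter = fc, workflow = wf, slide_args = slide_args)
}
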