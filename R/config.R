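# System configuration: one human-editable YAML file holding every tunable
# constant (sensor catalog, chosen assembly, rig geometry, detection
# thresholds, CNN recipe, class boundaries, action policy). Nothing in the
# processing logic hard-codes these values.

.default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "stereobird",
              mustWork = TRUE)
}

.known_keys <- list(
  top = c("seed", "sensor", "focal_length", "rig", "detection", "cnn",
          "boundaries", "policy", "sync_tolerance", "match", "sensors",
          "paths"),
  rig = c("baseline", "vsr_axis", "fov_axis", "tilt_alpha"),
  detection = c("kernel", "sigma", "diff_thresh", "merge_kernel",
                "merge_sigma", "binary_thresh", "min_w", "min_h", "refine",
                "refine_thresh", "crop_size"),
  cnn = c("lc1", "lc2", "lfc1", "lfc2", "kernel", "input_size", "channels",
          "learning_rate", "adam_epsilon", "epochs", "validation_split",
          "batch_size"),
  boundaries = c("wingspan", "height", "area"),
  policy = c("deterrent_distance", "stop_distance"),
  match = c("max_center_diff", "min_ydiff"),
  paths = c("archive", "media")
)

.check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop(sprintf("load_config: unknown key%s in %s: %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")))
}

#' Load and validate a system configuration
#'
#' Reads a YAML configuration, fills unspecified optional blocks from the
#' shipped defaults, rejects unknown keys, and validates every module-level
#' invariant on load. A `rig:` block, if present, must be complete -- the
#' rig is a physical unit and silently defaulting its geometry would be
#' unsafe -- so a missing geometry key is an error naming that key.
#'
#' @param path YAML file; `NULL` loads the shipped default configuration
#'   (C1 sensor, f = 3 mm, B = 1 m, FoV 63.0 degrees).
#' @return Object of class `system_config` with constructed components:
#'   `assembly`, `rig`, `detection`, `cnn`, `boundaries`, `policy`,
#'   `catalog`, plus the raw values.
#' @export
load_config <- function(path = NULL) {
  raw_default <- yaml::read_yaml(.default_config_path())
  raw <- if (is.null(path)) raw_default else yaml::read_yaml(path)
  .check_keys(raw, .known_keys$top, "configuration")
  for (blk in c("detection", "cnn", "boundaries", "policy", "match", "paths"))
    if (!is.null(raw[[blk]])) .check_keys(raw[[blk]], .known_keys[[blk]], blk)
  if (!is.null(raw$rig)) {
    .check_keys(raw$rig, .known_keys$rig, "rig")
    for (k in c("baseline", "vsr_axis", "fov_axis"))
      if (is.null(raw$rig[[k]]))
        stop(sprintf("load_config: rig block is missing required key \"%s\"", k))
  }
  cfg <- utils::modifyList(raw_default, raw)

  catalog <- lapply(names(cfg$sensors), function(nm) {
    s <- cfg$sensors[[nm]]
    sensor_spec(nm, s$vsr_h, s$vsr_v, s$vss_h, s$vss_v)
  })
  names(catalog) <- names(cfg$sensors)
  if (!cfg$sensor %in% names(catalog))
    stop(sprintf("load_config: sensor \"%s\" not in catalog", cfg$sensor))
  assembly <- optical_assembly(catalog[[cfg$sensor]], cfg$focal_length)
  rig <- stereo_rig(cfg$rig$baseline, cfg$rig$vsr_axis, cfg$rig$fov_axis,
                    if (is.null(cfg$rig$tilt_alpha)) cfg$rig$fov_axis / 2
                    else cfg$rig$tilt_alpha)
  pol <- cfg$policy
  to_named <- function(x) {
    v <- c(small = NA_real_, medium = NA_real_, large = NA_real_)
    for (nm in intersect(names(x), names(v)))
      if (!is.null(x[[nm]])) v[nm] <- as.numeric(x[[nm]])
    v
  }
  structure(list(
    seed = cfg$seed,
    assembly = assembly, rig = rig, catalog = catalog,
    detection = do.call(detection_params, cfg$detection),
    cnn = do.call(cnn_config, cfg$cnn),
    boundaries = size_class_boundaries(unlist(cfg$boundaries$wingspan),
                                       unlist(cfg$boundaries$height),
                                       unlist(cfg$boundaries$area)),
    policy = action_policy(to_named(pol$deterrent_distance),
                           to_named(pol$stop_distance)),
    sync_tolerance = cfg$sync_tolerance,
    match = cfg$match,
    paths = cfg$paths,
    raw = cfg
  ), class = "system_config")
}

#' Save a configuration back to YAML
#'
#' Writes the raw key/value form, so `load_config(save_config(cfg, f))`
#' round-trips.
#'
#' @param config a `system_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "system_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf("<system_config %s + f=%g mm | rig B=%g m, %d px, FoV %.1f deg | seed %d>\n",
              x$assembly$sensor$name, x$assembly$f, x$rig$baseline,
              x$rig$vsr_axis, x$rig$fov_axis, x$seed))
  invisible(x)
}

#' Export a selection table as CSV
#'
#' @param table result of [build_selection_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
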