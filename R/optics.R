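# Optical design calculator: fields of view, on-image object size, and
# sensor/lens feasibility for the detection-module case study.
#
# Unit conventions (enforced here, used package-wide):
#   sensor sizes (VSS) and focal lengths in millimetres,
#   object sizes and distances in metres,
#   angles in degrees at every public interface (radians only inside trig).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Vision sensor specification
#'
#' Describes a sensor by its resolution (px) and physical size (mm) on the
#' horizontal and vertical axes, mirroring a manufacturer data sheet.
#'
#' @param name sensor identifier, e.g. `"C1"`.
#' @param vsr_h,vsr_v resolution in pixels, horizontal / vertical.
#' @param vss_h,vss_v physical sensor size in mm, horizontal / vertical.
#' @return An object of class `sensor_spec`.
#' @export
#' @examples
#' sensor_spec("C1", 3280, 2464, 3.680, 2.760)
sensor_spec <- function(name, vsr_h, vsr_v, vss_h, vss_v) {
  vals <- c(vsr_h = vsr_h, vsr_v = vsr_v, vss_h = vss_h, vss_v = vss_v)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("sensor_spec: all resolution/size fields must be strictly positive")
  structure(list(name = as.character(name), vsr_h = vsr_h, vsr_v = vsr_v,
                 vss_h = vss_h, vss_v = vss_v),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec %s: %d x %d px, %.3f x %.3f mm (%.1f / %.1f px/mm)>\n",
              x$name, x$vsr_h, x$vsr_v, x$vss_h, x$vss_v,
              x$vsr_h / x$vss_h, x$vsr_v / x$vss_v))
  invisible(x)
}

#' Optical assembly: a sensor paired with a lens
#'
#' @param sensor a [sensor_spec()].
#' @param f focal length in mm (> 0).
#' @return An object of class `optical_assembly` with derived fields of view
#'   (degrees) and pixel-per-mm ratios.
#' @export
optical_assembly <- function(sensor, f) {
  stopifnot(inherits(sensor, "sensor_spec"))
  if (!is.finite(f) || f <= 0) stop("optical_assembly: focal length must be > 0")
  structure(list(sensor = sensor, f = f,
                 fov_h = compute_fov(sensor$vss_h, f),
                 fov_v = compute_fov(sensor$vss_v, f)),
            class = "optical_assembly")
}

#' @export
print.optical_assembly <- function(x, ...) {
  cat(sprintf("<optical_assembly %s + f=%g mm: FoV %.1f x %.1f deg>\n",
              x$sensor$name, x$f, x$fov_h, x$fov_v))
  invisible(x)
}

#' Field of view of a sensor extent behind a lens
#'
#' Pinhole relation `FoV = 2 atan(VSS / 2f)`.
#'
#' @param sensor_extent sensor size along the axis, mm.
#' @param f focal length, mm.
#' @return Field of view in degrees, in (0, 180).
#' @export
#' @examples
#' compute_fov(3.680, 3) # 63.0 deg (horizontal axis of a 1/4" 8MP sensor)
compute_fov <- function(sensor_extent, f) {
  if (any(!is.finite(sensor_extent)) || any(sensor_extent <= 0))
    stop("compute_fov: sensor extent must be > 0")
  if (any(!is.finite(f)) || any(f <= 0))
    stop("compute_fov: focal length must be > 0")
  rad2deg(2 * atan(sensor_extent / (2 * f)))
}

#' Coverage requirement for a multi-module installation
#'
#' @param n_modules_max maximum number of detection modules around the tower.
#' @param dead_zone_distance maximal acceptable dead-zone distance E, m.
#' @param blade_rotation_diameter rotor diameter RB, m.
#' @param min_detect_px_w,min_detect_px_h minimum on-image object size in px
#'   for reliable detection (rule of thumb: 12 x 2).
#' @return An object of class `coverage_requirement`.
#' @export
coverage_requirement <- function(n_modules_max = 10,
                                 dead_zone_distance = 40,
                                 blade_rotation_diameter = 80,
                                 min_detect_px_w = 12,
                                 min_detect_px_h = 2) {
  if (n_modules_max < 1) stop("coverage_requirement: n_modules_max must be >= 1")
  if (dead_zone_distance <= 0 || blade_rotation_diameter <= 0)
    stop("coverage_requirement: distances must be > 0")
  if (min_detect_px_w < 1 || min_detect_px_h < 1)
    stop("coverage_requirement: pixel minima must be >= 1")
  structure(list(n_modules_max = n_modules_max,
                 dead_zone_distance = dead_zone_distance,
                 blade_rotation_diameter = blade_rotation_diameter,
                 min_detect_px_w = min_detect_px_w,
                 min_detect_px_h = min_detect_px_h),
            class = "coverage_requirement")
}

#' Minimum required fields of view
#'
#' Horizontal: full 360 degree coverage split over `n_modules_max` modules.
#' Vertical: the dead zone below the rotor must not exceed
#' `dead_zone_distance`, giving `90 - atan(E / RB)` degrees. Values are
#' returned unrounded; presentation may floor them.
#'
#' @param req a [coverage_requirement()].
#' @return Named numeric vector `c(fov_h, fov_v)` in degrees.
#' @export
min_required_fovs <- function(req = coverage_requirement()) {
  stopifnot(inherits(req, "coverage_requirement"))
  c(fov_h = 360 / req$n_modules_max,
    fov_v = 90 - rad2deg(atan(req$dead_zone_distance /
                                req$blade_rotation_diameter)))
}

#' On-image size of an object
#'
#' Projects a physical extent through the pinhole model:
#' `px = size_m * f * (VSR / VSS) / distance_m`. Continuous value; no
#' rounding is applied.
#'
#' @param size_m physical object extent, m.
#' @param distance_m distance from the camera, m.
#' @param assembly an [optical_assembly()].
#' @param axis `"h"` or `"v"` -- which sensor axis the extent projects onto.
#' @return Object extent on the image in pixels (continuous).
#' @export
#' @examples
#' c1 <- optical_assembly(sensor_spec("C1", 3280, 2464, 3.680, 2.760), 3)
#' image_size_of_object(1.5, 300, c1, "h") # about 13.4 px
image_size_of_object <- function(size_m, distance_m, assembly, axis = c("h", "v")) {
  axis <- match.arg(axis)
  if (any(size_m <= 0) || any(assembly$f <= 0))
    stop("image_size_of_object: size and focal length must be > 0")
  if (any(!is.finite(distance_m)) || any(distance_m <= 0))
    stop("image_size_of_object: distance must be > 0")
  s <- assembly$sensor
  ratio <- if (axis == "h") s$vsr_h / s$vss_h else s$vsr_v / s$vss_v  # px/mm
  size_m * assembly$f * ratio / distance_m
}

#' Detectability of an object at distance
#'
#' Checks the projected pixel extents against the minimum detectable size
#' (default 12 x 2 px), per axis.
#'
#' @param size_w,size_h physical wingspan and body height, m.
#' @param distance distance from the camera, m.
#' @param assembly an [optical_assembly()].
#' @param req a [coverage_requirement()] carrying the pixel minima.
#' @return Logical vector `c(width_ok, height_ok)`.
#' @export
detectability_check <- function(size_w, size_h, distance, assembly,
                                req = coverage_requirement()) {
  if (!is.finite(distance) || distance <= 0) {
    # limit case distance -> Inf: nothing is resolvable
    return(c(width_ok = FALSE, height_ok = FALSE))
  }
  pw <- image_size_of_object(size_w, distance, assembly, "h")
  ph <- image_size_of_object(size_h, distance, assembly, "v")
  c(width_ok = pw >= req$min_detect_px_w,
    height_ok = ph >= req$min_detect_px_h)
}

#' Sensor/lens selection table
#'
#' One row per (sensor, focal length) pair: fields of view (rounded to
#' 0.1 degree for presentation), continuous projected pixel extents of a
#' reference bird, and a feasibility flag combining the FoV coverage
#' requirements with per-axis detectability.
#'
#' @param sensors list of [sensor_spec()] objects.
#' @param focal_lengths numeric vector of focal lengths, mm.
#' @param bird_w,bird_h reference bird wingspan and height, m.
#' @param distance design range, m.
#' @param req a [coverage_requirement()].
#' @return A data.frame with columns sensor, f, fov_h, fov_v, p_w, p_h,
#'   feasible.
#' @export
build_selection_table <- function(sensors, focal_lengths,
                                  bird_w = 1.5, bird_h = 0.55, distance = 300,
                                  req = coverage_requirement()) {
  if (length(sensors) == 0 || length(focal_lengths) == 0)
    stop("build_selection_table: sensors and focal_lengths must be non-empty")
  if (inherits(sensors, "sensor_spec")) sensors <- list(sensors)
  min_fov <- min_required_fovs(req)
  rows <- lapply(sensors, function(s) {
    lapply(focal_lengths, function(f) {
      a <- optical_assembly(s, f)
      det <- detectability_check(bird_w, bird_h, distance, a, req)
      data.frame(sensor = s$name, f = f,
                 fov_h = round(a$fov_h, 1), fov_v = round(a$fov_v, 1),
                 p_w = image_size_of_object(bird_w, distance, a, "h"),
                 p_h = image_size_of_object(bird_h, distance, a, "v"),
                 # The module is mounted with its wider-FoV sensor axis
                 # covering elevation, so the vertical-coverage bound (floored
                 # to the printed 63 degrees) applies to the larger FoV and
                 # the 360/N azimuth bound to the smaller one.
                 feasible = max(a$fov_h, a$fov_v) >= floor(min_fov[["fov_v"]]) &&
                   min(a$fov_h, a$fov_v) >= min_fov[["fov_h"]] &&
                   all(det))
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Default sensor catalog
#'
#' The four candidate sensors considered in the design study (C1 IMX219,
#' C2 IMX447, C3 AR1335, C4 AR1820HS).
#'
#' @return Named list of [sensor_spec()] objects.
#' @export
sensor_catalog <- function() {
  list(
    C1 = sensor_spec("C1", 3280, 2464, 3.680, 2.760),
    C2 = sensor_spec("C2", 4056, 3040, 6.287, 4.712),
    C3 = sensor_spec("C3", 4208, 3120, 6.300, 5.700),
    C4 = sensor_spec("C4", 4912, 3684, 7.660, 4.560)
  )
}
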