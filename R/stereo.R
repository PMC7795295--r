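# Tilted vertical-baseline stereo model.
#
# Two identical cameras are mounted one above the other on the turbine tower,
# separated by the baseline B and tilted upward by alpha (by construction,
# half the field of view along the baseline-aligned image axis, so that the
# lower FoV edge grazes the horizontal). An object projecting to rows y_u
# (upper camera) and y_d (lower camera) on the baseline-aligned axis has
# disparity ydiff = y_u - y_d >= 1 px; distance follows from similar
# triangles, and the integer-pixel disparity induces a closed-form
# quantization uncertainty.
#
# Row convention: y is continuous, increases away from the tilt direction,
# and the optical centre sits at y = vsr_axis / 2; for objects in front of
# the rig y_u > y_d.

#' Stereo rig description
#'
#' @param baseline camera separation B, m.
#' @param vsr_axis sensor resolution along the baseline-aligned image axis, px.
#' @param fov_axis field of view along that axis, degrees.
#' @param tilt_alpha rig tilt, degrees; defaults to `fov_axis / 2` (mounting
#'   that puts the lower FoV edge on the horizontal) but is independently
#'   configurable.
#' @return An object of class `stereo_rig`.
#' @export
#' @examples
#' stereo_rig() # the 1 m / 3280 px / 63.0 degree reference rig
stereo_rig <- function(baseline = 1, vsr_axis = 3280, fov_axis = 63.0,
                       tilt_alpha = fov_axis / 2) {
  if (baseline <= 0) stop("stereo_rig: baseline must be > 0")
  if (vsr_axis < 2) stop("stereo_rig: vsr_axis must be >= 2")
  if (fov_axis <= 0 || fov_axis >= 180) stop("stereo_rig: fov_axis must be in (0, 180)")
  if (tilt_alpha <= 0 || tilt_alpha >= 90) stop("stereo_rig: tilt_alpha must be in (0, 90)")
  structure(list(baseline = baseline, vsr_axis = vsr_axis,
                 fov_axis = fov_axis, tilt_alpha = tilt_alpha),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig B=%g m, %d px, FoV %.1f deg, tilt %.1f deg>\n",
              x$baseline, x$vsr_axis, x$fov_axis, x$tilt_alpha))
  invisible(x)
}

# focal length expressed in pixels along the baseline axis (per half-image):
# a disparity of ydiff px corresponds to Db = B * f_px / ydiff with
# f_px = VSR / (2 tan(FoV/2)).
.axis_focal_px <- function(rig) {
  rig$vsr_axis / (2 * tan(deg2rad(rig$fov_axis / 2)))
}

#' Distance from the stereo baseline
#'
#' `Db = B * VSR / (2 * ydiff * tan(FoV/2))` -- the stereo range equation on
#' the tilted baseline axis.
#'
#' @param ydiff disparity `y_u - y_d` in px (>= 1; may be continuous).
#' @param rig a [stereo_rig()].
#' @return Distance from the baseline midline, m.
#' @export
#' @examples
#' baseline_distance(15, stereo_rig()) # 178.4 m
baseline_distance <- function(ydiff, rig = stereo_rig()) {
  if (any(!is.finite(ydiff)) || any(ydiff < 1))
    stop("baseline_distance: invalid disparity (ydiff must be >= 1 px)")
  rig$baseline * .axis_focal_px(rig) / ydiff
}

#' View angle of an image row
#'
#' Angle between the optical axis and the ray through row `y` on the
#' baseline-aligned axis: `atan((2 y / VSR - 1) * tan(FoV/2))`. Zero at the
#' optical centre `y = VSR/2`, `FoV/2` at the sensor edge.
#'
#' @param y image row (1 <= y <= vsr_axis; continuous allowed).
#' @param rig a [stereo_rig()].
#' @return Angle in degrees.
#' @export
view_angle <- function(y, rig = stereo_rig()) {
  if (any(!is.finite(y)) || any(y < 0) || any(y > rig$vsr_axis))
    stop("view_angle: y out of sensor range")
  rad2deg(atan((2 * y / rig$vsr_axis - 1) * tan(deg2rad(rig$fov_axis / 2))))
}

#' Localize an object from a stereo observation
#'
#' Combines the range equation with the per-camera view angles to produce
#' the distance from the baseline (Db), the horizontal distance from the
#' tower (D), and the height above the lower camera (H):
#' `D = Db (tan(phi_u) sin(alpha) + cos(alpha))`,
#' `H = Db (tan(phi_d) cos(alpha) + sin(alpha))`.
#'
#' @param y_u,y_d object rows on the baseline-aligned axis, upper and lower
#'   camera (continuous allowed).
#' @param rig a [stereo_rig()].
#' @return A list of class `localization` with fields `d_b`, `d`, `h` (m)
#'   plus the intermediate angles `phi_u`, `phi_d` (degrees).
#' @export
localize <- function(y_u, y_d, rig = stereo_rig()) {
  ydiff <- y_u - y_d
  d_b <- baseline_distance(ydiff, rig)
  alpha <- deg2rad(rig$tilt_alpha)
  tan_u <- tan(deg2rad(view_angle(y_u, rig)))
  tan_d <- tan(deg2rad(view_angle(y_d, rig)))
  structure(list(
    d_b = d_b,
    d = d_b * (tan_u * sin(alpha) + cos(alpha)),
    h = d_b * (tan_d * cos(alpha) + sin(alpha)),
    phi_u = view_angle(y_u, rig), phi_d = view_angle(y_d, rig),
    ydiff = ydiff
  ), class = "localization")
}

#' @export
print.localization <- function(x, ...) {
  cat(sprintf("<localization Db=%.2f m, D=%.2f m, H=%.2f m (ydiff=%.2f px)>\n",
              x$d_b, x$d, x$h, x$ydiff))
  invisible(x)
}

#' Quantization uncertainty of a localization
#'
#' Integer-pixel disparity limits range resolution; by the exact-differential
#' propagation the symmetric half-widths are
#' `dDb = Db / (2 ydiff)`, `dD = (D + B sin(alpha)) / (2 ydiff)`,
#' `dH = (H + B cos(alpha)) / (2 ydiff)`.
#'
#' @param loc a [localize()] result, or a list with fields `d_b`, and
#'   optionally `d`, `h`.
#' @param ydiff disparity used for the measurement, px (>= 1).
#' @param rig a [stereo_rig()].
#' @return List of class `uncertainty_bounds` with `delta_db`, `delta_d`,
#'   `delta_h` (m; the latter two `NA` if `loc` lacks `d`/`h`).
#' @export
#' @examples
#' quantization_uncertainty(list(d_b = 100.69), 27)$delta_db # 1.86 m
quantization_uncertainty <- function(loc, ydiff, rig = stereo_rig()) {
  if (any(!is.finite(ydiff)) || any(ydiff < 1))
    stop("quantization_uncertainty: invalid disparity (ydiff must be >= 1 px)")
  alpha <- deg2rad(rig$tilt_alpha)
  d <- if (!is.null(loc$d)) loc$d else NA_real_
  h <- if (!is.null(loc$h)) loc$h else NA_real_
  structure(list(
    delta_db = loc$d_b / (2 * ydiff),
    delta_d = (d + rig$baseline * sin(alpha)) / (2 * ydiff),
    delta_h = (h + rig$baseline * cos(alpha)) / (2 * ydiff)
  ), class = "uncertainty_bounds")
}

#' Expected disparity at a given baseline distance
#'
#' Inverse of [baseline_distance()]; used by the scene simulator and for rig
#' design. The quantized value is the nearest integer, clamped below at 1 px.
#'
#' @param d_b distance from the baseline, m (> 0).
#' @param rig a [stereo_rig()].
#' @return List with `continuous` (px) and `quantized` (integer px >= 1).
#' @export
#' @examples
#' expected_disparity(178.4)$quantized # 15 px
expected_disparity <- function(d_b, rig = stereo_rig()) {
  if (any(!is.finite(d_b)) || any(d_b <= 0))
    stop("expected_disparity: d_b must be > 0")
  cont <- rig$baseline * .axis_focal_px(rig) / d_b
  list(continuous = cont, quantized = pmax(1L, as.integer(round(cont))))
}

#' Project a world position onto the two cameras
#'
#' Exact algebraic inverse of [localize()]: given the horizontal distance D
#' and height H of an object (tower/lower-camera frame), returns the
#' continuous rows y_u and y_d at which it appears on the baseline-aligned
#' axis of the upper and lower camera. `localize(y_u, y_d, rig)` recovers
#' (D, H) to machine precision.
#'
#' @param d horizontal distance from the tower, m.
#' @param h height above the lower camera, m.
#' @param rig a [stereo_rig()].
#' @return List with `y_u`, `y_d`, `ydiff` (continuous px), `d_b` (m) and
#'   `in_view` (logical: both projections within the sensor and in front of
#'   the rig).
#' @export
project_position <- function(d, h, rig = stereo_rig()) {
  alpha <- deg2rad(rig$tilt_alpha)
  sa <- sin(alpha); ca <- cos(alpha)
  b <- rig$baseline
  # Solve D = Db (tu sa + ca), H = Db (td ca + sa) with Db = B / (tu - td)
  # as a linear system in (tu, td):
  denom <- h * sa - d * ca + b * sa * ca
  tu <- (d * sa - h * ca - b * ca^2) / denom
  td <- (d * sa - h * ca - b * sa^2) / denom
  tt <- tan(deg2rad(rig$fov_axis / 2))
  y_u <- rig$vsr_axis / 2 * (1 + tu / tt)
  y_d <- rig$vsr_axis / 2 * (1 + td / tt)
  d_b <- b / (tu - td)
  in_view <- is.finite(y_u) && is.finite(y_d) && d_b > 0 &
    y_u >= 1 & y_u <= rig$vsr_axis & y_d >= 1 & y_d <= rig$vsr_axis
  list(y_u = y_u, y_d = y_d, ydiff = y_u - y_d, d_b = d_b,
       in_view = isTRUE(in_view))
}
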