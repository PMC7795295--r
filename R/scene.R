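# Synthetic stereo scene generator.
#
# Renders bird silhouettes (filled isosceles triangles: base = wingspan,
# height = body height) at exact 3D positions into stereo frame pairs,
# simulates flight paths, and produces labelled crop datasets for
# classifier training. Because projection is the exact algebraic inverse
# of the localization model, every rendered scene carries analytic ground
# truth for end-to-end validation.
#
# The camera is mounted portrait: the sensor's long (horizontal) axis runs
# along the tilted baseline (image rows), the short axis is transverse
# (image columns).

#' World-frame bird description
#'
#' @param distance horizontal distance from the tower, m.
#' @param height height above the lower camera, m.
#' @param azimuth degrees off the module's optical plane (0 = centred).
#' @param wingspan,body_height physical size, m (wingspan > body_height).
#' @param speed,heading optional motion, m/s and degrees.
#' @return List of class `world_bird`.
#' @export
world_bird <- function(distance, height, azimuth = 0,
                       wingspan = 1.5, body_height = 0.5,
                       speed = 0, heading = 0) {
  if (distance <= 0) stop("world_bird: distance must be > 0")
  if (!(wingspan > body_height && body_height > 0))
    stop("world_bird: need wingspan > body_height > 0")
  structure(list(distance = distance, height = height, azimuth = azimuth,
                 wingspan = wingspan, body_height = body_height,
                 speed = speed, heading = heading),
            class = "world_bird")
}

#' Scene configuration
#'
#' @param rig a [stereo_rig()].
#' @param assembly an [optical_assembly()]; frame size is
#'   `rig$vsr_axis` rows x `sensor$vsr_v` columns (portrait mounting).
#' @param background `"flat"`, `"gradient"` or `"clouds"`.
#' @param sky_intensity,bird_intensity mean sky / silhouette gray levels.
#' @param noise_sigma Gaussian pixel noise standard deviation, intensity
#'   levels (>= 0).
#' @param seed RNG seed for reproducible rendering.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(rig = stereo_rig(),
                         assembly = optical_assembly(sensor_catalog()$C1, 3),
                         background = c("flat", "gradient", "clouds"),
                         sky_intensity = 200, bird_intensity = 60,
                         noise_sigma = 2, seed = 1) {
  background <- match.arg(background)
  if (noise_sigma < 0) stop("scene_config: noise_sigma must be >= 0")
  structure(list(rig = rig, assembly = assembly, background = background,
                 sky_intensity = sky_intensity, bird_intensity = bird_intensity,
                 noise_sigma = noise_sigma, seed = seed,
                 n_rows = rig$vsr_axis, n_cols = assembly$sensor$vsr_v),
            class = "scene_config")
}

# pixel-per-metre scale factors at range d_b, for the portrait mounting:
# wingspan runs along image columns (transverse = sensor vertical axis),
# body height along image rows (baseline = sensor horizontal axis)
.px_scales <- function(assembly) {
  s <- assembly$sensor
  list(col_px_per_rad = s$vsr_v / (2 * tan(deg2rad(assembly$fov_v / 2))),
       wing = assembly$f * s$vsr_v / s$vss_v,    # px * m / m of range
       body = assembly$f * s$vsr_h / s$vss_h)
}

#' Project a bird onto one camera
#'
#' Pinhole projection through the tilted-rig geometry; the baseline-axis
#' row comes from the exact inverse of the localization model
#' ([project_position()]), the column from the azimuth, and the pixel
#' extents from the range.
#'
#' @param bird a [world_bird()].
#' @param camera `"upper"` or `"lower"`.
#' @param rig a [stereo_rig()].
#' @param assembly an [optical_assembly()].
#' @return List `y` (row), `x` (column), `p_w`, `p_h` (continuous px),
#'   `d_b` (m), `in_view` (logical).
#' @export
project_bird <- function(bird, camera = c("upper", "lower"),
                         rig = stereo_rig(),
                         assembly = optical_assembly(sensor_catalog()$C1, 3)) {
  camera <- match.arg(camera)
  pp <- project_position(bird$distance, bird$height, rig)
  sc <- .px_scales(assembly)
  n_cols <- assembly$sensor$vsr_v
  x <- n_cols / 2 * (1 + tan(deg2rad(bird$azimuth)) /
                       tan(deg2rad(assembly$fov_v / 2)))
  p_w <- bird$wingspan * sc$wing / pp$d_b
  p_h <- bird$body_height * sc$body / pp$d_b
  y <- if (camera == "upper") pp$y_u else pp$y_d
  list(y = y, x = x, p_w = p_w, p_h = p_h, d_b = pp$d_b,
       ydiff = pp$ydiff,
       in_view = pp$in_view && x >= 1 && x <= n_cols)
}

# rasterize a filled isosceles triangle (base down) into a matrix
.draw_triangle <- function(mat, x, y, p_w, p_h, intensity) {
  h <- nrow(mat); w <- ncol(mat)
  top <- y - p_h / 2
  # row span by nearest-pixel sampling so the base row carries the full
  # wingspan (a ceil/floor span systematically under-draws small targets)
  r0 <- max(1L, round(top)); r1 <- min(h, round(y + p_h / 2))
  if (r1 < r0) return(mat)
  for (r in r0:r1) {
    # width grows linearly from apex to base over the drawn rows, so the
    # base row always carries the full wingspan regardless of sub-pixel
    # placement
    frac <- if (r1 > r0) (r - r0) / (r1 - r0) else 1
    half <- p_w / 2 * min(1, max(0, frac))
    cc0 <- max(1L, ceiling(x - half)); cc1 <- min(w, floor(x + half))
    if (cc1 >= cc0) mat[r, cc0:cc1] <- intensity
  }
  mat
}

.render_background <- function(cfg) {
  bg <- matrix(cfg$sky_intensity, cfg$n_rows, cfg$n_cols)
  if (cfg$background == "gradient") {
    bg <- bg + matrix(seq(-20, 20, length.out = cfg$n_rows), cfg$n_rows, cfg$n_cols)
  } else if (cfg$background == "clouds") {
    # a few broad soft blobs
    for (i in 1:4) {
      rc <- stats::runif(1, 1, cfg$n_rows); cc <- stats::runif(1, 1, cfg$n_cols)
      s2 <- stats::runif(1, (cfg$n_rows / 8)^2, (cfg$n_rows / 4)^2)
      rr <- (seq_len(cfg$n_rows) - rc)^2
      cl <- (seq_len(cfg$n_cols) - cc)^2
      bg <- bg + 15 * exp(-outer(rr, cl, "+") / (2 * s2))
    }
  }
  bg
}

#' Render a stereo frame pair
#'
#' Draws every in-view bird as a filled triangle silhouette at its
#' projected position in both cameras, over the configured background with
#' seeded Gaussian pixel noise. Deterministic for fixed `(cfg$seed, t)`.
#'
#' @param birds list of [world_bird()] (may be empty).
#' @param cfg a [scene_config()].
#' @param t scene time, seconds (enters the noise seed).
#' @return List with `upper` and `lower` intensity matrices (0--255) and
#'   `truth` (data.frame of per-bird projections and ranges).
#' @export
render_stereo_frames <- function(birds, cfg = scene_config(), t = 0) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((cfg$seed * 1000003L + round(t * 1000)) %% .Machine$integer.max)
  if (inherits(birds, "world_bird")) birds <- list(birds)
  up <- .render_background(cfg)
  lo <- .render_background(cfg)
  truth <- list()
  for (b in birds) {
    pu <- project_bird(b, "upper", cfg$rig, cfg$assembly)
    pl <- project_bird(b, "lower", cfg$rig, cfg$assembly)
    if (pu$in_view)
      up <- .draw_triangle(up, pu$x, pu$y, pu$p_w, pu$p_h, cfg$bird_intensity)
    if (pl$in_view)
      lo <- .draw_triangle(lo, pl$x, pl$y, pl$p_w, pl$p_h, cfg$bird_intensity)
    truth[[length(truth) + 1L]] <- data.frame(
      distance = b$distance, height = b$height, d_b = pu$d_b,
      y_u = pu$y, y_d = pl$y, x = pu$x, p_w = pu$p_w, p_h = pu$p_h,
      in_view = pu$in_view && pl$in_view)
  }
  if (cfg$noise_sigma > 0) {
    up <- up + matrix(stats::rnorm(length(up), 0, cfg$noise_sigma), nrow(up))
    lo <- lo + matrix(stats::rnorm(length(lo), 0, cfg$noise_sigma), nrow(lo))
  }
  clamp <- function(m) pmin(pmax(m, 0), 255)
  list(upper = clamp(up), lower = clamp(lo), t = t,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate a flight path
#'
#' Sampled world positions along a path. The circular default reproduces
#' the drone validation geometry: radius 143.3 m, height 102.9 m, speed
#' 15 m/s, with optional GPS-style jitter (sd 2.5 m radial, 1.5 m
#' vertical).
#'
#' @param path `"circular"`, `"linear"` or `"waypoint"`.
#' @param params named list of path parameters. Circular: `radius`,
#'   `height`, `speed`, `radius_jitter`, `height_jitter`, `azimuth0`.
#'   Linear: `from`, `to` (each `c(distance, height, azimuth)`), `speed`.
#'   Waypoint: `waypoints` (matrix of distance/height/azimuth rows),
#'   `speed`.
#' @param duration seconds.
#' @param fps samples per second.
#' @param wingspan,body_height size carried by every sample, m.
#' @param seed RNG seed for the jitter.
#' @return data.frame: `t`, `distance`, `height`, `azimuth`, `wingspan`,
#'   `body_height`, `speed`, `heading`.
#' @export
simulate_flight <- function(path = c("circular", "linear", "waypoint"),
                            params = list(), duration = 60, fps = 1,
                            wingspan = 1.99, body_height = 1.03, seed = 1) {
  path <- match.arg(path)
  if (duration <= 0 || fps <= 0) stop("simulate_flight: duration and fps must be > 0")
  tt <- seq(0, duration, by = 1 / fps)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (path == "circular") {
    p <- utils::modifyList(list(radius = 143.3, height = 102.9, speed = 15,
                                radius_jitter = 2.5, height_jitter = 1.5,
                                azimuth0 = 0), params)
    omega <- p$speed / p$radius                 # rad/s around the tower
    az <- p$azimuth0 + rad2deg(omega * tt)
    r <- p$radius + stats::rnorm(length(tt), 0, p$radius_jitter)
    h <- p$height + stats::rnorm(length(tt), 0, p$height_jitter)
    out <- data.frame(t = tt, distance = r, height = h,
                      azimuth = ((az + 180) %% 360) - 180,
                      speed = p$speed, heading = az + 90)
  } else if (path == "linear") {
    p <- utils::modifyList(list(from = c(300, 100, -10), to = c(100, 80, 10),
                                speed = 15), params)
    frac <- tt / max(tt)
    out <- data.frame(t = tt,
                      distance = p$from[1] + frac * (p$to[1] - p$from[1]),
                      height = p$from[2] + frac * (p$to[2] - p$from[2]),
                      azimuth = p$from[3] + frac * (p$to[3] - p$from[3]),
                      speed = p$speed, heading = 0)
  } else {
    p <- params
    if (is.null(p$waypoints)) stop("simulate_flight: waypoint path needs params$waypoints")
    wp <- p$waypoints
    frac <- tt / max(tt)
    seg <- pmin(nrow(wp) - 1, floor(frac * (nrow(wp) - 1)) + 1)
    s <- frac * (nrow(wp) - 1) - (seg - 1)
    lerp <- function(k) wp[seg, k] + s * (wp[seg + 1, k] - wp[seg, k])
    out <- data.frame(t = tt, distance = lerp(1), height = lerp(2),
                      azimuth = lerp(3),
                      speed = if (is.null(p$speed)) 15 else p$speed, heading = 0)
  }
  out$wingspan <- wingspan
  out$body_height <- body_height
  out
}

#' Labelled crop dataset for classifier training
#'
#' Bird crops are triangle silhouettes at random scale, rotation and
#' contrast over noisy sky; non-bird crops are the artifact families the
#' motion detector also fires on: elongated plane-like streaks, small
#' high-contrast insect dots, and low-frequency cloud blobs (balanced
#' thirds). Deterministic under a fixed seed.
#'
#' @param n_birds,n_artifacts counts per class (>= 1).
#' @param size crop side, px.
#' @param channels 1 or 3.
#' @param seed RNG seed.
#' @return List with `crops` (list of `size` x `size` x `channels` arrays,
#'   0--255) and `labels` (logical, TRUE = bird), shuffled.
#' @export
generate_crop_dataset <- function(n_birds, n_artifacts, size = 100,
                                  channels = 3, seed = 1) {
  if (n_birds < 1 || n_artifacts < 1)
    stop("generate_crop_dataset: need at least one crop per class")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  crops <- vector("list", n_birds + n_artifacts)
  labels <- c(rep(TRUE, n_birds), rep(FALSE, n_artifacts))
  for (i in seq_len(n_birds)) crops[[i]] <- .crop_bird(size, channels)
  kinds <- rep_len(c("streak", "dot", "cloud"), n_artifacts)
  for (i in seq_len(n_artifacts))
    crops[[n_birds + i]] <- .crop_artifact(size, channels, kinds[i])
  ord <- sample.int(length(crops))
  list(crops = crops[ord], labels = labels[ord])
}

.crop_canvas <- function(size) {
  sky <- stats::runif(1, 150, 230)
  matrix(sky, size, size) + matrix(stats::rnorm(size^2, 0, 3), size)
}

.finish_crop <- function(m, channels) {
  m <- pmin(pmax(m, 0), 255)
  if (channels == 1) { dim(m) <- c(dim(m), 1L); return(m) }
  # mild channel tinting keeps the three planes distinct but correlated
  array(c(m * stats::runif(1, 0.9, 1), m * stats::runif(1, 0.9, 1), m),
        c(dim(m), 3L))
}

.crop_bird <- function(size, channels) {
  m <- .crop_canvas(size)
  w <- stats::runif(1, 0.16, 0.64) * size          # wingspan, px
  hgt <- w * stats::runif(1, 0.35, 0.5)
  ang <- stats::runif(1, -pi, pi)
  cx <- size / 2 + stats::runif(1, -size / 8, size / 8)
  cy <- size / 2 + stats::runif(1, -size / 8, size / 8)
  dark <- stats::runif(1, 20, 90)
  # rotated filled triangle via half-plane tests
  v <- rbind(c(-w / 2, hgt / 2), c(w / 2, hgt / 2), c(0, -hgt / 2))
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  v <- sweep(v %*% t(rot), 2, c(cx, cy), "+")
  xs <- matrix(rep(seq_len(size), each = size), size)   # col coords
  ys <- matrix(rep(seq_len(size), size), size)          # row coords
  inside <- rep(TRUE, size * size)
  for (e in 1:3) {
    a <- v[e, ]; b <- v[e %% 3 + 1, ]
    cr <- (b[1] - a[1]) * (ys - a[2]) - (b[2] - a[2]) * (xs - a[1])
    inside <- inside & (as.vector(cr) <= 0)
  }
  if (sum(inside) == 0) return(.crop_bird(size, channels))  # degenerate draw
  m[matrix(inside, size)] <- dark
  .finish_crop(m, channels)
}

.crop_artifact <- function(size, channels, kind) {
  m <- .crop_canvas(size)
  if (kind == "streak") {
    len <- stats::runif(1, 0.30, 0.80) * size
    thick <- stats::runif(1, 2, 4)
    ang <- stats::runif(1, -pi, pi)
    cx <- size / 2; cy <- size / 2
    xs <- matrix(rep(seq_len(size), each = size), size) - cx
    ys <- matrix(rep(seq_len(size), size), size) - cy
    along <- xs * cos(ang) + ys * sin(ang)
    across <- -xs * sin(ang) + ys * cos(ang)
    sel <- abs(along) <= len / 2 & abs(across) <= thick / 2
    m[sel] <- stats::runif(1, 20, 110)
  } else if (kind == "dot") {
    r <- stats::runif(1, 1, 4)
    cx <- size / 2 + stats::runif(1, -size / 4, size / 4)
    cy <- size / 2 + stats::runif(1, -size / 4, size / 4)
    xs <- matrix(rep(seq_len(size), each = size), size) - cx
    ys <- matrix(rep(seq_len(size), size), size) - cy
    m[xs^2 + ys^2 <= r^2] <- stats::runif(1, 10, 60)
  } else {
    rc <- stats::runif(1, size / 4, 3 * size / 4)
    cc <- stats::runif(1, size / 4, 3 * size / 4)
    s2 <- stats::runif(1, (size / 6)^2, (size / 3)^2)
    rr <- (seq_len(size) - rc)^2
    cl <- (seq_len(size) - cc)^2
    m <- m - stats::runif(1, 15, 35) * exp(-outer(rr, cl, "+") / (2 * s2))
  }
  .finish_crop(m, channels)
}

#' Scripted silhouette measurement campaign
#'
#' For each painted-canvas silhouette (small 0.8 x 0.3 m, medium
#' 1.2 x 0.4 m, large 1.5 x 0.5 m) and each reference distance (50--300 m
#' in 50 m steps), a stereo frame pair is scripted with the target centred
#' on the optical midline at that baseline distance, shifted laterally by
#' a few pixels between the two frames so the motion detector fires.
#' Scenes are rendered lazily via each descriptor's `render()` closure.
#'
#' @param rig a [stereo_rig()].
#' @param assembly an [optical_assembly()].
#' @param distances reference baseline distances, m.
#' @param silhouettes named list of `c(wingspan, height)` in m.
#' @param shift_px lateral shift between the paired frames, px.
#' @param cfg a [scene_config()] (rig/assembly are overridden).
#' @return List of scene descriptors: `silhouette`, `wingspan`,
#'   `body_height`, `d_ref`, `truth` (expected projection) and `render()`
#'   returning `list(prev, curr)` stereo pairs.
#' @export
generate_silhouette_campaign <- function(rig = stereo_rig(),
                                         assembly = optical_assembly(sensor_catalog()$C1, 3),
                                         distances = seq(50, 300, by = 50),
                                         silhouettes = list(small = c(0.8, 0.3),
                                                            medium = c(1.2, 0.4),
                                                            large = c(1.5, 0.5)),
                                         shift_px = 4,
                                         cfg = scene_config(rig, assembly)) {
  cfg$rig <- rig; cfg$assembly <- assembly
  sc <- .px_scales(assembly)
  out <- list()
  for (nm in names(silhouettes)) {
    sz <- silhouettes[[nm]]
    for (dref in distances) {
      # world position with the target on the optical midline (symmetric
      # rows) at baseline distance dref
      alpha <- deg2rad(rig$tilt_alpha)
      tu <- rig$baseline / (2 * dref); td <- -tu
      d <- dref * (tu * sin(alpha) + cos(alpha))
      h <- dref * (td * cos(alpha) + sin(alpha))
      bird <- world_bird(d, h, azimuth = 0, wingspan = sz[1], body_height = sz[2])
      az_shift <- rad2deg(atan(shift_px / sc$col_px_per_rad))
      bird2 <- bird; bird2$azimuth <- bird$azimuth + az_shift
      scene_t <- dref + match(nm, names(silhouettes)) * 1000
      desc <- list(
        silhouette = nm, wingspan = sz[1], body_height = sz[2], d_ref = dref,
        truth = c(project_bird(bird2, "upper", rig, assembly),
                  y_d = project_bird(bird2, "lower", rig, assembly)$y),
        render = local({
          b1 <- bird; b2 <- bird2; tt <- scene_t; cc <- cfg
          function() list(prev = render_stereo_frames(list(b1), cc, tt),
                          curr = render_stereo_frames(list(b2), cc, tt + 0.1))
        }))
      out[[length(out) + 1L]] <- desc
    }
  }
  out
}

#' Scripted drone-flight validation campaign
#'
#' Samples a circular drone flight ([simulate_flight()] defaults: radius
#' 143.3 m, height 102.9 m, 15 m/s with GPS-scale jitter), keeps the
#' samples whose azimuth falls inside one module's horizontal field of
#' view, and scripts a stereo frame pair for each (the drone advances
#' along its path for `dt` seconds between the two frames so the motion
#' detector fires). Scenes render lazily.
#'
#' @param rig a [stereo_rig()].
#' @param assembly an [optical_assembly()].
#' @param n_samples number of frame pairs to script.
#' @param dt intra-pair time step, s.
#' @param cfg a [scene_config()] (rig/assembly are overridden).
#' @param seed seed for the flight jitter.
#' @param flight optional precomputed [simulate_flight()] data.frame.
#' @return List of scene descriptors with `t`, `truth` (the sampled world
#'   state) and `render()`.
#' @export
generate_drone_campaign <- function(rig = stereo_rig(),
                                    assembly = optical_assembly(sensor_catalog()$C1, 3),
                                    n_samples = 24, dt = 0.1,
                                    cfg = scene_config(rig, assembly),
                                    seed = 1, flight = NULL) {
  cfg$rig <- rig; cfg$assembly <- assembly
  if (is.null(flight))
    flight <- simulate_flight("circular", duration = 8 * 60, fps = 1, seed = seed)
  half_fov_t <- assembly$fov_v / 2
  visible <- which(abs(flight$azimuth) < 0.8 * half_fov_t)
  visible <- visible[seq_len(min(n_samples, length(visible)))]
  out <- list()
  for (i in visible) {
    row <- flight[i, ]
    bird <- world_bird(row$distance, row$height, row$azimuth,
                       row$wingspan, row$body_height)
    # the drone advances dt along the circle between the paired frames
    omega_deg <- rad2deg(row$speed / row$distance)
    bird_prev <- bird
    bird_prev$azimuth <- bird$azimuth - omega_deg * dt
    desc <- list(
      t = row$t, truth = row,
      render = local({
        b1 <- bird_prev; b2 <- bird; tt <- row$t; cc <- cfg
        function() list(prev = render_stereo_frames(list(b1), cc, tt - dt),
                        curr = render_stereo_frames(list(b2), cc, tt))
      }))
    out[[length(out) + 1L]] <- desc
  }
  out
}

#' Write a rendered scene to PNG files with a JSON ground-truth sidecar
#'
#' @param scene result of [render_stereo_frames()].
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return Paths of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pu <- file.path(dir, paste0(stem, "_upper.png"))
  pl <- file.path(dir, paste0(stem, "_lower.png"))
  png::writePNG(scene$upper / 255, pu)
  png::writePNG(scene$lower / 255, pl)
  sidecar <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(list(t = scene$t, truth = scene$truth), sidecar,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(pu, pl, sidecar))
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory.
#' @param stem file name stem.
#' @return List with `upper`, `lower` (0--255 matrices), `t`, `truth`.
#' @export
read_scene <- function(dir, stem = "scene") {
  up <- png::readPNG(file.path(dir, paste0(stem, "_upper.png"))) * 255
  lo <- png::readPNG(file.path(dir, paste0(stem, "_lower.png"))) * 255
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, "_truth.json")),
                              simplifyVector = TRUE)
  list(upper = up, lower = lo, t = meta$t, truth = meta$truth)
}
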