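# Decision-making stage: fuse the upper/lower camera detection streams,
# match objects across the two views, estimate physical size from the
# stereo range, classify into small/medium/large (safety-first max rule)
# and choose the avoidance action.

#' Detection message
#'
#' The record a detection module emits per identified object: pixel sizes,
#' contour area and geometric centre (0-based image coordinates).
#'
#' @param camera `"upper"` or `"lower"`.
#' @param timestamp seconds.
#' @param o_s contour-enclosed area, px^2.
#' @param p_w,p_h bounding width / height, px.
#' @param xc,yc centroid coordinates, px.
#' @param module_id detection module identifier.
#' @return One-row data.frame.
#' @export
detection_message <- function(camera, timestamp, o_s, p_w, p_h, xc, yc,
                              module_id = "M1") {
  camera <- match.arg(camera, c("upper", "lower"))
  data.frame(module_id = module_id, camera = camera, timestamp = timestamp,
             o_s = o_s, p_w = p_w, p_h = p_h, xc = xc, yc = yc)
}

#' Synchronize the upper and lower camera message streams
#'
#' Groups each stream by frame timestamp and pairs frames whose timestamps
#' differ by at most `tolerance` (greedy nearest-timestamp pairing, which
#' for jitter below half the frame interval equals the optimal assignment).
#' Unmatched frames are dropped (reported via the `n_dropped` attribute).
#'
#' @param upper,lower data.frames of [detection_message()] rows, each
#'   time-sorted.
#' @param tolerance maximum timestamp difference, seconds.
#' @return List of pairs; each element has `t`, `upper`, `lower` (the
#'   co-timed message subsets).
#' @export
synchronize_streams <- function(upper, lower, tolerance = 0.05) {
  for (s in list(upper, lower))
    if (nrow(s) > 1 && is.unsorted(s$timestamp))
      stop("synchronize_streams: streams must be time-sorted")
  tu <- unique(upper$timestamp); tl <- unique(lower$timestamp)
  pairs <- list(); used <- logical(length(tl))
  if (length(tu) && length(tl)) {
    # all candidate pairings by ascending time difference
    dmat <- abs(outer(tu, tl, "-"))
    ord <- order(dmat)
    used_u <- logical(length(tu))
    for (o in ord) {
      if (dmat[o] > tolerance) break
      i <- (o - 1) %% length(tu) + 1; j <- (o - 1) %/% length(tu) + 1
      if (used_u[i] || used[j]) next
      used_u[i] <- TRUE; used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- list(
        t = tu[i],
        upper = upper[upper$timestamp == tu[i], , drop = FALSE],
        lower = lower[lower$timestamp == tl[j], , drop = FALSE])
    }
  }
  pairs <- pairs[order(vapply(pairs, `[[`, numeric(1), "t"))]
  n_dropped <- sum(!upper$timestamp %in% vapply(pairs, `[[`, numeric(1), "t")) +
    sum(!used[match(lower$timestamp, tl)])
  attr(pairs, "n_dropped") <- n_dropped
  pairs
}

#' Match objects across the two cameras
#'
#' Greedy centre-distance assignment: all L x M Euclidean centre distances
#' are sorted ascending and a pair is accepted if neither member is already
#' used, yielding min(L, M) pairs. The false-pair filter then removes pairs
#' with centre offsets above `max_center_diff` in x or y (near-field
#' insects / mismatches) or with disparity `yc_u - yc_d` below
#' `min_ydiff` (impossible geometry on this rig).
#'
#' @param upper_objs,lower_objs message data.frames from one synchronized
#'   instant.
#' @param max_center_diff false-pair threshold, px.
#' @param min_ydiff minimum admissible disparity, px.
#' @return data.frame of matched pairs with columns `u` and `d` (row indices
#'   into the inputs), `center_distance`, `yc_diff`, plus the upper/lower
#'   fields suffixed `_u` / `_d`.
#' @export
match_objects <- function(upper_objs, lower_objs,
                          max_center_diff = 150, min_ydiff = 1) {
  L <- nrow(upper_objs); M <- nrow(lower_objs)
  empty <- data.frame(u = integer(), d = integer(),
                      center_distance = numeric(), yc_diff = numeric())
  if (L == 0 || M == 0) return(empty)
  dx <- outer(upper_objs$xc, lower_objs$xc, "-")
  dy <- outer(upper_objs$yc, lower_objs$yc, "-")
  dist <- sqrt(dx^2 + dy^2)
  ord <- order(dist)
  used_u <- logical(L); used_d <- logical(M)
  rows <- list()
  for (o in ord) {
    i <- (o - 1) %% L + 1; j <- (o - 1) %/% L + 1
    if (used_u[i] || used_d[j]) next
    used_u[i] <- TRUE; used_d[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      u = i, d = j, center_distance = dist[i, j], yc_diff = dy[i, j])
    if (length(rows) == min(L, M)) break
  }
  out <- do.call(rbind, rows)
  # false-pair filter
  keep <- abs(upper_objs$xc[out$u] - lower_objs$xc[out$d]) <= max_center_diff &
    abs(upper_objs$yc[out$u] - lower_objs$yc[out$d]) <= max_center_diff &
    out$yc_diff >= min_ydiff
  out <- out[keep, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(out$u), , drop = FALSE]
  up <- upper_objs[out$u, c("o_s", "p_w", "p_h", "xc", "yc")]
  names(up) <- paste0(names(up), "_u")
  dn <- lower_objs[out$d, c("o_s", "p_w", "p_h", "xc", "yc")]
  names(dn) <- paste0(names(dn), "_d")
  cbind(out, up, dn, row.names = NULL)
}

#' Physical size estimate for a matched pair
#'
#' Range to the object centre from the centre-row disparity, then wingspan
#' `PW = Dbc * p_w * VSS_h / (f * VSR_h)` and height `PH` from the mean of
#' the two cameras' pixel sizes, contour area
#' `Os = o_s * (Dbc/f)^2 * (VSS_h/VSR_h) * (VSS_v/VSR_v)`, and the
#' isosceles-triangle approximation `Oapprox = PW * PH / 2`. Half-width
#' uncertainties propagate the disparity quantization bound.
#'
#' @param pair one row from [match_objects()].
#' @param rig a [stereo_rig()].
#' @param assembly an [optical_assembly()].
#' @param per_axis if TRUE use the vertical pixel pitch for PH (the printed
#'   model uses the horizontal pitch for both; the reference sensor's pixels
#'   are nearly square so the difference is ~0.2 %).
#' @return List of class `size_estimate`: `d_bc`, `delta_dbc`, `wingspan`,
#'   `wingspan_delta`, `body_height`, `body_height_delta`, `contour_area`,
#'   `approx_area` (m / m^2).
#' @export
estimate_size <- function(pair, rig = stereo_rig(), assembly = NULL,
                          per_axis = FALSE) {
  if (is.null(assembly))
    assembly <- optical_assembly(sensor_catalog()$C1, 3)
  ydiff <- pair$yc_u - pair$yc_d
  d_bc <- baseline_distance(ydiff, rig)
  delta_dbc <- d_bc / (2 * ydiff)
  s <- assembly$sensor
  scale_h <- s$vss_h / (assembly$f * s$vsr_h)   # m per (px * m of range)
  scale_v <- if (per_axis) s$vss_v / (assembly$f * s$vsr_v) else scale_h
  p_w <- mean(c(pair$p_w_u, pair$p_w_d))
  p_h <- mean(c(pair$p_h_u, pair$p_h_d))
  o_s <- mean(c(pair$o_s_u, pair$o_s_d))
  wingspan <- d_bc * p_w * scale_h
  body_height <- d_bc * p_h * scale_v
  structure(list(
    d_bc = d_bc, delta_dbc = delta_dbc,
    wingspan = wingspan, wingspan_delta = delta_dbc * p_w * scale_h,
    body_height = body_height, body_height_delta = delta_dbc * p_h * scale_v,
    contour_area = o_s * d_bc^2 * (s$vss_h / s$vsr_h) * (s$vss_v / s$vsr_v) /
      assembly$f^2,
    approx_area = wingspan * body_height / 2,
    ydiff = ydiff
  ), class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("<size_estimate Db=%.2f±%.2f m, PW=%.2f m, PH=%.2f m, Os=%.3f m^2, Oapprox=%.3f m^2>\n",
              x$d_bc, x$delta_dbc, x$wingspan, x$body_height,
              x$contour_area, x$approx_area))
  invisible(x)
}

#' Isosceles-triangle area approximation of a bird
#'
#' The gliding bird is approximated by an isosceles triangle whose base is
#' the wingspan and whose height is the body length, so its area is
#' `wingspan * body_height / 2`.
#'
#' @param wingspan m.
#' @param body_height m.
#' @return Area in m^2.
#' @export
#' @examples
#' approximate_bird_area(1.53, 0.51) # 0.39 m^2
approximate_bird_area <- function(wingspan, body_height) {
  if (any(wingspan < 0) || any(body_height < 0))
    stop("approximate_bird_area: sizes must be >= 0")
  wingspan * body_height / 2
}

#' Size-class boundaries
#'
#' Lower bounds of the small/medium/large classes for wingspan (m), body
#' height (m) and contour area (m^2). Values below the small bound are
#' "uncategorized". Stated class intervals have presentation gaps
#' (1.25 -> 1.26); they are bridged by the half-open convention
#' `[lo, next_lo)`.
#'
#' @param wingspan,height,area numeric `c(small, medium, large)` lower
#'   bounds.
#' @return List of class `size_boundaries`.
#' @export
size_class_boundaries <- function(wingspan = c(0.68, 1.26, 1.505),
                                  height = c(0.32, 0.40, 0.555),
                                  area = c(0.11, 0.25, 0.415)) {
  for (b in list(wingspan, height, area))
    if (length(b) != 3 || is.unsorted(b, strictly = TRUE))
      stop("size_class_boundaries: each parameter needs 3 strictly increasing bounds")
  structure(list(wingspan = wingspan, height = height, area = area),
            class = "size_boundaries")
}

.classify_param <- function(value, bounds) {
  # 0 = uncategorized, 1 = small, 2 = medium, 3 = large
  findInterval(value, bounds)
}

#' Classify a size estimate into a bird size class
#'
#' Wingspan, body height and contour area are classified independently;
#' for safety the final label is the LARGEST class any parameter indicates
#' (one "medium" vote among "small" votes makes the bird medium). All three
#' below the small bounds gives "uncategorized".
#'
#' @param est a [estimate_size()] result, or a list with `wingspan`,
#'   `body_height`, `contour_area`.
#' @param boundaries a [size_class_boundaries()].
#' @return Factor level as character: `"uncategorized"`, `"small"`,
#'   `"medium"` or `"large"`, with the per-parameter votes as an attribute.
#' @export
classify_size <- function(est, boundaries = size_class_boundaries()) {
  votes <- c(
    wingspan = .classify_param(est$wingspan, boundaries$wingspan),
    height = .classify_param(est$body_height, boundaries$height),
    area = .classify_param(est$contour_area, boundaries$area)
  )
  labels <- c("uncategorized", "small", "medium", "large")
  out <- labels[max(votes) + 1L]
  attr(out, "votes") <- labels[votes + 1L]
  out
}

#' Avoidance action policy
#'
#' Per-class trigger distances (m) for the strobe/audio deterrents and the
#' turbine stop. An action triggers when the object's horizontal distance D
#' is within (<=) its trigger distance; `NA` disables an action for a
#' class. Turbine stop implies the deterrents are also active. Defaults are
#' illustrative: deterrents at 300 m for every bird class, turbine stop at
#' 200 m for large birds only.
#'
#' @param deterrent_distance named numeric (small/medium/large), m.
#' @param stop_distance named numeric (small/medium/large), m (NA = never).
#' @return List of class `action_policy`.
#' @export
action_policy <- function(deterrent_distance = c(small = 300, medium = 300, large = 300),
                          stop_distance = c(small = NA, medium = NA, large = 200)) {
  if (any(deterrent_distance <= 0, na.rm = TRUE) || any(stop_distance <= 0, na.rm = TRUE))
    stop("action_policy: trigger distances must be positive")
  for (cl in c("small", "medium", "large"))
    if (!is.na(stop_distance[cl]) && !is.na(deterrent_distance[cl]) &&
        stop_distance[cl] > deterrent_distance[cl])
      stop("action_policy: turbine stop distance must not exceed the deterrent distance")
  structure(list(deterrent_distance = deterrent_distance,
                 stop_distance = stop_distance),
            class = "action_policy")
}

#' Decide the avoidance action
#'
#' @param size_class `"uncategorized"`, `"small"`, `"medium"` or `"large"`.
#' @param distance_d horizontal distance from the tower, m.
#' @param policy an [action_policy()].
#' @return Character vector: subset of `c("strobe", "audio",
#'   "turbine_stop")`, empty when outside all zones or uncategorized.
#' @export
decide_action <- function(size_class, distance_d, policy = action_policy()) {
  if (!size_class %in% c("small", "medium", "large")) return(character())
  acts <- character()
  det <- policy$deterrent_distance[[size_class]]
  stp <- policy$stop_distance[[size_class]]
  if (!is.na(stp) && distance_d <= stp) acts <- c("strobe", "audio", "turbine_stop")
  else if (!is.na(det) && distance_d <= det) acts <- c("strobe", "audio")
  acts
}

#' Build an event record
#'
#' The archival unit: a fused, classified detection with its localization,
#' size estimate and the chosen action.
#'
#' @param timestamp seconds.
#' @param module_id detection module identifier.
#' @param loc a [localize()] result.
#' @param est a [estimate_size()] result.
#' @param size_class classification label.
#' @param actions character vector from [decide_action()].
#' @param crop_path optional path of the archived crop image.
#' @return One-row data.frame.
#' @export
event_record <- function(timestamp, module_id, loc, est, size_class, actions,
                         crop_path = NA_character_) {
  data.frame(timestamp = timestamp, module_id = module_id,
             size_class = as.vector(size_class),
             d = loc$d, h = loc$h, d_b = loc$d_b,
             delta_db = est$delta_dbc,
             wingspan = est$wingspan, body_height = est$body_height,
             contour_area = est$contour_area, approx_area = est$approx_area,
             action = paste(actions, collapse = "+"),
             crop_path = crop_path)
}

#' Append events to an archive
#'
#' Append-only CSV plus JSON-lines sinks; rows are written in the order
#' given and can be read back loss-free with [read_event_archive()].
#'
#' @param events data.frame of [event_record()] rows.
#' @param path archive path without extension, or ending in `.csv`.
#' @param jsonl also write a JSON-lines twin next to the CSV.
#' @return The CSV path, invisibly.
#' @export
record_event <- function(events, path, jsonl = TRUE) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  new <- !file.exists(csv)
  tryCatch(
    utils::write.table(events, csv, sep = ",", append = !new, col.names = new,
                       row.names = FALSE, qmethod = "double"),
    error = function(e) stop("record_event: cannot write archive: ",
                             conditionMessage(e))
  )
  if (jsonl) {
    jl <- sub("\\.csv$", ".jsonl", csv)
    con <- file(jl, open = "a")
    on.exit(close(con))
    for (i in seq_len(nrow(events)))
      writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
  }
  invisible(csv)
}

#' @rdname record_event
#' @export
read_event_archive <- function(path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  utils::read.csv(csv, stringsAsFactors = FALSE)
}
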