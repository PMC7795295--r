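# End-to-end processing: per stereo frame pair, run single-camera motion
# detection on both views, (optionally) filter candidates through the
# classifier, fuse the two streams, match objects across views, localize,
# estimate physical size, classify and decide the avoidance action; every
# fused detection becomes one archived event row.

# detection candidates -> message stream rows
.candidates_to_messages <- function(cands, camera, t, module_id) {
  if (!length(cands)) return(detection_message(camera, t, 1, 1, 1, 0, 0)[0, ])
  do.call(rbind, lapply(cands, function(cd)
    detection_message(camera, t, cd$o_s, cd$p_w, cd$p_h,
                      cd$centroid[["xc"]], cd$centroid[["yc"]], module_id)))
}

.empty_archive <- function() {
  event_record(0, "x", list(d = 0, h = 0, d_b = 0),
               list(delta_dbc = 0, wingspan = 0, body_height = 0,
                    contour_area = 0, approx_area = 0),
               "small", character())[0, ]
}

#' Run the full pipeline over a sequence of stereo scenes
#'
#' Each scene provides a previous and a current frame for both cameras
#' (either directly as `list(prev = list(upper=, lower=), curr = ...)`
#' objects from [render_stereo_frames()], or lazily via a `render()`
#' closure as produced by [generate_silhouette_campaign()]).
#'
#' @param config a [load_config()] result.
#' @param scenes list of scene descriptors.
#' @param classifier optional trained [bird_cnn()]; when given, candidates
#'   with bird probability below 0.5 are discarded.
#' @param module_id identifier stamped on the events.
#' @param archive_path optional path stem; when given, events are appended
#'   via [record_event()].
#' @return data.frame event archive (zero rows if nothing was detected).
#' @export
run_pipeline <- function(config = load_config(), scenes, classifier = NULL,
                         module_id = "M1", archive_path = NULL) {
  stopifnot(inherits(config, "system_config"))
  rows <- list()
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    pair <- tryCatch({
      if (!is.null(sc$render)) sc$render()
      else sc
    }, error = function(e) {
      warning(sprintf("scene %d: render failed (%s); skipped", si,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(pair)) next
    t <- if (!is.null(pair$curr$t)) pair$curr$t else si
    ev <- tryCatch(
      .process_pair(config, pair, t, classifier, module_id),
      error = function(e) {
        warning(sprintf("scene %d: processing failed (%s); skipped", si,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(ev) && nrow(ev)) rows[[length(rows) + 1L]] <- ev
  }
  archive <- if (length(rows)) do.call(rbind, rows) else .empty_archive()
  if (!is.null(archive_path) && nrow(archive))
    record_event(archive, archive_path)
  archive
}

.process_pair <- function(config, pair, t, classifier, module_id) {
  dp <- config$detection
  keep_birds <- function(cands) {
    if (is.null(classifier) || !length(cands)) return(cands)
    crops <- lapply(cands, function(cd) cd$crop)
    p <- predict(classifier, crops, type = "prob")
    cands[p >= 0.5]
  }
  cu <- keep_birds(detect_motion(pair$prev$upper, pair$curr$upper, dp))
  cl <- keep_birds(detect_motion(pair$prev$lower, pair$curr$lower, dp))
  mu <- .candidates_to_messages(cu, "upper", t, module_id)
  ml <- .candidates_to_messages(cl, "lower", t, module_id)
  sync <- synchronize_streams(mu, ml, config$sync_tolerance)
  out <- list()
  for (sp in sync) {
    pairs <- match_objects(sp$upper, sp$lower,
                           max_center_diff = config$match$max_center_diff,
                           min_ydiff = config$match$min_ydiff)
    for (i in seq_len(nrow(pairs))) {
      pr <- pairs[i, ]
      est <- estimate_size(pr, config$rig, config$assembly)
      loc <- localize(pr$yc_u, pr$yc_d, config$rig)
      cls <- classify_size(est, config$boundaries)
      act <- decide_action(cls, loc$d, config$policy)
      out[[length(out) + 1L]] <-
        event_record(sp$t, module_id, loc, est, cls, act)
    }
  }
  if (length(out)) do.call(rbind, out) else .empty_archive()
}

#' Evaluate an event archive against scene ground truth
#'
#' Scene-level confusion: a scene expecting a detection that produced at
#' least one event is a true positive; events in empty scenes are false
#' positives, etc. Metrics follow the standard precision/recall/F1/
#' specificity/accuracy definitions.
#'
#' @param archive data.frame from [run_pipeline()].
#' @param expected data.frame with columns `t` (scene time) and `bird`
#'   (logical: should the scene produce an event).
#' @param tol timestamp matching tolerance, s.
#' @return A `metrics_report` (see [compute_metrics()]).
#' @export
evaluate_events <- function(archive, expected, tol = 0.05) {
  hit <- vapply(expected$t, function(t0)
    any(abs(archive$timestamp - t0) <= tol), logical(1))
  counts <- confusion_counts(tp = sum(hit & expected$bird),
                             fp = sum(hit & !expected$bird),
                             fn = sum(!hit & expected$bird),
                             tn = sum(!hit & !expected$bird))
  out <- compute_metrics(counts)
  attr(out, "counts") <- counts
  out
}
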