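# Two-frame motion detection pipeline:
#   Gaussian smoothing -> absolute frame difference -> difference threshold
#   -> Gaussian merge blur (fuses the two-fold motion ghosts) -> binary
#   threshold -> connected components -> per-component measurement
#   (bounding box, image-moment centroid, shoelace contour area) -> minimum
#   size filter (12 x 2 px) -> ROI cropping.
#
# Frames are numeric matrices (grayscale) or H x W x 3 arrays (RGB) with
# intensities in [0, 255]. Pixel coordinates in candidate records are
# 0-based, origin top-left, x rightward (columns), y downward (rows).

#' Frame image container
#'
#' @param pixels numeric matrix (grayscale) or H x W x 3 array (RGB),
#'   intensities 0--255.
#' @param timestamp acquisition time, seconds.
#' @return Object of class `frame_image`.
#' @export
frame_image <- function(pixels, timestamp = 0) {
  d <- dim(pixels)
  if (is.null(d) || length(d) < 2 || any(d[1:2] <= 0))
    stop("frame_image: pixels must be a matrix or H x W x 3 array")
  if (length(d) == 3 && d[3] != 3)
    stop("frame_image: color frames must have 3 channels")
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("frame_image: intensities must lie in [0, 255]")
  structure(list(pixels = pixels, timestamp = timestamp), class = "frame_image")
}

.as_pixels <- function(frame) {
  if (inherits(frame, "frame_image")) frame$pixels else frame
}

# luma conversion for color frames (Rec. 601 weights)
.to_gray <- function(px) {
  if (length(dim(px)) == 3)
    0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  else px
}

# normalized 1-D Gaussian taps for an odd kernel
.gauss_taps <- function(kernel, sigma) {
  r <- (kernel - 1) / 2
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

# reflect-border index vector for length n and radius r
.reflect_idx <- function(n, r) {
  idx <- (1 - r):(n + r)
  idx[idx < 1] <- 2 - idx[idx < 1]
  idx[idx > n] <- 2 * n - idx[idx > n]
  idx
}

# separable Gaussian filter of a single-channel matrix
.gauss_filter_mat <- function(m, kernel, sigma) {
  w <- .gauss_taps(kernel, sigma)
  r <- (kernel - 1) / 2
  n <- nrow(m); p <- ncol(m)
  # rows
  mp <- m[.reflect_idx(n, r), , drop = FALSE]
  out <- matrix(0, n, p)
  for (k in seq_len(kernel)) out <- out + w[k] * mp[(k):(k + n - 1), , drop = FALSE]
  # columns
  mp <- out[, .reflect_idx(p, r), drop = FALSE]
  out <- matrix(0, n, p)
  for (k in seq_len(kernel)) out <- out + w[k] * mp[, (k):(k + p - 1), drop = FALSE]
  out
}

#' Gaussian smoothing of a frame
#'
#' Separable Gaussian convolution with reflected borders; color frames are
#' filtered per channel. Suppresses sensor noise and small lighting changes
#' before differencing.
#'
#' @param frame matrix, H x W x 3 array, or [frame_image()].
#' @param kernel odd kernel size >= 3, px.
#' @param sigma Gaussian standard deviation, px.
#' @return Filtered pixels, same dimensions and type as the input pixels.
#' @export
gaussian_smooth <- function(frame, kernel = 5, sigma = 1.5) {
  if (kernel < 3 || kernel %% 2 == 0)
    stop("gaussian_smooth: kernel must be odd and >= 3")
  px <- .as_pixels(frame)
  if (length(dim(px)) == 3) {
    out <- px
    for (ch in 1:3) out[, , ch] <- .gauss_filter_mat(px[, , ch], kernel, sigma)
    out
  } else {
    .gauss_filter_mat(px, kernel, sigma)
  }
}

#' Detection pipeline parameters
#'
#' Tunable parameters of the motion-detection stage. The merge blur must be
#' wide enough to bridge the gap between the two motion ghosts of a fast
#' object (up to ~10 px with the defaults) while the low binary threshold
#' keeps 2 px thin birds alive; the refinement step then re-measures the
#' object in the current frame so sizes are not inflated by the motion
#' envelope.
#'
#' @param kernel,sigma pre-blur Gaussian (odd px; px).
#' @param diff_thresh minimum absolute frame difference kept, intensity.
#' @param merge_kernel,merge_sigma ghost-merging Gaussian.
#' @param binary_thresh binarization threshold after the merge blur.
#' @param min_w,min_h minimum candidate bounding box, px (artifact filter).
#' @param refine re-segment each mask component in the current frame
#'   against the local background (logical).
#' @param refine_thresh minimum |intensity - local background| for a pixel
#'   to belong to the refined object.
#' @param crop_size side of the square classification crop, px.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(kernel = 5, sigma = 1.5, diff_thresh = 25,
                             merge_kernel = 21, merge_sigma = 3.5,
                             binary_thresh = 10, min_w = 12, min_h = 2,
                             refine = TRUE, refine_thresh = 50,
                             crop_size = 100) {
  if (kernel %% 2 == 0 || merge_kernel %% 2 == 0)
    stop("detection_params: kernels must be odd")
  if (diff_thresh <= 0 || diff_thresh >= 255 || binary_thresh <= 0 || binary_thresh >= 255)
    stop("detection_params: thresholds must be in (0, 255)")
  structure(list(kernel = kernel, sigma = sigma, diff_thresh = diff_thresh,
                 merge_kernel = merge_kernel, merge_sigma = merge_sigma,
                 binary_thresh = binary_thresh, min_w = min_w, min_h = min_h,
                 refine = refine, refine_thresh = refine_thresh,
                 crop_size = crop_size),
            class = "detection_params")
}

#' Binary motion mask from two frames
#'
#' Absolute difference of the (already smoothed) frames, difference
#' threshold, Gaussian merge blur and binary threshold. The merge blur fuses
#' the "two-fold" ghosts a moving object leaves in the difference image into
#' a single connected blob.
#'
#' @param prev,curr frames of equal dimensions (matrix/array/[frame_image()]).
#' @param params a [detection_params()].
#' @return Logical matrix: TRUE where motion was detected.
#' @export
frame_difference_mask <- function(prev, curr, params = detection_params()) {
  a <- .to_gray(.as_pixels(prev)); b <- .to_gray(.as_pixels(curr))
  if (!identical(dim(a), dim(b)))
    stop("frame_difference_mask: frame dimensions differ")
  d <- abs(b - a)
  d[d < params$diff_thresh] <- 0
  merged <- .gauss_filter_mat(d, params$merge_kernel, params$merge_sigma)
  merged >= params$binary_thresh
}

#' Shoelace (Green's formula) polygon area
#'
#' Closed-form area of a simple polygon from its ordered vertices.
#'
#' @param poly two-column matrix of (x, y) vertices, closed implicitly.
#' @return Absolute enclosed area.
#' @export
#' @examples
#' green_area(cbind(c(0, 4, 0), c(0, 0, 3))) # 6
green_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# number of lattice points on the closed polygonal boundary
.boundary_lattice_count <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  g <- mapply(function(dx, dy) {
    dx <- abs(dx); dy <- abs(dy)
    if (dx == 0 && dy == 0) 0L else .gcd(dx, dy)
  }, xn - x, yn - y)
  sum(g)
}

.gcd <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }

# area of the pixel region bounded by a lattice contour through pixel
# centres: shoelace area plus Pick's-theorem boundary correction, so that a
# filled w x h rectangle yields exactly w*h pixels.
.contour_pixel_area <- function(poly) {
  if (nrow(poly) < 3) return(nrow(poly))
  green_area(poly) + .boundary_lattice_count(poly) / 2 + 1
}

# measure one labelled component: bounding box, moments, contour
.measure_component <- function(mask01, label_img, id) {
  sel <- which(label_img == id, arr.ind = TRUE)          # (row, col), 1-based
  rows <- sel[, 1]; cols <- sel[, 2]
  # image moments of the filled component (m00/m10/m01), 0-based coords
  xc <- mean(cols - 1); yc <- mean(rows - 1)
  p_w <- diff(range(cols)) + 1L
  p_h <- diff(range(rows)) + 1L
  oc <- EBImage::ocontour(EBImage::Image(label_img == id))[[1]]  # (x, y) 0-based
  o_s <- min(.contour_pixel_area(oc), p_w * p_h)
  list(contour = oc, p_w = as.integer(p_w), p_h = as.integer(p_h),
       o_s = o_s, centroid = c(xc = xc, yc = yc),
       bbox = c(x0 = min(cols) - 1L, y0 = min(rows) - 1L,
                x1 = max(cols) - 1L, y1 = max(rows) - 1L),
       n_px = nrow(sel))
}

#' Extract detection candidates from a motion mask
#'
#' Labels connected components of the mask, optionally refines each against
#' the current frame (segmenting pixels that deviate from the local
#' background inside the component's neighbourhood, which recovers the
#' object's true extent rather than its motion envelope), measures bounding
#' box, image-moment centroid and shoelace contour area, and drops
#' components smaller than the minimum detectable size.
#'
#' @param mask logical/0-1 matrix from [frame_difference_mask()].
#' @param source the current frame the mask was computed from.
#' @param params a [detection_params()]; `min_w`/`min_h` give the 12 x 2 px
#'   artifact filter.
#' @return List of `detection_candidate` objects (possibly empty), each with
#'   fields `contour` (0-based (x,y)), `p_w`, `p_h`, `o_s`, `centroid`,
#'   `crop` (`crop_size` square patch) and `bbox`.
#' @export
extract_candidates <- function(mask, source, params = detection_params()) {
  mask01 <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(mask01 > 0)) return(list())
  gray <- .to_gray(.as_pixels(source))
  labels <- EBImage::bwlabel(EBImage::Image(mask01))
  labels <- EBImage::imageData(labels)
  out <- list()
  for (id in seq_len(max(labels))) {
    comp <- .measure_component(mask01, labels, id)
    if (isTRUE(params$refine)) {
      ref <- .refine_component(gray, comp, params)
      # no current-frame object inside the grown ROI: the component is the
      # motion ghost of a departed object
      if (is.null(ref)) next
      comp <- ref
    }
    if (comp$p_w >= params$min_w && comp$p_h >= params$min_h) {
      # two mask components can refine onto the same object (unfused
      # ghosts); keep only one candidate per refined location
      dup <- any(vapply(out, function(o) {
        all(abs(o$centroid - comp$centroid) <= 2)
      }, logical(1)))
      if (!dup) {
        comp$crop <- crop_roi(comp, source, params$crop_size)
        out[[length(out) + 1L]] <- structure(comp, class = "detection_candidate")
      }
    }
  }
  out
}

# Re-segment the object inside (a margin around) the mask component using
# the current frame: pixels deviating from the local background (median of
# the ROI border) by more than refine_thresh. The ROI is grown while the
# refined object touches its edge, so an object only partially covered by
# the motion ghost is still measured in full. Returns NULL if the refined
# segmentation is empty (caller keeps the mask-based measurement).
.refine_component <- function(gray, comp, params) {
  h <- nrow(gray); w <- ncol(gray)
  m <- 2L
  repeat {
    r0 <- max(1L, comp$bbox[["y0"]] + 1L - m); r1 <- min(h, comp$bbox[["y1"]] + 1L + m)
    c0 <- max(1L, comp$bbox[["x0"]] + 1L - m); c1 <- min(w, comp$bbox[["x1"]] + 1L + m)
    roi <- gray[r0:r1, c0:c1, drop = FALSE]
    border <- c(roi[1, ], roi[nrow(roi), ], roi[, 1], roi[, ncol(roi)])
    bg <- stats::median(border)
    obj <- abs(roi - bg) > params$refine_thresh
    if (!any(obj)) return(NULL)
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(obj), nrow(roi)))))
    sizes <- tabulate(labels[labels > 0])
    comp2 <- .measure_component(obj, labels, which.max(sizes))
    touches <- comp2$bbox[["x0"]] == 0 && c0 > 1 ||
      comp2$bbox[["y0"]] == 0 && r0 > 1 ||
      comp2$bbox[["x1"]] == ncol(roi) - 1 && c1 < w ||
      comp2$bbox[["y1"]] == nrow(roi) - 1 && r1 < h
    if (!touches || m > max(h, w)) break
    m <- m * 4L
  }
  # shift ROI-local coordinates back to frame coordinates (0-based)
  off_x <- c0 - 1L; off_y <- r0 - 1L
  comp2$contour[, 1] <- comp2$contour[, 1] + off_x
  comp2$contour[, 2] <- comp2$contour[, 2] + off_y
  comp2$centroid <- comp2$centroid + c(off_x, off_y)
  comp2$bbox <- comp2$bbox + c(off_x, off_y, off_x, off_y)
  comp2
}

#' Crop a square classification patch around a candidate
#'
#' A `size` x `size` (default 100 x 100) patch centred on the candidate
#' centroid; if the candidate is larger than the mask, a square of side
#' `max(p_w, p_h)` is cropped first and rescaled down to `size`. Regions
#' outside the frame are zero-padded.
#'
#' @param candidate a `detection_candidate` (needs `centroid`, `p_w`, `p_h`).
#' @param source frame to crop from (matrix / array / [frame_image()]).
#' @param size output patch side, px.
#' @return `size` x `size` matrix or `size` x `size` x 3 array.
#' @export
crop_roi <- function(candidate, source, size = 100) {
  px <- .as_pixels(source)
  is_color <- length(dim(px)) == 3
  h <- dim(px)[1]; w <- dim(px)[2]
  side <- max(size, candidate$p_w, candidate$p_h)
  xc <- candidate$centroid[["xc"]]; yc <- candidate$centroid[["yc"]]
  # 1-based source window centred on the centroid
  r0 <- floor(yc + 1 - side / 2) + 1L; c0 <- floor(xc + 1 - side / 2) + 1L
  rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
  rin <- rows >= 1 & rows <= h; cin <- cols >= 1 & cols <= w
  grab <- function(m) {
    out <- matrix(0, side, side)
    out[rin, cin] <- m[rows[rin], cols[cin]]
    out
  }
  patch <- if (is_color) {
    ar <- array(0, c(side, side, 3))
    for (ch in 1:3) ar[, , ch] <- grab(px[, , ch])
    ar
  } else grab(px)
  if (side > size) patch <- .resize_patch(patch, size)
  patch
}

# nearest-neighbour downscale of a square patch (adequate for silhouettes)
.resize_patch <- function(patch, size) {
  side <- dim(patch)[1]
  idx <- pmin(side, floor((seq_len(size) - 0.5) * side / size) + 1L)
  if (length(dim(patch)) == 3) patch[idx, idx, , drop = FALSE] else patch[idx, idx, drop = FALSE]
}

#' Run the full single-camera detection pipeline on a frame pair
#'
#' Smoothing, differencing/merging, candidate extraction and cropping in
#' pipeline order.
#'
#' @param prev,curr consecutive frames from one camera.
#' @param params a [detection_params()].
#' @return List of `detection_candidate` objects.
#' @export
detect_motion <- function(prev, curr, params = detection_params()) {
  a <- gaussian_smooth(.to_gray(.as_pixels(prev)), params$kernel, params$sigma)
  b <- gaussian_smooth(.to_gray(.as_pixels(curr)), params$kernel, params$sigma)
  mask <- frame_difference_mask(a, b, params)
  extract_candidates(mask, curr, params)
}

#' @export
print.detection_candidate <- function(x, ...) {
  cat(sprintf("<detection_candidate %d x %d px, area %.1f px^2, centroid (%.1f, %.1f)>\n",
              x$p_w, x$p_h, x$o_s, x$centroid[["xc"]], x$centroid[["yc"]]))
  invisible(x)
}
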