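# Two-frame motion detection: smoothing, differencing/merging, contour
# measurement, ROI cropping and the composed pipeline.

test_that("Gaussian smoothing preserves DC, mass, and matches brute force", {
  const <- matrix(137, 20, 30)
  expect_equal(gaussian_smooth(const, 5, 1.5), const, tolerance = 1e-12)
  # single bright pixel: symmetric response, mass preserved
  imp <- matrix(0, 21, 21); imp[11, 11] <- 255
  sm <- gaussian_smooth(imp, 5, 1.5)
  expect_equal(sum(sm), 255, tolerance = 1e-9)
  expect_equal(sm, sm[21:1, ], tolerance = 1e-12)          # vertical symmetry
  expect_equal(sm, t(sm), tolerance = 1e-12)               # x/y symmetry
  expect_gt(sm[11, 11], sm[10, 11])
  # random image against the direct 2-D convolution oracle
  set.seed(5)
  m <- matrix(runif(15 * 12, 0, 255), 15, 12)
  taps <- exp(-((-2):2)^2 / (2 * 1.5^2)); taps <- taps / sum(taps)
  expect_lt(max(abs(gaussian_smooth(m, 5, 1.5) -
                      conv2_reflect_oracle(m, outer(taps, taps)))), 1)
  expect_error(gaussian_smooth(m, 4, 1.5), "odd")
})

test_that("difference mask fuses motion ghosts and ignores gain shifts", {
  sky <- matrix(200, 120, 120)
  sq <- function(r0, c0) { m <- sky; m[r0:(r0 + 19), c0:(c0 + 19)] <- 20; m }
  # identical frames: empty mask
  expect_false(any(frame_difference_mask(sq(50, 40), sq(50, 40))))
  # 20 px square moved by 10 px: the two difference ghosts merge into ONE
  # connected component
  mask <- frame_difference_mask(sq(50, 40), sq(50, 50))
  labs <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(mask), nrow(mask)))))
  expect_equal(max(labs), 1)
  # uniform +5 illumination shift below the difference threshold: empty
  expect_false(any(frame_difference_mask(sky, sky + 5)))
  expect_error(frame_difference_mask(sky, matrix(200, 60, 60)), "dimensions")
})

test_that("shoelace area is exact on polygons", {
  expect_equal(green_area(cbind(c(0, 4, 0), c(0, 0, 3))), 6)
  expect_equal(green_area(cbind(c(0, 10, 10, 0), c(0, 0, 5, 5))), 50)
  # orientation invariant
  expect_equal(green_area(cbind(c(0, 0, 10, 10), c(0, 5, 5, 0))), 50)
  # degenerate
  expect_equal(green_area(cbind(0:1, 0:1)), 0)
  set.seed(3)
  for (i in 1:20) {
    # random star-shaped polygon vs fan triangulation from its kernel (the
    # origin): triangles all share the origin and carry one edge each
    # angular gaps below pi keep the origin interior, so the fan is valid
    ang <- 2 * pi * (0:5) / 6 + runif(6, 0, pi / 4)
    r <- runif(6, 1, 5)
    poly <- cbind(r * cos(ang), r * sin(ang))
    nxt <- c(2:nrow(poly), 1)
    tri <- sum(abs(poly[, 1] * poly[nxt, 2] - poly[nxt, 1] * poly[, 2]) / 2)
    expect_equal(green_area(poly), tri, tolerance = 1e-9)
  }
})

test_that("candidate extraction measures rectangles exactly and drops motes", {
  mask <- matrix(FALSE, 80, 80)
  mask[30:37, 20:39] <- TRUE                       # 20 wide x 8 tall
  src <- matrix(200, 80, 80); src[30:37, 20:39] <- 20
  cands <- extract_candidates(mask, src, detection_params(refine = FALSE))
  expect_length(cands, 1)
  cd <- cands[[1]]
  expect_equal(cd$p_w, 20L)
  expect_equal(cd$p_h, 8L)
  expect_equal(cd$o_s, 160)                        # enclosed pixel area
  expect_lt(abs(cd$o_s - 160) / 160, 0.10)
  expect_equal(unname(cd$centroid), c((20 + 39) / 2 - 1, (30 + 37) / 2 - 1))
  # centroid inside the bounding box; area bounded by the box
  expect_true(cd$centroid[["xc"]] >= cd$bbox[["x0"]] &&
                cd$centroid[["xc"]] <= cd$bbox[["x1"]])
  expect_lte(cd$o_s, cd$p_w * cd$p_h)
  # a 5 x 1 blob is neglected as an artifact
  mask2 <- matrix(FALSE, 80, 80); mask2[40, 10:14] <- TRUE
  expect_length(extract_candidates(mask2, src, detection_params(refine = FALSE)), 0)
  expect_length(extract_candidates(matrix(FALSE, 10, 10), matrix(0, 10, 10)), 0)
})

test_that("ROI crops are centred, resized when large, and zero-padded", {
  src <- matrix(200, 300, 300); src[140:147, 130:149] <- 20
  cand <- list(centroid = c(xc = 139.5, yc = 143.5), p_w = 20L, p_h = 8L)
  crop <- crop_roi(cand, src, 100)
  expect_equal(dim(crop), c(100, 100))
  # the dark object sits in the middle of the patch
  expect_lt(crop[50, 50], 50)
  expect_equal(crop[5, 5], 200)
  # objects larger than the mask: crop max(p_w, p_h) then rescale
  big <- list(centroid = c(xc = 149.5, yc = 149.5), p_w = 160L, p_h = 40L)
  expect_equal(dim(crop_roi(big, src, 100)), c(100, 100))
  # corner object: zero padding fills the out-of-frame region
  corner <- list(centroid = c(xc = 2, yc = 2), p_w = 12L, p_h = 4L)
  cc <- crop_roi(corner, src, 100)
  expect_equal(dim(cc), c(100, 100))
  expect_equal(cc[1, 1], 0)
})

test_that("full pipeline finds rendered birds with accurate widths", {
  cfg <- mini_scene(seed = 9)
  # static sky: nothing
  s0 <- render_stereo_frames(list(), cfg, 0)
  s1 <- render_stereo_frames(list(), cfg, 0.1)
  expect_length(detect_motion(s0$upper, s1$upper), 0)
  # one bird moving ~15 px between frames: exactly one candidate, p_w
  # within 2 px of the rendered wingspan
  b <- world_bird(18, 12, 0, wingspan = 1.5, body_height = 0.5)
  b2 <- b; b2$azimuth <- 3.21   # about 15 px shift at this range
  f1 <- render_stereo_frames(list(b), cfg, 1)
  f2 <- render_stereo_frames(list(b2), cfg, 1.1)
  cands <- detect_motion(f1$upper, f2$upper)
  expect_length(cands, 1)
  # compare against the silhouette actually drawn in the current frame
  dark <- f2$upper < 130
  drawn_w <- diff(range(which(colSums(dark) > 0))) + 1
  drawn_h <- diff(range(which(rowSums(dark) > 0))) + 1
  expect_lte(abs(cands[[1]]$p_w - drawn_w), 2)
  expect_lte(abs(cands[[1]]$p_h - drawn_h), 2)
  expect_lte(abs(cands[[1]]$p_w - f2$truth$p_w), 3)
  # bounding boxes stay inside the frame, minimum size respected
  expect_gte(cands[[1]]$p_w, 12)
  expect_gte(cands[[1]]$p_h, 2)
  expect_true(cands[[1]]$bbox[["x1"]] < ncol(f2$upper))
  # two well-separated birds: two candidates
  ba <- world_bird(15, 10, -8, wingspan = 1.4, body_height = 0.5)
  bb <- world_bird(13, 8, 8, wingspan = 1.2, body_height = 0.45)
  ba2 <- ba; ba2$azimuth <- ba$azimuth + 2
  bb2 <- bb; bb2$azimuth <- bb$azimuth - 2
  g1 <- render_stereo_frames(list(ba, bb), cfg, 2)
  g2 <- render_stereo_frames(list(ba2, bb2), cfg, 2.1)
  expect_length(detect_motion(g1$upper, g2$upper), 2)
  # determinism: identical inputs give identical candidate lists
  expect_identical(detect_motion(f1$upper, f2$upper),
                   detect_motion(f1$upper, f2$upper))
})
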