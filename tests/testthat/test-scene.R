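# Synthetic scene generator: projection ground truth, rendering,
# flight paths, crop datasets and the silhouette campaign script.

test_that("projection is the exact inverse of localization", {
  rig <- ref_rig(); asm <- c1_assembly()
  set.seed(14)
  for (i in 1:100) {
    b <- world_bird(runif(1, 40, 350), runif(1, 20, 220),
                    runif(1, -15, 15), 1.5, 0.5)
    pu <- project_bird(b, "upper", rig, asm)
    pl <- project_bird(b, "lower", rig, asm)
    if (!(pu$in_view && pl$in_view)) next
    loc <- localize(pu$y, pl$y, rig)
    expect_equal(loc$d, b$distance, tolerance = 1e-9)
    expect_equal(loc$h, b$height, tolerance = 1e-9)
    # midline disparity equals the analytic expectation
    expect_equal(pu$y - pl$y,
                 expected_disparity(pu$d_b, rig)$continuous, tolerance = 1e-9)
  }
})

test_that("projected extents follow the pinhole scale", {
  rig <- ref_rig(); asm <- c1_assembly()
  # wingspan 1.5 m at ~300 m projects to ~13.4 px
  b <- world_bird(300 * cos(31.5 * pi / 180), 300 * sin(31.5 * pi / 180) + 1,
                  0, 1.5, 0.5)
  p <- project_bird(b, "upper", rig, asm)
  expect_equal(p$d_b, 300, tolerance = 2)
  expect_lt(abs(p$p_w - 13.4), 0.6)
  # doubling the range halves the extent
  b1 <- world_bird(100, 60, 0, 1.5, 0.5)
  b2 <- world_bird(200, 120, 0, 1.5, 0.5)
  p1 <- project_bird(b1, "upper", rig, asm)
  p2 <- project_bird(b2, "upper", rig, asm)
  expect_equal(p1$p_w / p2$p_w, p2$d_b / p1$d_b * 1, tolerance = 1e-9)
  # behind-the-rig positions are flagged out of view
  expect_false(project_bird(world_bird(1, 500, 0), "upper", rig, asm)$in_view)
})

test_that("rendering is deterministic and places silhouettes correctly", {
  cfg <- mini_scene(seed = 4)
  # empty scene, zero noise: pure background
  cfg0 <- cfg; cfg0$noise_sigma <- 0
  s <- render_stereo_frames(list(), cfg0, 0)
  expect_true(all(s$upper == cfg$sky_intensity))
  expect_equal(dim(s$upper), c(328, 246))
  # one bird: dark pixels only at the projected location
  b <- world_bird(20, 13, 0, 1.5, 0.5)
  s1 <- render_stereo_frames(list(b), cfg0, 0)
  dark <- which(s1$upper < 100, arr.ind = TRUE)
  expect_gt(nrow(dark), 0)
  expect_lte(max(abs(dark[, "col"] - 1 - s1$truth$x)), s1$truth$p_w / 2 + 1)
  expect_lte(max(abs(dark[, "row"] - s1$truth$y_u)), s1$truth$p_h / 2 + 1)
  # the lower camera sees the bird at a smaller row (positive disparity)
  dark_l <- which(s1$lower < 100, arr.ind = TRUE)
  expect_gt(mean(dark[, "row"]), mean(dark_l[, "row"]))
  # seeded noise: bit-identical frames for identical (seed, t)
  r1 <- render_stereo_frames(list(b), cfg, 3.2)
  r2 <- render_stereo_frames(list(b), cfg, 3.2)
  expect_identical(r1$upper, r2$upper)
  r3 <- render_stereo_frames(list(b), cfg, 3.3)
  expect_false(identical(r1$upper, r3$upper))
})

test_that("flight paths respect their geometry", {
  fl <- simulate_flight("circular", duration = 60, fps = 2, seed = 8)
  expect_equal(nrow(fl), 121)
  # jittered radius/height scatter around the programmed values
  expect_equal(mean(fl$distance), 143.3, tolerance = 1)
  expect_equal(mean(fl$height), 102.9, tolerance = 0.6)
  expect_lt(sd(fl$distance), 4)
  # without jitter the circle is exact
  fl0 <- simulate_flight("circular",
                         params = list(radius_jitter = 0, height_jitter = 0),
                         duration = 30, fps = 1)
  expect_true(all(fl0$distance == 143.3))
  expect_true(all(fl0$height == 102.9))
  # angular speed matches arc length: speed * duration = r * angle
  swept <- (fl0$azimuth[nrow(fl0)] - fl0$azimuth[1]) %% 360 * pi / 180
  expect_equal(143.3 * swept, 15 * 30, tolerance = 1e-6)
  # determinism
  expect_identical(simulate_flight("circular", duration = 10, seed = 3),
                   simulate_flight("circular", duration = 10, seed = 3))
  lin <- simulate_flight("linear", duration = 10, fps = 1)
  expect_equal(lin$distance[1], 300)
  expect_equal(lin$distance[nrow(lin)], 100)
})

test_that("crop datasets are balanced, deterministic and separable", {
  ds <- generate_crop_dataset(40, 40, size = 40, channels = 3, seed = 17)
  expect_length(ds$crops, 80)
  expect_equal(sum(ds$labels), 40)
  expect_true(all(vapply(ds$crops, function(cr)
    all(dim(cr) == c(40, 40, 3)), logical(1))))
  rng <- range(unlist(lapply(ds$crops[1:5], range)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 255)
  # same seed, same dataset
  ds2 <- generate_crop_dataset(40, 40, size = 40, channels = 3, seed = 17)
  expect_identical(ds, ds2)
  # a trivial dark-area threshold classifier clears the sanity floor on the
  # default (100 px) generator
  ds <- generate_crop_dataset(60, 60, size = 100, channels = 3, seed = 17)
  area <- vapply(ds$crops, function(cr) {
    g <- cr[, , 1]
    sum(abs(g - stats::median(g)) > 40)
  }, numeric(1))
  best <- max(vapply(seq(0, max(area), length.out = 120), function(th)
    max(mean((area >= th) == ds$labels), mean((area < th) == ds$labels)),
    numeric(1)))
  expect_gte(best, 0.80)
})

test_that("silhouette campaign scripts 18 scenes with exact targets", {
  rig <- ref_rig(); asm <- c1_assembly()
  camp <- generate_silhouette_campaign(rig, asm)
  expect_length(camp, 18)
  expect_equal(sort(unique(vapply(camp, `[[`, numeric(1), "d_ref"))),
               seq(50, 300, by = 50))
  sizes <- table(vapply(camp, `[[`, character(1), "silhouette"))
  expect_equal(unname(sizes[c("small", "medium", "large")]), rep(6L, 3),
               ignore_attr = TRUE)
  # the scripted target sits at the reference baseline distance
  for (i in c(1, 8, 18))
    expect_equal(camp[[i]]$truth$d_b, camp[[i]]$d_ref, tolerance = 1e-9)
  # the small silhouette drops under the 12 px width rule beyond ~180 m
  small200 <- camp[vapply(camp, function(s)
    s$silhouette == "small" && s$d_ref == 200, logical(1))][[1]]
  expect_lt(small200$truth$p_w, 12)
  large300 <- camp[vapply(camp, function(s)
    s$silhouette == "large" && s$d_ref == 300, logical(1))][[1]]
  expect_gte(large300$truth$p_w, 12)
})
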