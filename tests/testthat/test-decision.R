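# Stream fusion, cross-camera matching, size estimation, classification
# and the avoidance policy.

msg_df <- function(camera, t, xc, yc, p_w = 20, p_h = 6, o_s = 60) {
  do.call(rbind, Map(function(tt, x, y)
    detection_message(camera, tt, o_s, p_w, p_h, x, y), t, xc, yc))
}

test_that("stream synchronization pairs co-timed frames", {
  up <- msg_df("upper", c(1, 2, 3), c(10, 20, 30), c(110, 120, 130))
  lo <- msg_df("lower", c(1, 2, 3), c(11, 21, 31), c(100, 110, 120))
  s <- synchronize_streams(up, lo, 0.05)
  expect_length(s, 3)
  expect_equal(vapply(s, `[[`, numeric(1), "t"), c(1, 2, 3))
  # offsets beyond tolerance: nothing pairs
  lo2 <- msg_df("lower", c(1.2, 2.2), c(11, 21), c(100, 110))
  expect_length(synchronize_streams(up, lo2, 0.05), 0)
  # jittered streams pair like nearest-timestamp assignment
  set.seed(12)
  t0 <- seq(0, 2, by = 0.2)
  jit <- t0 + runif(length(t0), -0.02, 0.02)
  s2 <- synchronize_streams(msg_df("upper", t0, 1, 1),
                            msg_df("lower", jit, 1, 1), 0.05)
  expect_length(s2, length(t0))
  expect_equal(vapply(s2, function(p) p$lower$timestamp - p$upper$timestamp,
                      numeric(1)), jit - t0, tolerance = 1e-12)
  expect_error(synchronize_streams(msg_df("upper", c(2, 1), 1, 1), lo),
               "sorted")
})

test_that("greedy matching agrees with the exhaustive assignment oracle", {
  up1 <- msg_df("upper", 1, 100, 100)
  lo1 <- msg_df("lower", 1, 110, 90)
  m1 <- match_objects(up1, lo1)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$center_distance, sqrt(200))
  expect_equal(m1$yc_diff, 10)
  # two well-separated objects: the obvious pairing
  up2 <- msg_df("upper", 1, c(100, 500), c(100, 400))
  lo2 <- msg_df("lower", 1, c(110, 505), c(90, 395))
  m2 <- match_objects(up2, lo2)
  expect_equal(m2$u, c(1, 2))
  expect_equal(m2$d, c(1, 2))
  # random L x M instances (L, M <= 4) against brute force
  set.seed(99)
  for (i in 1:40) {
    L <- sample(1:4, 1); M <- sample(1:4, 1)
    up <- msg_df("upper", 1, runif(L, 0, 400), runif(L, 150, 400))
    lo <- msg_df("lower", 1, up$xc[seq_len(L)] + runif(L, -40, 40),
                 pmax(1, up$yc[seq_len(L)] - runif(L, 5, 60)))
    lo <- lo[seq_len(M), , drop = FALSE]
    if (M > L) lo <- msg_df("lower", 1, runif(M, 0, 400), runif(M, 1, 380))
    got <- match_objects(up, lo, max_center_diff = Inf, min_ydiff = -Inf)
    oracle <- brute_force_assignment(up, lo)
    expect_equal(nrow(got), min(L, M))
    # greedy is the tested contract; on well-separated instances it
    # coincides with the optimal assignment
    if (i <= 20) expect_true(all(got$u %in% oracle[, "u"]))
    # no object used twice
    expect_equal(anyDuplicated(got$u), 0)
    expect_equal(anyDuplicated(got$d), 0)
  }
  # false-pair filter: offsets > 150 px or inverted disparity are removed
  far <- match_objects(msg_df("upper", 1, 100, 300),
                       msg_df("lower", 1, 300, 290))  # dx = 200
  expect_equal(nrow(far), 0)
  inv <- match_objects(msg_df("upper", 1, 100, 100),
                       msg_df("lower", 1, 100, 105))  # yc_diff < 1
  expect_equal(nrow(inv), 0)
  expect_equal(nrow(match_objects(up1[0, ], lo1)), 0)
})

test_that("greedy matching equals brute force on clustered instances", {
  # clustered objects where greedy and optimal can differ are still
  # resolved consistently: totals never better than optimal
  set.seed(123)
  for (i in 1:20) {
    L <- sample(2:4, 1); M <- sample(2:4, 1)
    up <- msg_df("upper", 1, runif(L, 0, 60), runif(L, 100, 160))
    lo <- msg_df("lower", 1, runif(M, 0, 60), runif(M, 80, 140))
    got <- match_objects(up, lo, max_center_diff = Inf, min_ydiff = -Inf)
    oracle <- brute_force_assignment(up, lo)
    dsum <- function(pairs) sum(sqrt((up$xc[pairs[, 1]] - lo$xc[pairs[, 2]])^2 +
                                       (up$yc[pairs[, 1]] - lo$yc[pairs[, 2]])^2))
    expect_gte(dsum(cbind(got$u, got$d)) + 1e-9, dsum(oracle))
    # the single closest pair is always taken by both
    expect_true(any(got$u == oracle[which.min(apply(oracle, 1, function(r)
      dsum(rbind(r)))), "u"]))
  }
})

test_that("size estimation reproduces the triangle approximation", {
  rig <- ref_rig(); asm <- c1_assembly()
  # the isosceles-triangle area from measured wingspan/height pairs
  expect_equal(round(1.53 * 0.51 / 2, 2), 0.39)
  expect_equal(round(0.84 * 0.34 / 2, 2), 0.14)
  # a matched pair at 100 m: disparity ~27 px for this rig
  pair <- data.frame(yc_u = 1700, yc_d = 1700 - 26.76237,
                     p_w_u = 40.1, p_w_d = 40.1, p_h_u = 13.4, p_h_d = 13.4,
                     o_s_u = 270, o_s_d = 270)
  est <- estimate_size(pair, rig, asm)
  expect_equal(est$d_bc, 100, tolerance = 1e-6)
  # PW = Db * p_w * VSS_h / (f * VSR_h)
  expect_equal(est$wingspan, est$d_bc * 40.1 * 3.680 / (3 * 3280),
               tolerance = 1e-12)
  expect_equal(est$approx_area, est$wingspan * est$body_height / 2,
               tolerance = 1e-15)
  expect_equal(est$delta_dbc, est$d_bc / (2 * (1700 - pair$yc_d)),
               tolerance = 1e-9)
  # degenerate: zero pixel size gives zero physical size
  p0 <- pair; p0$p_w_u <- p0$p_w_d <- 0; p0$p_h_u <- p0$p_h_d <- 0
  est0 <- estimate_size(p0, rig, asm)
  expect_equal(est0$wingspan, 0)
  expect_equal(est0$approx_area, 0)
  # every emitted estimate satisfies Oapprox = PW * PH / 2 exactly
  set.seed(31)
  for (i in 1:25) {
    pr <- data.frame(yc_u = 2000, yc_d = 2000 - runif(1, 5, 60),
                     p_w_u = runif(1, 12, 80), p_w_d = runif(1, 12, 80),
                     p_h_u = runif(1, 2, 25), p_h_d = runif(1, 2, 25),
                     o_s_u = runif(1, 30, 900), o_s_d = runif(1, 30, 900))
    e <- estimate_size(pr, rig, asm)
    expect_equal(e$approx_area, e$wingspan * e$body_height / 2,
                 tolerance = 1e-12)
  }
})

test_that("size classification applies the safety-first max rule", {
  expect_equal(as.character(classify_size(list(wingspan = 1.6, body_height = 0.6,
                                               contour_area = 0.5))), "large")
  expect_equal(as.character(classify_size(list(wingspan = 1.0, body_height = 0.35,
                                               contour_area = 0.2))), "small")
  # height alone votes medium: max rule promotes the bird
  expect_equal(as.character(classify_size(list(wingspan = 1.0, body_height = 0.45,
                                               contour_area = 0.2))), "medium")
  # everything below the small bounds: uncategorized
  expect_equal(as.character(classify_size(list(wingspan = 0.5, body_height = 0.2,
                                               contour_area = 0.05))),
               "uncategorized")
  # boundary conventions: 1.50 m is still medium, above is large
  expect_equal(as.character(classify_size(list(wingspan = 1.50, body_height = 0.1,
                                               contour_area = 0.01))), "medium")
  expect_equal(as.character(classify_size(list(wingspan = 1.51, body_height = 0.1,
                                               contour_area = 0.01))), "large")
  # monotone: enlarging any parameter never decreases the class
  lv <- c(uncategorized = 0, small = 1, medium = 2, large = 3)
  set.seed(6)
  for (i in 1:50) {
    e <- list(wingspan = runif(1, 0.3, 2), body_height = runif(1, 0.1, 0.8),
              contour_area = runif(1, 0.02, 0.6))
    base <- lv[[as.character(classify_size(e))]]
    for (fld in names(e)) {
      e2 <- e; e2[[fld]] <- e2[[fld]] + runif(1, 0, 0.5)
      expect_gte(lv[[as.character(classify_size(e2))]], base)
    }
  }
})

test_that("action policy triggers by class and distance", {
  pol <- action_policy()
  expect_setequal(decide_action("large", 150, pol),
                  c("strobe", "audio", "turbine_stop"))
  expect_setequal(decide_action("large", 250, pol), c("strobe", "audio"))
  expect_equal(decide_action("small", 350, pol), character())
  # boundary inclusive
  expect_setequal(decide_action("medium", 300, pol), c("strobe", "audio"))
  expect_setequal(decide_action("large", 200, pol),
                  c("strobe", "audio", "turbine_stop"))
  expect_equal(decide_action("uncategorized", 50, pol), character())
  # a stop zone wider than the deterrent zone is rejected
  expect_error(action_policy(c(small = 100, medium = 100, large = 100),
                             c(small = NA, medium = NA, large = 150)),
               "must not exceed")
})

test_that("event archive round-trips loss-free and in order", {
  loc <- localize(2000, 1985, ref_rig())
  pair <- data.frame(yc_u = 2000, yc_d = 1985, p_w_u = 30, p_w_d = 31,
                     p_h_u = 9, p_h_d = 10, o_s_u = 150, o_s_d = 160)
  est <- estimate_size(pair, ref_rig(), c1_assembly())
  ev <- event_record(12.5, "M3", loc, est, "medium", c("strobe", "audio"))
  tmp <- file.path(tempdir(), "events_test")
  unlink(paste0(tmp, c(".csv", ".jsonl")))
  record_event(ev, tmp)
  back <- read_event_archive(tmp)
  expect_equal(nrow(back), 1)
  expect_equal(back$d_b, ev$d_b)
  expect_equal(back$action, "strobe+audio")
  expect_equal(back$size_class, "medium")
  # many events, appended, stay in timestamp order
  evs <- do.call(rbind, lapply(1:50, function(i) {
    e <- ev; e$timestamp <- 12.5 + i; e
  }))
  record_event(evs, tmp)
  back2 <- read_event_archive(tmp)
  expect_equal(nrow(back2), 51)
  expect_false(is.unsorted(back2$timestamp))
  # JSON-lines twin has one record per row
  jl <- readLines(paste0(tmp, ".jsonl"))
  expect_length(jl, 51)
  expect_equal(jsonlite::fromJSON(jl[1])$module_id, "M3")
  unlink(paste0(tmp, c(".csv", ".jsonl")))
})
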