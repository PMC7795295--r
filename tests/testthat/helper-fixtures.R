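# Shared fixtures: the reference optical assembly / rig and a down-scaled
# "mini" rig (same fields of view, 10x fewer pixels) that keeps image-level
# tests fast.

c1_assembly <- function(f = 3) optical_assembly(sensor_catalog()$C1, f)

ref_rig <- function() stereo_rig(baseline = 1, vsr_axis = 3280, fov_axis = 63.0)

mini_assembly <- function(f = 3)
  optical_assembly(sensor_spec("mini", 328, 246, 3.680, 2.760), f)

mini_rig <- function(baseline = 1)
  stereo_rig(baseline = baseline, vsr_axis = 328, fov_axis = 63.0)

mini_scene <- function(seed = 1, noise = 2)
  scene_config(mini_rig(), mini_assembly(), noise_sigma = noise, seed = seed)

# brute-force 2-D convolution oracle (reflected borders), for checking the
# separable Gaussian implementation
conv2_reflect_oracle <- function(m, kern) {
  r <- (nrow(kern) - 1) / 2
  n <- nrow(m); p <- ncol(m)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r)
      acc <- acc + kern[a + r + 1, b + r + 1] * m[refl(i + a, n), refl(j + b, p)]
    out[i, j] <- acc
  }
  out
}

# exhaustive minimal-sum assignment oracle for cross-camera matching
brute_force_assignment <- function(up, lo) {
  L <- nrow(up); M <- nrow(lo)
  k <- min(L, M)
  dist <- outer(seq_len(L), seq_len(M), function(i, j)
    sqrt((up$xc[i] - lo$xc[j])^2 + (up$yc[i] - lo$yc[j])^2))
  if (L <= M) {
    perms <- .permutations(M, k)
    best <- NULL; best_sum <- Inf
    for (r in seq_len(nrow(perms))) {
      s <- sum(dist[cbind(seq_len(k), perms[r, ])])
      if (s < best_sum) { best_sum <- s; best <- cbind(u = seq_len(k), d = perms[r, ]) }
    }
  } else {
    perms <- .permutations(L, k)
    best <- NULL; best_sum <- Inf
    for (r in seq_len(nrow(perms))) {
      s <- sum(dist[cbind(perms[r, ], seq_len(k))])
      if (s < best_sum) { best_sum <- s; best <- cbind(u = perms[r, ], d = seq_len(k)) }
    }
  }
  best[order(best[, "u"]), , drop = FALSE]
}

.permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- NULL
  rec <- function(chosen) {
    if (length(chosen) == k) { out <<- rbind(out, chosen); return() }
    for (i in setdiff(seq_len(n), chosen)) rec(c(chosen, i))
  }
  rec(integer(0))
  out
}
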