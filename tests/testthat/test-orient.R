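# Shared small fixtures for the orientation machinery: a coarse 32-pixel
# detector for the cheap algebraic checks and a 64-pixel one (12 rings,
# 128 azimuths) where interpolation error is small enough for the
# simulator cross-checks.
geom_o <- detector_geometry(1, 32L, 500, 0.128)
model_o <- phantom_model(60, 25, seed = 2)
vol_o <- build_reference_volume(model_o, geom_o)
cfg_o <- spirecon:::resolve_cm_config(cm_config(), geom_o, 2L)
geom_f <- detector_geometry(1, 64L, 500, 0.128)
vol_f <- build_reference_volume(model_o, geom_f)
cfg_f <- spirecon:::resolve_cm_config(cm_config(), geom_f, 2L)

test_that("trilinear slice extraction is exact on a linear field", {
  n <- 32; dq <- vol_o$dq
  k <- seq_len(n) - (n / 2 + 1)
  ramp <- array(rep(3.5 * k * dq, times = n * n), c(n, n, n))  # f(q) = a qx
  vol <- fourier_volume(ramp, dq, kind = "intensity")
  sl <- extract_slice(vol, c(0, 0, 0), geom_o, 2L)
  qm <- ewald_qmap(geom_o, 2L)
  expect_equal(sl, 3.5 * qm$qx, tolerance = 1e-10)
})

test_that("a reference slice reproduces the noiseless pattern at that orientation", {
  p <- simulation_params(1e15, 0.1, poisson = FALSE)
  e <- c(2.2, 0.8, 0.6)
  pat <- bin2x2(simulate_pattern(model_o, geom_f, p, e))
  cal <- p$fluence * R_E_ANGSTROM^2 * solid_angle_map(geom_f, 2L)
  sl <- extract_slice(vol_f, e, geom_f, 2L)
  ## ring-wise Pearson within the correlation band
  pp <- cartesian_to_polar(pat$counts / cal, geom_f, 2L, cfg_f)
  sp <- cartesian_to_polar(sl, geom_f, 2L, cfg_f)
  for (r in seq_len(nrow(pp$values))) {
    expect_gt(cor(pp$values[r, ], sp$values[r, ]), 0.99)
  }
})

test_that("in-plane rotation of the orientation circularly shifts the polar slice", {
  nth <- cfg_f$n_theta
  k <- 9
  phi <- 2 * pi * k / nth
  s0 <- cartesian_to_polar(extract_slice(vol_f, c(1.1, 0.9, 0), geom_f, 2L),
                           geom_f, 2L, cfg_f)
  s1 <- cartesian_to_polar(extract_slice(vol_f, c(1.1, 0.9, phi), geom_f, 2L),
                           geom_f, 2L, cfg_f)
  ## gamma advances the pattern azimuth: s1(theta) = s0(theta + phi),
  ## up to the trilinear interpolation error of two independent samplings
  shifted <- s0$values[, 1 + (seq_len(nth) - 1 + k) %% nth]
  ok <- !is.na(shifted) & !is.na(s1$values)
  expect_gt(cor(shifted[ok], s1$values[ok]), 0.98)
})

test_that("polar resampling respects radial symmetry and point positions", {
  n <- 32
  ctr <- spirecon:::binned_center(geom_f, 2L) + 1
  xg <- matrix(seq_len(n), n, n) - ctr[1]
  yg <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr[2]
  rad <- sqrt(xg^2 + yg^2)
  pol <- cartesian_to_polar(exp(-rad / 6), geom_f, 2L, cfg_f)
  for (r in seq_len(nrow(pol$values)))
    expect_lt(diff(range(pol$values[r, ])) / mean(pol$values[r, ]), 0.015)
  ## an off-axis Gaussian spot lands on the right (ring, azimuth)
  spot_r <- 8; spot_th <- 2 * pi * 33 / cfg_f$n_theta
  sx <- spot_r * cos(spot_th); sy <- spot_r * sin(spot_th)
  img <- exp(-((xg - sx)^2 + (yg - sy)^2) / 2)
  pol2 <- cartesian_to_polar(img, geom_f, 2L, cfg_f)
  pk <- which(pol2$values == max(pol2$values), arr.ind = TRUE)
  expect_lte(abs(pol2$rings[pk[1]] - spot_r), 1)
  dth <- abs(pk[2] - 1 - 33) %% cfg_f$n_theta
  expect_lte(min(dth, cfg_f$n_theta - dth), 1)
})

test_that("ring normalization gives zero mean, unit variance, affine invariance", {
  pr <- random_polar_pair(8, 64, seed = 3)$a
  for (r in 1:8) {
    expect_equal(mean(pr$values[r, ]), 0, tolerance = 1e-10)
    expect_equal(mean(pr$values[r, ]^2), 1, tolerance = 1e-10)
  }
  raw <- matrix(rnorm(8 * 64), 8, 64)
  mk <- function(v) structure(list(values = v, rings = 2:9, n_theta = 64L),
                              class = "polar_slice")
  n1 <- normalize_rings(mk(raw))
  n2 <- normalize_rings(mk(3.7 * raw + 11))
  expect_equal(n1$values, n2$values, tolerance = 1e-9)
  ## constant ring is flagged invalid
  raw2 <- raw; raw2[3, ] <- 5
  n3 <- normalize_rings(mk(raw2))
  expect_false(attr(n3, "valid")[3])
  expect_true(all(is.na(n3$values[3, ])))
  ## hand-computed z-score for a ring with one outlier
  x <- c(rep(1, 63), 10)
  n4 <- normalize_rings(mk(matrix(rep(x, each = 8), 8, 64, byrow = FALSE)))
  mu <- mean(x); sig <- sqrt(mean((x - mu)^2))
  expect_equal(n4$values[1, ], (x - mu) / sig, tolerance = 1e-12)
})

test_that("FFT in-plane correlation equals brute-force shift correlation", {
  for (seed in 1:5) {
    pp <- random_polar_pair(10, 64, seed = seed)
    ic <- inplane_correlate(pp$a, pp$b)
    brute <- oracle_shift_corr(pp$a$values, pp$b$values)
    expect_equal(ic$curve, brute, tolerance = 1e-10)
  }
})

test_that("self-correlation peaks at gamma 0 with C = 1; shifts are exact", {
  pp <- random_polar_pair(10, 64, seed = 9)$a
  ic <- inplane_correlate(pp, pp)
  expect_equal(ic$gamma_best, 0)
  expect_equal(ic$c_max, 1, tolerance = 1e-6)
  ## a pattern that leads the reference by k samples reports gamma = 2 pi k / n
  k <- 11
  lead <- pp
  lead$values <- pp$values[, 1 + (seq_len(64) - 1 + k) %% 64]
  ic2 <- inplane_correlate(lead, pp)
  expect_equal(ic2$gamma_best, 2 * pi * k / 64)
  expect_equal(ic2$c_max, 1, tolerance = 1e-6)
})

test_that("best_orientation recovers noiseless orientations within the grid step", {
  p <- simulation_params(1e15, 0.1, poisson = FALSE)
  grid <- sample_orientation_grid(0.1)
  set.seed(14)
  for (i in 1:4) {
    e <- random_eulers(1)[1, ]
    pat <- bin2x2(simulate_pattern(model_o, geom_o, p, e))
    cal <- p$fluence * R_E_ANGSTROM^2 * solid_angle_map(geom_o, 2L)
    b <- best_orientation(pat$counts / cal, vol_o, grid, geom_o, 2L, cm_config())
    dev <- rotation_angle_between(euler_to_matrix(b$euler), euler_to_matrix(e))
    expect_lt(dev * pi / 180, 1.5 * 0.1)
  }
  ## degenerate one-direction grid returns that direction
  g1 <- data.frame(alpha = 0.4, beta = 1.0)
  b1 <- best_orientation(matrix(rnorm(256)^2, 16, 16), vol_o, g1, geom_o, 2L,
                         cm_config())
  expect_equal(unname(b1$euler[1:2]), c(0.4, 1.0))
})

test_that("matched patterns out-correlate pure noise", {
  p <- simulation_params(1e15, 0.1, poisson = FALSE)
  grid <- sample_orientation_grid(0.2)
  set.seed(5)
  e <- random_eulers(1)[1, ]
  pat <- bin2x2(simulate_pattern(model_o, geom_o, p, e))
  bm <- best_orientation(pat$counts, vol_o, grid, geom_o, 2L, cm_config())
  noise <- matrix(rnorm(256)^2, 16, 16)
  bn <- best_orientation(noise, vol_o, grid, geom_o, 2L, cm_config())
  expect_gt(bm$c_max, bn$c_max)
})

test_that("merging is a weighted mean: constant fields and idempotency", {
  stack <- array(7, c(16, 16, 1))
  e <- matrix(c(0.3, 0.8, 1.2), 1)
  v1 <- merge_volume(stack, e, geom_o, 2L)
  pop <- !is.na(v1$values)
  expect_gt(sum(pop), 200)
  expect_equal(unname(range(v1$values[pop])), c(7, 7), tolerance = 1e-6)
  ## two identical patterns at the same orientation merge to the same volume
  v2 <- merge_volume(array(7, c(16, 16, 2)), rbind(e, e), geom_o, 2L)
  expect_equal(v2$values, v1$values, tolerance = 1e-12)
})

test_that("merged noiseless volume correlates with the true intensity per shell", {
  p <- simulation_params(1e15, 0.1, poisson = FALSE)
  ds <- make_dataset(model_o, geom_o, p, 150, seed = 6)
  prep <- preprocess_dataset(ds)
  mv <- merge_volume(prep$stack, ds$euler_true, geom_o, 2L)
  cs <- cc_shell(mv, vol_o)
  mid <- cs$value[cs$shell >= 4 & cs$shell <= 13]
  expect_gt(mean(mid, na.rm = TRUE), 0.95)
  ## Friedel symmetry of the merged intensity, statistically
  v <- mv$values
  n <- mv$dim
  flip <- c(1L, n:2L)
  vf <- v[flip, flip, flip]
  ok <- !is.na(v) & !is.na(vf)
  expect_gt(cor(v[ok], vf[ok]), 0.9)
})

test_that("a single CM pass equals per-pattern best_orientation", {
  p <- simulation_params(1e15, 0.1, poisson = FALSE)
  ds <- make_dataset(model_o, geom_o, p, 5, seed = 8)
  prep <- preprocess_dataset(ds)
  st <- run_cm(prep, vol_o, cm_config(delta_beta = 0.2, max_iters = 1),
               refine = FALSE)
  grid <- sample_orientation_grid(0.2)
  cfg <- spirecon:::resolve_cm_config(cm_config(delta_beta = 0.2), geom_o, 2L)
  for (i in 1:5) {
    b <- best_orientation(prep$stack[, , i], vol_o, grid, geom_o, 2L, cfg)
    expect_equal(unname(st$eulers[i, ]), unname(b$euler), tolerance = 1e-12)
  }
})

test_that("the CM trace is non-decreasing within tolerance after iteration 2", {
  p <- simulation_params(1e15, 0.1, poisson = FALSE)
  ds <- make_dataset(model_o, geom_o, p, 150, seed = 10)
  prep <- preprocess_dataset(ds)
  st <- run_cm(prep, vol_o, cm_config(delta_beta = 0.2, max_iters = 6),
               refine = TRUE)
  tr <- st$cc_mean_trace
  if (length(tr) > 2) expect_true(all(diff(tr[-1]) > -1e-3))
  ad <- angular_deviation_report(st$eulers, ds$euler_true)
  expect_lt(ad$median, 5)
})

test_that("cc_map has a dominant peak for matched patterns and none for noise", {
  ## contrast grows with ring count, so this check runs on a 128-px detector
  ## (26 rings); the coarser fixtures leave too high an off-peak baseline
  geom_m <- detector_geometry(1, 128L, 500, 0.128)
  vol_m <- build_reference_volume(model_o, geom_m)
  p <- simulation_params(1e15, 0.1, poisson = FALSE)
  grid <- sample_orientation_grid(0.2)
  set.seed(77)
  e <- random_eulers(1)[1, ]
  pat <- bin2x2(simulate_pattern(model_o, geom_m, p, e))
  cm <- cc_map(pat$counts, vol_m, grid, geom_m, 2L, cm_config())
  best <- attr(cm, "best")
  ## off-peak excludes the peak neighbourhood and its Friedel mate (the
  ## antipodal direction matches almost as well at weak Ewald curvature)
  v <- direction_vectors(cm)
  far <- abs(as.vector(v %*% v[best, ])) < cos(3 * 0.2)
  expect_gte(cm$c[best], 2 * stats::quantile(cm$c[far], 0.99))
  ## the argmax direction is near the true normal
  vtrue <- direction_vectors(data.frame(alpha = e[1], beta = e[2]))
  expect_lt(acos(min(sum(vtrue * v[best, ]), 1)), 2.5 * 0.2)
  noise <- matrix(rnorm(64^2)^2, 64, 64)
  cn <- cc_map(noise, vol_m, grid, geom_m, 2L, cm_config())
  vb <- direction_vectors(cn)[attr(cn, "best"), ]
  farn <- abs(as.vector(direction_vectors(cn) %*% vb)) < cos(3 * 0.2)
  expect_lt(max(cn$c), 2 * stats::quantile(cn$c[farn], 0.99))
  g1 <- data.frame(alpha = 1, beta = 1)
  expect_equal(nrow(cc_map(pat$counts, vol_m, g1, geom_m, 2L, cm_config())), 1)
})
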