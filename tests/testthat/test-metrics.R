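test_that("self-correlation curves are identically 1; negation flips cc_shell", {
  set.seed(1)
  v <- array(runif(16^3), rep(16, 3))
  cs <- cc_shell(v, v, dq = 0.01)
  expect_true(all(abs(cs$value[cs$n >= 2] - 1) < 1e-10))
  cn <- cc_shell(v, -v, dq = 0.01)
  expect_true(all(abs(cn$value[cn$n >= 2] + 1) < 1e-10))
  m <- array(rnorm(16^3), rep(16, 3))
  fc <- fsc(m, m, pitch_A = 2)
  expect_true(all(abs(fc$value - 1) < 1e-10))
  ## missing voxels are excluded pairwise without breaking the curve
  v2 <- v; v2[1:3, , ] <- NA
  cs2 <- cc_shell(v2, v, dq = 0.01)
  expect_true(all(abs(cs2$value[cs2$n >= 2] - 1) < 1e-10))
})

test_that("independent noise volumes decorrelate per shell", {
  set.seed(42)
  a <- array(rnorm(24^3), rep(24, 3))
  b <- array(rnorm(24^3), rep(24, 3))
  cs <- cc_shell(a, b, dq = 0.01)
  sel <- which(cs$n >= 100)
  expect_true(all(abs(cs$value[sel]) < 4 / sqrt(cs$n[sel])))
  expect_lt(mean(abs(cs$value[sel]) * sqrt(cs$n[sel])), 2)
})

test_that("translation degrades FSC until the maps are aligned", {
  set.seed(5)
  m <- phantom_model(20, 10, seed = 5)
  den <- model_to_density(m, spacing = 2, sigma = 2.5, dim = 32)$values
  shifted <- den[c(5:32, 1:4), c(2:32, 1), ]
  ## unaligned: the phase ramp varies across each shell and pulls FSC below 1
  fc_raw <- fsc(den, shifted, pitch_A = 2)
  expect_lt(min(fc_raw$value[fc_raw$shell %in% 5:14]), 0.9)
  ## after integer-translation alignment the curve returns to 1
  fc_al <- fsc(den, align_map(shifted, den), pitch_A = 2)
  expect_true(all(fc_al$value[fc_al$shell <= 14] > 1 - 1e-8))
})

test_that("FSC follows the SNR relation for additive white noise", {
  set.seed(11)
  n <- 32
  ## smooth random signal with a broad spectrum
  sig <- array(rnorm(n^3), rep(n, 3))
  k <- spirecon:::shell_index(n)
  Fs <- fftshift(fft(sig)) * exp(-(k / 10)^2)
  sig <- Re(spirecon:::cifftn(Fs))
  sigma_n <- stats::sd(sig) * 0.5
  ## independent noise on both maps, as for half-map FSC
  a <- sig + array(rnorm(n^3, sd = sigma_n), rep(n, 3))
  b <- sig + array(rnorm(n^3, sd = sigma_n), rep(n, 3))
  fc <- fsc(a, b, pitch_A = 1)
  ## per-shell SNR from the actual signal power spectrum
  FS <- fftshift(fft(sig))
  keep <- k <= n / 2
  pow <- rowsum(Mod(FS[keep])^2, k[keep])
  cnt <- rowsum(rep(1, sum(keep)), k[keep])
  snr <- (pow / cnt) / (sigma_n^2 * length(sig))
  pred <- snr / (snr + 1)
  sel <- which(cnt >= 200 & pred > 0.2 & pred < 0.98)
  expect_true(all(abs(fc$value[sel] - pred[sel]) < 0.05))
})

test_that("PRTF is 1 for identical runs, 0 for opposite phases, ~1/sqrt(n) for random", {
  set.seed(2)
  v <- array(complex(real = rnorm(16^3), imaginary = rnorm(16^3)), rep(16, 3))
  p1 <- prtf(list(v, v, v), dq = 0.01)
  expect_true(all(abs(p1$value - 1) < 1e-10))
  p0 <- prtf(list(v, -v), dq = 0.01)
  expect_true(all(p0$value < 1e-10))
  expect_error(prtf(list(v)))
  nrun <- 6
  runs <- lapply(1:nrun, function(s) {
    set.seed(s + 10)
    array(complex(argument = runif(16^3, 0, 2 * pi), modulus = 1), rep(16, 3))
  })
  pr <- prtf(runs, dq = 0.01)
  sel <- pr$n >= 50
  expect_true(all(pr$value[sel] > 0.5 / sqrt(nrun)))
  expect_true(all(pr$value[sel] < 1.6 / sqrt(nrun)))
})

test_that("angular deviation reporting matches constructed rotations", {
  set.seed(6)
  truth <- random_eulers(300)
  z <- angular_deviation_report(truth, truth)
  expect_true(all(z$degrees < 1e-5))
  expect_equal(z$histogram[1], 300L)
  ## compose each truth with a random 5-degree rotation
  assigned <- t(vapply(seq_len(300), function(i) {
    R <- euler_to_matrix(truth[i, ]) %*% oracle_axis_rot(rnorm(3), 5 * pi / 180)
    matrix_to_euler(R)
  }, numeric(3)))
  a5 <- angular_deviation_report(assigned, truth)
  expect_true(all(abs(a5$degrees - 5) < 1e-6))
  ## all mass lands in the bins bracketing 5 degrees
  expect_true(which.max(a5$histogram) %in% 5:6)
  expect_equal(sum(a5$histogram[5:6]), 300L)
  ## uniform random assignments: mean geodesic angle of uniform SO(3) pairs
  rnd <- random_eulers(300)
  ar <- angular_deviation_report(rnd, truth)
  expect_equal(ar$mean, 126.5, tolerance = 0.04)
})

test_that("threshold crossings interpolate linearly and flag non-crossing curves", {
  cv <- shell_curve(0:4, c(0, 0.1, 0.2, 0.3, 0.4), c(1, 0.9, 0.7, 0.3, 0.1),
                    rep(10, 5))
  res <- resolution_at_threshold(cv, 0.5)
  expect_true(attr(res, "crossed"))
  expect_equal(as.numeric(res), 1 / 0.25)   # crossing halfway between shells 2,3
  flat <- shell_curve(0:4, c(0, 0.1, 0.2, 0.3, 0.4), rep(0.9, 5), rep(10, 5))
  r2 <- resolution_at_threshold(flat, 0.5)
  expect_false(attr(r2, "crossed"))
  expect_equal(as.numeric(r2), 1 / 0.4)
})

test_that("the half-map protocol is reproducible and consistent on clean data", {
  dd <- desk_dataset("tiny", seed = 5)
  ext <- spirecon:::model_extent(dd$model) + 8
  h <- half_fsc_protocol(dd$dataset, dd$truth,
                         cm_config(delta_beta = 0.2, max_iters = 3),
                         phasing_schedule("prior", n_er = 200), ext,
                         prior_volume = dd$pm_volume, seed = 9)
  ## noiseless halves agree closely at low resolution
  expect_true(all(h$fsc$value[1:4] > 0.97))
  expect_gt(mean(h$fsc$value[1:8]), 0.9)
  h2 <- half_fsc_protocol(dd$dataset, dd$truth,
                          cm_config(delta_beta = 0.2, max_iters = 3),
                          phasing_schedule("prior", n_er = 200), ext,
                          prior_volume = dd$pm_volume, seed = 9)
  expect_identical(h$fsc$value, h2$fsc$value)
  ## a two-pattern dataset still runs through the whole protocol
  sub <- dd$dataset
  sub$counts <- sub$counts[, , 1:2, drop = FALSE]
  sub$euler_true <- sub$euler_true[1:2, , drop = FALSE]
  expect_no_error(half_fsc_protocol(sub, dd$truth,
                                    cm_config(delta_beta = 0.3, max_iters = 1),
                                    phasing_schedule("prior", n_er = 50), ext,
                                    prior_volume = dd$pm_volume, seed = 2,
                                    refine = FALSE))
})
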