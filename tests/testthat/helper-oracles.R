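# Independent R-level oracles used across the suite. These deliberately
# re-derive quantities with the most literal formulation available (scalar
# loops, direct sums) so they share no code path with the package internals.

# elementary rotation matrices written out longhand
oracle_rz <- function(a) matrix(c(cos(a), sin(a), 0,
                                  -sin(a), cos(a), 0,
                                  0, 0, 1), 3, 3)
oracle_rx <- function(a) matrix(c(1, 0, 0,
                                  0, cos(a), sin(a),
                                  0, -sin(a), cos(a)), 3, 3)

# rotation about an arbitrary unit axis (Rodrigues)
oracle_axis_rot <- function(u, phi) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
}

# scalar |q| at a detector radius: 2 sin(arctan(rho/D)/2) / lambda
oracle_qmod <- function(rho_m, D_m, lambda_A) {
  2 * sin(0.5 * atan(rho_m / D_m)) / lambda_A
}

# direct Gaussian-atom structure-factor sum, one q at a time
oracle_sf <- function(model, q, sigma = 1) {
  vapply(seq_len(nrow(q)), function(k) {
    env <- exp(-2 * pi^2 * sigma^2 * sum(q[k, ]^2))
    env * sum(model$weight * exp(-2i * pi * (model$xyz %*% q[k, ])))
  }, complex(1))
}

# brute-force shift-and-dot in-plane correlation of two normalized polar
# matrices (rows = rings); returns the full curve over lags 0..n_theta-1
oracle_shift_corr <- function(M, S) {
  nth <- ncol(M)
  vapply(0:(nth - 1), function(lag) {
    idx <- 1 + (seq_len(nth) - 1 + lag) %% nth
    mean(vapply(seq_len(nrow(M)), function(r) sum(M[r, idx] * S[r, ]) / nth,
                numeric(1)))
  }, numeric(1))
}

# explicit double-loop 2x2 block sum
oracle_block_sum <- function(x) {
  n <- nrow(x) / 2
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sum(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  out
}

# normalized polar slice pair (random, valid everywhere) for correlation tests
random_polar_pair <- function(n_r, n_theta, seed) {
  set.seed(seed)
  mk <- function() {
    v <- matrix(rnorm(n_r * n_theta), n_r, n_theta)
    structure(list(values = v, rings = seq_len(n_r) + 1L, n_theta = n_theta),
              class = "polar_slice")
  }
  list(a = normalize_rings(mk()), b = normalize_rings(mk()))
}

# compact blob phantom + density + exact-support setup for phasing tests
phasing_fixture <- function(dim = 32, pitch = 4, sigma = 4, seed = 7) {
  m <- phantom_model(40, 10, seed = seed)
  den <- model_to_density(m, spacing = pitch, sigma = sigma, dim = dim)
  ext <- 2 * sqrt(max(rowSums(center_model(m)$xyz^2))) + 8 * sigma
  sup <- make_support(ext, pitch, dim, margin_factor = 1)
  A <- Mod(spirecon:::cfftn(den$values))
  list(model = m, truth = den$values, support = sup, amplitudes = A,
       phases = Arg(spirecon:::cfftn(den$values)), pitch = pitch)
}
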