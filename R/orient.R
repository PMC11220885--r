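## Correlation-maximization orientation determination.
##
## Patterns and reference slices are compared on a polar grid of concentric
## resolution rings. Each ring is z-scored (zero mean, unit variance) so no
## ring dominates; the Pearson correlation
##   C(gamma) = (1/N_r) sum_r <M(r,.), S(r,. - gamma)> / n_theta
## is evaluated for all in-plane rotations gamma at once with a 1D FFT along
## the azimuth (cross-correlation theorem). The search over slice normals
## (alpha, beta) is exhaustive on a quasi-uniform grid; merging deposits each
## measured pixel onto the 8 neighbouring voxels with trilinear weights.

#' Configuration for the correlation-maximization loop
#'
#' @param delta_beta coarse angular sampling step (rad)
#' @param refine_delta_beta refinement step (rad); refinement searches a
#'   geodesic cap of radius `3 * delta_beta` around each current direction
#' @param r_min,r_max inner/outer resolution rings (binned pixels) used in the
#'   correlation; defaults (computed from the geometry when `NULL`):
#'   `r_min` = binned beam-stop radius + 2, `r_max` = 0.85 x Nyquist ring
#' @param n_theta azimuthal samples (power of two >= 2 pi r_max when `NULL`)
#' @param max_iters maximum assignment/merge iterations
#' @param tol convergence tolerance on the change of mean correlation
#' @return an object of class `cm_config`
#' @export
cm_config <- function(delta_beta = 0.1, refine_delta_beta = 0.02,
                      r_min = NULL, r_max = NULL, n_theta = NULL,
                      max_iters = 20L, tol = 1e-3) {
  stopifnot(delta_beta > 0, delta_beta <= pi / 2, refine_delta_beta > 0)
  structure(list(delta_beta = delta_beta, refine_delta_beta = refine_delta_beta,
                 r_min = r_min, r_max = r_max, n_theta = n_theta,
                 max_iters = as.integer(max_iters), tol = tol),
            class = "cm_config")
}

## fill in geometry-dependent defaults
resolve_cm_config <- function(config, geom, binning, beam_stop_px = 0L) {
  nyq <- geom$n_pixels / binning / 2
  if (is.null(config$r_max)) config$r_max <- floor(0.85 * nyq)
  if (is.null(config$r_min))
    config$r_min <- max(2L, ceiling(beam_stop_px / binning / 2) + 2L)
  stopifnot(config$r_min < config$r_max, config$r_max <= nyq)
  if (is.null(config$n_theta))
    config$n_theta <- max(64L, 2^ceiling(log2(2 * pi * config$r_max)))
  config
}

## Ewald q-vectors of the detector polar grid (theta fastest within each ring)
polar_qpoints <- function(geom, binning, rings, n_theta) {
  p_m <- geom$pixel_um * binning * 1e-6
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  r_m <- rings * p_m
  x <- as.vector(outer(cos(th), r_m))          # theta fastest
  y <- as.vector(outer(sin(th), r_m))
  D <- geom$distance_m
  nrm <- sqrt(x^2 + y^2 + D^2)
  lam <- geom$wavelength_A
  cbind(x / (nrm * lam), y / (nrm * lam), (D / nrm - 1) / lam)
}

#' Extract a Fourier slice from a volume on the binned detector grid
#'
#' The Ewald sphere is rotated forward by the Euler triplet (`R q` per
#' binned pixel) and the volume is sampled there by trilinear interpolation. Out-of-volume or missing voxels give `NA`.
#'
#' @param vol a [fourier_volume()] (intensity view is used for complex input)
#' @param euler orientation `c(alpha, beta, gamma)`
#' @param geom a [detector_geometry()]
#' @param binning detector binning factor
#' @return matrix (binned grid) of interpolated intensities
#' @export
extract_slice <- function(vol, euler, geom, binning = 2L) {
  qm <- ewald_qmap(geom, binning)
  R <- euler_to_matrix(euler)
  pts <- (qm$points %*% t(R)) / vol$dq + (vol$dim / 2 + 1)
  v <- cpp_trilinear_gather(as.vector(volume_intensity(vol)), rep(vol$dim, 3), pts)
  matrix(v, qm$n, qm$n)
}

#' Resample a Cartesian slice onto the polar ring grid
#'
#' Bilinear interpolation onto rings `r_min..r_max` (binned pixels from the
#' beam center) with `n_theta` equally spaced azimuths; masked (`NA`) pixels
#' propagate to the polar samples.
#'
#' @param slice matrix on the binned grid (`NA` = invalid)
#' @param geom a [detector_geometry()]
#' @param binning binning factor of `slice`
#' @param config a resolved [cm_config()] (or list with `r_min`, `r_max`,
#'   `n_theta`)
#' @return an object of class `polar_slice`: list with `values`
#'   (n_r x n_theta), `rings`, `n_theta`
#' @export
cartesian_to_polar <- function(slice, geom, binning, config) {
  nb <- nrow(slice)
  stopifnot(config$r_max <= nb / 2)
  rings <- config$r_min:config$r_max
  ctr <- binned_center(geom, binning) + 1   # 1-based
  th <- 2 * pi * (seq_len(config$n_theta) - 1) / config$n_theta
  px <- as.vector(outer(cos(th), rings)) ; py <- as.vector(outer(sin(th), rings))
  v <- cpp_bilinear_gather(slice, cbind(ctr[1] + px, ctr[2] + py))
  structure(list(values = t(matrix(v, config$n_theta, length(rings))),
                 rings = rings, n_theta = config$n_theta),
            class = "polar_slice")
}

#' Ring-wise z-score normalization of a polar slice
#'
#' Each resolution ring is independently transformed to zero mean and unit
#' (population) variance over its valid samples, so high-intensity
#' low-resolution rings cannot dominate the correlation. Rings with fewer
#' than 2 valid samples or zero variance are flagged invalid (all `NA`).
#'
#' @param polar a `polar_slice`
#' @return the normalized `polar_slice` with attribute `valid` (logical per ring)
#' @export
normalize_rings <- function(polar) {
  v <- polar$values
  nth <- ncol(v)
  mu <- rowMeans(v, na.rm = TRUE)
  cen <- v - mu
  sig <- sqrt(rowMeans(cen^2, na.rm = TRUE))
  nval <- rowSums(!is.na(v))
  valid <- nval >= 2 & is.finite(sig) & sig > 1e-12
  out <- cen / sig
  out[!valid, ] <- NA_real_
  polar$values <- out
  attr(polar, "valid") <- valid
  polar
}

## FFT of a normalized polar slice along theta (NA -> 0); n_r x n_theta complex
polar_fft <- function(polarN) {
  v <- polarN$values
  v[is.na(v)] <- 0
  t(mvfft(t(v)))
}

#' In-plane correlation of two polar slices for all rotations at once
#'
#' Computes `C(gamma) = (1/(N_r n_theta)) sum_r sum_t M(r, t + gamma) S(r, t)`
#' for every azimuthal shift via 1D FFTs, i.e. the Pearson correlation between
#' the pattern and the self-rotated reference slice, averaged over rings.
#'
#' @param pattern_polar,ref_polar `polar_slice` objects on the same ring set
#'   (normalized internally if not already)
#' @param refine parabolic sub-sample refinement of the peak
#' @return list with `gamma_best` (rad), `c_max`, and the full `curve`
#'   (length `n_theta`, value k is gamma = 2 pi (k-1)/n_theta)
#' @export
inplane_correlate <- function(pattern_polar, ref_polar, refine = FALSE) {
  if (is.null(attr(pattern_polar, "valid"))) pattern_polar <- normalize_rings(pattern_polar)
  if (is.null(attr(ref_polar, "valid"))) ref_polar <- normalize_rings(ref_polar)
  stopifnot(identical(pattern_polar$rings, ref_polar$rings))
  both <- attr(pattern_polar, "valid") & attr(ref_polar, "valid")
  if (!any(both)) stop("no common valid rings")
  nth <- pattern_polar$n_theta
  Pf <- polar_fft(pattern_polar)[both, , drop = FALSE]
  Sf <- polar_fft(ref_polar)[both, , drop = FALSE]
  prod <- colSums(Pf * Conj(Sf))
  curve <- Re(fft(prod, inverse = TRUE)) / nth / (sum(both) * nth)
  k <- which.max(curve)
  ## lag k-1 maximizes sum_u M(u + k - 1) S(u); a pattern simulated with
  ## Euler gamma leads the gamma = 0 slice by gamma, so gamma = -lag
  gamma <- wrap_2pi(-2 * pi * (k - 1) / nth)
  if (refine) {
    km <- if (k == 1) nth else k - 1
    kp <- if (k == nth) 1 else k + 1
    y1 <- curve[km]; y2 <- curve[k]; y3 <- curve[kp]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-15) {
      off <- clamp(0.5 * (y1 - y3) / den, -0.5, 0.5)
      gamma <- wrap_2pi(gamma - off * 2 * pi / nth)
    }
  }
  list(gamma_best = gamma, c_max = max(curve), curve = curve)
}

## ---- batched machinery -----------------------------------------------------

## Precompute the FFT'd, ring-normalized reference polar stack for a set of
## directions. Returns conj(FFT) as an array (n_r, n_dir, n_theta) plus the
## per-(ring, dir) validity matrix.
reference_polar_stack <- function(vol, dirs, geom, binning, config,
                                  qpts = NULL) {
  rings <- config$r_min:config$r_max
  n_r <- length(rings); nth <- config$n_theta
  if (is.null(qpts)) qpts <- polar_qpoints(geom, binning, rings, nth)
  vals <- volume_intensity(vol)
  dimv <- rep(vol$dim, 3)
  ctr <- vol$dim / 2 + 1
  n_dir <- nrow(dirs)
  pts <- matrix(0, n_dir * n_r * nth, 3)
  blk <- n_r * nth
  for (d in seq_len(n_dir)) {
    R <- rot_z(dirs$alpha[d]) %*% rot_x(dirs$beta[d])
    pts[((d - 1) * blk + 1):(d * blk), ] <- (qpts %*% t(R)) / vol$dq + ctr
  }
  g <- cpp_trilinear_gather(as.vector(vals), as.integer(dimv), pts)
  ## layout: theta fastest, then ring, then dir -> (n_theta, n_r, n_dir)
  arr <- array(g, c(nth, n_r, n_dir))
  mu <- colMeans(arr, na.rm = TRUE, dims = 1)                 # n_r x n_dir
  cen <- arr - rep(mu, each = nth)
  sig <- sqrt(colMeans(cen^2, na.rm = TRUE, dims = 1))
  nval <- colSums(!is.na(arr), dims = 1)
  valid <- nval >= 2 & is.finite(sig) & sig > 1e-12           # n_r x n_dir
  z <- cen / rep(sig, each = nth)
  z[is.na(z)] <- 0
  z[rep(!valid, each = nth)] <- 0
  ## FFT along theta for every (ring, dir) column at once
  Zf <- mvfft(matrix(z, nth, n_r * n_dir))
  ## store ring-fastest so per-pattern products need no transposition
  list(conj_fft = Conj(aperm(array(Zf, c(nth, n_r, n_dir)), c(2, 1, 3))),
       valid = valid, dirs = dirs, n_r = n_r, n_theta = nth)
}

## Correlate one pattern (normalized polar FFT, n_r x n_theta, + validity)
## against a stack. Returns per-direction max correlation, its gamma, and the
## global best.
correlate_stack <- function(Pf, p_valid, stack, refine_gamma = FALSE) {
  nth <- stack$n_theta; n_r <- stack$n_r
  n_dir <- dim(stack$conj_fft)[3]
  both <- stack$valid & p_valid                               # n_r x n_dir
  ## invalid pattern rings are zero in Pf; invalid ref rings zeroed in the stack
  Z <- stack$conj_fft * as.vector(Pf)                         # recycle over dirs
  S <- colSums(Z, dims = 1)                                   # (n_theta, n_dir)
  curves <- Re(mvfft(matrix(S, nth, n_dir), inverse = TRUE)) / nth
  denom <- pmax(colSums(both), 1L) * nth
  curves <- sweep(curves, 2, denom, `/`)
  k <- max.col(t(curves), ties.method = "first")
  cmax <- curves[cbind(k, seq_len(n_dir))]
  gamma <- wrap_2pi(-2 * pi * (k - 1) / nth)
  if (refine_gamma) {
    km <- ifelse(k == 1, nth, k - 1); kp <- ifelse(k == nth, 1, k + 1)
    y1 <- curves[cbind(km, seq_len(n_dir))]
    y2 <- cmax
    y3 <- curves[cbind(kp, seq_len(n_dir))]
    den <- y1 - 2 * y2 + y3
    off <- ifelse(abs(den) > 1e-15, clamp(0.5 * (y1 - y3) / den, -0.5, 0.5), 0)
    gamma <- wrap_2pi(gamma - off * 2 * pi / nth)
  }
  best <- which.max(cmax)
  list(c_dir = cmax, gamma_dir = gamma, best = best)
}

## pattern polar preparation: normalized polar FFT + validity, for each pattern
prepare_pattern_polars <- function(prep, config) {
  np <- dim(prep$stack)[3]
  lapply(seq_len(np), function(i) {
    sl <- prep$stack[, , i]
    pol <- normalize_rings(cartesian_to_polar(sl, prep$geom, prep$binning, config))
    list(fft = polar_fft(pol), valid = attr(pol, "valid"))   # n_r x n_theta
  })
}

#' Best orientation of one pattern by exhaustive grid search
#'
#' Exhaustive search over the (alpha, beta) grid with the in-plane angle
#' resolved by FFT; ties broken by first occurrence in grid order.
#'
#' @param pattern matrix on the binned grid (`NA` = invalid), or a
#'   `diffraction_pattern` whose `counts` are used
#' @param ref_volume a [fourier_volume()]
#' @param grid an orientation grid (data frame with `alpha`, `beta`)
#' @param geom a [detector_geometry()]
#' @param binning binning factor of the pattern
#' @param config a [cm_config()]
#' @return list with `euler` (best `c(alpha, beta, gamma)`), `c_max`, and
#'   `c_dir` (per-direction maxima, for CC maps)
#' @export
best_orientation <- function(pattern, ref_volume, grid, geom, binning = 2L,
                             config = cm_config()) {
  if (inherits(pattern, "diffraction_pattern")) pattern <- pattern$counts
  config <- resolve_cm_config(config, geom, binning)
  stack <- reference_polar_stack(ref_volume, grid, geom, binning, config)
  pol <- normalize_rings(cartesian_to_polar(pattern, geom, binning, config))
  res <- correlate_stack(polar_fft(pol), attr(pol, "valid"), stack)
  b <- res$best
  list(euler = c(alpha = grid$alpha[b], beta = grid$beta[b],
                 gamma = res$gamma_dir[b]),
       c_max = res$c_dir[b], c_dir = res$c_dir)
}

#' Correlation map over the orientation grid for one pattern
#'
#' The per-direction maxima (over gamma) of the Pearson correlation,
#' suitable for plotting in the (alpha, beta) plane; its argmax is the
#' assigned orientation.
#'
#' @inheritParams best_orientation
#' @return a data frame with `alpha`, `beta`, `c` and attribute `best` (row index)
#' @export
cc_map <- function(pattern, ref_volume, grid, geom, binning = 2L,
                   config = cm_config()) {
  res <- best_orientation(pattern, ref_volume, grid, geom, binning, config)
  structure(data.frame(alpha = grid$alpha, beta = grid$beta, c = res$c_dir),
            best = which.max(res$c_dir))
}

#' Merge oriented patterns into a 3D intensity volume
#'
#' Every measured binned pixel deposits its (calibrated) value at the
#' rotated Ewald coordinate `R q` onto the 8 neighbouring voxels with
#' trilinear weights; voxel intensity is the weighted mean and zero-weight
#' voxels are flagged missing.
#'
#' @param stack nb x nb x n array of calibrated binned patterns (`NA` masked)
#' @param eulers n x 3 matrix of orientations
#' @param geom a [detector_geometry()]
#' @param binning binning factor of the stack
#' @param dim volume side (voxels); default `2 * nb`
#' @param dq voxel pitch (1/A); default from [voxel_dq()]
#' @return an intensity [fourier_volume()] with `weight` and `NA` missing voxels
#' @export
merge_volume <- function(stack, eulers, geom, binning = 2L,
                         dim = NULL, dq = NULL) {
  if (length(base::dim(stack)) == 2) stack <- array(stack, c(base::dim(stack), 1))
  np <- base::dim(stack)[3]
  stopifnot(nrow(eulers) == np)
  dq <- dq %||% voxel_dq(geom, binning, 2L)
  dim <- dim %||% (2L * base::dim(stack)[1])
  qm <- ewald_qmap(geom, binning)
  ctr <- dim / 2 + 1
  acc <- numeric(dim^3); wt <- numeric(dim^3)
  for (i in seq_len(np)) {
    R <- euler_to_matrix(eulers[i, ])
    pts <- (qm$points %*% t(R)) / dq + ctr
    out <- cpp_trilinear_scatter(as.integer(rep(dim, 3)), pts,
                                 as.vector(stack[, , i]))
    acc <- acc + out$sum
    wt <- wt + out$weight
  }
  vals <- ifelse(wt > 0, acc / pmax(wt, .Machine$double.eps), NA_real_)
  fourier_volume(array(vals, rep(dim, 3)), dq, kind = "intensity",
                 weight = array(wt, rep(dim, 3)))
}

#' Random positive starting volume for the classical (non-seeded) method
#'
#' Uniform positive voxels smoothed by a 3-voxel Gaussian and
#' Friedel-symmetrized.
#'
#' @param dim volume side (even)
#' @param dq voxel pitch (1/A)
#' @param seed RNG seed
#' @return an intensity [fourier_volume()]
#' @export
random_volume <- function(dim, dq, seed = 1L) {
  set.seed(seed)
  v <- array(runif(dim^3), rep(dim, 3))
  ## Gaussian smoothing via the centered FFT (sigma = 3 voxels)
  k <- seq_len(dim) - (dim / 2 + 1)
  g <- exp(-2 * pi^2 * 9 * (k / dim)^2)
  G <- outer(outer(g, g), g)
  v <- Re(cifftn(cfftn(v) * G))
  flip <- c(1L, dim:2L)      # index reflection about the centered origin
  v <- v + v[flip, flip, flip]   # Friedel symmetrization I(q) + I(-q)
  v <- v - min(v) + 1e-6
  fourier_volume(v, dq, kind = "intensity")
}

#' Run the correlation-maximization loop
#'
#' Alternates orientation assignment of every pattern against the current
#' volume with re-merging, until the mean best correlation changes by less
#' than `tol` (or `max_iters` is reached); then performs one refinement pass
#' at `refine_delta_beta` restricted to a geodesic cap of radius
#' `3 * delta_beta` around each pattern's current direction (with parabolic
#' gamma refinement), and a final merge.
#'
#' @param prep output of [preprocess_dataset()]
#' @param initial_volume a [fourier_volume()]: the predicted-model reference
#'   ([build_reference_volume()]) or [random_volume()]
#' @param config a [cm_config()]
#' @param refine run the refinement pass
#' @param beam_stop_px native-pixel beam-stop size (for the `r_min` default)
#' @param verbose print per-iteration mean correlation
#' @return an object of class `cm_state`: list with `volume` (merged
#'   intensity), `eulers` (n x 3), `cc` (per-pattern best correlation),
#'   `cc_mean_trace`, `iterations`, `config`
#' @export
run_cm <- function(prep, initial_volume, config = cm_config(), refine = TRUE,
                   beam_stop_px = 0L, verbose = FALSE) {
  geom <- prep$geom; binning <- prep$binning
  config <- resolve_cm_config(config, geom, binning, beam_stop_px)
  rings <- config$r_min:config$r_max
  qpts <- polar_qpoints(geom, binning, rings, config$n_theta)
  pats <- prepare_pattern_polars(prep, config)
  np <- length(pats)
  grid <- sample_orientation_grid(config$delta_beta)
  vol <- initial_volume
  dim_out <- 2L * base::dim(prep$stack)[1]
  dq_out <- voxel_dq(geom, binning, 2L)
  eulers <- matrix(0, np, 3)
  cc <- numeric(np)
  trace <- numeric(0)
  for (it in seq_len(config$max_iters)) {
    stack <- reference_polar_stack(vol, grid, geom, binning, config, qpts)
    for (i in seq_len(np)) {
      r <- correlate_stack(pats[[i]]$fft, pats[[i]]$valid, stack)
      b <- r$best
      eulers[i, ] <- c(grid$alpha[b], grid$beta[b], r$gamma_dir[b])
      cc[i] <- r$c_dir[b]
    }
    cm <- mean(cc)
    if (is.na(cm)) stop("correlation-maximization diverged (CC_mean is NaN)")
    trace <- c(trace, cm)
    if (verbose) message(sprintf("iter %d: CC_mean = %.4f", it, cm))
    vol <- merge_volume(prep$stack, eulers, geom, binning, dim_out, dq_out)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < config$tol) break
  }
  iterations <- length(trace)
  if (refine) {
    cap <- 3 * config$delta_beta
    for (i in seq_len(np)) {
      g <- local_orientation_grid(eulers[i, 1], eulers[i, 2],
                                  config$refine_delta_beta, cap)
      st <- reference_polar_stack(vol, g, geom, binning, config, qpts)
      r <- correlate_stack(pats[[i]]$fft, pats[[i]]$valid, st,
                           refine_gamma = TRUE)
      b <- r$best
      eulers[i, ] <- c(g$alpha[b], g$beta[b], r$gamma_dir[b])
      cc[i] <- r$c_dir[b]
    }
    trace <- c(trace, mean(cc))
    if (verbose) message(sprintf("refine: CC_mean = %.4f", mean(cc)))
    vol <- merge_volume(prep$stack, eulers, geom, binning, dim_out, dq_out)
  }
  structure(list(volume = vol, eulers = eulers, cc = cc,
                 cc_mean_trace = trace, iterations = iterations,
                 refined = refine, config = config),
            class = "cm_state")
}

#' @export
print.cm_state <- function(x, ...) {
  cat(sprintf("<cm_state> %d patterns, %d iterations%s, CC_mean %.4f\n",
              length(x$cc), x$iterations, if (x$refined) " + refinement" else "",
              mean(x$cc)))
  invisible(x)
}
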