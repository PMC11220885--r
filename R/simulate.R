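## Snapshot diffraction-pattern simulation: per-pixel intensity
## I = J * r_e^2 * Omega * |F(R q)|^2 (forward Ewald-sphere rotation), Poisson noise, beam stop, 2x2 binning.

#' Classical electron radius in Angstrom
#' @export
R_E_ANGSTROM <- 2.818e-5

#' Simulation parameters
#'
#' @param photons_per_pulse photons in one XFEL pulse
#' @param focus_um beam focus diameter in micrometres (uniform disc profile)
#' @param seed master seed for the per-pattern Poisson streams
#' @param poisson sample Poisson counts (`FALSE`: return expected intensities)
#' @param beam_stop_px side of the masked central square, in native pixels (even)
#' @return an object of class `simulation_params`; the derived fluence
#'   `J = photons_per_pulse / (pi (focus/2)^2)` is stored in photons per
#'   square Angstrom
#' @export
simulation_params <- function(photons_per_pulse = 1e12, focus_um = 0.1,
                              seed = 1L, poisson = TRUE, beam_stop_px = 0L) {
  stopifnot(photons_per_pulse >= 0, focus_um > 0,
            beam_stop_px >= 0, beam_stop_px %% 2 == 0)
  focus_A <- focus_um * 1e4
  structure(list(photons_per_pulse = photons_per_pulse, focus_um = focus_um,
                 fluence = photons_per_pulse / (pi * (focus_A / 2)^2),
                 seed = as.integer(seed), poisson = poisson,
                 beam_stop_px = as.integer(beam_stop_px)),
            class = "simulation_params")
}

#' Simulate one snapshot diffraction pattern
#'
#' The model (rotated by the Euler triplet) diffracts onto the detector:
#' each pixel receives `J r_e^2 Omega |F(R q)|^2` expected photons, with
#' optional Poisson sampling and a central beam stop.
#'
#' @param model an [atomic_model()] (centered internally)
#' @param geom a [detector_geometry()]
#' @param params a [simulation_params()]
#' @param euler orientation `c(alpha, beta, gamma)` in radians
#' @param sigma Gaussian atomic width (A)
#' @param seed optional seed for this pattern's Poisson draw
#' @return an object of class `diffraction_pattern`: list with `counts`
#'   (matrix, `NA` under the mask), `mask` (TRUE = unmeasured), `euler`,
#'   `binning`
#' @export
simulate_pattern <- function(model, geom, params, euler = c(0, 0, 0),
                             sigma = 1, seed = NULL) {
  model <- center_model(model)
  qm <- ewald_qmap(geom, 1L)
  R <- euler_to_matrix(euler)
  qrot <- qm$points %*% t(R)           # rows are (R q)^T: the Ewald
  ## sphere is rotated forward into the object frame
  F <- cpp_structure_factor(model$xyz, model$weight, qrot, sigma)
  I <- params$fluence * R_E_ANGSTROM^2 * solid_angle_map(geom, 1L) *
    matrix(Mod(F)^2, qm$n, qm$n)
  if (params$poisson) {
    if (!is.null(seed)) set.seed(seed)
    I <- matrix(rpois(length(I), lambda = as.vector(I)), qm$n, qm$n)
  }
  pat <- structure(list(counts = I, mask = matrix(FALSE, qm$n, qm$n),
                        euler = euler, binning = 1L),
                   class = "diffraction_pattern")
  if (params$beam_stop_px > 0) pat <- apply_beam_stop(pat, params$beam_stop_px)
  pat
}

#' @export
print.diffraction_pattern <- function(x, ...) {
  cat(sprintf("<diffraction_pattern> %d x %d (binning %d), %.0f photons, %d masked px\n",
              nrow(x$counts), ncol(x$counts), x$binning,
              sum(x$counts[!x$mask]), sum(x$mask)))
  invisible(x)
}

#' Mask the central beam-stop square of a pattern
#'
#' @param pattern a `diffraction_pattern`
#' @param size_px side of the masked central square (even, in current-grid pixels)
#' @export
apply_beam_stop <- function(pattern, size_px) {
  n <- nrow(pattern$counts)
  stopifnot(size_px >= 0, size_px %% 2 == 0, size_px <= n)
  if (size_px == 0) return(pattern)
  idx <- (n / 2 - size_px / 2 + 1):(n / 2 + size_px / 2)
  pattern$mask[idx, idx] <- TRUE
  pattern$counts[idx, idx] <- NA_real_
  pattern
}

#' 2x2 binning of a diffraction pattern
#'
#' Sums each 2x2 block; an output pixel is masked if any input pixel in its
#' block is masked. Total unmasked photon count is conserved.
#'
#' @param pattern a `diffraction_pattern` with even dimensions
#' @export
bin2x2 <- function(pattern) {
  n <- nrow(pattern$counts)
  stopifnot(n %% 2 == 0, ncol(pattern$counts) %% 2 == 0)
  cs <- pattern$counts
  cs[is.na(cs)] <- 0
  b <- cs[seq(1, n, 2), ] + cs[seq(2, n, 2), ]
  b <- b[, seq(1, n, 2)] + b[, seq(2, n, 2)]
  m <- pattern$mask[seq(1, n, 2), ] | pattern$mask[seq(2, n, 2), ]
  m <- m[, seq(1, n, 2)] | m[, seq(2, n, 2)]
  b[m] <- NA_real_
  pattern$counts <- b
  pattern$mask <- m
  pattern$binning <- pattern$binning * 2L
  pattern
}

#' Simulate a stack of patterns at uniform random orientations
#'
#' Orientations are uniform on SO(3) (alpha, gamma uniform; beta from the
#' arccos rule). Per-pattern Poisson streams are derived from
#' `(seed, pattern index)` so any subset is reproducible.
#'
#' @param model an [atomic_model()]
#' @param geom a [detector_geometry()]
#' @param params a [simulation_params()]
#' @param n_patterns number of patterns
#' @param seed master seed (defaults to `params$seed`)
#' @return an object of class `spi_dataset`: list with `counts`
#'   (n x n x n_patterns array), `mask` (matrix), `euler_true`
#'   (n_patterns x 3), `geom`, `params`
#' @export
make_dataset <- function(model, geom, params, n_patterns, seed = NULL) {
  stopifnot(n_patterns >= 1)
  seed <- as.integer(seed %||% params$seed)
  set.seed(seed)
  eulers <- random_eulers(n_patterns)
  n <- geom$n_pixels
  counts <- array(NA_real_, c(n, n, n_patterns))
  mask <- NULL
  for (i in seq_len(n_patterns)) {
    p <- simulate_pattern(model, geom, params, eulers[i, ],
                          seed = child_seed(seed, i))
    counts[, , i] <- p$counts
    mask <- p$mask
  }
  structure(list(counts = counts, mask = mask, euler_true = eulers,
                 geom = geom, params = params, seed = seed),
            class = "spi_dataset")
}

#' @export
print.spi_dataset <- function(x, ...) {
  cat(sprintf("<spi_dataset> %d patterns of %d x %d px, mean %.0f photons/pattern\n",
              dim(x$counts)[3], dim(x$counts)[1], dim(x$counts)[2],
              mean(apply(x$counts, 3, sum, na.rm = TRUE))))
  invisible(x)
}

#' Preprocess a dataset for orientation determination
#'
#' Bins each pattern 2x2 and divides by the per-pixel factor
#' `J r_e^2 Omega`, so that the working patterns (and any volume merged from
#' them) are on the `|F|^2` scale of the reference volume.
#'
#' @param dataset an `spi_dataset`
#' @param binning binning factor (default 2)
#' @return list with `stack` (nb x nb x n calibrated patterns, `NA` masked),
#'   `mask`, `binning`, `geom`
#' @export
preprocess_dataset <- function(dataset, binning = 2L) {
  geom <- dataset$geom
  n <- geom$n_pixels
  nb <- n / binning
  np <- dim(dataset$counts)[3]
  cal <- dataset$params$fluence * R_E_ANGSTROM^2 *
    solid_angle_map(geom, binning) * binning^0  # Omega already per binned pixel
  stack <- array(NA_real_, c(nb, nb, np))
  maskb <- NULL
  for (i in seq_len(np)) {
    p <- structure(list(counts = dataset$counts[, , i], mask = dataset$mask,
                        euler = dataset$euler_true[i, ], binning = 1L),
                   class = "diffraction_pattern")
    if (binning == 2L) p <- bin2x2(p) else stopifnot(binning == 1L)
    stack[, , i] <- p$counts / cal
    maskb <- p$mask
  }
  list(stack = stack, mask = maskb, binning = as.integer(binning), geom = geom)
}
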