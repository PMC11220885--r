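## Diffraction geometry: Ewald mapping, Euler conventions, orientation sampling.
##
## Conventions used throughout the package:
##  * crystallographic scattering vector, |q| = 2 sin(theta) / lambda (no 2*pi),
##    resolution d = 1/|q|;
##  * pixel coordinates are 0-based with pixel centers at integer indices; the
##    beam center defaults to the geometric detector center (n - 1)/2;
##  * Euler angles follow the intrinsic z-x'-z'' convention,
##    R = Rz(alpha) %*% Rx(beta) %*% Rz(gamma).

#' Square flat-detector geometry for an XFEL snapshot experiment
#'
#' @param wavelength_A X-ray wavelength in Angstrom
#' @param n_pixels detector side length in pixels (even)
#' @param pixel_um pixel pitch in micrometres
#' @param distance_m sample-to-detector distance in metres
#' @param beam_center beam center as 0-based fractional pixel coordinates
#'   (length 2); defaults to the detector center `(n_pixels - 1)/2`
#' @return an object of class `detector_geometry`
#' @export
detector_geometry <- function(wavelength_A = 1, n_pixels = 512L, pixel_um = 300,
                              distance_m = 0.5, beam_center = NULL) {
  stopifnot(wavelength_A > 0, pixel_um > 0, distance_m > 0,
            n_pixels >= 2, n_pixels %% 2 == 0)
  if (is.null(beam_center)) beam_center <- rep((n_pixels - 1) / 2, 2)
  stopifnot(length(beam_center) == 2)
  structure(list(wavelength_A = wavelength_A, n_pixels = as.integer(n_pixels),
                 pixel_um = pixel_um, distance_m = distance_m,
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d x %d px, %g um pitch, D = %g m, lambda = %g A\n",
              x$n_pixels, x$n_pixels, x$pixel_um, x$distance_m, x$wavelength_A))
  cat(sprintf("  edge resolution: %.2f A\n",
              resolution_at_radius(x, x$n_pixels / 2)))
  invisible(x)
}

## beam center on the binned grid (0-based pixel-center coordinates)
binned_center <- function(geom, binning) (geom$beam_center + 0.5) / binning - 0.5

#' Per-pixel scattering vectors on the Ewald sphere
#'
#' Maps every detector pixel to its scattering vector
#' q = (s_hat - z_hat) / lambda, where s_hat is the unit vector from the sample
#' to the pixel center and z_hat points along the incident beam.
#'
#' @param geom a [detector_geometry()]
#' @param binning integer binning factor (1 = native pixels)
#' @return a list with `n` (binned side), matrices `qx`, `qy`, `qz`, `qmod`
#'   (all in reciprocal Angstrom) and `two_theta` (rad), plus the flat
#'   `points` matrix (n^2 x 3, column-major pixel order)
#' @export
ewald_qmap <- function(geom, binning = 1L) {
  nb <- geom$n_pixels / binning
  stopifnot(nb == round(nb))
  p_m <- geom$pixel_um * binning * 1e-6
  ctr <- binned_center(geom, binning)
  off <- seq_len(nb) - 1
  x <- (off - ctr[1]) * p_m              # along rows
  y <- (off - ctr[2]) * p_m              # along columns
  X <- matrix(x, nb, nb)
  Y <- matrix(y, nb, nb, byrow = TRUE)
  D <- geom$distance_m
  nrm <- sqrt(X^2 + Y^2 + D^2)
  lam <- geom$wavelength_A
  qx <- X / (nrm * lam)
  qy <- Y / (nrm * lam)
  qz <- (D / nrm - 1) / lam
  qmod <- sqrt(qx^2 + qy^2 + qz^2)
  list(n = as.integer(nb), qx = qx, qy = qy, qz = qz, qmod = qmod,
       two_theta = acos(D / nrm),
       points = cbind(as.vector(qx), as.vector(qy), as.vector(qz)))
}

#' Per-pixel solid angle of a flat detector
#'
#' Omega = A cos^3(2 theta) / D^2 for a pixel of area A at scattering angle
#' 2 theta on a flat detector at distance D.
#'
#' @inheritParams ewald_qmap
#' @return matrix of solid angles (sr) on the binned grid
#' @export
solid_angle_map <- function(geom, binning = 1L) {
  qm <- ewald_qmap(geom, binning)
  p_m <- geom$pixel_um * binning * 1e-6
  (p_m^2 / geom$distance_m^2) * cos(qm$two_theta)^3
}

#' Resolution at a given detector radius
#'
#' @param geom a [detector_geometry()]
#' @param radius_px radius from the beam center in (native) pixels
#' @return resolution d = lambda / (2 sin theta) in Angstrom; `Inf` at radius 0
#' @export
resolution_at_radius <- function(geom, radius_px) {
  stopifnot(all(radius_px >= 0))
  rho <- radius_px * geom$pixel_um * 1e-6
  theta <- 0.5 * atan2(rho, geom$distance_m)
  d <- geom$wavelength_A / (2 * sin(theta))
  d[radius_px == 0] <- Inf
  d
}

## scattering-vector modulus at a detector radius (binned pixels)
q_at_radius <- function(geom, radius_px, binning = 1L) {
  rho <- radius_px * geom$pixel_um * binning * 1e-6
  theta <- 0.5 * atan2(rho, geom$distance_m)
  2 * sin(theta) / geom$wavelength_A
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' Rotation matrix from intrinsic z-x'-z'' Euler angles
#'
#' `R = Rz(alpha) %*% Rx(beta) %*% Rz(gamma)`: gamma is the in-plane
#' self-rotation about the slice normal, (alpha, beta) orient the normal.
#'
#' @param euler numeric length-3 vector `c(alpha, beta, gamma)` in radians
#' @return a 3x3 rotation matrix
#' @export
euler_to_matrix <- function(euler) {
  stopifnot(length(euler) == 3)
  rot_z(euler[1]) %*% rot_x(euler[2]) %*% rot_z(euler[3])
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]; at the gimbal degeneracy (beta = 0 or pi)
#' gamma is reported as 0 and the full in-plane rotation is folded into alpha.
#'
#' @param R a 3x3 rotation matrix
#' @return numeric `c(alpha, beta, gamma)`, alpha and gamma in `[0, 2*pi)`,
#'   beta in `[0, pi]`
#' @export
matrix_to_euler <- function(R) {
  beta <- acos(clamp(R[3, 3], -1, 1))
  if (sin(beta) > 1e-9) {
    alpha <- atan2(R[1, 3], -R[2, 3])
    gamma <- atan2(R[3, 1], R[3, 2])
  } else {
    ## beta ~ 0 (pi): only alpha + gamma (alpha - gamma) is defined;
    ## fold the whole in-plane rotation into alpha
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  c(alpha = wrap_2pi(alpha), beta = beta, gamma = wrap_2pi(gamma))
}

#' Geodesic angle between two rotations
#'
#' @param R1,R2 orthonormal 3x3 rotation matrices
#' @return the rotation angle of `R1 %*% t(R2)` in degrees, in `[0, 180]`
#' @export
rotation_angle_between <- function(R1, R2) {
  tr <- sum(diag(R1 %*% t(R2)))
  acos(clamp((tr - 1) / 2, -1, 1)) * 180 / pi
}

#' Quasi-uniform sampling of slice-normal directions
#'
#' beta rings at multiples of `delta_beta` up to pi; each ring carries
#' `max(1, round(2 pi sin(beta) / delta_beta))` equally spaced alpha values so
#' that the alpha step times sin(beta) stays close to `delta_beta`. The poles
#' are represented by a single direction each. gamma is not sampled: the
#' in-plane rotation is searched by FFT.
#'
#' @param delta_beta angular step in radians (0 < delta_beta <= pi/2)
#' @return a data frame with columns `alpha`, `beta` and attribute `delta_beta`
#' @export
sample_orientation_grid <- function(delta_beta = 0.1) {
  stopifnot(delta_beta > 0, delta_beta <= pi / 2)
  betas <- seq(0, pi, by = delta_beta)
  alpha <- numeric(0); beta <- numeric(0)
  for (b in betas) {
    na <- max(1L, as.integer(round(2 * pi * sin(b) / delta_beta)))
    alpha <- c(alpha, 2 * pi * (seq_len(na) - 1) / na)
    beta <- c(beta, rep(b, na))
  }
  structure(data.frame(alpha = alpha, beta = beta),
            delta_beta = delta_beta, class = c("orientation_grid", "data.frame"))
}

#' Unit normal-axis vectors of grid directions
#'
#' The slice normal for direction (alpha, beta) is
#' `Rz(alpha) Rx(beta) z_hat = (sin b sin a, -sin b cos a, cos b)`.
#'
#' @param grid a data frame with `alpha`, `beta` columns
#' @return an n x 3 matrix of unit vectors
#' @export
direction_vectors <- function(grid) {
  sb <- sin(grid$beta)
  cbind(sb * sin(grid$alpha), -sb * cos(grid$alpha), cos(grid$beta))
}

#' Local refinement grid around a direction
#'
#' Fine directions (step `delta_beta`) inside a geodesic cap of the given
#' radius around (alpha0, beta0); the cap center itself is always included.
#'
#' @param alpha0,beta0 cap center (rad)
#' @param delta_beta fine angular step (rad)
#' @param radius cap radius (rad)
#' @return a data frame with `alpha`, `beta` columns
#' @export
local_orientation_grid <- function(alpha0, beta0, delta_beta = 0.02, radius = 0.3) {
  b_lo <- max(0, beta0 - radius)
  b_hi <- min(pi, beta0 + radius)
  betas <- unique(clamp(seq(floor(b_lo / delta_beta), ceiling(b_hi / delta_beta)) * delta_beta, 0, pi))
  alpha <- numeric(0); beta <- numeric(0)
  for (b in betas) {
    na <- max(1L, as.integer(round(2 * pi * sin(b) / delta_beta)))
    al <- 2 * pi * (seq_len(na) - 1) / na
    if (na > 1) {
      half <- radius / max(sin(b), 1e-9) + 2 * pi / na
      dal <- abs((al - alpha0 + pi) %% (2 * pi) - pi)
      al <- al[dal <= half]
    }
    alpha <- c(alpha, al)
    beta <- c(beta, rep(b, length(al)))
  }
  g <- data.frame(alpha = alpha, beta = beta)
  v0 <- direction_vectors(data.frame(alpha = alpha0, beta = beta0))
  keep <- direction_vectors(g) %*% t(v0) >= cos(radius) - 1e-12
  g <- g[as.vector(keep), , drop = FALSE]
  g <- rbind(data.frame(alpha = wrap_2pi(alpha0), beta = beta0), g)
  structure(g[!duplicated(round(cbind(g$alpha, g$beta), 10)), , drop = FALSE],
            delta_beta = delta_beta)
}

#' Uniform random orientations on SO(3)
#'
#' alpha and gamma uniform on `[0, 2*pi)`; beta = acos(1 - 2u) so that the
#' slice normal is uniform on the sphere.
#'
#' @param n number of orientations
#' @return an n x 3 matrix with columns alpha, beta, gamma (radians)
#' @export
random_eulers <- function(n) {
  cbind(alpha = runif(n, 0, 2 * pi),
        beta = acos(1 - 2 * runif(n)),
        gamma = runif(n, 0, 2 * pi))
}
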