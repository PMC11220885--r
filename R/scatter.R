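## Atomic model -> electron density -> structure factors -> reference volume.
##
## Atoms are modelled as isotropic 3D Gaussians (default sigma = 1 A) whose
## integrated weight is the electron count, so the analytic transform of one
## atom is w * exp(-2 pi^2 sigma^2 |q|^2) * exp(-2 pi i q.r). Structure factors
## are evaluated by exact direct summation over atoms (compiled kernel).

element_electrons <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                       NA. = 11, MG = 12, CL = 17, K = 19, CA = 20,
                       MN = 25, FE = 26, ZN = 30, SE = 34)

#' Atomic model container
#'
#' @param xyz n x 3 matrix of coordinates in Angstrom
#' @param element character vector of element symbols (recycled)
#' @param weight scattering weights (electron counts); derived from `element`
#'   when `NULL`
#' @return an object of class `atomic_model`
#' @export
atomic_model <- function(xyz, element = "C", weight = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) >= 1, all(is.finite(xyz)))
  element <- rep_len(toupper(element), nrow(xyz))
  if (is.null(weight)) {
    weight <- unname(element_electrons[element])
    if (anyNA(weight)) {
      warning("unknown element(s) assigned carbon weight 6: ",
              paste(unique(element[is.na(weight)]), collapse = ", "))
      weight[is.na(weight)] <- 6
    }
  }
  structure(list(xyz = xyz, element = element, weight = as.numeric(weight)),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %g electrons, Rg = %.2f A\n",
              nrow(x$xyz), sum(x$weight), radius_of_gyration(x)))
  invisible(x)
}

#' Weighted radius of gyration of a model (Angstrom)
#' @param model an [atomic_model()]
#' @export
radius_of_gyration <- function(model) {
  com <- colSums(model$xyz * model$weight) / sum(model$weight)
  d2 <- rowSums(sweep(model$xyz, 2, com)^2)
  sqrt(sum(model$weight * d2) / sum(model$weight))
}

#' Center a model at its weighted center of mass
#' @param model an [atomic_model()]
#' @export
center_model <- function(model) {
  com <- colSums(model$xyz * model$weight) / sum(model$weight)
  model$xyz <- sweep(model$xyz, 2, com)
  model
}

## maximum centered half-extent (A): radius of the bounding sphere about the com
model_extent <- function(model) {
  m <- center_model(model)
  2 * sqrt(max(rowSums(m$xyz^2)))
}

#' Real-space density map container
#'
#' @param values real 3D array (cubic)
#' @param pitch_A voxel pitch in Angstrom
#' @param origin optional 3D offset of voxel (1,1,1) in Angstrom
#' @export
density_map <- function(values, pitch_A, origin = NULL) {
  stopifnot(length(dim(values)) == 3, length(unique(dim(values))) == 1)
  structure(list(values = values, pitch_A = pitch_A,
                 origin = origin %||% rep(-(dim(values)[1] / 2) * pitch_A, 3)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d^3 voxels, pitch %.3g A, sum %.4g\n",
              dim(x$values)[1], x$pitch_A, sum(x$values)))
  invisible(x)
}

#' Rasterize a model into an electron-density map
#'
#' The model is centered at its center of mass and each atom deposits a 3D
#' Gaussian of integrated weight equal to its electron count onto a cubic grid.
#'
#' @param model an [atomic_model()]
#' @param spacing voxel pitch in Angstrom
#' @param sigma Gaussian atomic width in Angstrom
#' @param dim grid side in voxels (even); chosen from the model extent when `NULL`
#' @return a [density_map()]
#' @export
model_to_density <- function(model, spacing = 1, sigma = 1, dim = NULL) {
  stopifnot(spacing > 0, sigma > 0)
  model <- center_model(model)
  if (is.null(dim)) {
    half <- max(sqrt(rowSums(model$xyz^2))) + 6 * sigma
    dim <- 2 * ceiling(half / spacing)
  }
  stopifnot(dim %% 2 == 0)
  n <- as.integer(dim)
  ctr <- n / 2 + 1
  vals <- array(0, c(n, n, n))
  cut <- ceiling(5 * sigma / spacing)
  ax <- (seq_len(n) - ctr) * spacing
  norm <- (2 * pi * sigma^2)^(-3 / 2)
  for (j in seq_len(nrow(model$xyz))) {
    r <- model$xyz[j, ]
    ic <- round(r / spacing) + ctr
    ix <- max(1, ic[1] - cut):min(n, ic[1] + cut)
    iy <- max(1, ic[2] - cut):min(n, ic[2] + cut)
    iz <- max(1, ic[3] - cut):min(n, ic[3] + cut)
    gx <- exp(-(ax[ix] - r[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[iy] - r[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[iz] - r[3])^2 / (2 * sigma^2))
    blk <- outer(outer(gx, gy), gz) * (model$weight[j] * norm)
    vals[ix, iy, iz] <- vals[ix, iy, iz] + blk
  }
  density_map(vals, spacing)
}

#' Structure factors of a model at arbitrary scattering vectors
#'
#' Exact direct summation of the Gaussian-atom transform
#' `F(q) = exp(-2 pi^2 sigma^2 |q|^2) sum_j w_j exp(-2 pi i q.r_j)`.
#'
#' @param model an [atomic_model()]
#' @param q_points m x 3 matrix of scattering vectors (1/A)
#' @param sigma Gaussian atomic width (A)
#' @return complex vector of length m
#' @export
structure_factor <- function(model, q_points, sigma = 1) {
  q_points <- matrix(as.numeric(q_points), ncol = 3)
  stopifnot(all(is.finite(q_points)))
  cpp_structure_factor(model$xyz, model$weight, q_points, sigma)
}

#' Reciprocal-space volume container
#'
#' Holds either a complex reference volume (`values` complex) or a merged /
#' intensity volume (`values` real, `NA` at missing voxels, with a `weight`
#' array). The grid is cubic and centered: voxel `dim/2 + 1` is q = 0 and the
#' voxel pitch is `dq` reciprocal Angstrom.
#'
#' @param values complex or real 3D array
#' @param dq voxel pitch in 1/A
#' @param kind `"reference"` (complex amplitudes) or `"intensity"`
#' @param weight optional accumulation-weight array (merged volumes)
#' @export
fourier_volume <- function(values, dq, kind = c("reference", "intensity"),
                           weight = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(dim(values)) == 3, length(unique(dim(values))) == 1,
            dim(values)[1] %% 2 == 0, dq > 0)
  structure(list(values = values, dq = dq, dim = dim(values)[1],
                 kind = kind, weight = weight),
            class = "fourier_volume")
}

#' @export
print.fourier_volume <- function(x, ...) {
  miss <- if (is.complex(x$values)) 0 else mean(is.na(x$values))
  cat(sprintf("<fourier_volume:%s> %d^3, dq = %.4g 1/A (FOV %.0f A), %.1f%% missing\n",
              x$kind, x$dim, x$dq, 1 / x$dq, 100 * miss))
  invisible(x)
}

#' Intensity (squared modulus) view of a Fourier volume
#' @param vol a [fourier_volume()]
#' @return a real array; complex reference volumes are squared, intensity
#'   volumes are returned as stored
#' @export
volume_intensity <- function(vol) {
  if (is.complex(vol$values)) Mod(vol$values)^2 else vol$values
}

## q-grid voxel pitch implied by a geometry: binned center-pixel pitch / os
voxel_dq <- function(geom, binning = 2L, oversampling = 2L) {
  (geom$pixel_um * binning * 1e-6 / geom$distance_m) / geom$wavelength_A / oversampling
}

#' Reference Fourier volume from an atomic model
#'
#' Evaluates the complex structure factors of the (centered) model on a
#' regular cubic q-grid compatible with the binned detector: voxel pitch
#' `dq = (binned center-pixel q pitch) / oversampling` and side
#' `oversampling * n_pixels / binning`, then applies a Gaussian low-pass
#' (1/e^2 at the pattern edge resolution unless `lowpass_A` is given).
#'
#' @param model an [atomic_model()]
#' @param geom a [detector_geometry()]
#' @param binning detector binning factor used downstream (default 2)
#' @param oversampling linear oversampling of the q grid (default 2)
#' @param lowpass_A low-pass 1/e^2 cutoff resolution in Angstrom (`NULL`:
#'   pattern edge resolution); `NA` disables the filter
#' @param sigma Gaussian atomic width (A)
#' @return a complex [fourier_volume()]
#' @export
build_reference_volume <- function(model, geom, binning = 2L, oversampling = 2L,
                                   lowpass_A = NULL, sigma = 1) {
  model <- center_model(model)
  dq <- voxel_dq(geom, binning, oversampling)
  n <- as.integer(oversampling * geom$n_pixels / binning)
  if (model_extent(model) >= 1 / dq)
    stop("model larger than the real-space field of view 1/dq = ", 1 / dq, " A")
  k <- seq_len(n) - (n / 2 + 1)
  q1 <- k * dq
  grid <- cbind(rep(q1, times = n * n),
                rep(rep(q1, each = n), times = n),
                rep(q1, each = n * n))
  F <- array(cpp_structure_factor(model$xyz, model$weight, grid, sigma), c(n, n, n))
  if (!(length(lowpass_A) == 1 && is.na(lowpass_A))) {
    q_c <- 1 / (lowpass_A %||% resolution_at_radius(geom, geom$n_pixels / 2))
    qmod2 <- array(rowSums(grid^2), c(n, n, n))
    F <- F * exp(-2 * qmod2 / q_c^2)
  }
  fourier_volume(F, dq, kind = "reference")
}

#' Band-limited real-space density of a complex Fourier volume
#'
#' Centered inverse FFT of the complex reference volume; the natural
#' ground-truth map for comparing phase-retrieval output, since it carries
#' exactly the information content of the diffraction data.
#'
#' @param vol a complex [fourier_volume()]
#' @return a [density_map()] with pitch `1 / (dim * dq)` Angstrom
#' @export
volume_to_density <- function(vol) {
  stopifnot(is.complex(vol$values))
  pitch <- 1 / (vol$dim * vol$dq)
  ## scale so that values approximate electrons / A^3: F samples * dq^3 * N
  rho <- Re(cifftn(vol$values)) * vol$dq^3 * length(vol$values)
  density_map(rho, pitch)
}
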