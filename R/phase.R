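## Hybrid HIO-ER phase retrieval of merged 3D amplitudes with a cubic
## real-space support, positivity inside the support, and floating missing
## (beam-stopped / unmeasured) voxels.

#' Phasing schedule
#'
#' Default schedules: random starting phases use 1000 HIO iterations followed
#' by 100 ER iterations (exploratory start); prior phases from a predicted
#' model use 1100 ER iterations only, since HIO's feedback can kick a
#' near-correct iterate into a wrong basin.
#'
#' @param init `"random"` or `"prior"`
#' @param n_hio,n_er iteration counts (defaults depend on `init`)
#' @param beta_fb HIO feedback parameter in (0, 1]
#' @return an object of class `phasing_schedule`: list of
#'   `(algorithm, n_iterations)` segments
#' @export
phasing_schedule <- function(init = c("random", "prior"), n_hio = NULL,
                             n_er = NULL, beta_fb = 0.9) {
  init <- match.arg(init)
  if (is.null(n_hio)) n_hio <- if (init == "random") 1000L else 0L
  if (is.null(n_er)) n_er <- if (init == "random") 100L else 1100L
  stopifnot(n_hio >= 0, n_er >= 0, beta_fb > 0, beta_fb <= 1)
  segments <- list()
  if (n_hio > 0) segments <- c(segments, list(list(algorithm = "HIO", n = as.integer(n_hio))))
  if (n_er > 0) segments <- c(segments, list(list(algorithm = "ER", n = as.integer(n_er))))
  structure(list(segments = segments, beta_fb = beta_fb, init = init),
            class = "phasing_schedule")
}

#' Cubic real-space support mask
#'
#' A centered cube whose side covers the particle extent times a margin.
#'
#' @param extent_A particle extent (A), e.g. the bounding-sphere diameter
#' @param pitch_A real-space voxel pitch (A)
#' @param dim grid side (voxels)
#' @param margin_factor multiplicative margin on the extent
#' @return logical 3D array (TRUE inside the support)
#' @export
make_support <- function(extent_A, pitch_A, dim, margin_factor = 1.2) {
  stopifnot(extent_A > 0, pitch_A > 0)
  side <- ceiling(margin_factor * extent_A / pitch_A)
  if (side > dim) stop("support (", side, " voxels) exceeds the grid (", dim, ")")
  s <- array(FALSE, rep(dim, 3))
  ctr <- dim / 2 + 1
  idx <- (ctr - floor((side - 1) / 2)):(ctr + ceiling((side - 1) / 2))
  s[idx, idx, idx] <- TRUE
  attr(s, "side") <- as.integer(side)
  s
}

## random Friedel-consistent phases: the phase field of the FFT of a real
## white-noise array satisfies phi(-q) = -phi(q) by construction
random_phases <- function(dim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- array(rnorm(dim^3), rep(dim, 3))
  Arg(cfftn(w))
}

#' Iterative HIO / ER phase retrieval
#'
#' Alternates the real-space constraint (density outside the support and
#' negative density inside it is suppressed: set to zero by ER, damped by the
#' HIO feedback) with the Fourier-modulus projection (measured amplitudes are
#' reimposed; modulus and phase of missing voxels float freely). The
#' imaginary part of the real-space iterate is discarded every cycle.
#'
#' @param amplitudes real 3D array of Fourier amplitudes (centered grid);
#'   values under `missing_mask` are ignored
#' @param missing_mask logical array: TRUE where data are unmeasured
#'   (beam-stop cube, unfilled voxels)
#' @param support logical real-space support ([make_support()])
#' @param schedule a [phasing_schedule()]
#' @param init_phases prior phase array (rad), or `NULL` for random phases
#' @param init_complex optional full complex prior volume used to seed the
#'   missing region (defaults to 0 there)
#' @param seed RNG seed for random phases
#' @param pitch_A real-space voxel pitch for the returned map (default 1 voxel)
#' @return list with `density` ([density_map()]), `volume` (final complex
#'   array, measured moduli equal `amplitudes` exactly), `error_trace`
#'   (relative Fourier-modulus residual per iteration)
#' @export
run_phasing <- function(amplitudes, missing_mask, support, schedule,
                        init_phases = NULL, init_complex = NULL, seed = NULL,
                        pitch_A = 1) {
  dims <- dim(amplitudes)
  stopifnot(length(dims) == 3, all(dims == dims[1]),
            identical(dim(missing_mask), dims), identical(dim(support), dims))
  n <- dims[1]
  measured <- !missing_mask
  A <- amplitudes
  A[missing_mask] <- 0
  if (any(A[measured] < 0)) stop("amplitudes must be non-negative")
  if (!any(measured)) stop("empty measured set")
  if (is.null(init_phases)) init_phases <- random_phases(n, seed)
  G <- array(0 + 0i, dims)
  G[measured] <- A[measured] * exp(1i * init_phases[measured])
  if (!is.null(init_complex)) G[missing_mask] <- init_complex[missing_mask]
  rho_prev <- array(0, dims)
  err <- numeric(0)
  amp_norm <- sqrt(sum(A[measured]^2))
  for (seg in schedule$segments) {
    for (it in seq_len(seg$n)) {
      rho <- Re(cifftn(G))
      viol <- (!support) | (support & rho < 0)
      if (seg$algorithm == "ER") {
        rho_new <- rho
        rho_new[viol] <- 0
      } else {
        rho_new <- rho
        rho_new[viol] <- rho_prev[viol] - schedule$beta_fb * rho[viol]
      }
      rho_prev <- rho_new
      Gh <- cfftn(rho_new)
      err <- c(err, sqrt(sum((Mod(Gh)[measured] - A[measured])^2)) / amp_norm)
      Gnew <- Gh
      mod <- Mod(Gh[measured])
      ph <- ifelse(mod > 0, Gh[measured] / mod, 1 + 0i)
      Gnew[measured] <- A[measured] * ph
      G <- Gnew
      if (any(!is.finite(Re(G)))) stop("phase retrieval diverged (NaN)")
    }
  }
  rho <- Re(cifftn(G))
  list(density = density_map(rho, pitch_A), volume = G, error_trace = err)
}

#' Band-limited upsampling of a phased map to fine spacing
#'
#' Extracts the support region, forward transforms it, zero-pads the spectrum
#' to the dimension implied by the target spacing and inverse transforms.
#' Total density is conserved.
#'
#' @param density a [density_map()]
#' @param side side of the centered cube to extract (voxels); default whole grid
#' @param target_A target spacing (A), default 1
#' @return a [density_map()] at the fine spacing
#' @export
upsample_map <- function(density, side = NULL, target_A = 1) {
  n <- dim(density$values)[1]
  side <- side %||% n
  side <- side + side %% 2          # even extraction keeps the origin centered
  stopifnot(target_A <= density$pitch_A, side <= n)
  ctr <- n / 2 + 1
  idx <- (ctr - side / 2):(ctr + side / 2 - 1)
  cube <- density$values[idx, idx, idx]
  s <- length(idx)
  n2 <- 2 * ceiling(s * density$pitch_A / target_A / 2)
  if (n2 <= s) return(density_map(cube, density$pitch_A))
  Fc <- cfftn(cube)
  pad <- array(0 + 0i, rep(n2, 3))
  ctr2 <- n2 / 2 + 1
  ii <- (ctr2 - s / 2):(ctr2 + s / 2 - 1)
  pad[ii, ii, ii] <- Fc
  out <- Re(cifftn(pad)) * (n2^3 / s^3)
  density_map(out, density$pitch_A * s / n2)
}

## the 48 axis permutation / reflection operators applied to a cubic array
apply_cube_op <- function(x, perm, flips) {
  y <- aperm(x, perm)
  n <- dim(y)[1]
  rev_idx <- c(1L, n:2L)   # reflection about the centered origin
  idx <- lapply(flips, function(f) if (f) rev_idx else seq_len(n))
  y[idx[[1]], idx[[2]], idx[[3]]]
}

cube_ops <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  flips <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE), f3 = c(FALSE, TRUE))
  out <- list()
  for (p in perms) for (k in seq_len(nrow(flips)))
    out[[length(out) + 1]] <- list(perm = p, flips = as.logical(flips[k, ]))
  out
}

#' Overall correlation between a recovered and a true map, after alignment
#'
#' Phase retrieval determines the object only up to the trivial ambiguities
#' (translation, inversion through the origin); the recovered map is aligned
#' to the truth over the 48 axis permutation/reflection operators (which
#' include the inversion) combined with the best integer translation
#' (found by FFT cross-correlation) before the Pearson correlation is taken.
#'
#' @param recovered,truth [density_map()]s (or bare arrays) on the same grid
#' @param threshold success threshold on the aligned correlation
#' @param ops subset of alignment operators (default all 48)
#' @return list with `cc`, `success`, `op` (operator index), `shift`
#' @export
phasing_success <- function(recovered, truth, threshold = 0.5, ops = NULL) {
  a <- if (inherits(recovered, "density_map")) recovered$values else recovered
  b <- if (inherits(truth, "density_map")) truth$values else truth
  stopifnot(identical(dim(a), dim(b)))
  ops <- ops %||% cube_ops()
  b0 <- b - mean(b)
  Fb <- Conj(fft(b0))
  nb <- sqrt(sum(b0^2))
  best <- list(cc = -Inf, op = NA_integer_, shift = c(0, 0, 0))
  for (k in seq_along(ops)) {
    a1 <- apply_cube_op(a, ops[[k]]$perm, ops[[k]]$flips)
    a0 <- a1 - mean(a1)
    xc <- Re(fft(fft(a0) * Fb, inverse = TRUE)) / length(a0)
    cc <- max(xc) / (sqrt(sum(a0^2)) * nb)
    if (cc > best$cc) {
      w <- which.max(xc)
      sh <- arrayInd(w, dim(a)) - 1L
      best <- list(cc = cc, op = k, shift = as.integer(sh))
    }
  }
  best$success <- best$cc > threshold
  best
}

#' Aligned copy of a map (best of the 48 ops x integer translation)
#'
#' @param x map to transform, `ref` the target; both [density_map()] or arrays
#' @param ref reference map
#' @return array: `x` transformed into the frame of `ref`
#' @export
align_map <- function(x, ref) {
  a <- if (inherits(x, "density_map")) x$values else x
  res <- phasing_success(x, ref, threshold = -Inf)
  op <- cube_ops()[[res$op]]
  a1 <- apply_cube_op(a, op$perm, op$flips)
  n <- dim(a1)
  ## xc[s] = sum_x a(x + s) b(x), so the aligned map is a(x + shift)
  idx <- lapply(1:3, function(d) 1L + (seq_len(n[d]) - 1L + res$shift[d]) %% n[d])
  a1[idx[[1]], idx[[2]], idx[[3]]]
}
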