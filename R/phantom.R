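## Download-free phantom fixtures: synthetic "protein" models, perturbed
## "predicted" models, and desk-scale datasets sized so the full pipeline
## runs in minutes on one CPU. Phantom atoms all carry carbon weight 6;
## element diversity adds nothing to the algorithms exercised here.

#' Reproducible phantom atomic model
#'
#' Pseudo-random atom clouds with an exactly rescaled radius of gyration.
#' Styles: `"blob"` (isotropic Gaussian cloud), `"chain"` (self-avoiding
#' random walk with 3.8 A steps, then isotropically rescaled), `"two-lobe"`
#' (two displaced clusters, emulating a two-trimer assembly).
#'
#' @param n_atoms number of atoms (>= 1)
#' @param rg_A target radius of gyration (A)
#' @param seed RNG seed
#' @param style one of `"blob"`, `"chain"`, `"two-lobe"`
#' @return an [atomic_model()] centered at the origin
#' @export
phantom_model <- function(n_atoms = 150L, rg_A = 30, seed = 1L,
                          style = c("blob", "chain", "two-lobe")) {
  style <- match.arg(style)
  stopifnot(n_atoms >= 1, rg_A > 0)
  set.seed(seed)
  if (n_atoms == 1) return(atomic_model(matrix(0, 1, 3)))
  xyz <- switch(style,
    blob = matrix(rnorm(3 * n_atoms), ncol = 3),
    chain = {
      pos <- matrix(0, n_atoms, 3)
      for (i in 2:n_atoms) {
        for (try in 1:50) {
          step <- rnorm(3)
          cand <- pos[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
          d2 <- rowSums(sweep(pos[seq_len(i - 2 + 1), , drop = FALSE], 2, cand)^2)
          if (all(d2 > 9) || try == 50) break
        }
        pos[i, ] <- cand
      }
      pos
    },
    `two-lobe` = {
      half <- floor(n_atoms / 2)
      a <- matrix(rnorm(3 * half), ncol = 3)
      b <- matrix(rnorm(3 * (n_atoms - half)), ncol = 3)
      sep <- c(3.5, 0, 0)
      rbind(sweep(a, 2, sep / 2, `+`), sweep(b, 2, sep / 2, `-`))
    })
  m <- atomic_model(xyz)
  m <- center_model(m)
  m$xyz <- m$xyz * (rg_A / radius_of_gyration(m))
  m
}

#' Root-mean-square deviation between two conformations of one model
#'
#' @param a,b [atomic_model()]s with identical atom counts
#' @return RMSD in Angstrom (no superposition)
#' @export
model_rmsd <- function(a, b) {
  stopifnot(nrow(a$xyz) == nrow(b$xyz))
  sqrt(mean(rowSums((a$xyz - b$xyz)^2)))
}

#' Perturb a model to a prescribed RMSD
#'
#' Emulates the discrepancy between a predicted and a true structure.
#' `"jitter"` applies spatially correlated Gaussian displacements (smooth
#' random modes plus a small white component), rescaled so the achieved RMSD
#' matches the target exactly. `"domain-shift"` rigidly translates one half
#' of the atoms (split along the first principal axis), leaving each half's
#' internal geometry untouched.
#'
#' @param model an [atomic_model()]
#' @param target_rmsd_A target RMSD (A)
#' @param seed RNG seed
#' @param mode `"jitter"` or `"domain-shift"`
#' @return the perturbed [atomic_model()]
#' @export
perturb_model <- function(model, target_rmsd_A, seed = 1L,
                          mode = c("jitter", "domain-shift")) {
  mode <- match.arg(mode)
  stopifnot(target_rmsd_A >= 0)
  if (target_rmsd_A == 0) return(model)
  set.seed(seed)
  n <- nrow(model$xyz)
  if (mode == "jitter") {
    L <- max(radius_of_gyration(model), 1)
    disp <- matrix(rnorm(3 * n, sd = 0.3), n, 3)
    for (k in 1:5) {
      ctr <- model$xyz[sample(n, 1), ]
      w <- exp(-rowSums(sweep(model$xyz, 2, ctr)^2) / (2 * L^2))
      disp <- disp + outer(w, rnorm(3))
    }
    disp <- disp * (target_rmsd_A / sqrt(mean(rowSums(disp^2))))
    model$xyz <- model$xyz + disp
  } else {
    pc1 <- svd(scale(model$xyz, scale = FALSE))$v[, 1]
    proj <- model$xyz %*% pc1
    half <- proj > stats::median(proj)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    t_len <- target_rmsd_A / sqrt(mean(half))
    model$xyz[half, ] <- sweep(model$xyz[half, , drop = FALSE], 2, t_len * dir, `+`)
    attr(model, "shifted_half") <- half
  }
  model
}

#' Desk-scale reference datasets
#'
#' Fully seeded end-to-end fixtures: a phantom "true" model, a jittered
#' "predicted" model, a detector geometry scaled so the binned pattern edge
#' sits at working resolution, and a simulated pattern stack.
#'
#' Tiers: `tiny` (32^2 detector, 50 noiseless patterns), `small` (64^2
#' detector, 500 Poisson patterns at a photon budget of roughly 2000
#' photons/pattern), `medium` (128^2 detector, 2000 Poisson patterns).
#' `fluence_scale` multiplies the pulse energy for fluence sweeps.
#'
#' @param name `"tiny"`, `"small"` or `"medium"`
#' @param seed master seed
#' @param noise override the tier's Poisson default (`TRUE`/`FALSE`)
#' @param fluence_scale multiplier on the tier's photons per pulse
#' @param n_patterns override the tier's pattern count
#' @param pm_rmsd_A RMSD of the jittered "predicted" model (default 6 A,
#'   about a fifth of the phantom radius of gyration)
#' @return list with `model`, `pm_model`, `geom`, `params`, `dataset`,
#'   `truth` (complex reference volume of the true model), `pm_volume`
#'   (complex reference volume of the predicted model), `name`
#' @export
desk_dataset <- function(name = c("tiny", "small", "medium"), seed = 1L,
                         noise = NULL, fluence_scale = 1, n_patterns = NULL,
                         pm_rmsd_A = 6) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = list(n_px = 32L, n_pat = 50L, poisson = FALSE, jp = 5e15),
    small = list(n_px = 64L, n_pat = 500L, poisson = TRUE, jp = 5e15),
    medium = list(n_px = 128L, n_pat = 2000L, poisson = TRUE, jp = 5e15))
  if (!is.null(noise)) cfg$poisson <- noise
  if (!is.null(n_patterns)) cfg$n_pat <- as.integer(n_patterns)
  ## 500 um pixels at 0.128 m: binned pixel subtends 1/128 rad, so the q-grid
  ## field of view is 256 A -- comfortably oversampling a 30 A-Rg phantom
  geom <- detector_geometry(wavelength_A = 1, n_pixels = cfg$n_px,
                            pixel_um = 500, distance_m = 0.128)
  model <- phantom_model(150L, 30, seed = child_seed(seed, 91))
  pm <- perturb_model(model, pm_rmsd_A, seed = child_seed(seed, 92))
  params <- simulation_params(photons_per_pulse = cfg$jp * fluence_scale,
                              focus_um = 0.1, seed = seed,
                              poisson = cfg$poisson)
  ds <- make_dataset(model, geom, params, cfg$n_pat, seed = seed)
  truth <- build_reference_volume(model, geom)
  pm_vol <- build_reference_volume(pm, geom)
  list(model = model, pm_model = pm, geom = geom, params = params,
       dataset = ds, truth = truth, pm_volume = pm_vol, name = name)
}
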