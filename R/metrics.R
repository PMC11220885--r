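## Reconstruction-quality metrics: CC shell, FSC, half-map FSC protocol,
## PRTF, angular deviation, with threshold-based resolution read-outs.

#' Shell-curve container
#'
#' @param shell integer shell index (voxel radius)
#' @param q shell center |q| (1/A)
#' @param value per-shell correlation / transfer value
#' @param n voxels per shell
#' @return a `shell_curve` data frame
#' @export
shell_curve <- function(shell, q, value, n) {
  structure(data.frame(shell = shell, q = q, value = value, n = n),
            class = c("shell_curve", "data.frame"))
}

#' Resolution at the first threshold crossing of a shell curve
#'
#' Scans from low q and linearly interpolates the first downward crossing of
#' the threshold; curves that never cross report the band-limit resolution
#' with attribute `crossed = FALSE`.
#'
#' @param curve a [shell_curve()]
#' @param threshold crossing level (e.g. 0.5, 0.143, `exp(-1)`)
#' @return resolution in Angstrom (`1/q` at the crossing)
#' @export
resolution_at_threshold <- function(curve, threshold = 0.5) {
  ok <- is.finite(curve$value) & curve$q > 0
  cv <- curve[ok, ]
  if (nrow(cv) == 0) return(structure(NA_real_, crossed = FALSE))
  below <- which(cv$value < threshold)
  below <- below[below > 1]
  if (length(below) == 0)
    return(structure(1 / max(cv$q), crossed = FALSE))
  i <- below[1]
  q1 <- cv$q[i - 1]; q2 <- cv$q[i]
  v1 <- cv$value[i - 1]; v2 <- cv$value[i]
  qc <- q1 + (threshold - v1) * (q2 - q1) / (v2 - v1)
  structure(1 / qc, crossed = TRUE)
}

## shell-wise grouping helper: sums of x per shell (x real vector)
shell_sums <- function(x, sh) {
  as.vector(rowsum(x, sh, reorder = TRUE))
}

#' Per-shell Pearson correlation of two intensity volumes
#'
#' Shells are 1-voxel wide in |q|; voxels missing (NA) in either volume are
#' excluded pairwise. Empty shells are flagged with `NA`.
#'
#' @param volA,volB [fourier_volume()]s (or bare arrays) on the same grid
#' @param dq voxel pitch (taken from `volA` if it is a `fourier_volume`)
#' @return a [shell_curve()]
#' @export
cc_shell <- function(volA, volB, dq = NULL) {
  a <- if (inherits(volA, "fourier_volume")) volume_intensity(volA) else volA
  b <- if (inherits(volB, "fourier_volume")) volume_intensity(volB) else volB
  dq <- dq %||% (if (inherits(volA, "fourier_volume")) volA$dq else 1)
  stopifnot(identical(dim(a), dim(b)))
  n <- dim(a)[1]
  sh <- shell_index(n)
  ok <- !is.na(a) & !is.na(b) & sh <= n / 2
  shv <- sh[ok]; av <- a[ok]; bv <- b[ok]
  cnt <- shell_sums(rep(1, length(shv)), shv)
  shells <- sort(unique(shv))
  sa <- shell_sums(av, shv); sb <- shell_sums(bv, shv)
  saa <- shell_sums(av^2, shv); sbb <- shell_sums(bv^2, shv)
  sab <- shell_sums(av * bv, shv)
  num <- sab - sa * sb / cnt
  den <- sqrt(pmax(saa - sa^2 / cnt, 0) * pmax(sbb - sb^2 / cnt, 0))
  val <- ifelse(cnt >= 2 & den > 0, num / den, NA_real_)
  all_sh <- 0:(n / 2)
  full <- rep(NA_real_, length(all_sh)); nfull <- rep(0L, length(all_sh))
  full[match(shells, all_sh)] <- val
  nfull[match(shells, all_sh)] <- cnt
  shell_curve(all_sh, all_sh * dq, full, nfull)
}

#' Fourier shell correlation between two real-space maps
#'
#' `FSC(s) = |sum F_A conj(F_B)| / sqrt(sum |F_A|^2 sum |F_B|^2)` per 1-voxel
#' shell. Conventional thresholds: 0.5 against an independent truth, 0.143
#' between half-maps.
#'
#' @param mapA,mapB [density_map()]s (or arrays) on the same grid
#' @param pitch_A voxel pitch (A), taken from `mapA` when possible
#' @return a [shell_curve()] with q in 1/A
#' @export
fsc <- function(mapA, mapB, pitch_A = NULL) {
  a <- if (inherits(mapA, "density_map")) mapA$values else mapA
  b <- if (inherits(mapB, "density_map")) mapB$values else mapB
  pitch_A <- pitch_A %||% (if (inherits(mapA, "density_map")) mapA$pitch_A else 1)
  stopifnot(identical(dim(a), dim(b)))
  n <- dim(a)[1]
  FA <- fftshift(fft(a)); FB <- fftshift(fft(b))
  sh <- shell_index(n)
  keep <- sh <= n / 2
  shv <- sh[keep]
  cross <- FA[keep] * Conj(FB[keep])
  re <- shell_sums(Re(cross), shv); im <- shell_sums(Im(cross), shv)
  pa <- shell_sums(Mod(FA[keep])^2, shv); pb <- shell_sums(Mod(FB[keep])^2, shv)
  cnt <- shell_sums(rep(1, length(shv)), shv)
  val <- sqrt(re^2 + im^2) / sqrt(pmax(pa * pb, .Machine$double.xmin))
  shells <- sort(unique(shv))
  dq <- 1 / (n * pitch_A)
  shell_curve(shells, shells * dq, val, cnt)
}

#' Phase retrieval transfer function across independent reconstructions
#'
#' Per voxel the unit phasors `F/|F|` are averaged over runs; the shell mean
#' of the averaged-phasor magnitude is the PRTF. Resolution is conventionally
#' read at the `1/e` crossing.
#'
#' @param volumes list of >= 2 aligned complex Fourier volumes (arrays or
#'   `fourier_volume`s, centered grids)
#' @param dq voxel pitch (1/A)
#' @return a [shell_curve()]
#' @export
prtf <- function(volumes, dq = NULL) {
  stopifnot(length(volumes) >= 2)
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "fourier_volume")) v$values else v)
  dq <- dq %||% (if (inherits(volumes[[1]], "fourier_volume")) volumes[[1]]$dq else 1)
  n <- dim(arrs[[1]])[1]
  acc <- array(0 + 0i, dim(arrs[[1]]))
  for (a in arrs) {
    m <- Mod(a)
    acc <- acc + ifelse(m > 0, a / m, 0 + 0i)
  }
  pv <- Mod(acc) / length(arrs)
  sh <- shell_index(n)
  keep <- sh <= n / 2
  shv <- sh[keep]
  val <- shell_sums(pv[keep], shv) / shell_sums(rep(1, sum(keep)), shv)
  shells <- sort(unique(shv))
  shell_curve(shells, shells * dq, val,
              as.vector(table(shv)))
}

#' Angular deviations between assigned and true orientations
#'
#' @param assigned,truth n x 3 Euler matrices (alpha, beta, gamma in rad)
#' @return list with `degrees` (per pattern geodesic angle), `histogram`
#'   (counts in 1-degree bins 0..180), `median`, `mean`
#' @export
angular_deviation_report <- function(assigned, truth) {
  assigned <- matrix(assigned, ncol = 3)
  truth <- matrix(truth, ncol = 3)
  stopifnot(nrow(assigned) == nrow(truth))
  deg <- vapply(seq_len(nrow(assigned)), function(i) {
    rotation_angle_between(euler_to_matrix(assigned[i, ]),
                           euler_to_matrix(truth[i, ]))
  }, numeric(1))
  h <- tabulate(pmin(floor(deg), 180) + 1L, nbins = 181L)  # 1-degree bins
  list(degrees = deg, histogram = h, median = stats::median(deg),
       mean = mean(deg))
}

#' Half-map FSC protocol
#'
#' Splits the dataset randomly into two halves, reconstructs each half
#' independently (orientation determination from the same starting reference,
#' then phase retrieval), aligns the two maps and returns their FSC; the
#' resolution is conventionally read at 0.143.
#'
#' @param dataset an `spi_dataset`
#' @param reference starting [fourier_volume()] for the CM loop
#' @param config a [cm_config()]
#' @param schedule a [phasing_schedule()]
#' @param support_extent_A support cube extent passed to [make_support()]
#' @param prior_volume optional complex volume supplying prior phases
#' @param seed seed for the split and for random phases
#' @param refine run the CM refinement pass on each half
#' @return list with `fsc` ([shell_curve()]), `resolution_A` (at 0.143),
#'   `maps`, `states`
#' @export
half_fsc_protocol <- function(dataset, reference, config, schedule,
                              support_extent_A, prior_volume = NULL,
                              seed = 1L, refine = TRUE) {
  np <- dim(dataset$counts)[3]
  stopifnot(np >= 2)
  set.seed(seed)
  idx <- sample(np)
  halves <- list(idx[seq_len(floor(np / 2))], idx[(floor(np / 2) + 1):np])
  maps <- list(); states <- list()
  for (h in 1:2) {
    sub <- dataset
    sub$counts <- dataset$counts[, , halves[[h]], drop = FALSE]
    sub$euler_true <- dataset$euler_true[halves[[h]], , drop = FALSE]
    prep <- preprocess_dataset(sub)
    st <- run_cm(prep, reference, config, refine = refine,
                 beam_stop_px = dataset$params$beam_stop_px)
    vol <- st$volume
    amps <- sqrt(pmax(volume_intensity(vol), 0))
    missing <- is.na(volume_intensity(vol))
    amps[missing] <- 0
    pitch <- 1 / (vol$dim * vol$dq)
    sup <- make_support(support_extent_A, pitch, vol$dim)
    ph <- if (!is.null(prior_volume)) Arg(prior_volume$values) else NULL
    res <- run_phasing(amps, missing, sup, schedule, init_phases = ph,
                       seed = child_seed(seed, h), pitch_A = pitch)
    maps[[h]] <- res$density
    states[[h]] <- st
  }
  m2 <- align_map(maps[[2]], maps[[1]])
  curve <- fsc(maps[[1]]$values, m2, pitch_A = maps[[1]]$pitch_A)
  list(fsc = curve, resolution_A = resolution_at_threshold(curve, 0.143),
       maps = maps, states = states)
}
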