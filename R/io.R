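## Readers/writers and configuration: PDB/mmCIF models (via bio3d), a
## minimal MRC2014 (mode 2, float32) map writer/reader, YAML run configs.

#' Read an atomic model from PDB or mmCIF
#'
#' Element symbols are mapped to electron counts; waters are skipped by
#' default and the first model of multi-model files is used.
#'
#' @param path file path (`.pdb`, `.ent`, `.cif`)
#' @param include_waters keep water molecules
#' @return an [atomic_model()]
#' @export
read_model <- function(path, include_waters = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path, multi = FALSE)
         else bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  if (!include_waters) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after filtering: ", path)
  elem <- toupper(trimws(at$elesy %||% at$elety))
  ## fall back to the first letter of the atom name when the element field is blank
  blank <- is.na(elem) | elem == ""
  elem[blank] <- substr(gsub("[0-9]", "", toupper(at$elety[blank])), 1, 1)
  atomic_model(cbind(at$x, at$y, at$z), element = elem)
}

#' Write a map or volume as an MRC2014 file (mode 2, float32)
#'
#' Axis order is X fastest, Z slowest (MAPC/MAPR/MAPS = 1/2/3); the voxel
#' pitch is recorded in the cell dimensions.
#'
#' @param x a [density_map()], [fourier_volume()] (intensity written) or array
#' @param path output path
#' @param pitch voxel pitch recorded in the header (A per voxel); inferred
#'   from `x` when possible
#' @export
write_mrc <- function(x, path, pitch = NULL) {
  if (inherits(x, "density_map")) { vals <- x$values; pitch <- pitch %||% x$pitch_A }
  else if (inherits(x, "fourier_volume")) { vals <- volume_intensity(x); pitch <- pitch %||% x$dq }
  else vals <- x
  pitch <- pitch %||% 1
  vals[is.na(vals)] <- 0
  d <- dim(vals)
  stopifnot(length(d) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                     # NX NY NZ
  wi(2)                     # MODE 2 = float32
  wi(c(0, 0, 0))            # NXSTART..
  wi(d)                     # MX MY MZ
  wf(d * pitch)             # CELLA
  wf(c(90, 90, 90))         # CELLB
  wi(c(1, 2, 3))            # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1)                     # ISPG
  wi(0)                     # NSYMBT
  writeBin(raw(100), con)   # EXTRA
  wf(c(0, 0, 0))            # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vals))
  wi(0)                     # NLABL
  writeBin(raw(800), con)   # labels
  wf(as.vector(vals))
  invisible(path)
}

#' Read an MRC map written by [write_mrc()]
#'
#' @param path file path
#' @return a [density_map()] (pitch from the header cell)
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only MRC mode 2 (float32) is supported")
  ri(3); mx <- ri(3)
  cella <- rf(3); rf(3)
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L))) stop("unsupported axis order")
  seek(con, 1024)
  vals <- rf(prod(d))
  density_map(array(vals, d), pitch_A = cella[1] / d[1])
}

config_schema <- list(
  geometry = c("wavelength_A", "n_pixels", "pixel_um", "distance_m", "beam_center"),
  simulation = c("photons_per_pulse", "focus_um", "poisson", "beam_stop_px",
                 "n_patterns"),
  cm = c("delta_beta", "refine_delta_beta", "r_min", "r_max", "n_theta",
         "max_iters", "tol", "reference", "random_init"),
  phasing = c("init", "n_hio", "n_er", "beta_fb", "support_extent_A",
              "margin_factor"),
  metrics = c("thresholds"),
  seed = NULL, output = NULL, model = NULL)

#' Read and validate a YAML run configuration
#'
#' Unknown sections or keys are rejected by name.
#'
#' @param path YAML file path
#' @return the validated configuration list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in names(cfg)) {
    if (!sec %in% names(config_schema))
      stop("unknown config section: '", sec, "'")
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    extra <- setdiff(names(cfg[[sec]]), allowed)
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
  }
  required <- c("geometry")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) stop("missing config section(s): ", paste(miss, collapse = ", "))
  cfg
}

#' Geometry from a config list
#' @param cfg a validated configuration ([read_run_config()])
#' @export
config_geometry <- function(cfg) {
  g <- cfg$geometry
  detector_geometry(wavelength_A = g$wavelength_A %||% 1,
                    n_pixels = g$n_pixels %||% 512L,
                    pixel_um = g$pixel_um %||% 300,
                    distance_m = g$distance_m %||% 0.5,
                    beam_center = g$beam_center)
}

#' Provenance record for a pipeline run
#'
#' @param cfg configuration list
#' @param seed effective seed
#' @param path output JSON path
#' @export
write_provenance <- function(cfg, seed, path) {
  txt <- paste(deparse(cfg), collapse = "")
  ## small rolling hash; enough to detect config drift between runs
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 131 + v) %% 2^31
  prov <- list(
    config_hash = sprintf("%08x", h),
    config = cfg, seed = seed,
    package_version = as.character(utils::packageVersion("spirecon")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
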