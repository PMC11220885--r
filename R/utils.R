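## small numerical helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Swap array halves so the centered origin moves to index 1 (and back)
#'
#' For even-sided arrays the operation is its own inverse, which is the only
#' case used internally (all grids in this package have even sides).
#'
#' @param x a vector, matrix or array with even extents
#' @return an object of the same shape with halves swapped along every axis
#' @export
fftshift <- function(x) {
  d <- dim(x) %||% length(x)
  idx <- lapply(d, function(n) {
    h <- floor(n / 2)
    c((h + 1):n, seq_len(h))
  })
  if (is.null(dim(x))) return(x[idx[[1]]])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## centered n-dimensional FFT pair: origin at index dim/2 + 1 on both sides
cfftn <- function(x) fftshift(fft(fftshift(x)))

cifftn <- function(x) fftshift(fft(fftshift(x), inverse = TRUE)) / length(x)

ifftn <- function(x) fft(x, inverse = TRUE) / length(x)

## integer shell index (radius in voxels, rounded) about the centered origin
shell_index <- function(dim) {
  ax <- seq_len(dim) - (dim / 2 + 1)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  array(as.integer(round(sqrt(r2))), dim = c(dim, dim, dim))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

wrap_2pi <- function(x) x %% (2 * pi)

## deterministic per-stream child seed below 2^31
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(k)) %% 2147483629) + 1L
}
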