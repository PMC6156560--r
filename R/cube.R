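#' Hyperspectral absorbance cubes
#'
#' An `ir_cube` holds a rows x cols x channels absorbance array together with
#' its wavenumber axis (cm^-1, ascending, constant spacing), a logical tissue
#' mask and the projected pixel size in micrometres.  High-definition FT-IR
#' imaging uses ~1.1 um pixels; the standard-definition grid (~5.5 um) is
#' obtained from it by 5x binning, see [bin_cube()].
#'
#' @param data numeric array, rows x cols x channels, finite everywhere.
#' @param wavenumbers numeric vector of channel wavenumbers in cm^-1,
#'   strictly increasing with constant spacing; length must equal
#'   `dim(data)[3]`.
#' @param mask logical matrix (rows x cols), `TRUE` on tissue.  Defaults to
#'   all-tissue.
#' @param pixel_size projected pixel size in micrometres (> 0).
#' @return An object of class `ir_cube`.
#' @examples
#' cube <- ir_cube(array(0, c(2, 2, 3)), c(1000, 1004, 1008))
#' cube_spacing(cube)
#' @export
ir_cube <- function(data, wavenumbers, mask = NULL, pixel_size = 1.1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x channels)")
  d <- dim(data)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != d[3L])
    stop("length(wavenumbers) [", length(wavenumbers),
         "] does not match channel count [", d[3L], "]")
  if (length(wavenumbers) > 1L) {
    dw <- diff(wavenumbers)
    if (any(dw <= 0)) stop("`wavenumbers` must be strictly increasing")
    if (max(dw) - min(dw) > 1e-6 * mean(dw))
      stop("`wavenumbers` must be evenly spaced")
  }
  if (!all(is.finite(data))) stop("`data` must be finite everywhere")
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), d[1:2]))
    stop("`mask` shape must equal the spatial dimensions of `data`")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(data = data, wavenumbers = wavenumbers, mask = mask,
                 pixel_size = as.numeric(pixel_size)),
            class = "ir_cube")
}

#' Default wavenumber axis
#'
#' The conventional transmission FT-IR acquisition range, 900 to 3900 cm^-1
#' at a spectral resolution of 4 cm^-1 (751 channels).  Spacing is
#' configurable because instruments may store interpolated 2 cm^-1 grids.
#'
#' @param lo,hi axis end points in cm^-1.
#' @param by channel spacing in cm^-1.
#' @return numeric vector of wavenumbers.
#' @export
wn_axis <- function(lo = 900, hi = 3900, by = 4) {
  if (by <= 0 || hi <= lo) stop("invalid axis specification")
  seq(lo, hi, by = by)
}

#' @export
print.ir_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ir_cube> %d x %d pixels, %d channels (%g-%g cm-1, step %g)\n",
              d[1], d[2], d[3], min(x$wavenumbers), max(x$wavenumbers),
              cube_spacing(x)))
  cat(sprintf("  pixel size %.2f um; %d/%d tissue pixels\n",
              x$pixel_size, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
summary.ir_cube <- function(object, ...) {
  print(object)
  cat(sprintf("  absorbance range [%.4g, %.4g], mean %.4g on tissue\n",
              min(object$data), max(object$data),
              mean(cube_matrix(object, tissue_only = TRUE))))
  invisible(object)
}

#' Channel spacing of a cube axis
#' @param cube an `ir_cube`.
#' @return spacing in cm^-1 (0 for a single-channel cube).
#' @export
cube_spacing <- function(cube) {
  wn <- cube$wavenumbers
  if (length(wn) < 2L) return(0)
  mean(diff(wn))
}

n_channels <- function(cube) dim(cube$data)[3L]

#' Flatten a cube to a pixels x channels matrix
#'
#' Pixels are taken in column-major (R array) order so that
#' [matrix_to_cube()] restores them losslessly.
#'
#' @param cube an `ir_cube`.
#' @param tissue_only if `TRUE`, return only rows for mask pixels.
#' @return numeric matrix, pixels x channels.
#' @export
cube_matrix <- function(cube, tissue_only = FALSE) {
  d <- dim(cube$data)
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])
  if (tissue_only) m <- m[as.vector(cube$mask), , drop = FALSE]
  m
}

#' Rebuild a cube from a pixels x channels matrix
#'
#' Inverse of [cube_matrix()].  When `tissue_only` rows are supplied, the
#' remaining pixels are copied from `template`.
#'
#' @param m pixels x channels matrix.
#' @param template `ir_cube` supplying geometry, axis, mask, pixel size.
#' @param tissue_only whether `m` holds only the tissue rows.
#' @return an `ir_cube`.
#' @export
matrix_to_cube <- function(m, template, tissue_only = FALSE) {
  d <- dim(template$data)
  if (tissue_only) {
    full <- matrix(template$data, d[1L] * d[2L], d[3L])
    full[as.vector(template$mask), ] <- m
    m <- full
  }
  ir_cube(array(m, d), template$wavenumbers, template$mask,
          template$pixel_size)
}

#' Nearest channel index for a wavenumber
#'
#' Ties between two equally near channels resolve toward the lower index.
#'
#' @param cube an `ir_cube`.
#' @param wavenumber target in cm^-1; must lie within the axis range.
#' @return integer channel index.
#' @export
band_index <- function(cube, wavenumber) {
  wn <- cube$wavenumbers
  if (wavenumber < min(wn) || wavenumber > max(wn))
    stop("wavenumber ", wavenumber, " outside axis range [",
         min(wn), ", ", max(wn), "]")
  dist <- abs(wn - wavenumber)
  which(dist <= min(dist) + 1e-12)[1L]
}

#' Extract a single-band image
#'
#' Returns the 2-D image of the channel nearest to the requested wavenumber,
#' e.g. the amide I band at 1650 cm^-1 or the N-H/O-H stretch at 3300 cm^-1
#' used for spatial-denoising evaluation.
#'
#' @inheritParams band_index
#' @return numeric matrix (rows x cols).
#' @export
band_image <- function(cube, wavenumber) {
  cube$data[, , band_index(cube, wavenumber)]
}

#' Spatially bin a cube
#'
#' Block-averages `factor` x `factor` pixel blocks, emulating a larger
#' projected pixel size (5x binning of a 1.1 um grid yields the 5.5 um
#' standard-definition grid).  Trailing rows/columns that do not fill a
#' block are trimmed.  The output mask is `TRUE` where at least half of the
#' block is tissue; the pixel size is multiplied by `factor`.
#'
#' @param cube an `ir_cube`.
#' @param factor positive integer binning factor.
#' @return a binned `ir_cube`.
#' @export
bin_cube <- function(cube, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(cube)
  d <- dim(cube$data)
  r2 <- d[1L] %/% factor
  c2 <- d[2L] %/% factor
  if (r2 < 1L || c2 < 1L) stop("binning factor larger than the image")
  x <- cube$data[seq_len(r2 * factor), seq_len(c2 * factor), , drop = FALSE]
  x <- block_mean3(x, factor)
  mk <- cube$mask[seq_len(r2 * factor), seq_len(c2 * factor), drop = FALSE]
  mfrac <- block_mean3(array(as.numeric(mk), c(dim(mk), 1L)), factor)[, , 1L]
  ir_cube(x, cube$wavenumbers, mfrac >= 0.5, cube$pixel_size * factor)
}

# mean over f x f blocks of a (f*r2) x (f*c2) x n array
block_mean3 <- function(x, f) {
  d <- dim(x)
  r2 <- d[1L] %/% f
  c2 <- d[2L] %/% f
  y <- colMeans(array(x, c(f, r2, d[2L] * d[3L])), dims = 1L)  # r2 x c x n
  y <- aperm(array(y, c(r2, d[2L], d[3L])), c(2L, 1L, 3L))     # c x r2 x n
  y <- colMeans(array(y, c(f, c2, r2 * d[3L])), dims = 1L)     # c2 x r2 x n
  aperm(array(y, c(c2, r2, d[3L])), c(2L, 1L, 3L))
}

# run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# counter-based fan-out of a master seed into per-stage seeds (< 2^31)
derive_seed <- function(seed, counter) {
  (as.double(seed) * 48271 + 97 * as.double(counter) + 11) %% 2147483647
}
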