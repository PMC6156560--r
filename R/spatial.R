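#' Kernel specification for spatial filters
#'
#' @param kind `"mean"`, `"wmean"`, `"gauss"` or `"median"`.
#' @param size odd kernel side length in pixels (>= 3).
#' @param sigma Gaussian SD in pixels (`gauss` only; defaults to `size/5`).
#' @param weights `size x size` nonnegative weight matrix (`wmean` only).
#'   The default is the classic center-weighted 3 x 3 binomial kernel
#'   `[[1,2,1],[2,4,2],[1,2,1]]/16`.  Weights are normalized to sum to 1.
#' @return list of class `ir_kernel`.
#' @export
kernel_spec <- function(kind = c("mean", "wmean", "gauss", "median"),
                        size = 3, sigma = NULL, weights = NULL) {
  kind <- match.arg(kind)
  if (size %% 2 != 1 || size < 3) stop("`size` must be an odd integer >= 3")
  if (kind == "gauss" && is.null(sigma)) sigma <- size / 5
  if (kind == "wmean") {
    if (is.null(weights))
      weights <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16
    if (!all(dim(weights) == c(size, size)))
      stop("`weights` must be a ", size, " x ", size, " matrix")
    if (any(weights < 0)) stop("`weights` must be nonnegative")
    weights <- weights / sum(weights)
  }
  structure(list(kind = kind, size = as.integer(size), sigma = sigma,
                 weights = weights), class = "ir_kernel")
}

kernel_weights <- function(spec) {
  switch(spec$kind,
    mean  = matrix(1 / spec$size^2, spec$size, spec$size),
    wmean = spec$weights,
    gauss = {
      r <- (spec$size - 1L) %/% 2L
      w <- outer(exp(-0.5 * ((-r):r / spec$sigma)^2),
                 exp(-0.5 * ((-r):r / spec$sigma)^2))
      w / sum(w)
    },
    stop("no static weights for kind `", spec$kind, "`"))
}

# reflect-pad a matrix by `r` pixels on every side (whole-sample reflection)
reflect_pad <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  if (r >= nr || r >= nc) stop("kernel larger than the image")
  ri <- c((r + 1L):2L, seq_len(nr), (nr - 1L):(nr - r))
  ci <- c((r + 1L):2L, seq_len(nc), (nc - 1L):(nc - r))
  img[ri, ci, drop = FALSE]
}

#' Masked 2-D kernel filtering
#'
#' Applies a mean, weighted-mean, Gaussian or median filter to a band
#' image.  Boundaries are reflect-padded.  When a tissue mask is given,
#' off-mask pixels are excluded from every neighborhood (weights are
#' renormalized over the on-mask members; the median is taken over on-mask
#' members only) and off-mask pixels pass through unchanged, so empty
#' space never influences tissue values.
#'
#' @param image 2-D numeric matrix.
#' @param spec an [kernel_spec()].
#' @param mask optional logical matrix of the same shape; default all-on.
#' @return filtered matrix.
#' @export
kernel_filter <- function(image, spec, mask = NULL) {
  stopifnot(inherits(spec, "ir_kernel"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  r <- (spec$size - 1L) %/% 2L
  pim <- reflect_pad(image, r)
  pmk <- reflect_pad(mask * 1, r)
  nr <- nrow(image); nc <- ncol(image)
  if (spec$kind == "median") {
    vals <- matrix(NA_real_, nr * nc, spec$size^2)
    col <- 0L
    for (dx in 0:(spec$size - 1L)) for (dy in 0:(spec$size - 1L)) {
      col <- col + 1L
      v <- pim[dy + seq_len(nr), dx + seq_len(nc)]
      m <- pmk[dy + seq_len(nr), dx + seq_len(nc)]
      v[m == 0] <- NA_real_
      vals[, col] <- v
    }
    out <- matrix(apply(vals, 1L, stats::median, na.rm = TRUE), nr, nc)
  } else {
    w <- kernel_weights(spec)
    num <- matrix(0, nr, nc)
    den <- matrix(0, nr, nc)
    for (dx in 0:(spec$size - 1L)) for (dy in 0:(spec$size - 1L)) {
      wk <- w[dy + 1L, dx + 1L]
      m <- pmk[dy + seq_len(nr), dx + seq_len(nc)]
      num <- num + wk * pim[dy + seq_len(nr), dx + seq_len(nc)] * m
      den <- den + wk * m
    }
    den[den <= 0] <- NA_real_
    out <- num / den
  }
  out[!mask] <- image[!mask]
  out[is.na(out)] <- image[is.na(out)]
  out
}

# Extrapolate tissue values into the empty surround by Gaussian-weighted
# averaging of on-mask pixels (feathering), so that global transforms see
# no cliff at the core boundary.  The fill depends only on mask geometry
# and tissue values, so off-mask data never influence on-mask results.
feather_fill <- function(image, mask, sigma = 4) {
  if (all(mask)) return(image)
  Kr <- reflect_conv_mat(nrow(image), gauss_kernel_1d(sigma))
  Kc <- reflect_conv_mat(ncol(image), gauss_kernel_1d(sigma))
  mk <- mask * 1
  den <- Kr %*% mk %*% t(Kc)
  num <- Kr %*% (image * mk) %*% t(Kc)
  fill <- ifelse(den > 1e-6, num / den, mean(image[mask]))
  out <- image
  out[!mask] <- fill[!mask]
  out
}

#' Radial 2-D Fourier low-pass filtering
#'
#' 2-D DFT of the band image, isotropic (radial) low-pass at
#' `cutoff_fraction` of the Nyquist frequency, optional raised-cosine
#' taper, inverse transform, real part.  When a mask is given, off-mask
#' pixels are replaced by a feathered extrapolation of nearby tissue
#' values before the transform (so empty space neither influences tissue
#' values nor presents a cliff that would ring) and restored afterwards.
#'
#' @param image 2-D numeric matrix.
#' @param cutoff_fraction pass-band radius as a fraction of Nyquist, (0, 1].
#' @param taper `"none"` or `"cosine"` (roll-off from half the cutoff).
#' @param mask optional logical tissue mask.
#' @return filtered matrix.
#' @export
ft2d_denoise <- function(image, cutoff_fraction = 0.5,
                         taper = c("none", "cosine"), mask = NULL) {
  taper <- match.arg(taper)
  if (cutoff_fraction <= 0) stop("`cutoff_fraction` must be positive")
  work <- image
  if (!is.null(mask) && !all(mask)) work <- feather_fill(image, mask)
  nr <- nrow(work); nc <- ncol(work)
  fr <- pmin(0:(nr - 1L), nr - 0:(nr - 1L)) / (nr / 2)
  fc <- pmin(0:(nc - 1L), nc - 0:(nc - 1L)) / (nc / 2)
  # corner frequencies have radius up to sqrt(2); cap at 1 so that
  # cutoff_fraction = 1 is an all-pass (identity)
  rho <- pmin(sqrt(outer(fr^2, fc^2, `+`)), 1)
  w <- (rho <= cutoff_fraction) * 1
  if (taper == "cosine") {
    lo <- cutoff_fraction / 2
    ramp <- rho > lo & rho <= cutoff_fraction
    w[ramp] <- 0.5 * (1 + cos(pi * (rho[ramp] - lo) / (cutoff_fraction - lo)))
  }
  out <- Re(stats::fft(stats::fft(work) * w, inverse = TRUE)) / (nr * nc)
  if (!is.null(mask) && !all(mask)) out[!mask] <- image[!mask]
  out
}

#' 2-D wavelet shrinkage of a band image
#'
#' Reflect-pads the image to a square power-of-two side, applies multilevel
#' 2-D orthogonal wavelet shrinkage ([wavelet_shrink_image()]) and crops.
#' Mask handling is as in [ft2d_denoise()].
#'
#' @param image 2-D numeric matrix.
#' @inheritParams wavelet_shrink_rows
#' @param mask optional logical tissue mask.
#' @return denoised matrix.
#' @export
wavelet2d_denoise <- function(image, family = "sym6", level = 3,
                              rule = c("soft", "hard"), threshold_scale = 1,
                              mask = NULL) {
  rule <- match.arg(rule)
  work <- image
  if (!is.null(mask) && !all(mask)) work <- feather_fill(image, mask)
  nr <- nrow(work); nc <- ncol(work)
  n <- 2^ceiling(log2(max(nr, nc)))
  wp <- work[sym_pad_index(nr, n), sym_pad_index(nc, n), drop = FALSE]
  den <- wavelet_shrink_image(wp, family, level, rule, threshold_scale)
  out <- den[seq_len(nr), seq_len(nc), drop = FALSE]
  if (!is.null(mask) && !all(mask)) out[!mask] <- image[!mask]
  out
}

#' Channel-wise spatial denoising of a cube
#'
#' Applies a 2-D denoiser to the selected band images of a cube (default:
#' every channel), leaving all other channels untouched.  The evaluation
#' workflow typically targets the 3300 and 1650 cm^-1 bands.
#'
#' @param cube an [ir_cube()].
#' @param method `"mean"`, `"wmean"`, `"gauss"`, `"median"`, `"ft2d"` or
#'   `"wavelet2d"`.
#' @param bands numeric wavenumbers to process, or `"all"`.
#' @param ... parameters passed to the underlying filter
#'   ([kernel_spec()] fields, `cutoff_fraction`/`taper`, or the wavelet
#'   arguments).
#' @return `ir_cube` with the selected channels denoised.
#' @export
spatial_denoise_cube <- function(cube,
                                 method = c("mean", "wmean", "gauss",
                                            "median", "ft2d", "wavelet2d"),
                                 bands = "all", ...) {
  method <- match.arg(method)
  if (identical(bands, "all")) {
    chan <- seq_len(n_channels(cube))
  } else {
    chan <- unique(vapply(bands, function(b) band_index(cube, b), 1L))
  }
  out <- cube$data
  args <- list(...)
  for (k in chan) {
    img <- cube$data[, , k]
    out[, , k] <- switch(method,
      ft2d = do.call(ft2d_denoise,
                     c(list(image = img, mask = cube$mask), args)),
      wavelet2d = do.call(wavelet2d_denoise,
                          c(list(image = img, mask = cube$mask), args)),
      kernel_filter(img, do.call(kernel_spec, c(list(kind = method), args)),
                    cube$mask))
  }
  ir_cube(out, cube$wavenumbers, cube$mask, cube$pixel_size)
}
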