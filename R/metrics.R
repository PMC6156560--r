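# Metric conventions: per-pixel quantities are aggregated by the arithmetic
# mean over tissue pixels; infinities (perfect reconstruction, zero noise)
# are reported as the capped sentinel 1e12 so tables stay finite.
IR_INF_SENTINEL <- 1e12

#' Spectral signal-to-noise ratio
#'
#' The signal value is fixed at unity; the noise of each tissue pixel is
#' the standard deviation, after slope correction, of its spectrum in the
#' absorption-free 2150-2080 cm^-1 window: a straight line is fitted to
#' the window and the residual SD (RSS / (m - 2) degrees of freedom) is the
#' noise estimate, so SNR = 1 / noise.  A pixel whose window is exactly
#' linear gets the 1e12 sentinel.
#'
#' @param cube an [ir_cube()] whose axis covers 2080-2150 cm^-1.
#' @param window wavenumber bounds of the noise window (cm^-1).
#' @return list with `per_pixel` (matrix, `NA` off-mask) and `mean`
#'   (arithmetic mean over tissue pixels).
#' @export
snr <- function(cube, window = c(2080, 2150)) {
  wn <- cube$wavenumbers
  idx <- which(wn >= window[1L] & wn <= window[2L])
  if (length(idx) < 3L)
    stop("noise window [", window[1L], ", ", window[2L],
         "] not covered by the axis")
  x <- cube_matrix(cube)[, idx, drop = FALSE]
  X <- cbind(1, wn[idx])
  Q <- diag(length(idx)) - X %*% solve(crossprod(X), t(X))
  rss <- rowSums((x %*% Q)^2)
  noise <- sqrt(rss / (length(idx) - 2L))
  s <- ifelse(noise > 0, 1 / noise, Inf)
  s <- pmin(s, IR_INF_SENTINEL)
  per_pixel <- matrix(ifelse(as.vector(cube$mask), s, NA_real_),
                      nrow(cube$mask), ncol(cube$mask))
  list(per_pixel = per_pixel, mean = mean(s[as.vector(cube$mask)]))
}

#' SNR gain of a denoised cube
#'
#' Ratio of the tissue-mean [snr()] of the denoised cube to that of the
#' noisy input.
#'
#' @param denoised,noisy congruent [ir_cube()]s.
#' @return dimensionless gain (> 1 means improvement).
#' @export
snr_gain <- function(denoised, noisy) {
  sn <- snr(noisy)$mean
  if (sn == 0) stop("noisy cube has zero SNR")
  snr(denoised)$mean / sn
}

#' Signal distortion
#'
#' Percentage of the total signal lost by denoising: per tissue pixel, sum
#' |denoised - clean| over only those channels where that difference
#' exceeds the magnitude of the noise actually added to the clean signal,
#' divided by the pixel's total absolute clean signal, times 100.  Under
#' the strict inequality, the noisy cube itself scores exactly 0 (each
#' difference equals |added noise|), as does a perfect reconstruction.
#'
#' @param denoised,clean congruent [ir_cube()]s.
#' @param added_noise array of the realized noise (`noisy - clean`).
#' @return list with `per_pixel` (matrix, `NA` off-mask) and `mean`.
#' @export
signal_distortion <- function(denoised, clean, added_noise) {
  if (is.null(added_noise)) stop("`added_noise` is required")
  d <- dim(clean$data)
  np <- d[1L] * d[2L]
  diff <- matrix(abs(denoised$data - clean$data), np, d[3L])
  eps <- matrix(abs(added_noise), np, d[3L])
  cl <- matrix(abs(clean$data), np, d[3L])
  # strict inequality with a float guard: when denoised == noisy the
  # recomputed |d - c| differs from |eps| only by rounding and must not
  # count as distortion
  num <- rowSums(diff * (diff > eps * (1 + 1e-9) + 1e-12))
  den <- rowSums(cl)
  sd_pct <- ifelse(den > 0, 100 * num / den, 0)
  keep <- as.vector(clean$mask)
  per_pixel <- matrix(ifelse(keep, sd_pct, NA_real_), d[1L], d[2L])
  list(per_pixel = per_pixel, mean = mean(sd_pct[keep]))
}

#' Linear peak signal-to-noise ratio and its gain
#'
#' `psnr_lin(x, ref) = max(ref)^2 / MSE(x, ref)` over the tissue mask (no
#' decibel transform).  The gain of a denoised band image is
#' `psnr_lin(denoised) / psnr_lin(noisy)`, which algebraically equals
#' `MSE(noisy) / MSE(denoised)`.  A perfect reconstruction yields the 1e12
#' sentinel.
#'
#' @param image,reference congruent band images (matrices).
#' @param mask optional logical tissue mask.
#' @return `psnr_lin` returns the linear pSNR.
#' @export
psnr_lin <- function(image, reference, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(reference), ncol(reference))
  peak <- max(reference[mask])
  if (diff(range(reference[mask])) == 0)
    stop("reference band has zero variance")
  mse <- mean((image[mask] - reference[mask])^2)
  if (mse == 0) return(IR_INF_SENTINEL)
  min(peak^2 / mse, IR_INF_SENTINEL)
}

#' @rdname psnr_lin
#' @param denoised,noisy,clean congruent band images; `clean` is the
#'   reference.
#' @export
psnr_gain <- function(denoised, noisy, clean, mask = NULL) {
  pd <- psnr_lin(denoised, clean, mask)
  pn <- psnr_lin(noisy, clean, mask)
  if (pd >= IR_INF_SENTINEL) return(IR_INF_SENTINEL)
  min(pd / pn, IR_INF_SENTINEL)
}

#' Structural similarity index
#'
#' Standard SSIM: local means, variances and covariance from an 11 x 11
#' Gaussian window (sigma 1.5, reflect boundary), stability constants
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with `K1 = 0.01`, `K2 = 0.03` and
#' dynamic range `L = max(reference) - min(reference)` (over the mask when
#' given).  The luminance-contrast-structure product is averaged over the
#' tissue mask.  `ssim_index(x, x)` is exactly 1.
#'
#' @param image,reference congruent matrices.
#' @param mask optional logical tissue mask.
#' @param k1,k2 stability constants.
#' @param win_size,win_sigma Gaussian window size (odd) and SD in pixels.
#' @return SSIM in [-1, 1].
#' @export
ssim_index <- function(image, reference, mask = NULL, k1 = 0.01, k2 = 0.03,
                       win_size = 11, win_sigma = 1.5) {
  if (!all(dim(image) == dim(reference)))
    stop("`image` and `reference` must be congruent")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(reference), ncol(reference))
  L <- diff(range(reference[mask]))
  if (L == 0) stop("reference has zero dynamic range")
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  r <- (win_size - 1L) %/% 2L
  g <- gauss_kernel_1d(win_sigma, r)
  smooth <- function(m) {
    p <- reflect_pad(m, r)
    nr <- nrow(m); nc <- ncol(m)
    acc <- matrix(0, nr, nc)
    for (dy in 0:(win_size - 1L)) {
      row <- matrix(0, nr, nc)
      for (dx in 0:(win_size - 1L))
        row <- row + g[dx + 1L] * p[dy + seq_len(nr), dx + seq_len(nc)]
      acc <- acc + g[dy + 1L] * row
    }
    acc
  }
  mu1 <- smooth(image); mu2 <- smooth(reference)
  s11 <- smooth(image^2) - mu1^2
  s22 <- smooth(reference^2) - mu2^2
  s12 <- smooth(image * reference) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(map[mask])
}

#' Pearson correlation between two spectra
#'
#' Thin wrapper around [stats::cor()] with an explicit zero-variance error,
#' used to guard wavelet-parameter selection against oversmoothing
#' (flattened spectra correlate poorly with the clean reference).
#'
#' @param spectrum_a,spectrum_b equal-length numeric vectors.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(spectrum_a, spectrum_b) {
  if (length(spectrum_a) != length(spectrum_b))
    stop("spectra must have equal length")
  if (stats::sd(spectrum_a) == 0 || stats::sd(spectrum_b) == 0)
    stop("zero-variance spectrum")
  stats::cor(spectrum_a, spectrum_b)
}

# tissue-mean of per-pixel Pearson correlations between two cubes
mean_pixel_pearson <- function(a, b, mask) {
  ma <- matrix(a, length(mask), length(a) / length(mask))[as.vector(mask), ,
                                                          drop = FALSE]
  mb <- matrix(b, length(mask), length(b) / length(mask))[as.vector(mask), ,
                                                          drop = FALSE]
  ca <- ma - rowMeans(ma)
  cb <- mb - rowMeans(mb)
  num <- rowSums(ca * cb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  mean(ifelse(den > 0, num / den, NA_real_), na.rm = TRUE)
}

#' Score one denoising result
#'
#' Produces benchmark rows for a denoised cube against its simulation
#' bundle: one "spectral" row (SNR gain, signal distortion, tissue-mean
#' per-pixel Pearson r against the clean spectra) plus one row per
#' evaluation band (linear pSNR gain and SSIM of the band image).
#'
#' @param bundle an `ir_bundle` from [add_noise()] / [simulate_bundles()].
#' @param denoised the denoised [ir_cube()].
#' @param method,params method label and parameter string recorded in the
#'   output.
#' @param bands wavenumbers (cm^-1) of the band images to score.
#' @return data.frame of `MetricsRecord` rows.
#' @export
evaluate_denoised <- function(bundle, denoised, method = "unknown",
                              params = "", bands = c(1650, 3300)) {
  mask <- bundle$clean$mask
  rec <- data.frame(
    method = method, params = params,
    noise_level = bundle$level$index, scans = bundle$level$scans,
    pixel_size = bundle$clean$pixel_size, band = "spectral",
    snr_gain = snr_gain(denoised, bundle$noisy),
    sd_percent = signal_distortion(denoised, bundle$clean,
                                   bundle$added_noise)$mean,
    pearson_r = mean_pixel_pearson(denoised$data, bundle$clean$data, mask),
    psnr_gain = NA_real_, ssim = NA_real_,
    stringsAsFactors = FALSE)
  for (b in bands) {
    db <- band_image(denoised, b)
    nb <- band_image(bundle$noisy, b)
    cb <- band_image(bundle$clean, b)
    rec <- rbind(rec, data.frame(
      method = method, params = params,
      noise_level = bundle$level$index, scans = bundle$level$scans,
      pixel_size = bundle$clean$pixel_size, band = as.character(b),
      snr_gain = NA_real_, sd_percent = NA_real_, pearson_r = NA_real_,
      psnr_gain = psnr_gain(db, nb, cb, mask),
      ssim = ssim_index(db, cb, mask),
      stringsAsFactors = FALSE))
  }
  rec
}
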