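#' Savitzky-Golay smoothing along the spectral axis
#'
#' Replaces each pixel's spectrum by sliding local least-squares polynomial
#' fits of the given degree over an odd window.  Interior channels use the
#' central fit; the first and last half-windows use the corresponding
#' off-center fits of the terminal window (polynomial extrapolation), as in
#' the standard Savitzky-Golay treatment.  A polynomial of degree <= `degree`
#' is reproduced exactly.
#'
#' @param cube an [ir_cube()].
#' @param degree polynomial degree (3 in the reference benchmark).
#' @param window odd window length, > `degree` and < channel count
#'   (15 or 17 in the reference benchmark).
#' @return smoothed `ir_cube` on the same axis.
#' @export
savgol_denoise <- function(cube, degree = 3, window = 17) {
  n <- n_channels(cube)
  if (window %% 2 != 1) stop("`window` must be odd")
  if (window <= degree) stop("`window` must exceed `degree`")
  if (window >= n) stop("`window` must be smaller than the channel count")
  A <- savgol_operator(n, degree, window)
  m <- cube_matrix(cube) %*% t(A)
  matrix_to_cube(m, cube)
}

# full n x n linear operator of Savitzky-Golay filtering (banded interior,
# polynomial-fit rows at the edges), built from signal::sgolay
savgol_operator <- function(n, degree, window) {
  FF <- unclass(signal::sgolay(p = degree, n = window))
  h <- (window - 1L) %/% 2L
  A <- matrix(0, n, n)
  center <- FF[h + 1L, ]
  for (i in (h + 1L):(n - h))
    A[i, (i - h):(i + h)] <- center
  A[seq_len(h), seq_len(window)] <- FF[seq_len(h), ]
  A[(n - h + 1L):n, (n - window + 1L):n] <- FF[(h + 2L):window, ]
  A
}

#' Fourier low-pass filtering along the spectral axis
#'
#' Per spectrum: discrete Fourier transform, zeroing (or cosine roll-off) of
#' coefficients above `cutoff_fraction` of the Nyquist frequency, inverse
#' transform, real part.  `cutoff_fraction = 1` with no apodization is the
#' identity.  The filter is a circulant linear operator, precomputed once
#' per (length, cutoff, apodization) and applied by matrix multiplication.
#'
#' @param cube an [ir_cube()].
#' @param cutoff_fraction pass-band edge as a fraction of Nyquist, in (0, 1].
#' @param apodization `"none"` (brick wall) or `"cosine"` (raised-cosine
#'   roll-off from half the cutoff to the cutoff, limiting ringing).
#' @return filtered `ir_cube`.
#' @export
ft_spectral_denoise <- function(cube, cutoff_fraction = 0.5,
                                apodization = c("none", "cosine")) {
  apodization <- match.arg(apodization)
  if (cutoff_fraction <= 0) stop("`cutoff_fraction` must be positive")
  n <- n_channels(cube)
  M <- ft_lowpass_operator(n, cutoff_fraction, apodization)
  matrix_to_cube(cube_matrix(cube) %*% t(M), cube)
}

ft_lowpass_weights <- function(n, cutoff, apodization) {
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / (n / 2)  # frequency as a fraction of Nyquist
  w <- as.numeric(f <= cutoff)
  if (apodization == "cosine") {
    lo <- cutoff / 2
    ramp <- f > lo & f <= cutoff
    w[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - lo) / (cutoff - lo)))
  }
  w
}

ft_lowpass_operator <- function(n, cutoff, apodization) {
  w <- ft_lowpass_weights(n, cutoff, apodization)
  m <- Re(stats::fft(w, inverse = TRUE)) / n  # impulse response (circular)
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  matrix(m[idx], n, n)
}

#' Wavelet shrinkage along the spectral axis
#'
#' Applies [wavelet_shrink_rows()] to every pixel spectrum: multilevel
#' orthogonal wavelet decomposition, universal-threshold shrinkage of the
#' detail coefficients (soft or hard), reconstruction.
#'
#' @param cube an [ir_cube()].
#' @inheritParams wavelet_shrink_rows
#' @return denoised `ir_cube`.
#' @export
wavelet_spectral_denoise <- function(cube, family = "sym6", level = 5,
                                     rule = c("soft", "hard"),
                                     threshold_scale = 1) {
  m <- wavelet_shrink_rows(cube_matrix(cube), family, level,
                           match.arg(rule), threshold_scale)
  matrix_to_cube(m, cube)
}

#' PCA decomposition of the tissue spectra
#'
#' Column-mean-centers the tissue-pixel spectra matrix and computes its
#' singular value decomposition once, so that reconstructions at several
#' component counts are cheap.  The sign of each component is fixed so that
#' its largest-magnitude loading element is positive.
#'
#' @param cube an [ir_cube()].
#' @return list of class `ir_pca` with `u`, `d`, `v`, `mean`, `template`.
#' @export
pca_fit <- function(cube) {
  x <- cube_matrix(cube, tissue_only = TRUE)
  mu <- colMeans(x)
  s <- svd(sweep(x, 2L, mu))
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  structure(list(u = s$u, d = s$d, v = s$v, mean = mu, template = cube),
            class = "ir_pca")
}

#' @rdname pca_fit
#' @param fit an `ir_pca` object.
#' @param n_components rank of the reconstruction.
#' @return `pca_reconstruct` returns the denoised `ir_cube` (empty pixels
#'   pass through unchanged).
#' @export
pca_reconstruct <- function(fit, n_components) {
  r <- length(fit$d)
  if (n_components < 1 || n_components > r)
    stop("`n_components` must be in 1..", r)
  k <- seq_len(n_components)
  xr <- fit$u[, k, drop = FALSE] %*%
    (fit$d[k] * t(fit$v[, k, drop = FALSE]))
  xr <- sweep(xr, 2L, fit$mean, `+`)
  matrix_to_cube(xr, fit$template, tissue_only = TRUE)
}

#' PCA reconstruction denoising
#'
#' Denoises the whole cube at once by keeping only the first
#' `n_components` principal components of the tissue spectra (empty-space
#' pixels pass through untouched).  With white noise and a low-rank signal,
#' the retained subspace carries the signal while only a fraction
#' `k/channels` of the noise power survives.
#'
#' @inheritParams pca_fit
#' @inheritParams pca_reconstruct
#' @return denoised `ir_cube`.
#' @export
pca_denoise <- function(cube, n_components) {
  pca_reconstruct(pca_fit(cube), n_components)
}

#' Shift-difference noise covariance
#'
#' Estimates the channel x channel noise covariance from differences of
#' spatially adjacent tissue pixels, assuming adjacent spectra differ only
#' by noise.  Both horizontal and vertical neighbor pairs are pooled; pairs
#' crossing the mask are excluded; each difference is divided by sqrt(2) so
#' that iid noise of variance sigma^2 per channel yields a diagonal close
#' to sigma^2.  On structured images the assumption is violated and the
#' estimate also captures signal, increasingly so for coarser pixels.
#'
#' @param cube an [ir_cube()].
#' @return channels x channels covariance matrix.
#' @export
shift_difference_noise <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])
  msk <- cube$mask
  idx <- matrix(seq_len(d[1L] * d[2L]), d[1L], d[2L])
  pairs_a <- integer(0); pairs_b <- integer(0)
  if (d[1L] > 1L) {
    ok <- msk[-d[1L], , drop = FALSE] & msk[-1L, , drop = FALSE]
    pairs_a <- c(pairs_a, idx[-d[1L], ][ok])
    pairs_b <- c(pairs_b, idx[-1L, ][ok])
  }
  if (d[2L] > 1L) {
    ok <- msk[, -d[2L], drop = FALSE] & msk[, -1L, drop = FALSE]
    pairs_a <- c(pairs_a, idx[, -d[2L]][ok])
    pairs_b <- c(pairs_b, idx[, -1L][ok])
  }
  if (length(pairs_a) == 0L)
    stop("no adjacent tissue-pixel pairs available")
  D <- (m[pairs_a, , drop = FALSE] - m[pairs_b, , drop = FALSE]) / sqrt(2)
  crossprod(D) / length(pairs_a)
}

#' Minimum noise fraction denoising
#'
#' MNF adds a noise-whitening step before the PCA decomposition: the noise
#' covariance (estimated by [shift_difference_noise()] unless supplied) is
#' eigendecomposed, the tissue spectra are transformed so that the noise
#' becomes white, a principal decomposition is performed in the whitened
#' space (which orders components by decreasing SNR rather than variance),
#' the top `n_components` are kept, and the transform is inverted.  Under an
#' identity noise covariance MNF coincides with PCA.
#'
#' @param cube an [ir_cube()].
#' @param n_components rank of the reconstruction.
#' @param noise_cov optional precomputed channels x channels noise
#'   covariance; default is the shift-difference estimate from `cube`.
#' @param reg relative ridge added to the noise covariance
#'   (`reg * trace/channels` on the diagonal) for numerical stability.
#' @return denoised `ir_cube` (empty pixels pass through).
#' @export
mnf_denoise <- function(cube, n_components, noise_cov = NULL, reg = 1e-8) {
  fit <- mnf_fit(cube, noise_cov, reg)
  mnf_reconstruct(fit, n_components)
}

#' @rdname mnf_denoise
#' @export
mnf_fit <- function(cube, noise_cov = NULL, reg = 1e-8) {
  if (is.null(noise_cov)) noise_cov <- shift_difference_noise(cube)
  n <- n_channels(cube)
  noise_cov <- noise_cov + diag(reg * sum(diag(noise_cov)) / n, n)
  e <- eigen(noise_cov, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("noise covariance is singular beyond regularization")
  W <- e$vectors %*% diag(1 / sqrt(e$values))      # whitening
  Winv <- diag(sqrt(e$values)) %*% t(e$vectors)    # inverse transform
  x <- cube_matrix(cube, tissue_only = TRUE)
  mu <- colMeans(x)
  s <- svd(sweep(x, 2L, mu) %*% W)
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  structure(list(u = s$u, d = s$d, v = s$v, mean = mu, winv = Winv,
                 template = cube),
            class = "ir_mnf")
}

#' @rdname mnf_denoise
#' @param fit an `ir_mnf` object.
#' @export
mnf_reconstruct <- function(fit, n_components) {
  r <- length(fit$d)
  if (n_components < 1 || n_components > r)
    stop("`n_components` must be in 1..", r)
  k <- seq_len(n_components)
  zr <- fit$u[, k, drop = FALSE] %*%
    (fit$d[k] * t(fit$v[, k, drop = FALSE]))
  xr <- sweep(zr %*% fit$winv, 2L, fit$mean, `+`)
  matrix_to_cube(xr, fit$template, tissue_only = TRUE)
}

#' SNR gain as a function of reconstruction rank
#'
#' Diagnostic sweep over the number of components kept by PCA or MNF,
#' reporting the SNR gain of each reconstruction relative to the input
#' cube.  With too many components the reconstruction readmits noise and
#' the gain falls back toward 1; MNF typically drops faster than PCA
#' beyond the signal rank because its later components are ordered by SNR.
#'
#' @param cube noisy [ir_cube()].
#' @param method `"pca"` or `"mnf"`.
#' @param k_values integer vector of component counts.
#' @return data.frame with columns `k` and `snr_gain`.
#' @export
band_count_sweep <- function(cube, method = c("pca", "mnf"),
                             k_values = c(2:10, 15, 20, 30)) {
  method <- match.arg(method)
  fit <- if (method == "pca") pca_fit(cube) else mnf_fit(cube)
  base_snr <- snr(cube)$mean
  gains <- vapply(k_values, function(k) {
    den <- if (method == "pca") pca_reconstruct(fit, k)
           else mnf_reconstruct(fit, k)
    snr(den)$mean / base_snr
  }, numeric(1))
  data.frame(k = as.integer(k_values), snr_gain = gains)
}
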