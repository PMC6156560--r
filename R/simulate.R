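#' Simulation configuration
#'
#' Collects every knob of the synthetic tissue-core generator.  Defaults are
#' the package's desk-scale study conditions: a 128 x 128 high-definition
#' (1.1 um) grid, the 900-3900 cm^-1 axis at 4 cm^-1, three fuzzy
#' components, per-pixel band variability (heights 5%, centers 0.2-1.8%
#' drawn per band, widths 1%), a 0.61 lambda/NA Gaussian point-spread
#' blur with NA 0.5, random linear baselines, and an eight-step noise
#' ladder emulating 2-256 co-added scans with 40% relative noise at the
#' most intense band for 2 scans.
#'
#' @param rows,cols grid size in pixels (>= 16).
#' @param wavenumbers channel axis, see [wn_axis()].
#' @param pixel_size projected pixel size in micrometres.
#' @param numerical_aperture objective NA for the point-spread blur.
#' @param length_scale spatial correlation length (pixels) of the fuzzy
#'   component fields.
#' @param softmax_temp temperature of the softmax converting Gaussian random
#'   fields into memberships; larger = fuzzier mixing.
#' @param mask_radius core radius as a fraction of `min(rows, cols)`.
#' @param offset_sd,slope_sd SD of the per-pixel baseline offset and slope
#'   (absorbance; slope per full axis range).
#' @param baseline_scale spatial correlation length (pixels) of the
#'   baseline fields; baselines in tissue arise from scattering off the
#'   morphology and vary smoothly, not pixel-by-pixel.
#' @param height_cv,fwhm_cv per-pixel coefficients of variation of band
#'   heights and widths.
#' @param center_cv_range range from which each band's center coefficient of
#'   variation is drawn (uniform, once per simulation).
#' @param profiles band table, see [default_profiles()].
#' @param sigma_rel_max relative noise at the most intense band for the
#'   noisiest (2-scan) level.
#' @param a_floor absorbance floor entering the additive noise term
#'   `sigma_base = sigma_rel * a_floor`, so band-free regions carry noise.
#' @return a list of class `ir_sim_config`.
#' @export
ir_sim_config <- function(rows = 128, cols = 128, wavenumbers = wn_axis(),
                          pixel_size = 1.1, numerical_aperture = 0.5,
                          length_scale = 8, softmax_temp = 1.5,
                          mask_radius = 0.42,
                          offset_sd = 0.05, slope_sd = 0.05,
                          baseline_scale = 16,
                          height_cv = 0.05,
                          center_cv_range = c(0.002, 0.018),
                          fwhm_cv = 0.01,
                          profiles = default_profiles(),
                          sigma_rel_max = 0.40, a_floor = 0.05) {
  validate_profiles(profiles)
  if (rows < 16 || cols < 16) stop("grid must be at least 16 x 16")
  structure(as.list(environment()), class = "ir_sim_config")
}

#' The eight-step noise ladder
#'
#' Noise levels emulate 2, 4, 8, ..., 256 co-added scans.  Assuming
#' detector-noise-limited acquisition, noise scales as 1/sqrt(scans):
#' `sigma_rel(k) = sigma_rel_max * sqrt(2 / scans(k))`, anchored at
#' `sigma_rel_max` (default 40%) for 2 scans.  `sigma_base` adds a floor so
#' band-free spectral regions are noisy too.
#'
#' @inheritParams ir_sim_config
#' @return data.frame with columns `index`, `scans`, `sigma_rel`,
#'   `sigma_base`.
#' @export
noise_levels <- function(sigma_rel_max = 0.40, a_floor = 0.05) {
  scans <- 2^(1:8)
  sigma_rel <- sigma_rel_max * sqrt(2 / scans)
  data.frame(index = 1:8, scans = scans, sigma_rel = sigma_rel,
             sigma_base = sigma_rel * a_floor)
}

#' Synthetic tissue-core structure
#'
#' Generates the spatial scaffold of a simulated tissue core: a roughly
#' circular mask with a harmonically perturbed boundary (occupying about
#' half of the frame, surrounded by empty space) and, on the mask, smooth
#' fuzzy membership fields for `n_classes` components.  Memberships are
#' Gaussian random fields (white noise smoothed at `length_scale`) passed
#' through a softmax, so they are nonnegative and sum to one on tissue
#' pixels and are exactly zero on empty pixels.
#'
#' @inheritParams ir_sim_config
#' @param n_classes number of components (3 in the standard study).
#' @param seed integer RNG seed; equal seeds give identical output.
#' @return list with `mask` (logical rows x cols) and `concentrations`
#'   (rows x cols x n_classes array).
#' @export
generate_structure <- function(rows, cols, n_classes = 3, length_scale = 8,
                               seed = 1, mask_radius = 0.42,
                               softmax_temp = 1.5) {
  if (rows < 16 || cols < 16) stop("grid must be at least 16 x 16")
  with_seed(seed, {
    ci <- (rows + 1) / 2
    cj <- (cols + 1) / 2
    ii <- matrix(seq_len(rows), rows, cols)
    jj <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    theta <- atan2(jj - cj, ii - ci)
    dist <- sqrt((ii - ci)^2 + (jj - cj)^2)
    r0 <- mask_radius * min(rows, cols)
    rr <- r0
    for (m in 2:5)
      rr <- rr + r0 * stats::rnorm(1, 0, 0.04) * cos(m * theta +
                                                     stats::runif(1, 0, 2 * pi))
    mask <- dist <= rr
    z <- vapply(seq_len(n_classes), function(k) {
      f <- gauss_field(rows, cols, length_scale)
      f / stats::sd(f)
    }, matrix(0, rows, cols))
    e <- exp(z / softmax_temp)
    conc <- e / array(rep(rowSums(matrix(e, rows * cols, n_classes)),
                          n_classes), dim(e))
    conc <- conc * array(mask, dim(conc))
    list(mask = mask, concentrations = conc)
  })
}

# periodic Gaussian random field: white noise smoothed at `scale` pixels
gauss_field <- function(rows, cols, scale) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  fx <- c(0:(rows %/% 2), -((rows - rows %/% 2 - 1):1)) / rows
  fy <- c(0:(cols %/% 2), -((cols - cols %/% 2 - 1):1)) / cols
  H <- exp(-2 * pi^2 * scale^2 * outer(fx^2, fy^2, `+`))
  Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (rows * cols)
}

#' Render the noise-free hypercube
#'
#' Builds each tissue pixel's spectrum as the membership-weighted sum of the
#' three component profiles, with band heights, centers and widths
#' independently randomized per pixel (normal perturbations around the
#' nominal values; draws below 10% of nominal are clipped there).  Empty
#' pixels get a zero spectrum.  Each band is a mixed Gaussian-Lorentzian,
#' see [mixed_band()].
#'
#' @param concentrations rows x cols x 3 membership array (see
#'   [generate_structure()]).
#' @inheritParams ir_sim_config
#' @param seed integer RNG seed.
#' @return an [ir_cube()] whose mask marks pixels with nonzero membership.
#' @export
render_clean_cube <- function(concentrations, profiles = default_profiles(),
                              wavenumbers = wn_axis(), seed = 1,
                              height_cv = 0.05,
                              center_cv_range = c(0.002, 0.018),
                              fwhm_cv = 0.01, pixel_size = 1.1) {
  validate_profiles(profiles)
  if (max(profiles$center) > max(wavenumbers) ||
      min(profiles$center) < min(wavenumbers))
    stop("axis does not cover all band centers")
  d <- dim(concentrations)
  rows <- d[1L]; cols <- d[2L]
  nchan <- length(wavenumbers)
  mask <- apply(concentrations, c(1, 2), sum) > 1e-9
  keep <- as.vector(mask)
  np <- sum(keep)
  conc_m <- matrix(concentrations, rows * cols, d[3L])[keep, , drop = FALSE]
  classes <- c("protein", "lipid", "nucleic")
  S <- with_seed(seed, {
    center_cv <- stats::runif(nrow(profiles), center_cv_range[1L],
                              center_cv_range[2L])
    WN <- matrix(wavenumbers, np, nchan, byrow = TRUE)
    acc <- matrix(0, np, nchan)
    for (k in seq_len(d[3L])) {
      wt <- conc_m[, k]
      hts <- profiles[[classes[k]]]
      for (b in seq_len(nrow(profiles))) {
        h0 <- hts[b]; c0 <- profiles$center[b]; w0 <- profiles$fwhm[b]
        h <- pmax(stats::rnorm(np, h0, h0 * height_cv), 0.1 * h0)
        cc <- pmax(stats::rnorm(np, c0, c0 * center_cv[b]), 0.1 * c0)
        w <- pmax(stats::rnorm(np, w0, w0 * fwhm_cv), 0.1 * w0)
        if (h0 == 0) next
        U <- (WN - cc) / w
        acc <- acc + (h * wt) *
          (0.5 * exp(-4 * log(2) * U^2) + 0.5 / (1 + 4 * U^2))
      }
    }
    acc
  })
  full <- matrix(0, rows * cols, nchan)
  full[keep, ] <- S
  ir_cube(array(full, c(rows, cols, nchan)), wavenumbers, mask, pixel_size)
}

#' Wavelength-dependent point-spread blur
#'
#' Convolves each channel image with a Gaussian point-spread function whose
#' FWHM follows the diffraction limit, `0.61 * lambda / NA` with
#' `lambda[um] = 1e4 / wavenumber`, converted to pixels via the cube's pixel
#' size.  Longer wavelengths (lower wavenumbers, e.g. amide I at 1650
#' cm^-1, lambda = 6.06 um) are blurred more than shorter ones (3300 cm^-1,
#' 3.03 um).  Boundaries are reflected; on the tissue mask the kernel is
#' renormalized over tissue pixels so empty space does not bleed darkness
#' into the core.  Empty pixels stay zero.
#'
#' @param cube an `ir_cube`.
#' @param numerical_aperture objective NA (> 0).
#' @return blurred `ir_cube`.
#' @export
apply_psf_blur <- function(cube, numerical_aperture = 0.5) {
  if (numerical_aperture <= 0) stop("`numerical_aperture` must be positive")
  d <- dim(cube$data)
  wn <- cube$wavenumbers
  fwhm_px <- 0.61 * (1e4 / wn) / numerical_aperture / cube$pixel_size
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  # group channels with near-equal blur to reuse kernels
  sgrp <- round(sigma / 0.05) * 0.05
  out <- cube$data
  maskn <- cube$mask * 1
  for (s in unique(sgrp)) {
    if (s < 0.15) next  # sub-pixel kernel: identity
    idx <- which(sgrp == s)
    Kr <- reflect_conv_mat(d[1L], gauss_kernel_1d(s))
    Kc <- reflect_conv_mat(d[2L], gauss_kernel_1d(s))
    den <- Kr %*% maskn %*% t(Kc)
    den[den <= 0] <- 1
    for (k in idx) {
      num <- Kr %*% (cube$data[, , k] * maskn) %*% t(Kc)
      out[, , k] <- (num / den) * maskn
    }
  }
  ir_cube(out, wn, cube$mask, cube$pixel_size)
}

gauss_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  w <- exp(-0.5 * ((-radius):radius / sigma)^2)
  w / sum(w)
}

# n x n matrix applying 1-D convolution with kernel w under reflect padding
reflect_conv_mat <- function(n, w) {
  radius <- (length(w) - 1L) %/% 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in (-radius):radius) {
    j <- i + o
    # whole-sample reflection, folded repeatedly for kernels wider than n
    repeat {
      bad_lo <- j < 1L
      bad_hi <- j > n
      if (!any(bad_lo | bad_hi)) break
      j[bad_lo] <- 2L - j[bad_lo]
      j[bad_hi] <- 2L * n - j[bad_hi]
    }
    K[cbind(i, j)] <- K[cbind(i, j)] + w[o + radius + 1L]
  }
  K
}

#' Random linear baselines
#'
#' Adds to every pixel (tissue and empty space) a straight-line baseline
#' `b0 + b1 * (v - v_mid)/(v_hi - v_lo)` with `b0 ~ N(0, offset_sd^2)` and
#' `b1 ~ N(0, slope_sd^2)`, emulating the slowly varying offsets of
#' experimental absorbance spectra (scattering and interference).  With
#' `length_scale = NULL` the coefficients are drawn independently per
#' pixel; given a positive `length_scale` they form smooth Gaussian random
#' fields with that spatial correlation length, which matches the
#' morphology-bound character of scattering baselines in tissue (the
#' simulator's default).
#'
#' @param cube an `ir_cube`.
#' @inheritParams ir_sim_config
#' @param seed integer RNG seed.
#' @param length_scale spatial correlation length of the baseline fields in
#'   pixels, or `NULL` for pixel-independent draws.
#' @return `ir_cube` with baselines added.
#' @export
add_baseline <- function(cube, offset_sd = 0.05, slope_sd = 0.05, seed = 1,
                         length_scale = NULL) {
  d <- dim(cube$data)
  np <- d[1L] * d[2L]
  wn <- cube$wavenumbers
  ramp <- (wn - (min(wn) + max(wn)) / 2) / (max(wn) - min(wn))
  with_seed(seed, {
    if (is.null(length_scale)) {
      b0 <- stats::rnorm(np, 0, offset_sd)
      b1 <- stats::rnorm(np, 0, slope_sd)
    } else {
      f0 <- gauss_field(d[1L], d[2L], length_scale)
      f1 <- gauss_field(d[1L], d[2L], length_scale)
      b0 <- as.vector(f0 / stats::sd(f0)) * offset_sd
      b1 <- as.vector(f1 / stats::sd(f1)) * slope_sd
    }
    m <- matrix(cube$data, np, d[3L]) + b0 + outer(b1, ramp)
    ir_cube(array(m, d), wn, cube$mask, cube$pixel_size)
  })
}

#' Corrupt a clean cube with a random baseline and scan-level noise
#'
#' The corruption has two parts, both stored in `added_noise` so that
#' `noisy == clean + added_noise` holds bitwise.  (1) An optional random
#' linear baseline per pixel (`b0 + b1 * ramp`, as in [add_baseline()]) —
#' baselines belong to the raw-signal corruption, not to the clean
#' reference, which is why the SNR metric removes a fitted slope before
#' measuring noise.  (2) Zero-mean Gaussian noise whose SD is
#' signal-dependent, `sigma(x, v) = sigma_base + sigma_rel *
#' max(clean(x, v), 0)`: the multiplicative part reproduces the observed
#' proportionality of FT-IR noise to absorbance (40% at the most intense
#' band for the 2-scan level), while `sigma_base` keeps band-free windows
#' measurably noisy.
#'
#' @param clean a noise-free `ir_cube`.
#' @param level either a row index into [noise_levels()] (1 = noisiest) or a
#'   one-row data.frame with columns `index`, `scans`, `sigma_rel`,
#'   `sigma_base`.
#' @param seed integer RNG seed.
#' @param offset_sd,slope_sd baseline SDs (0 = no baseline corruption).
#' @param ladder noise ladder table, see [noise_levels()].
#' @return an `ir_bundle`: list with `clean`, `noisy`, `added_noise`
#'   (array), `level` (ladder row), `seed`.
#' @export
add_noise <- function(clean, level = 1, seed = 1, offset_sd = 0,
                      slope_sd = 0, ladder = noise_levels()) {
  if (is.numeric(level) && length(level) == 1L) level <- ladder[level, ]
  d <- dim(clean$data)
  np <- d[1L] * d[2L]
  wn <- clean$wavenumbers
  ramp <- (wn - (min(wn) + max(wn)) / 2) / (max(wn) - min(wn))
  eps <- with_seed(seed, {
    sigma <- level$sigma_base + level$sigma_rel * pmax(clean$data, 0)
    e <- array(stats::rnorm(prod(d)), d) * sigma
    if (offset_sd > 0 || slope_sd > 0) {
      b0 <- stats::rnorm(np, 0, offset_sd)
      b1 <- stats::rnorm(np, 0, slope_sd)
      e <- e + array(b0 + outer(b1, ramp), d)
    }
    e
  })
  noisy <- ir_cube(clean$data + eps, clean$wavenumbers, clean$mask,
                   clean$pixel_size)
  structure(list(clean = clean, noisy = noisy, added_noise = eps,
                 level = level, seed = seed, concentrations = NULL),
            class = "ir_bundle")
}

#' @export
print.ir_bundle <- function(x, ...) {
  cat(sprintf("<ir_bundle> level %d (%d scans, sigma_rel %.4f), %s pixels\n",
              x$level$index, x$level$scans, x$level$sigma_rel,
              paste(dim(x$clean$data)[1:2], collapse = " x ")))
  invisible(x)
}

#' Run the full simulation
#'
#' Renders one clean high-definition cube (structure, spectra,
#' point-spread blur, smooth scattering baselines) and corrupts it with
#' independent noise realizations at the requested ladder levels.
#' Optionally each bundle is
#' also produced on the standard-definition grid by 5x binning of the clean
#' and noisy HD cubes (noise is added before binning, matching the
#' experimental HD-to-SD pathway, so SD noise is the 25-pixel average of HD
#' noise).
#'
#' @param config an [ir_sim_config()].
#' @param seed master integer seed; all stage seeds are derived from it.
#' @param levels subset of 1:8 noise-ladder levels to realize.
#' @param include_sd also produce 5x-binned standard-definition bundles.
#' @return list of class `ir_simulation` with elements `hd` (list of
#'   `ir_bundle`), `sd` (same, or `NULL`), `clean`, `structure`, `config`,
#'   `seed`.
#' @export
simulate_bundles <- function(config = ir_sim_config(), seed = 1,
                             levels = 1:8, include_sd = FALSE) {
  st <- generate_structure(config$rows, config$cols, 3,
                           config$length_scale, derive_seed(seed, 1),
                           config$mask_radius, config$softmax_temp)
  clean <- render_clean_cube(st$concentrations, config$profiles,
                             config$wavenumbers, derive_seed(seed, 2),
                             config$height_cv, config$center_cv_range,
                             config$fwhm_cv, config$pixel_size)
  clean <- apply_psf_blur(clean, config$numerical_aperture)
  clean <- add_baseline(clean, config$offset_sd, config$slope_sd,
                        derive_seed(seed, 3),
                        length_scale = config$baseline_scale)
  ladder <- noise_levels(config$sigma_rel_max, config$a_floor)
  hd <- lapply(levels, function(k) {
    b <- add_noise(clean, k, derive_seed(seed, 10 + k), ladder = ladder)
    b$concentrations <- st$concentrations
    b
  })
  names(hd) <- paste0("level", levels)
  sd_bundles <- NULL
  if (include_sd) {
    clean_sd <- bin_cube(clean, 5L)
    sd_bundles <- lapply(hd, function(b) {
      noisy_sd <- bin_cube(b$noisy, 5L)
      structure(list(clean = clean_sd, noisy = noisy_sd,
                     added_noise = noisy_sd$data - clean_sd$data,
                     level = b$level, seed = b$seed,
                     concentrations = NULL),
                class = "ir_bundle")
    })
  }
  structure(list(hd = hd, sd = sd_bundles, clean = clean, structure = st,
                 config = config, seed = seed),
            class = "ir_simulation")
}

#' @export
print.ir_simulation <- function(x, ...) {
  cat(sprintf("<ir_simulation> %d x %d grid, %d channels, %d HD level(s)%s\n",
              x$config$rows, x$config$cols, length(x$config$wavenumbers),
              length(x$hd), if (is.null(x$sd)) "" else " + SD"))
  invisible(x)
}
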