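test_that("the mixed Gaussian-Lorentzian band has exact height and FWHM", {
  wn <- seq(900, 3900, 2)
  b <- mixed_band(wn, center = 1650, height = 0.8, fwhm = 40)
  expect_equal(b[wn == 1650], 0.8)
  expect_equal(mixed_band(1650 + 20, 1650, 0.8, 40), 0.4)  # half max at c+w/2
  expect_equal(mixed_band(1650 - 20, 1650, 0.8, 40), 0.4)
  expect_identical(mixed_band(wn, 1650, 0, 40), rep(0, length(wn)))
  expect_error(mixed_band(wn, 1650, 1, -1), "fwhm")
})

test_that("structure generation yields normalized fuzzy maps on a core mask", {
  st <- generate_structure(48, 48, seed = 3)
  sums <- apply(st$concentrations, c(1, 2), sum)
  expect_true(all(abs(sums[st$mask] - 1) < 1e-12))
  expect_true(all(sums[!st$mask] == 0))
  expect_true(all(st$concentrations >= 0))
  frac <- mean(st$mask)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.8)
  expect_identical(st, generate_structure(48, 48, seed = 3))
  expect_error(generate_structure(8, 8), "16")
})

test_that("larger length scales give longer-range membership correlation", {
  roughness <- function(scale) {
    st <- generate_structure(48, 48, length_scale = scale, seed = 5)
    f <- st$concentrations[, , 1]
    ok <- st$mask[-1, ] & st$mask[-48, ]
    # mean squared difference of vertical neighbors, normalized
    mean((f[-1, ][ok] - f[-48, ][ok])^2) / var(f[st$mask])
  }
  expect_lt(roughness(8), roughness(2))
})

test_that("rendering with zero variability reproduces nominal mixtures", {
  conc <- array(0, c(16, 16, 3))
  conc[2, 2, 1] <- 1                      # pure protein pixel
  conc[3, 3, ] <- c(1, 1, 1) / 3          # even mixture
  wn <- wn_axis()
  cube <- render_clean_cube(conc, wavenumbers = wn, seed = 1,
                            height_cv = 0, center_cv_range = c(0, 0),
                            fwhm_cv = 0)
  nominal <- function(class) {
    p <- component_profile(class)
    rowSums(sapply(seq_len(nrow(p)),
                   function(i) mixed_band(wn, p$center[i], p$height[i],
                                          p$fwhm[i])))
  }
  expect_equal(cube$data[2, 2, ], nominal("protein"), tolerance = 1e-12)
  mix <- (nominal("protein") + nominal("lipid") + nominal("nucleic")) / 3
  expect_equal(cube$data[3, 3, ], mix, tolerance = 1e-12)
  expect_true(all(cube$data[5, 5, ] == 0))  # empty pixel
  expect_error(render_clean_cube(conc, wavenumbers = seq(1000, 2000, 4)),
               "band centers")
})

test_that("per-pixel height variability shows up as the sample CV", {
  conc <- array(0, c(100, 100, 3))
  conc[, , 1] <- 1  # pure protein everywhere
  cube <- render_clean_cube(conc, seed = 9, height_cv = 0.05,
                            center_cv_range = c(0, 0), fwhm_cv = 0)
  amp <- as.vector(band_image(cube, 1650))
  expect_lt(abs(sd(amp) / mean(amp) - 0.05), 0.005)
})

test_that("the point-spread blur is wavelength-dependent and mask-safe", {
  # constant cube: blur must not change it (kernel normalization)
  const <- ir_cube(array(2, c(24, 24, 3)), c(1650, 1654, 1658))
  expect_equal(apply_psf_blur(const, 0.5)$data, const$data, tolerance = 1e-10)
  # huge NA -> sub-pixel kernel -> identity
  cube <- rand_cube(16, 16, 8, lo = 1650)
  expect_equal(apply_psf_blur(cube, 100)$data, cube$data, tolerance = 1e-6)
  # same random image at 1650 and 3300: the longer wavelength (1650) is
  # blurred more, so its variance drops further
  set.seed(4)
  img <- matrix(rnorm(32 * 32), 32, 32)
  two <- ir_cube(array(rep(img, 2), c(32, 32, 2)), c(1650, 3300))
  bl <- apply_psf_blur(two, 0.5)
  expect_lt(var(as.vector(bl$data[, , 1])), var(as.vector(bl$data[, , 2])))
  # masked normalization keeps a constant tissue core constant at the edge
  mask <- matrix(FALSE, 24, 24); mask[7:18, 7:18] <- TRUE
  core <- ir_cube(array(as.numeric(mask), c(24, 24, 1)) * 3,
                  1650, mask)
  blc <- apply_psf_blur(core, 0.5)
  expect_equal(blc$data[, , 1][mask], rep(3, sum(mask)), tolerance = 1e-10)
  expect_true(all(blc$data[, , 1][!mask] == 0))
  expect_error(apply_psf_blur(cube, -1), "positive")
})

test_that("baselines are exactly linear per pixel and centered", {
  cube <- rand_cube(20, 20, 64)
  expect_equal(add_baseline(cube, 0, 0, 1)$data, cube$data)
  wb <- add_baseline(cube, 0.1, 0.2, seed = 6)
  added <- wb$data[3, 4, ] - cube$data[3, 4, ]
  fit <- lm(added ~ wb$wavenumbers)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  # CLT: mean added value at the axis midpoint ~ 0 +- 3*offset_sd/sqrt(n)
  mid <- (min(cube$wavenumbers) + max(cube$wavenumbers)) / 2
  k <- which.min(abs(cube$wavenumbers - mid))
  offs <- as.vector(wb$data[, , k] - cube$data[, , k])
  expect_lt(abs(mean(offs)), 3 * 0.1 / sqrt(length(offs)) +
              0.2 * abs(cube$wavenumbers[k] - mid) / diff(range(cube$wavenumbers)))
  # smooth baseline fields vary less between neighbors than iid ones
  zero <- ir_cube(array(0, dim(cube$data)), cube$wavenumbers)
  sm <- add_baseline(zero, 0.1, 0, seed = 6, length_scale = 8)
  iid <- add_baseline(zero, 0.1, 0, seed = 6)
  neigh_var <- function(x) mean((x$data[-1, , k] - x$data[-20, , k])^2)
  expect_lt(neigh_var(sm), neigh_var(iid) / 4)
})

test_that("noise obeys the scan-scaling law and the bundle contract", {
  lad <- noise_levels()
  expect_equal(lad$sigma_rel[8], 0.40 / sqrt(128))
  expect_equal(lad$sigma_rel, 0.40 * sqrt(2 / lad$scans))
  cube <- rand_cube(10, 10, 32)
  silent <- data.frame(index = 1, scans = 2, sigma_rel = 0, sigma_base = 0)
  b0 <- add_noise(cube, silent, seed = 2)
  expect_identical(b0$noisy$data, cube$data)
  b <- add_noise(cube, 1, seed = 2)
  expect_identical(b$noisy$data, b$clean$data + b$added_noise)
})

test_that("simulation bundles are reproducible and share one clean cube", {
  s1 <- simulate_bundles(ir_sim_config(rows = 24, cols = 24), seed = 5,
                         levels = c(1, 8))
  s2 <- simulate_bundles(ir_sim_config(rows = 24, cols = 24), seed = 5,
                         levels = c(1, 8))
  expect_identical(s1$hd$level1$noisy$data, s2$hd$level1$noisy$data)
  expect_identical(s1$hd$level1$clean, s1$hd$level8$clean)
  expect_identical(s1$hd$level1$noisy$data,
                   s1$hd$level1$clean$data + s1$hd$level1$added_noise)
  # empty-space pixels: zero clean signal apart from baseline (linear in wn)
  off <- which(!s1$clean$mask, arr.ind = TRUE)[1, ]
  spec <- s1$clean$data[off[1], off[2], ]
  fit <- lm(spec ~ s1$clean$wavenumbers)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("with zero variability and no baseline the clean cube has rank 3", {
  # the wavelength-dependent blur mixes channels with different kernels and
  # would itself raise the numerical rank, so it is switched off here via a
  # sub-pixel point spread (huge NA)
  cfg <- ir_sim_config(rows = 24, cols = 24, height_cv = 0,
                       center_cv_range = c(0, 0), fwhm_cv = 0,
                       offset_sd = 0, slope_sd = 0,
                       numerical_aperture = 100)
  sim <- simulate_bundles(cfg, seed = 2, levels = 1)
  sv <- svd(cube_matrix(sim$clean, tissue_only = TRUE))$d
  expect_lt(sv[4], 1e-10 * sv[1])
  expect_gt(sv[3], 1e-10 * sv[1])
})

test_that("5x binning divides flat-window noise SD by about 5", {
  sim <- small_sim()
  b <- sim$hd$level1
  bsd <- sim$sd$level1
  noise_sd <- function(bundle) {
    eps <- bundle$added_noise
    wn <- bundle$clean$wavenumbers
    idx <- which(wn >= 2080 & wn <= 2150)
    sd(as.vector(eps[, , idx]))
  }
  expect_equal(noise_sd(b) / noise_sd(bsd), 5, tolerance = 0.10)
})
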