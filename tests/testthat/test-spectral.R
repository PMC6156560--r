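test_that("Savitzky-Golay reproduces polynomials up to its degree", {
  wn <- wn_axis()
  poly <- 1e-9 * wn^3 - 2e-6 * wn^2 + 0.01 * wn + 1
  cube <- ir_cube(array(rep(poly, each = 4), c(2, 2, length(wn))), wn)
  sg <- savgol_denoise(cube, degree = 3, window = 17)
  expect_lt(max(abs(sg$data - cube$data)), 1e-10)
  expect_error(savgol_denoise(cube, 3, 16), "odd")
  expect_error(savgol_denoise(cube, 3, 3), "degree")
  expect_error(savgol_denoise(cube, 3, 1001), "channel count")
})

test_that("Savitzky-Golay reduces white-noise variance", {
  cube <- rand_cube(16, 16, 256, seed = 8)
  sg <- savgol_denoise(cube, 3, 17)
  # drop edge windows where the off-center fits have higher gain
  core <- 20:237
  expect_lt(var(as.vector(sg$data[, , core])),
            0.5 * var(as.vector(cube$data[, , core])))
})

test_that("Fourier low-pass: identity at cutoff 1, DC preserved, stop-band kills", {
  cube <- rand_cube(4, 4, 128)
  expect_lt(max(abs(ft_spectral_denoise(cube, 1, "none")$data - cube$data)),
            1e-10)
  const <- ir_cube(array(3, c(2, 2, 128)), seq(2000, by = 4, length.out = 128))
  expect_equal(ft_spectral_denoise(const, 0.2, "cosine")$data, const$data,
               tolerance = 1e-12)
  # pure cosine above the cutoff is zeroed (40 cycles / 128 samples = 0.625)
  cosx <- cos(2 * pi * 40 * (0:127) / 128)
  cc <- ir_cube(array(rep(cosx, each = 1), c(1, 1, 128)),
                seq(2000, by = 4, length.out = 128))
  out <- ft_spectral_denoise(cc, 0.5, "none")
  expect_lt(max(abs(out$data)), 1e-8)
  expect_error(ft_spectral_denoise(cube, 0), "positive")
})

test_that("PCA: full-rank identity and exact recovery of rank-3 cubes", {
  cube <- rand_cube(16, 16, 64, seed = 1)
  full <- pca_denoise(cube, 64)
  expect_lt(max(abs(full$data - cube$data)), 1e-8)
  r3 <- rank3_cube()
  rec <- pca_denoise(r3, 3)
  expect_lt(max(abs(rec$data - r3$data)), 1e-8)
  expect_error(pca_denoise(cube, 0), "n_components")
})

test_that("PCA passes only ~k/channels of white noise in a band-free window", {
  r3 <- rank3_cube(40, 40, 48, amplitude = 20)
  set.seed(6)
  sigma <- 0.1
  noisy <- ir_cube(r3$data + array(rnorm(length(r3$data), sd = sigma),
                                   dim(r3$data)),
                   r3$wavenumbers)
  den <- pca_denoise(noisy, 3)
  resid_var <- mean((den$data - r3$data)^2)
  expected <- sigma^2 * 3 / 48
  expect_gt(resid_var, expected / 3)
  expect_lt(resid_var, expected * 3)
})

test_that("empty pixels pass through multivariate denoisers untouched", {
  mask <- matrix(TRUE, 16, 16); mask[1:4, ] <- FALSE
  cube <- rand_cube(16, 16, 32, seed = 3, mask = mask)
  for (den in list(pca_denoise(cube, 5),
                   mnf_denoise(cube, 5, noise_cov = diag(32)))) {
    expect_identical(den$data[1:4, , ], cube$data[1:4, , ])
    expect_false(identical(den$data[5:16, , ], cube$data[5:16, , ]))
  }
})

test_that("shift differences recover the iid noise variance", {
  cube <- flat_noise_cube(72, 72, nchan = 8, sigma = 0.3, seed = 9)
  # > 1e4 adjacent pairs at 72 x 72
  S <- shift_difference_noise(cube)
  expect_true(all(abs(diag(S) / 0.09 - 1) < 0.05))
  # noiseless constant image -> zero covariance
  const <- ir_cube(array(1, c(8, 8, 4)), seq(2000, by = 4, length.out = 4))
  expect_true(all(shift_difference_noise(const) == 0))
  # noiseless structured image: the only-noise assumption is violated and
  # the estimate captures signal
  grad <- rank3_cube(16, 16, 24)
  expect_gt(max(abs(shift_difference_noise(grad))), 1e-6)
  one <- ir_cube(array(1, c(1, 1, 4)), seq(2000, by = 4, length.out = 4))
  expect_error(shift_difference_noise(one), "adjacent")
})

test_that("MNF equals PCA under identity noise covariance", {
  for (seed in 1:5) {
    cube <- rand_cube(16, 16, 64, seed = seed)
    p <- pca_denoise(cube, 6)
    m <- mnf_denoise(cube, 6, noise_cov = diag(64))
    expect_lt(max(abs(p$data - m$data)), 1e-6)
  }
})

test_that("MNF at full rank is the identity", {
  sim <- small_sim()
  cube <- sim$hd$level5$noisy
  k <- min(sum(cube$mask), length(cube$wavenumbers))
  m <- mnf_denoise(cube, k)
  expect_lt(max(abs(m$data - cube$data)) / max(abs(cube$data)), 1e-6)
})

test_that("MNF beats PCA under channel-correlated noise", {
  r3 <- rank3_cube(24, 24, 48, amplitude = 5)
  set.seed(12)
  # strongly colored noise: a few channels are much noisier than the rest
  sds <- rep(0.05, 48); sds[c(5, 20, 35)] <- 0.8
  eps <- matrix(rnorm(24 * 24 * 48), 24 * 24, 48) %*% diag(sds)
  noisy <- ir_cube(r3$data + array(eps, dim(r3$data)), r3$wavenumbers)
  mse <- function(d) mean((d$data - r3$data)^2)
  expect_lt(mse(mnf_denoise(noisy, 3)), mse(pca_denoise(noisy, 3)))
})

test_that("band-count sweep: identity at full rank, noise readmission beyond", {
  sim <- small_sim()
  cube <- sim$hd$level1$noisy
  full <- min(sum(cube$mask), length(cube$wavenumbers))
  sw <- band_count_sweep(cube, "pca", c(3, 30, full))
  expect_equal(sw$snr_gain[sw$k == full], 1, tolerance = 1e-6)
  expect_gte(sw$snr_gain[sw$k == 3], sw$snr_gain[sw$k == 30])
})

test_that("beyond the signal rank MNF readmits noise faster than PCA", {
  # needs the default-scale core: small grids estimate the shift-difference
  # covariance too coarsely for the ordering to be reliable
  cube <- acceptance_sim()$hd$level1$noisy
  drop <- sapply(c(pca = "pca", mnf = "mnf"), function(m) {
    sw <- band_count_sweep(cube, m, c(3, 20))
    sw$snr_gain[sw$k == 3] / sw$snr_gain[sw$k == 20]
  })
  expect_gt(drop[["mnf"]], drop[["pca"]])
})

test_that("spectral denoisers preserve shape, axis and mask", {
  sim <- small_sim()
  cube <- sim$hd$level8$noisy
  for (den in list(savgol_denoise(cube, 3, 15),
                   ft_spectral_denoise(cube, 0.3, "cosine"),
                   wavelet_spectral_denoise(cube, "db4", 4, "hard", 1),
                   pca_denoise(cube, 4),
                   mnf_denoise(cube, 4))) {
    expect_identical(dim(den$data), dim(cube$data))
    expect_identical(den$wavenumbers, cube$wavenumbers)
    expect_identical(den$mask, cube$mask)
  }
})
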