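# shared fixtures, all generated in code

# random cube with a valid axis; default covers the 2080-2150 noise window
rand_cube <- function(rows = 8, cols = 8, nchan = 64, seed = 1,
                      lo = 2000, by = 4, sd = 1, mask = NULL,
                      pixel_size = 1.1) {
  set.seed(seed)
  ir_cube(array(rnorm(rows * cols * nchan, sd = sd), c(rows, cols, nchan)),
          seq(lo, by = by, length.out = nchan), mask, pixel_size)
}

# constant image + iid noise cube (flat spectra), for noise-metric checks
flat_noise_cube <- function(rows = 32, cols = 32, nchan = 64, sigma = 0.1,
                            seed = 1, level = 0.5) {
  set.seed(seed)
  arr <- array(level + rnorm(rows * cols * nchan, sd = sigma),
               c(rows, cols, nchan))
  ir_cube(arr, seq(2000, by = 4, length.out = nchan))
}

# rank-3 spatial-spectral signal on a small grid (smooth score fields so
# adjacent pixels are nearly equal, as the shift-difference stat assumes)
rank3_cube <- function(rows = 24, cols = 24, nchan = 48, seed = 1,
                       amplitude = 1) {
  set.seed(seed)
  wn <- seq(2000, by = 4, length.out = nchan)
  centers <- c(2020, 2120, 2180)
  profiles <- sapply(centers, function(cc) mixed_band(wn, cc, 1, 40))
  xg <- outer(seq(0, 1, length.out = rows), rep(1, cols))
  yg <- outer(rep(1, rows), seq(0, 1, length.out = cols))
  scores <- cbind(as.vector(0.5 + 0.5 * sin(2 * pi * xg)),
                  as.vector(0.5 + 0.5 * cos(2 * pi * yg)),
                  as.vector(0.3 + 0.4 * xg * yg)) * amplitude
  m <- scores %*% t(profiles)
  ir_cube(array(m, c(rows, cols, nchan)), wn)
}

# small, fast simulation shared by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_bundles(
        ir_sim_config(rows = 40, cols = 40), seed = 11,
        levels = c(1, 5, 8), include_sd = TRUE)
    cache
  }
})

# the default desk-scale study conditions, built once for the acceptance
# suite (128 x 128 HD grid, all eight noise levels, fixed seed)
acceptance_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_bundles(ir_sim_config(), seed = 101)
    cache
  }
})
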