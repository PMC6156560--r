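test_that("run_sweep yields one record set per level and grid row", {
  sim <- small_sim()
  spec <- sweep_spec("savgol", expand.grid(degree = 3, window = c(11, 15)),
                     levels = c(1, 8))
  rec <- run_sweep(sim$hd, spec)
  # 2 levels x 2 grid rows x (1 spectral + 2 band rows)
  expect_equal(nrow(rec), 12)
  expect_false(any(rec$failed))
  expect_equal(sort(unique(rec$noise_level)), c(1, 8))
})

test_that("an identity method scores snr_gain of exactly 1", {
  sim <- small_sim()
  spec <- sweep_spec("ft", data.frame(cutoff_fraction = 1,
                                      apodization = "none",
                                      stringsAsFactors = FALSE),
                     levels = 1)
  rec <- run_sweep(sim$hd, spec)
  expect_equal(rec$snr_gain[rec$band == "spectral"], 1, tolerance = 1e-6)
})

test_that("failed sweep cells are recorded without aborting", {
  sim <- small_sim()
  spec <- sweep_spec("savgol", expand.grid(degree = 3, window = c(15, 1001)),
                     levels = 1)
  rec <- run_sweep(sim$hd, spec)
  sp <- rec[rec$band == "spectral", ]
  expect_equal(sum(sp$failed), 1)
  expect_match(sp$error[sp$failed], "channel")
  expect_false(sp$failed[grepl("window=15", sp$params)])
})

test_that("optimum selection respects the distortion cap and Pearson rule", {
  rec <- data.frame(method = "ft", params = c("a", "b"), noise_level = 1,
                    scans = 2, pixel_size = 1.1, band = "spectral",
                    snr_gain = c(5, 8), sd_percent = c(1, 20),
                    pearson_r = c(0.99, 0.99), psnr_gain = NA, ssim = NA,
                    failed = FALSE, error = "", stringsAsFactors = FALSE)
  sel <- select_optimum(rec, sd_cap = 15)
  expect_equal(sel$params, "a")           # cap binds: gain 8 has SD 20
  expect_false(sel$warn_infeasible)
  one <- select_optimum(rec[1, ])
  expect_equal(one$params, "a")
  # wavelet rows additionally need pearson_r >= 0.95
  w <- rec; w$method <- "wavelet"; w$sd_percent <- c(1, 2)
  w$pearson_r <- c(0.99, 0.90)
  expect_equal(select_optimum(w)$params, "a")
  # nothing feasible -> min-SD fallback, flagged
  w$pearson_r <- c(0.5, 0.5)
  fb <- select_optimum(w)
  expect_true(fb$warn_infeasible)
  expect_equal(fb$params, "a")
})

test_that("pareto selection returns the non-dominated front", {
  rec <- data.frame(method = "ft", params = c("a", "b", "c"),
                    noise_level = 1, scans = 2, pixel_size = 1.1,
                    band = "spectral",
                    snr_gain = c(5, 8, 3), sd_percent = c(1, 5, 0.2),
                    pearson_r = 0.99, psnr_gain = NA, ssim = NA,
                    failed = FALSE, error = "", stringsAsFactors = FALSE)
  sel <- select_optimum(rec, rule = "pareto")
  expect_equal(sort(sel$params), c("a", "b", "c"))
  dom <- rec; dom$snr_gain[3] <- 4; dom$sd_percent[3] <- 2  # c dominated by a
  expect_equal(sort(select_optimum(dom, rule = "pareto")$params), c("a", "b"))
})

test_that("reports are deterministic and tolerate empty selections", {
  sim <- small_sim()
  spec <- sweep_spec("savgol", data.frame(degree = 3, window = 15),
                     levels = c(1, 8))
  rec <- run_sweep(sim$hd, spec)
  sel <- select_optimum(rec)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  report(sel, d1); report(sel, d2)
  expect_identical(readLines(file.path(d1, "selected.csv")),
                   readLines(file.path(d2, "selected.csv")))
  empty <- rec[0, ]
  expect_no_error(report(empty, file.path(tempdir(), "rep_empty")))
})

test_that("MNF's distortion is worse on the binned 5.5 um grid than in HD", {
  sim <- small_sim()
  for (lvl in c("level1", "level5")) {
    hd <- sim$hd[[lvl]]; sdb <- sim$sd[[lvl]]
    sd_hd <- signal_distortion(mnf_denoise(hd$noisy, 4), hd$clean,
                               hd$added_noise)$mean
    sd_sd <- signal_distortion(mnf_denoise(sdb$noisy, 4), sdb$clean,
                               sdb$added_noise)$mean
    expect_gt(sd_sd, sd_hd)
  }
})

test_that("a small end-to-end benchmark is reproducible and sane", {
  cfg <- ir_sim_config(rows = 24, cols = 24)
  b1 <- ir_benchmark(cfg, seed = 4, levels = 1,
                     methods = c("savgol", "pca"))
  b2 <- ir_benchmark(cfg, seed = 4, levels = 1,
                     methods = c("savgol", "pca"))
  expect_identical(b1$records, b2$records)
  sel <- b1$selected
  expect_setequal(sel$method, c("savgol", "pca"))
  # multivariate denoising clearly outgains single-spectrum smoothing
  expect_gt(sel$snr_gain[sel$method == "pca"],
            sel$snr_gain[sel$method == "savgol"])
  expect_true(all(sel$sd_percent >= 0 & is.finite(sel$sd_percent)))
})
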