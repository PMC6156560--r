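# irdenoise

Benchmarking spectral and spatial denoising for FT-IR hyperspectral
imaging of tissue.

High-definition (HD) FT-IR microscopy images tissue at ~1.1 µm projected
pixels — 25× less light per pixel than the standard 5.5 µm grid, and a
correspondingly worse signal-to-noise ratio.  Denoising can recover much
of that loss, but on experimental data it is impossible to tell how much
*signal* a method destroys while doing so, because no noise-free reference
exists.  `irdenoise` answers this with a simulation-based benchmark for
spectroscopists and imaging methodologists: it generates ground-truth
tissue-core hypercubes bound by realistic experimental parameters, applies
the field's standard denoisers, and scores them against the known truth.

**Simulator.** Three fuzzy component maps (protein / lipid / nucleic-acid
-like) on a perturbed-disk core mask; per component, 16 absorption bands at
the canonical tissue wavenumbers, each a 50:50 Gaussian–Lorentzian mixture

&nbsp;&nbsp;&nbsp;&nbsp;A(ν) = h·[½·exp(−4 ln2 (ν−c)²/w²) + ½/(1 + 4((ν−c)/w)²)]

with per-pixel randomized heights, centers and widths; a wavelength-
dependent Gaussian point-spread blur (FWHM = 0.61 λ/NA); smooth random
linear baselines; and eight noise levels emulating 2–256 co-added scans
with σ(x,ν) = σ_base + σ_rel·clean(x,ν)⁺ and σ_rel ∝ 1/√scans, anchored at
40% relative noise for 2 scans.  5× binning maps the HD grid to the 5.5 µm
standard grid.

**Denoisers.** Spectral: Savitzky–Golay, Fourier low-pass, orthogonal
wavelet shrinkage, PCA reconstruction, minimum noise fraction (MNF =
noise-whitening via the shift-difference covariance, then PCA in whitened
space).  Spatial, per band image: mean, weighted mean, Gaussian, median,
radial 2-D Fourier low-pass, 2-D wavelets — all mask-aware.

**Metrics.** SNR gain (noise = residual SD in the band-free 2150–2080 cm⁻¹
window after slope correction, signal ≡ 1), signal distortion (% of total
signal where |denoised−clean| exceeds the realized added noise), linear
pSNR gain (= MSE(noisy)/MSE(denoised)), SSIM, and Pearson correlation with
the clean spectra.

## Worked example

Simulate the noisiest (2-scan-equivalent) condition on a 64 × 64 HD grid,
denoise with MNF keeping 4 components, and score it:

```r
library(irdenoise)
sim <- simulate_bundles(ir_sim_config(rows = 64, cols = 64), seed = 1,
                        levels = c(1, 8))
b <- sim$hd$level1
den <- mnf_denoise(b$noisy, 4)
evaluate_denoised(b, den, method = "mnf", params = "n_components=4")
```

```
  method     band snr_gain sd_percent pearson_r psnr_gain  ssim
1    mnf spectral       20      0.829     0.997        NA    NA
2    mnf     1650       NA         NA        NA      66.3 0.748
3    mnf     3300       NA         NA        NA      97.8 0.790
```

Read: MNF raised the mean spectral SNR 20-fold over the noisy input while
distorting only 0.83% of the total signal; the denoised spectra correlate
at r = 0.997 with the clean truth; on the amide I (1650 cm⁻¹) and N–H/O–H
stretch (3300 cm⁻¹) band images the mean-squared error dropped 66× and
98×.  The rank sweep shows the usual trade-off — more components readmit
noise:

```r
band_count_sweep(b$noisy, "pca", c(2, 4, 8, 16))
```

```
   k snr_gain
1  2    26.16
2  4    19.87
3  8    13.91
4 16     9.51
```

The full orchestration — sweep every method's parameter grid over all
noise levels, select per-level optima (max SNR gain subject to a 15%
distortion cap, Pearson guard for wavelets), and emit comparison tables
and scatter plots — is one call:

```r
bench <- ir_benchmark(ir_sim_config(), seed = 1)
print(bench)
plot(bench)
report(bench$selected, "results/")
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/irdenoise` (`convert`, `bin`, `simulate`, `denoise`, `evaluate`,
`benchmark`), and cubes can be exchanged with other software as ENVI
(.hdr + float32 BSQ) files via `read_cube()` / `write_cube()`.

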