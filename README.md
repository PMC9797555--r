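# astivol

Depth-resolved reconstruction for **astigmatic wide-field fluorescence
microscopy**, in R.

## The problem and the method

Wide-field fluorescence imaging covers centimetre-scale fields of view at
kilohertz frame rates, but a conventional camera image integrates all
depths. Inserting a weak cylindrical lens between objective and tube lens
splits the focus into **two axially separated focal planes**, one per
lateral axis of the point-spread function (PSF). A point emitter at depth
*z* then images as an elliptical Gaussian

```
f(x, y) = a · exp( −2 (x − x₀)² / wₓ² − 2 (y − y₀)² / w_y² ) + c
```

whose axis widths follow the defocus law
`w(z) = w₀ √(1 + ((z − z_f)/z_R)²)` with different focal depths `z_f` per
axis. The **ellipticity**

```
e = (wₓ − w_y) / (wₓ + w_y)
```

is strictly monotone in *z* between the two focal planes and therefore
encodes depth over several hundred micrometres. Because the quotient
normalises a common broadening of both axes, it is the PSF-shape metric
most robust to scattering blur — more so than the single-axis width.

The package implements everything around this encoding:

- **`astig_optics`** — closed-form astigmatic PSF model
  (`psf_params()`, `psf_widths()`, `ellipticity()`, `render_psf()`,
  `fwhm_from_width()`);
- **`calibration`** — spatially variant ellipticity→depth look-up tables
  from a fluorescent-slide z-stack, one monotone curve per FOV subregion
  (`build_calibration()`, `lookup_depth()`, `compare_depth_metrics()`);
- **`localization`** — adaptive-threshold candidate detection and
  Levenberg–Marquardt elliptical-Gaussian fitting with analytic Jacobian
  (`detect_candidates()`, `fit_elliptical_gaussian()`, `assign_depth()`);
- **`sl_pipeline`** — sparse localization: Hungarian frame-to-frame
  linking with gap closing, 3D/2D velocimetry, compounded depth /
  velocity / density maps (`reconstruct_sl()`);
- **`mi_pipeline`** — multifocal illumination: reference-guided spot
  extraction, digital pinholing, volume compounding and time-to-peak
  perfusion mapping (`record_reference()`, `compound_volume()`,
  `compute_ttp()`, `roi_perfusion_stats()`);
- **`vessel_quant`** — Frangi-based vessel segmentation, skeleton branch
  analysis, fill fraction, and paired t / Cohen's d statistics
  (`quantify_roi()`, `paired_stats()`);
- **`synthetic_scene`** — a full acquisition simulator (phantoms, bead
  flows, perfusion boluses, scanned illumination lattices, Poisson + read
  noise, scattering blur) that exports ground truth for every stage.

Detections, tracks, calibration samples and statistics are tibbles and
compose with the pipe; maps and fitted objects have `autoplot()` methods;
`paired_stats` objects have `tidy()`/`glance()` methods.

## Worked example

Calibrate, simulate a flowing-bead acquisition, and reconstruct:

```r
library(astivol)

psf <- default_psf_params()        # 12.6 um in-focus FWHM, 600 um range
px  <- 5.56                        # um per pixel
cfg <- reference_noise(acquisition_config(162, 162, pixel_size_um = px,
                                      frame_rate_hz = 200, seed = 41))

# depth calibration from a simulated fluorescent-slide z-stack, 50 um
# steps, four jittered exposures per plane
cal <- simulate_calibration_stack(seq(-300, 300, 50), psf,
                                  reference_noise(acquisition_config(
                                    162, 162, pixel_size_um = px, seed = 12)),
                                  spot_grid = c(6, 6), n_exposures = 4)
lut <- build_calibration(cal$stack, cal$z_um, subregions = c(5, 5),
                         pixel_size_um = px)
lut
#> <depth LUT: 5 x 5 subregions, metric 'ellipticity', 0 empty>
#>   sampled depths: -300 .. 300 um (13 planes)

# beads at 2 mm/s through two crossing channels 200 um apart in depth
ph <- make_crossing_channels(separation_um = 200, diameter_um = 40,
                             fov_mm = 162 * px / 1000)
em <- simulate_bead_flow(ph, linear_density_per_mm = 2,
                         speed_range_mm_s = c(2, 2), n_frames = 120,
                         frame_rate_hz = 200, seed = 13)
stack <- simulate_widefield_acquisition(em, psf, cfg)

res <- reconstruct_sl(stack, lut, frame_rate_hz = 200, pixel_size_um = px,
                      max_disp_um = 25, max_gap = 1, use_3d = FALSE)
res$maps
#> <rendered maps 162 x 162 px: 262 occupied pixels>
mean(res$links$speed_mm_s)
#> [1] 2.011942
```

The recovered mean speed (2.01 mm/s, 0.6% from the simulated 2 mm/s) and
the per-pixel depth map come out of one pass over the frames;
`autoplot(res$maps, "depth")` renders the colour-coded depth map.

For the multifocal mode, `simulate_mi_acquisition()` +
`record_reference()` + `compound_volume()` produce a compounded intensity
and depth map per 45 × 45 (or 15 × 15) scan cycle, and
`effective_volume_rate(2250, 225)` gives the 10 Hz volume rate of a
2.25 kHz scan.

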