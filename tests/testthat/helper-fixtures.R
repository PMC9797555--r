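# Shared fixtures, built once per session and cached. All synthetic, all
# seeded; sizes chosen so the whole suite stays desk-scale.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

PX <- 5.56  # um, object-plane pixel pitch used throughout the tests

fx_psf <- function() default_psf_params()

cal_z <- function() seq(-300, 300, by = 50)

# noiseless calibration z-stack, 220 px, 10 x 10 spot grid (>= 4 spots per
# 5 x 5 subregion at every plane)
fx_cal <- function() fx("cal", function() {
  cfg <- acquisition_config(220, 220, pixel_size_um = PX)
  simulate_calibration_stack(cal_z(), fx_psf(), cfg, spot_grid = c(10, 10))
})

fx_lut55 <- function() fx("lut55", function() {
  cal <- fx_cal()
  build_calibration(cal$stack, cal$z_um, c(5, 5), pixel_size_um = PX)
})

fx_lut11 <- function() fx("lut11", function() {
  cal <- fx_cal()
  build_calibration(cal$stack, cal$z_um, c(1, 1), pixel_size_um = PX)
})

# same geometry with smooth field-dependent aberration
fx_aberration <- function() list(zf_amp_um = 80, w0_rel = 0.1)

fx_cal_aber <- function() fx("cal_aber", function() {
  cfg <- acquisition_config(220, 220, pixel_size_um = PX)
  simulate_calibration_stack(cal_z(), fx_psf(), cfg, spot_grid = c(10, 10),
                             aberration = fx_aberration())
})

fx_lut55_aber <- function() fx("lut55_aber", function() {
  cal <- fx_cal_aber()
  build_calibration(cal$stack, cal$z_um, c(5, 5), pixel_size_um = PX)
})

fx_lut11_aber <- function() fx("lut11_aber", function() {
  cal <- fx_cal_aber()
  build_calibration(cal$stack, cal$z_um, c(1, 1), pixel_size_um = PX)
})

# small noiseless stack for the metric-robustness comparison
fx_cal_small <- function() fx("cal_small", function() {
  cfg <- acquisition_config(124, 124, pixel_size_um = PX)
  simulate_calibration_stack(cal_z(), fx_psf(), cfg, spot_grid = c(4, 4))
})

# calibration under the reference noise conditions (bright slide spots,
# jittered exposures per plane as a scanned lattice provides). Dense enough
# that per-subregion curve nodes average ~15 spot fits: the node error
# (~2 um) stays small against the depth-accuracy bounds the tests assert.
fx_cal_noisy <- function() fx("cal_noisy", function() {
  cfg <- reference_noise(acquisition_config(162, 162, pixel_size_um = PX, seed = 12))
  simulate_calibration_stack(cal_z(), fx_psf(), cfg, spot_grid = c(7, 7),
                             n_exposures = 8)
})

fx_lut_noisy <- function() fx("lut_noisy", function() {
  cal <- fx_cal_noisy()
  build_calibration(cal$stack, cal$z_um, c(5, 5), pixel_size_um = PX)
})

# brute-force minimum-cost bipartite matching by permutation enumeration
# (oracle for the assignment solver, n <= 6)
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    cst <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (cst < best) best <- cst
  }
  best
}

# detections of every aberrated calibration plane, localized once
fx_det_aber <- function() fx("det_aber", function() {
  cal <- fx_cal_aber()
  purrr::map(seq_along(cal$z_um), function(f) {
    d <- localize_frame(cal$stack[, , f], PX, 10)
    d <- d[d$flag == "ok", ]
    d$z_true <- cal$z_um[f]
    d
  }) |> dplyr::bind_rows()
})

# mean absolute depth error of the aberrated planes under a given LUT
aber_depth_error <- function(lut) {
  det <- fx_det_aber()
  d <- assign_depth(det, lut)
  keep <- d$flag == "ok"
  mean(abs(d$z_um[keep] - d$z_true[keep]))
}

# PSF-shape-metric robustness table under isotropic blur
fx_metric_table <- function() fx("metric_table", function() {
  cal <- fx_cal_small()
  compare_depth_metrics(cal$stack, cal$z_um, blur_levels_um = c(0, 5, 10),
                        pixel_size_um = PX)
})

# full SL reconstruction of a constant-speed bead flow (2 mm/s, 200 fps,
# reference noise conditions)
fx_sl_run <- function() fx("sl_run", function() {
  p <- fx_psf()
  lut <- fx_lut_noisy()
  n <- 162
  cfg <- reference_noise(acquisition_config(n, n, pixel_size_um = PX,
                                        frame_rate_hz = 200, seed = 41))
  ph <- make_crossing_channels(separation_um = 200, diameter_um = 40,
                               fov_mm = n * PX / 1000)
  em <- simulate_bead_flow(ph, linear_density_per_mm = 2,
                           speed_range_mm_s = c(2, 2), n_frames = 120,
                           frame_rate_hz = 200, seed = 13)
  st <- simulate_widefield_acquisition(em, p, cfg)
  list(stack = st, lut = lut,
       res = reconstruct_sl(st, lut, frame_rate_hz = 200, pixel_size_um = PX,
                            max_disp_um = 25, max_gap = 1, use_3d = FALSE))
})

# full MI reconstruction of the crossing-channels phantom: 50 um channels
# separated by 260 um, 45 x 45 scan, reference noise conditions
crossing_channels_depth_difference <- function(seed) {
  p <- default_psf_params()
  n <- 162
  cfg <- reference_noise(acquisition_config(n, n, pixel_size_um = PX,
                                        frame_rate_hz = 2250,
                                        seed = seed))
  fov_um <- c(n, n) * PX
  scan <- make_scan_pattern(lattice_dim = c(2, 2), scan_dim = c(45, 45),
                            fov_um = fov_um, frame_rate_hz = 2250)
  ph <- make_crossing_channels(separation_um = 260, diameter_um = 50,
                               fov_mm = fov_um / 1000)
  sim <- simulate_mi_acquisition(ph, scan, p, cfg)
  ref <- record_reference(sim$reference, scan, PX)
  cal_cfg <- reference_noise(acquisition_config(n, n, pixel_size_um = PX,
                                            seed = seed + 1))
  cal <- simulate_calibration_stack(seq(-300, 300, 50), p, cal_cfg,
                                    spot_grid = c(6, 6), n_exposures = 4)
  lut <- build_calibration(cal$stack, cal$z_um, c(5, 5), pixel_size_um = PX)
  vol <- compound_volume(sim$acquisition, ref, lut, pinhole_radius_px = 4)
  # assign depth-map pixels to each channel by construction geometry,
  # excluding the crossing neighbourhood
  xc <- fov_um[1] / 2; yc <- fov_um[2] / 2; r <- 25
  xs <- (seq_len(n) - 1) * PX
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  ch_low <- abs(Y - yc) <= r & abs(X - xc) > 3 * r
  ch_high <- abs(X - xc) <= r & abs(Y - yc) > 3 * r
  d_low <- median(vol$depth_um[ch_low], na.rm = TRUE)
  d_high <- median(vol$depth_um[ch_high], na.rm = TRUE)
  list(difference_um = d_high - d_low, volume = vol,
       n_px = sum(!is.na(vol$depth_um[ch_low])) +
              sum(!is.na(vol$depth_um[ch_high])))
}

fx_t2 <- function() fx("t2", function() crossing_channels_depth_difference(11))
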