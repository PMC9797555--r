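# Phantom generators and the synthetic acquisition forward model.

test_that("tilted slide ramps linearly across the FOV", {
  ph <- make_tilted_slide(600, fov_mm = 2)
  ctr <- astivol:::phantom_contributions(ph, 1000, 500)
  expect_equal(ctr$z_um, 0)
  left <- astivol:::phantom_contributions(ph, 0, 500)$z_um
  right <- astivol:::phantom_contributions(ph, 2000, 500)$z_um
  expect_equal(right - left, 600)
  expect_equal(c(left, right), c(-300, 300))
})

test_that("crossing channels sit at +/- separation/2", {
  ph <- make_crossing_channels(260, 50, fov_mm = 2)
  # sample ground truth along both centrelines
  z1 <- sapply(seq(100, 1900, 200), function(x)
    astivol:::phantom_contributions(ph, x, 1000)$z_um[1])
  z2 <- sapply(seq(100, 1900, 200), function(y) {
    ctr <- astivol:::phantom_contributions(ph, 1000, y)
    ctr$z_um[ctr$primitive == 2][1]
  })
  expect_equal(mean(z2, na.rm = TRUE) - mean(z1), 260)
  ph0 <- make_crossing_channels(0, 50, fov_mm = 2)
  expect_equal(ph0$primitives[[1]]$p0[3], 0)
  expect_equal(ph0$primitives[[2]]$p0[3], 0)
})

test_that("vessel tree honours its branch-count contract and seed", {
  ph0 <- make_vessel_tree(0, 300, fov_mm = 1, seed = 4)
  expect_equal(ph0$branch_count, 1)
  expect_length(ph0$primitives, 1)
  ph1 <- make_vessel_tree(1, 300, fov_mm = 1, seed = 4)
  expect_equal(ph1$branch_count, 3)
  expect_length(ph1$primitives, 3)
  expect_equal(ph1$branch_point_count, 1)
  again <- make_vessel_tree(1, 300, fov_mm = 1, seed = 4)
  expect_identical(ph1, again)
  other <- make_vessel_tree(1, 300, fov_mm = 1, seed = 5)
  expect_false(identical(ph1, other))
})

test_that("bead flow advects beads at the sampled speeds", {
  ph <- make_crossing_channels(200, 40, fov_mm = 2)
  em <- simulate_bead_flow(ph, 2, c(2, 2), n_frames = 50, frame_rate_hz = 200,
                           seed = 3)
  # constant speed: every frame-to-frame displacement is v / frame rate
  steps <- em |>
    dplyr::group_by(bead_id) |>
    dplyr::arrange(frame, .by_group = TRUE) |>
    dplyr::summarise(d = list(sqrt(diff(x_um)^2 + diff(y_um)^2 + diff(z_um)^2)),
                     .groups = "drop")
  disp <- unlist(steps$d)
  expect_gt(length(disp), 10)
  expect_equal(disp, rep(2000 / 200, length(disp)), tolerance = 1e-9)
  expect_true(all(em$speed_mm_s == 2))
  # zero density -> empty series
  em0 <- simulate_bead_flow(ph, 0, c(1, 2), 10, 200, seed = 1)
  expect_equal(nrow(em0), 0)
  expect_error(simulate_bead_flow(make_tilted_slide(600, 1), 1, c(1, 2), 10, 200),
               "channel")
})

test_that("bead count per frame is Poisson-consistent with the linear density", {
  ph <- make_crossing_channels(200, 40, fov_mm = 2)
  density <- 3
  em <- simulate_bead_flow(ph, density, c(2, 2), n_frames = 100,
                           frame_rate_hz = 200, seed = 8)
  # expected beads present per frame = density * total channel length (mm)
  expected <- density * 4
  counts <- table(factor(em$frame, levels = 0:99))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected))
})

test_that("perfusion bolus peaks at delay + time constant per branch", {
  ph <- make_crossing_channels(200, 40, fov_mm = 2)
  pf <- simulate_perfusion(ph, delays_s = c(0, 1.5), tau_s = 2,
                           n_frames = 80, volume_rate_hz = 10)
  expect_equal(pf$ttp_truth$ttp_s, c(2, 3.5))
  peak1 <- pf$times_s[which.max(pf$concentration[1, ])]
  peak2 <- pf$times_s[which.max(pf$concentration[2, ])]
  expect_equal(peak1, 2, tolerance = 0.11)
  expect_equal(peak2 - peak1, 1.5, tolerance = 0.11)
  # degenerate flat inflow: TTP is the arrival time (first frame at maximum)
  pf0 <- simulate_perfusion(ph, delays_s = 0.6, tau_s = 0, n_frames = 20,
                            volume_rate_hz = 10)
  expect_equal(pf0$ttp_truth$ttp_s[1], 0.6)
  expect_equal(pf0$times_s[which.max(pf0$concentration[1, ])], 0.6)
})

test_that("wide-field forward model is linear, symmetric and seed-stable", {
  p <- fx_psf()
  cfg <- acquisition_config(60, 60, pixel_size_um = PX, background = 5)
  # no emitters, no noise: constant background
  empty <- tibble::tibble(frame = integer(), x_um = numeric(), y_um = numeric(),
                          z_um = numeric(), intensity = numeric())
  st <- simulate_widefield_acquisition(empty, p, cfg, n_frames = 2)
  expect_true(all(st == 5))
  # a midpoint emitter with symmetric optics fits to ellipticity 0
  em <- tibble::tibble(frame = 0L, x_um = 160, y_um = 170, z_um = 0,
                       intensity = 2e4)
  st1 <- simulate_widefield_acquisition(em, p, cfg, n_frames = 1)
  fit <- fit_elliptical_gaussian(st1[25:45, 22:42, 1], PX)
  expect_lt(abs(fit$ellipticity), 1e-6)
  # doubling intensity doubles the background-subtracted integral
  em2 <- dplyr::mutate(em, intensity = 4e4)
  st2 <- simulate_widefield_acquisition(em2, p, cfg, n_frames = 1)
  expect_equal(sum(st2[, , 1] - 5), 2 * sum(st1[, , 1] - 5), tolerance = 1e-9)
  # fixed seed -> bit-identical noisy stacks
  cfgn <- reference_noise(acquisition_config(60, 60, pixel_size_um = PX, seed = 77))
  a <- simulate_widefield_acquisition(em, p, cfgn, n_frames = 1)
  b <- simulate_widefield_acquisition(em, p, cfgn, n_frames = 1)
  expect_identical(a, b)
})

test_that("MI acquisition illuminates only foci covered by the scene", {
  p <- fx_psf()
  cfg <- acquisition_config(120, 120, pixel_size_um = PX)
  fov_um <- c(120, 120) * PX
  scan <- make_scan_pattern(c(2, 2), c(2, 2), fov_um, 2250)
  # scene with fluorophore only in the left half
  ph <- structure(list(primitives = list(list(
    type = "channel", p0 = c(0, fov_um[2] / 4, 50),
    p1 = c(fov_um[1], fov_um[2] / 4, 50), radius_um = fov_um[2] / 4,
    weight = 1)), fov_um = fov_um), class = "phantom")
  sim <- simulate_mi_acquisition(ph, scan, p, cfg)
  # reference frames contain the full lattice everywhere
  for (k in seq_len(n_scan_positions(scan))) {
    cand <- detect_candidates(sim$reference[, , k], PX)
    expect_equal(nrow(cand), 4)
  }
  # acquisition frames only show spots where the scene emits (top band)
  cand <- detect_candidates(sim$acquisition[, , 1], PX)
  expect_lt(nrow(cand), 4)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$y_um < fov_um[2] / 2))
  # a 15 x 15 scan yields one volume per 225 frames
  scan15 <- make_scan_pattern(c(17, 17), c(15, 15), c(5600, 5600), 2250)
  expect_equal(n_scan_positions(scan15), 225)
})

test_that("phantom geometry serialises to JSON and back", {
  ph <- make_crossing_channels(260, 50, fov_mm = 1.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_json(ph, path)
  back <- read_phantom_json(path)
  expect_equal(back$primitives, ph$primitives)
  expect_equal(back$fov_um, ph$fov_um)
  expect_equal(back$separation_um, ph$separation_um)
})
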