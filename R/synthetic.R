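# Synthetic phantoms and acquisitions. Phantoms are lists of geometric
# primitives (tilted plane, cylindrical channels) with fluorophore-density
# weights; acquisitions render astigmatic PSFs from point emitters or from
# multifocal illumination spots, with Poisson shot noise, Gaussian read
# noise and optional scattering pre-blur.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

new_phantom <- function(primitives, fov_um, ...) {
  structure(list(primitives = primitives, fov_um = fov_um, ...),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  types <- vapply(x$primitives, `[[`, "", "type")
  cat(sprintf("<phantom: %d primitives (%s), FOV %.0f x %.0f um>\n",
              length(types), paste(unique(types), collapse = ", "),
              x$fov_um[1], x$fov_um[2]))
  invisible(x)
}

as_fov_um <- function(fov_mm) {
  fov <- rep(fov_mm, length.out = 2) * 1000
  if (any(fov <= 0)) stop("FOV must be positive", call. = FALSE)
  fov
}

#' Tilted fluorescent slide phantom
#'
#' A plane whose depth ramps linearly along the x axis from `-depth_span/2`
#' at the left FOV edge to `+depth_span/2` at the right edge, providing a
#' continuously varying ground-truth depth for axial-accuracy tests.
#'
#' @param depth_span_um Total depth range across the FOV (um), > 0.
#' @param fov_mm Lateral FOV (mm), scalar or `c(x, y)`.
#' @param weight Fluorophore density weight.
#' @return A `phantom` object.
#' @export
make_tilted_slide <- function(depth_span_um = 600, fov_mm = 5.6, weight = 1) {
  if (depth_span_um <= 0) stop("`depth_span_um` must be > 0", call. = FALSE)
  fov <- as_fov_um(fov_mm)
  prim <- list(type = "plane",
               z0 = -depth_span_um / 2,
               gx = depth_span_um / fov[1], gy = 0,
               weight = weight)
  new_phantom(list(prim), fov, depth_span_um = depth_span_um)
}

#' Crossing microfluidic channels phantom
#'
#' Two straight cylindrical channels crossing in lateral projection, with
#' centrelines axially offset to `z = -separation/2` and `z = +separation/2`.
#' Defaults reproduce the reference phantom: 50 um inner diameter,
#' ~260 um axial separation.
#'
#' @param separation_um Axial centreline separation (um), >= 0.
#' @param diameter_um Channel inner diameter (um), > 0.
#' @param fov_mm Lateral FOV (mm).
#' @param weight Fluorophore density weight.
#' @return A `phantom` whose first primitive is the lower channel (along x)
#'   and second the upper channel (along y).
#' @export
make_crossing_channels <- function(separation_um = 260, diameter_um = 50,
                                   fov_mm = 5.6, weight = 1) {
  if (separation_um < 0) stop("`separation_um` must be >= 0", call. = FALSE)
  if (diameter_um <= 0) stop("`diameter_um` must be > 0", call. = FALSE)
  fov <- as_fov_um(fov_mm)
  r <- diameter_um / 2
  ch1 <- list(type = "channel",
              p0 = c(0, fov[2] / 2, -separation_um / 2),
              p1 = c(fov[1], fov[2] / 2, -separation_um / 2),
              radius_um = r, weight = weight)
  ch2 <- list(type = "channel",
              p0 = c(fov[1] / 2, 0, separation_um / 2),
              p1 = c(fov[1] / 2, fov[2], separation_um / 2),
              radius_um = r, weight = weight)
  new_phantom(list(ch1, ch2), fov, separation_um = separation_um,
              diameter_um = diameter_um)
}

#' Random branching vessel-tree phantom
#'
#' Grows a binary tree of straight cylindrical segments from the left FOV
#' edge. Each of the `n_branch_points` bifurcations splits one growing tip
#' into two, so the ground-truth branch count is `2 * n_branch_points + 1`.
#' Segment depths are drawn within `+/- depth_span_um / 2`.
#'
#' @param n_branch_points Number of bifurcations, >= 0.
#' @param depth_span_um Axial extent of the tree (um).
#' @param fov_mm Lateral FOV (mm).
#' @param radius_um Segment radius (um).
#' @param seed Integer seed; same seed gives identical geometry.
#' @return A `phantom` with attributes `branch_count` and
#'   `branch_point_count` in its list fields.
#' @export
make_vessel_tree <- function(n_branch_points = 3, depth_span_um = 400,
                             fov_mm = 2, radius_um = 15, seed = 1) {
  if (n_branch_points < 0) stop("`n_branch_points` must be >= 0", call. = FALSE)
  fov <- as_fov_um(fov_mm)
  with_seed(seed, {
    margin <- 0.06 * fov
    zlim <- depth_span_um / 2
    seg_len <- (fov[1] - 2 * margin[1]) / (n_branch_points + 1)
    root <- list(
      pos = c(margin[1], fov[2] / 2, runif(1, -zlim / 2, zlim / 2)),
      dir = c(1, 0)
    )
    tips <- list(root)
    segments <- list()
    grow <- function(tip, dtheta) {
      th <- atan2(tip$dir[2], tip$dir[1]) + dtheta
      d <- c(cos(th), sin(th))
      p1 <- tip$pos[1:2] + d * seg_len
      p1 <- clamp(p1, margin, fov - margin)
      z1 <- clamp(tip$pos[3] + runif(1, -0.35, 0.35) * zlim, -zlim, zlim)
      list(pos = c(p1, z1), dir = d, from = tip$pos)
    }
    # root segment first
    t0 <- grow(root, 0)
    segments[[1]] <- list(type = "channel", p0 = root$pos, p1 = t0$pos,
                          radius_um = radius_um, weight = 1)
    tips <- list(t0)
    for (b in seq_len(n_branch_points)) {
      i <- sample.int(length(tips), 1)
      tip <- tips[[i]]
      tips[[i]] <- NULL
      for (dtheta in c(-1, 1) * runif(1, 0.35, 0.7)) {
        child <- grow(tip, dtheta)
        segments[[length(segments) + 1]] <-
          list(type = "channel", p0 = tip$pos, p1 = child$pos,
               radius_um = radius_um * 0.85, weight = 1)
        tips[[length(tips) + 1]] <- child
      }
    }
    new_phantom(segments, fov,
                branch_count = 2 * n_branch_points + 1,
                branch_point_count = n_branch_points,
                depth_span_um = depth_span_um)
  })
}

# Fluorophore contributions of a phantom at a lateral position.
# Returns a tibble (primitive, weight, z_um); zero rows where nothing emits.
phantom_contributions <- function(phantom, x_um, y_um) {
  rows <- purrr::imap(phantom$primitives, function(pr, i) {
    if (pr$type == "plane") {
      return(tibble::tibble(primitive = i, weight = pr$weight,
                            z_um = pr$z0 + pr$gx * x_um + pr$gy * y_um))
    }
    if (pr$type == "channel") {
      a <- pr$p0; b <- pr$p1
      ab <- b[1:2] - a[1:2]
      len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else clamp(sum((c(x_um, y_um) - a[1:2]) * ab) / len2, 0, 1)
      foot <- a[1:2] + t * ab
      d <- sqrt(sum((c(x_um, y_um) - foot)^2))
      if (d > pr$radius_um) return(NULL)
      # chord-length weighting: thicker emission column towards the axis
      w <- pr$weight * sqrt(max(0, 1 - (d / pr$radius_um)^2))
      return(tibble::tibble(primitive = i, weight = w,
                            z_um = a[3] + t * (b[3] - a[3])))
    }
    NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    tibble::tibble(primitive = integer(), weight = numeric(), z_um = numeric())
  } else {
    out
  }
}

#' Acquisition and camera-noise configuration
#'
#' @param ny_px,nx_px Frame size (pixels), > 0.
#' @param pixel_size_um Object-plane pixel pitch (um); the default 5.56
#'   corresponds to a 5.6 mm FOV across 1008 pixels.
#' @param frame_rate_hz Camera frame rate (Hz).
#' @param background Constant background level (counts).
#' @param shot_noise Apply Poisson shot noise to signal + background.
#' @param read_noise_sd SD of additive Gaussian read noise (counts).
#' @param scatter_blur_um SD of the isotropic Gaussian scattering pre-blur
#'   (um, 0 disables).
#' @param seed Integer seed; fixed seed gives bit-identical stacks.
#' @return An object of class `acq_config`.
#' @export
acquisition_config <- function(ny_px, nx_px, pixel_size_um = 5.56,
                               frame_rate_hz = 200, background = 0,
                               shot_noise = FALSE, read_noise_sd = 0,
                               scatter_blur_um = 0, seed = NULL) {
  if (ny_px < 1 || nx_px < 1) stop("image size must be positive", call. = FALSE)
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0", call. = FALSE)
  structure(list(ny_px = as.integer(ny_px), nx_px = as.integer(nx_px),
                 pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
                 background = background, shot_noise = shot_noise,
                 read_noise_sd = read_noise_sd,
                 scatter_blur_um = scatter_blur_um, seed = seed),
            class = "acq_config")
}

#' Noise settings emulating the reference acquisitions
#'
#' Applies Poisson shot noise on signal plus a 20-count background and
#' 3 counts RMS read noise to an existing configuration.
#'
#' @param cfg An [acquisition_config()].
#' @return The modified configuration.
#' @export
reference_noise <- function(cfg) {
  cfg$background <- 20
  cfg$shot_noise <- TRUE
  cfg$read_noise_sd <- 3
  cfg
}

# Add one elliptical Gaussian into `frame` in place-ish (returns updated frame),
# evaluating only within +/- 4 widths of the centre.
add_psf_to_frame <- function(frame, a, x0, y0, wx, wy, pixel_size_um) {
  ny <- nrow(frame); nx <- ncol(frame)
  half <- 4 * max(wx, wy)
  c0 <- um_to_px(x0 - half, pixel_size_um); c1 <- um_to_px(x0 + half, pixel_size_um)
  r0 <- um_to_px(y0 - half, pixel_size_um); r1 <- um_to_px(y0 + half, pixel_size_um)
  cols <- max(1, c0):min(nx, c1)
  rows <- max(1, r0):min(ny, r1)
  if (length(cols) == 0 || length(rows) == 0 ||
      max(1, c0) > min(nx, c1) || max(1, r0) > min(ny, r1)) return(frame)
  x_um <- px_to_um(cols, pixel_size_um)
  y_um <- px_to_um(rows, pixel_size_um)
  frame[rows, cols] <- frame[rows, cols] +
    eval_elliptical_gaussian(a, x0, y0, wx, wy, 0, x_um, y_um)
  frame
}

# Camera model: scattering blur, shot noise, read noise. Operates per frame.
apply_camera <- function(frame, cfg) {
  if (cfg$scatter_blur_um > 0) {
    frame <- blur_matrix(frame, cfg$scatter_blur_um / cfg$pixel_size_um)
  }
  frame <- frame + cfg$background
  if (cfg$shot_noise) {
    frame[] <- rpois(length(frame), lambda = pmax(frame, 0))
  }
  if (cfg$read_noise_sd > 0) {
    frame <- frame + rnorm(length(frame), 0, cfg$read_noise_sd)
  }
  frame
}

#' Simulate flowing beads along the channels of a phantom
#'
#' Beads are advected along channel centrelines at constant per-bead speeds
#' drawn uniformly from `speed_range_mm_s`. Bead arrivals form a stationary
#' Poisson process so the expected number present per frame is
#' `linear_density_per_mm * channel length (mm)`.
#'
#' @param phantom A `phantom` containing at least one channel primitive.
#' @param linear_density_per_mm Expected beads per mm of channel.
#' @param speed_range_mm_s Length-2 speed range (mm/s).
#' @param n_frames Number of frames, >= 1.
#' @param frame_rate_hz Frame rate (Hz), > 0.
#' @param intensity Integrated counts per bead (constant per bead).
#' @param seed Integer seed.
#' @return A tibble (class `emitter_series`) with columns `frame` (0-based),
#'   `bead_id`, `x_um`, `y_um`, `z_um`, `intensity`, `speed_mm_s`, and
#'   attributes `frame_rate_hz`, `n_frames`.
#' @export
simulate_bead_flow <- function(phantom, linear_density_per_mm, speed_range_mm_s,
                               n_frames, frame_rate_hz, intensity = 2e4,
                               seed = 1) {
  channels <- purrr::keep(phantom$primitives, ~ .x$type == "channel")
  if (length(channels) == 0) {
    stop("phantom has no channel primitives to carry beads", call. = FALSE)
  }
  if (frame_rate_hz <= 0 || n_frames < 1) {
    stop("`frame_rate_hz` must be > 0 and `n_frames` >= 1", call. = FALSE)
  }
  T_s <- n_frames / frame_rate_hz
  vbar <- mean(speed_range_mm_s) * 1000  # um/s
  with_seed(seed, {
    rows <- purrr::imap(channels, function(ch, ci) {
      L <- sqrt(sum((ch$p1 - ch$p0)^2))
      n_beads <- rpois(1, linear_density_per_mm * (L + vbar * T_s) / 1000)
      if (n_beads == 0) return(NULL)
      v <- runif(n_beads, speed_range_mm_s[1], speed_range_mm_s[2]) * 1000
      s0 <- runif(n_beads, -v * T_s, L)
      purrr::map(seq_len(n_beads), function(b) {
        t_frames <- (seq_len(n_frames) - 1) / frame_rate_hz
        s <- s0[b] + v[b] * t_frames
        keep <- s >= 0 & s <= L
        if (!any(keep)) return(NULL)
        tt <- s[keep] / L
        tibble::tibble(
          frame = which(keep) - 1L,
          bead_id = sprintf("c%d_b%d", ci, b),
          x_um = ch$p0[1] + tt * (ch$p1[1] - ch$p0[1]),
          y_um = ch$p0[2] + tt * (ch$p1[2] - ch$p0[2]),
          z_um = ch$p0[3] + tt * (ch$p1[3] - ch$p0[3]),
          intensity = intensity,
          speed_mm_s = v[b] / 1000
        )
      }) |> dplyr::bind_rows()
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      out <- tibble::tibble(frame = integer(), bead_id = character(),
                            x_um = numeric(), y_um = numeric(), z_um = numeric(),
                            intensity = numeric(), speed_mm_s = numeric())
    }
    out <- dplyr::arrange(out, .data$frame, .data$bead_id)
    structure(out, frame_rate_hz = frame_rate_hz, n_frames = as.integer(n_frames),
              class = c("emitter_series", class(out)))
  })
}

#' Simulate a dye-perfusion bolus through phantom branches
#'
#' Each channel primitive receives a gamma-variate inflow curve
#' `((t - d)/tp)^2 * exp(2 (1 - (t - d)/tp))` peaking (value 1) at
#' `t = d + tp`, where `d` is the branch arrival delay and `tp` the inflow
#' time constant. A zero time constant degenerates to a step, whose
#' time-to-peak is defined as the first frame at maximum.
#'
#' @param phantom A `phantom`; one delay per primitive.
#' @param delays_s Numeric vector of arrival delays (s), recycled.
#' @param tau_s Inflow time-to-peak constant (s), >= 0.
#' @param n_frames Number of volumes, >= 1.
#' @param volume_rate_hz Volume rate (Hz), > 0.
#' @return A list of class `perfusion_series`: `concentration` (primitives x
#'   frames), `times_s`, and `ttp_truth` tibble (`primitive`, `ttp_s`).
#' @export
simulate_perfusion <- function(phantom, delays_s, tau_s, n_frames,
                               volume_rate_hz) {
  if (volume_rate_hz <= 0) stop("`volume_rate_hz` must be > 0", call. = FALSE)
  np <- length(phantom$primitives)
  delays_s <- rep(delays_s, length.out = np)
  times <- (seq_len(n_frames) - 1) / volume_rate_hz
  conc <- matrix(0, np, n_frames)
  for (i in seq_len(np)) {
    u <- times - delays_s[i]
    conc[i, ] <- if (tau_s > 0) {
      ifelse(u > 0, (u / tau_s)^2 * exp(2 * (1 - u / tau_s)), 0)
    } else {
      as.numeric(u >= 0)
    }
  }
  structure(list(
    concentration = conc,
    times_s = times,
    ttp_truth = tibble::tibble(primitive = seq_len(np),
                               ttp_s = delays_s + tau_s)
  ), class = "perfusion_series")
}

#' Render a wide-field acquisition from point emitters
#'
#' Each frame is the sum of astigmatic elliptical-Gaussian PSFs at the
#' emitter positions (widths from the defocus law at each emitter's depth,
#' peak amplitude `2 * intensity / (pi * wx * wy)` so integrated counts are
#' conserved under defocus), plus background, optional scattering blur, and
#' Poisson/Gaussian camera noise.
#'
#' @param emitters An `emitter_series` tibble (columns `frame`, `x_um`,
#'   `y_um`, `z_um`, `intensity`; frame 0-based).
#' @param psf A [psf_params()] object.
#' @param cfg An [acquisition_config()].
#' @param n_frames Number of frames; defaults to the series' attribute.
#' @param aberration Optional field-dependent aberration, a list with
#'   `zf_amp_um` and/or `w0_rel` (see the calibration vignette).
#' @return A 3D array `[ny, nx, n_frames]` of counts with attribute `config`.
#' @export
simulate_widefield_acquisition <- function(emitters, psf, cfg,
                                           n_frames = NULL, aberration = NULL) {
  n_frames <- n_frames %||% attr(emitters, "n_frames") %||%
    (if (nrow(emitters) > 0) max(emitters$frame) + 1L else 1L)
  stack <- array(0, dim = c(cfg$ny_px, cfg$nx_px, n_frames))
  fov <- c(cfg$nx_px, cfg$ny_px) * cfg$pixel_size_um
  with_seed(cfg$seed, {
    for (f in seq_len(n_frames)) {
      fr <- matrix(0, cfg$ny_px, cfg$nx_px)
      em <- emitters[emitters$frame == (f - 1L), , drop = FALSE]
      if (nrow(em) > 0) {
        for (i in seq_len(nrow(em))) {
          p <- psf_at_position(psf, em$x_um[i], em$y_um[i], fov, aberration)
          w <- psf_widths(p, em$z_um[i])
          a <- 2 * em$intensity[i] / (pi * w$wx_um * w$wy_um)
          fr <- add_psf_to_frame(fr, a, em$x_um[i], em$y_um[i],
                                 w$wx_um, w$wy_um, cfg$pixel_size_um)
        }
      }
      stack[, , f] <- apply_camera(fr, cfg)
    }
  })
  attr(stack, "config") <- cfg
  stack
}

#' Multifocal scan pattern
#'
#' A base lattice of illumination foci (`lattice_dim` spots spanning the
#' FOV) raster-scanned over `scan_dim` positions; each scan step translates
#' the whole lattice by `pitch / scan_dim`, so one complete volume consumes
#' `prod(scan_dim)` frames.
#'
#' @param lattice_dim `c(nx, ny)` spots in the base lattice.
#' @param scan_dim `c(nx, ny)` scan positions.
#' @param fov_um Lateral FOV `c(x, y)` in um.
#' @param frame_rate_hz Scanning/camera frame rate (Hz).
#' @return An object of class `scan_pattern`.
#' @export
make_scan_pattern <- function(lattice_dim = c(17, 17), scan_dim = c(15, 15),
                              fov_um = c(5600, 5600), frame_rate_hz = 2250) {
  if (any(lattice_dim < 1) || any(scan_dim < 1)) {
    stop("lattice and scan dimensions must be >= 1", call. = FALSE)
  }
  fov_um <- rep(fov_um, length.out = 2)
  pitch <- fov_um / lattice_dim
  lattice <- tidyr::expand_grid(
    iy = seq_len(lattice_dim[2]), ix = seq_len(lattice_dim[1])
  ) |>
    dplyr::mutate(x_um = (.data$ix - 1) * pitch[1] + pitch[1] / (2 * scan_dim[1]),
                  y_um = (.data$iy - 1) * pitch[2] + pitch[2] / (2 * scan_dim[2])) |>
    dplyr::select("x_um", "y_um")
  offsets <- tidyr::expand_grid(
    sy = seq_len(scan_dim[2]) - 1, sx = seq_len(scan_dim[1]) - 1
  ) |>
    dplyr::mutate(dx_um = .data$sx * pitch[1] / scan_dim[1],
                  dy_um = .data$sy * pitch[2] / scan_dim[2]) |>
    dplyr::select("dx_um", "dy_um")
  structure(list(lattice = lattice, offsets = offsets,
                 lattice_dim = as.integer(lattice_dim),
                 scan_dim = as.integer(scan_dim),
                 pitch_um = pitch, fov_um = fov_um,
                 frame_rate_hz = frame_rate_hz),
            class = "scan_pattern")
}

#' Number of scan positions in a pattern
#' @param scan A [make_scan_pattern()] object.
#' @return Integer count of scan positions (frames per volume).
#' @export
n_scan_positions <- function(scan) nrow(scan$offsets)

#' Illumination focus coordinates at one scan position
#' @param scan A [make_scan_pattern()] object.
#' @param position Scan position index, 1-based.
#' @return Tibble with `x_um`, `y_um`, one row per lattice spot.
#' @export
scan_spot_positions <- function(scan, position) {
  off <- scan$offsets[position, ]
  tibble::tibble(x_um = scan$lattice$x_um + off$dx_um,
                 y_um = scan$lattice$y_um + off$dy_um)
}

#' Simulate a multifocal-illumination acquisition plus its reference
#'
#' For each scan position, emission arises only at the illuminated foci,
#' weighted by the local fluorophore density of the scene (optionally
#' modulated over volumes by a perfusion series). The reference stack is
#' the identical scan recorded on a uniformly fluorescent slide at
#' `reference_z_um`.
#'
#' @param phantom Scene `phantom` (or NULL for reference-only).
#' @param scan A [make_scan_pattern()].
#' @param psf A [psf_params()].
#' @param cfg An [acquisition_config()]; frame size must cover the scan FOV.
#' @param n_volumes Number of complete scan cycles.
#' @param perfusion Optional [simulate_perfusion()] result; column v of its
#'   concentration matrix scales primitive densities during volume v.
#' @param spot_intensity Integrated counts of a fully illuminated focus.
#' @param reference_z_um Depth of the uniform reference slide (um).
#' @param aberration Optional field-dependent aberration (see
#'   [simulate_widefield_acquisition()]).
#' @return List with `acquisition` (`[ny, nx, n_volumes * P]` array),
#'   `reference` (`[ny, nx, P]` array), and `scan`.
#' @export
simulate_mi_acquisition <- function(phantom, scan, psf, cfg, n_volumes = 1,
                                    perfusion = NULL, spot_intensity = 2e4,
                                    reference_z_um = 0, aberration = NULL) {
  P <- n_scan_positions(scan)
  if (P == 0) stop("scan pattern is empty", call. = FALSE)
  fov <- c(cfg$nx_px, cfg$ny_px) * cfg$pixel_size_um

  render_frame <- function(spots_df) {
    fr <- matrix(0, cfg$ny_px, cfg$nx_px)
    if (nrow(spots_df) > 0) {
      for (i in seq_len(nrow(spots_df))) {
        p <- psf_at_position(psf, spots_df$x_um[i], spots_df$y_um[i], fov, aberration)
        w <- psf_widths(p, spots_df$z_um[i])
        a <- 2 * spots_df$intensity[i] / (pi * w$wx_um * w$wy_um)
        fr <- add_psf_to_frame(fr, a, spots_df$x_um[i], spots_df$y_um[i],
                               w$wx_um, w$wy_um, cfg$pixel_size_um)
      }
    }
    apply_camera(fr, cfg)
  }

  acq <- NULL
  if (!is.null(phantom)) {
    acq <- array(0, dim = c(cfg$ny_px, cfg$nx_px, n_volumes * P))
    with_seed(cfg$seed, {
      for (v in seq_len(n_volumes)) {
        for (k in seq_len(P)) {
          foci <- scan_spot_positions(scan, k)
          spots <- purrr::map(seq_len(nrow(foci)), function(i) {
            contrib <- phantom_contributions(phantom, foci$x_um[i], foci$y_um[i])
            if (nrow(contrib) == 0) return(NULL)
            if (!is.null(perfusion)) {
              contrib$weight <- contrib$weight *
                perfusion$concentration[contrib$primitive, v]
            }
            contrib <- contrib[contrib$weight > 0, , drop = FALSE]
            if (nrow(contrib) == 0) return(NULL)
            tibble::tibble(x_um = foci$x_um[i], y_um = foci$y_um[i],
                           z_um = contrib$z_um,
                           intensity = spot_intensity * contrib$weight)
          }) |> dplyr::bind_rows()
          acq[, , (v - 1) * P + k] <- render_frame(spots)
        }
      }
    })
    attr(acq, "config") <- cfg
  }

  ref <- array(0, dim = c(cfg$ny_px, cfg$nx_px, P))
  ref_seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 1L
  with_seed(ref_seed, {
    for (k in seq_len(P)) {
      foci <- scan_spot_positions(scan, k)
      spots <- dplyr::mutate(foci, z_um = reference_z_um,
                             intensity = spot_intensity)
      ref[, , k] <- render_frame(spots)
    }
  })
  attr(ref, "config") <- cfg

  list(acquisition = acq, reference = ref, scan = scan)
}

#' Simulate the depth-calibration z-stack of a uniform fluorescent slide
#'
#' Renders a grid of illumination spots on a uniform slide at each
#' commanded z position - the input expected by [build_calibration()].
#' The calibration slide is a bright, high-SNR target (unlike in vivo
#' emitters), hence the higher default intensity. With `n_exposures > 1`
#' each plane is recorded several times with the spot grid laterally
#' jittered by sub-pitch offsets, accumulating more calibration spots per
#' FOV subregion, as a scanned illumination lattice does.
#'
#' @param z_um Vector of slide depths (um), one per plane.
#' @param psf A [psf_params()].
#' @param cfg An [acquisition_config()].
#' @param spot_grid `c(nx, ny)` spots spanning the frame.
#' @param spot_intensity Integrated counts per spot.
#' @param n_exposures Frames recorded per plane (grid jittered between
#'   exposures).
#' @param aberration Optional field-dependent aberration.
#' @return List: `stack` (`[ny, nx, length(z_um) * n_exposures]`), `z_um`
#'   (per frame), `spots` tibble (base grid).
#' @export
simulate_calibration_stack <- function(z_um, psf, cfg, spot_grid = c(10, 10),
                                       spot_intensity = 1e5, n_exposures = 1,
                                       aberration = NULL) {
  fov <- c(cfg$nx_px, cfg$ny_px) * cfg$pixel_size_um
  pitch <- fov / spot_grid
  spots <- tidyr::expand_grid(iy = seq_len(spot_grid[2]),
                              ix = seq_len(spot_grid[1])) |>
    dplyr::mutate(x_um = (.data$ix - 0.5) * pitch[1],
                  y_um = (.data$iy - 0.5) * pitch[2]) |>
    dplyr::select("x_um", "y_um")
  k <- ceiling(sqrt(n_exposures))
  z_frames <- rep(z_um, each = n_exposures)
  emitters <- purrr::map(seq_along(z_frames), function(f) {
    e <- (f - 1L) %% n_exposures
    dx <- ((e %% k) - (k - 1) / 2) * pitch[1] / (2 * k)
    dy <- ((e %/% k) - (k - 1) / 2) * pitch[2] / (2 * k)
    dplyr::mutate(spots, x_um = .data$x_um + dx, y_um = .data$y_um + dy,
                  frame = f - 1L, z_um = z_frames[f],
                  intensity = spot_intensity)
  }) |> dplyr::bind_rows()
  stack <- simulate_widefield_acquisition(emitters, psf, cfg,
                                          n_frames = length(z_frames),
                                          aberration = aberration)
  list(stack = stack, z_um = z_frames, spots = spots)
}

#' Serialise a phantom to JSON
#'
#' Geometry and ground-truth metadata (branch counts, separations) with
#' explicit field names and micrometre units.
#'
#' @param phantom A `phantom`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  jsonlite::write_json(unclass(phantom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom from JSON
#' @param path File written by [write_phantom_json()].
#' @return A `phantom` object.
#' @export
read_phantom_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  prims <- purrr::map(p$primitives, function(pr) {
    out <- list(type = pr$type)
    for (f in setdiff(names(pr), "type")) {
      out[[f]] <- as.numeric(unlist(pr[[f]]))
    }
    out
  })
  extra <- purrr::map(p[setdiff(names(p), c("primitives", "fov_um"))],
                      function(v) if (is.numeric(unlist(v)) || is.null(v))
                        as.numeric(unlist(v)) else unlist(v))
  do.call(new_phantom,
          c(list(primitives = prims, fov_um = as.numeric(unlist(p$fov_um))),
            extra))
}

#' Rasterize a phantom to a fluorophore-density map
#'
#' Projects the phantom's primitives onto the pixel raster: planes
#' contribute their weight everywhere, channels contribute their
#' chord-weighted density within one radius of the projected centreline.
#' Useful as a noise-free intensity map for segmentation tests.
#'
#' @param phantom A `phantom`.
#' @param ny_px,nx_px Raster size (pixels).
#' @param pixel_size_um Pixel pitch (um).
#' @return Numeric matrix `ny_px x nx_px`.
#' @export
phantom_density_map <- function(phantom, ny_px, nx_px, pixel_size_um) {
  xs <- px_to_um(seq_len(nx_px), pixel_size_um)
  ys <- px_to_um(seq_len(ny_px), pixel_size_um)
  X <- matrix(xs, ny_px, nx_px, byrow = TRUE)
  Y <- matrix(ys, ny_px, nx_px)
  out <- matrix(0, ny_px, nx_px)
  for (pr in phantom$primitives) {
    if (pr$type == "plane") {
      out <- out + pr$weight
    } else if (pr$type == "channel") {
      a <- pr$p0; b <- pr$p1
      ab <- b[1:2] - a[1:2]
      len2 <- sum(ab^2)
      t <- if (len2 == 0) {
        matrix(0, ny_px, nx_px)
      } else {
        clamp(((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2, 0, 1)
      }
      d2 <- (X - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2
      w <- pr$weight * sqrt(pmax(0, 1 - d2 / pr$radius_um^2))
      out <- out + w
    }
  }
  out
}
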