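# Multifocal-illumination reconstruction: localize the scanned lattice of
# excitation foci against a reference recorded on a uniform slide, fit each
# present spot's astigmatic PSF for depth, reject cross-talk with a digital
# pinhole, and superimpose all filtered frames into a compounded volume.
# A sequence of compounded volumes feeds the time-to-peak perfusion map.

#' Effective volume rate of a scanned acquisition
#'
#' One compounded volume consumes one frame per scan position, so the
#' volume rate is `frame_rate / scan_positions` (2250 Hz with a 15 x 15
#' scan gives 10 Hz).
#'
#' @param frame_rate_hz Camera/AOD frame rate (Hz).
#' @param scan_positions Number of scan positions, >= 1.
#' @return Volume rate (Hz).
#' @export
effective_volume_rate <- function(frame_rate_hz, scan_positions) {
  if (scan_positions < 1) stop("`scan_positions` must be >= 1", call. = FALSE)
  frame_rate_hz / scan_positions
}

#' Record the illumination reference pattern
#'
#' Localizes every lattice spot in each frame of a uniform-slide scan
#' (one frame per scan position). A frame yielding fewer than 90% of the
#' expected lattice spots is an error naming the scan position.
#'
#' @param reference_stack Stack with one frame per scan position.
#' @param scan A [make_scan_pattern()] describing the acquisition.
#' @param pixel_size_um Pixel pitch (um).
#' @param threshold_k,min_area Candidate-detection settings.
#' @return Object of class `reference_pattern`: tibble `spots`
#'   (`position`, `spot_id`, `x_um`, `y_um`, `x_px`, `y_px`), the `scan`,
#'   and `n_expected` spots per frame.
#' @export
record_reference <- function(reference_stack, scan, pixel_size_um = 5.56,
                             threshold_k = 4, min_area = 4) {
  reference_stack <- as_stack(reference_stack)
  P <- n_scan_positions(scan)
  if (dim(reference_stack)[3] != P) {
    stop("reference stack must have one frame per scan position (",
         P, "), got ", dim(reference_stack)[3], call. = FALSE)
  }
  n_expected <- nrow(scan$lattice)
  spots <- purrr::map(seq_len(P), function(k) {
    fr <- reference_stack[, , k]
    cand <- detect_candidates(fr - median(fr), pixel_size_um,
                              threshold_k, min_area)
    if (nrow(cand) < 0.9 * n_expected) {
      stop(sprintf(
        "scan position %d: only %d of %d expected illumination spots found",
        k, nrow(cand), n_expected), call. = FALSE)
    }
    dplyr::mutate(cand, position = k, spot_id = dplyr::row_number())
  }) |> dplyr::bind_rows()
  structure(list(spots = spots, scan = scan, n_expected = n_expected,
                 pixel_size_um = pixel_size_um),
            class = "reference_pattern")
}

#' @export
print.reference_pattern <- function(x, ...) {
  cat(sprintf("<reference pattern: %d scan positions x %d spots>\n",
              n_scan_positions(x$scan), x$n_expected))
  invisible(x)
}

#' Localize illumination spots in one acquisition frame
#'
#' For every pre-recorded reference spot of the scan position, searches for
#' the local maximum within `search_radius_px` of the reference position
#' and accepts it if above the adaptive threshold
#' `median + threshold_k * robust SD` of the frame. Spots dark in the scene
#' are reported absent, not errors.
#'
#' @param frame Raw acquisition frame (matrix).
#' @param ref_spots Reference spots of this scan position (tibble with
#'   `x_px`, `y_px`, `spot_id`).
#' @param pixel_size_um Pixel pitch (um).
#' @param search_radius_px Search radius around each reference position.
#' @param threshold_k Adaptive threshold in robust SDs.
#' @return Tibble: `spot_id`, `present`, `x_px`, `y_px`, `x_um`, `y_um`,
#'   `peak`.
#' @export
localize_spots <- function(frame, ref_spots, pixel_size_um = 5.56,
                           search_radius_px = 4, threshold_k = 4) {
  thr <- adaptive_threshold(frame, threshold_k)
  ny <- nrow(frame); nx <- ncol(frame)
  purrr::map(seq_len(nrow(ref_spots)), function(i) {
    r <- round(ref_spots$y_px[i]); c <- round(ref_spots$x_px[i])
    rr <- max(1, r - search_radius_px):min(ny, r + search_radius_px)
    cc <- max(1, c - search_radius_px):min(nx, c + search_radius_px)
    win <- frame[rr, cc, drop = FALSE]
    pk <- which.max(win)
    pr <- rr[((pk - 1) %% length(rr)) + 1]
    pc <- cc[((pk - 1) %/% length(rr)) + 1]
    present <- frame[pr, pc] > thr
    tibble::tibble(
      spot_id = ref_spots$spot_id[i], present = present,
      x_px = if (present) pc else NA_real_,
      y_px = if (present) pr else NA_real_,
      x_um = if (present) (pc - 1) * pixel_size_um else NA_real_,
      y_um = if (present) (pr - 1) * pixel_size_um else NA_real_,
      peak = frame[pr, pc]
    )
  }) |> dplyr::bind_rows()
}

#' Apply a digital pinhole to a subimage
#'
#' Zeroes every pixel outside the disc of `radius_px` pixels about
#' `center_px`, rejecting cross-talk from adjacent emitters and
#' out-of-focus light; pixels inside are unchanged.
#'
#' @param sub Numeric matrix.
#' @param center_px `c(row, col)` of the pinhole centre (1-based, may be
#'   fractional).
#' @param radius_px Pinhole radius (pixels), > 0.
#' @return The masked matrix.
#' @export
apply_digital_pinhole <- function(sub, center_px, radius_px) {
  if (radius_px <= 0) stop("`radius_px` must be > 0", call. = FALSE)
  rr <- matrix(seq_len(nrow(sub)), nrow(sub), ncol(sub))
  cc <- matrix(seq_len(ncol(sub)), nrow(sub), ncol(sub), byrow = TRUE)
  sub[(rr - center_px[1])^2 + (cc - center_px[2])^2 > radius_px^2] <- 0
  sub
}

#' Compound one scan cycle into a volume
#'
#' The three-step MI reconstruction: (1) localize each illumination spot
#' against its reference position, (2) fit the elliptical Gaussian and map
#' ellipticity to depth through the spatially variant LUT (subregion chosen
#' by the spot's position), (3) apply the digital pinhole about the
#' localized centre and superimpose all filtered frames. The depth map is
#' the per-pixel amplitude-weighted mean of contributing spot depths.
#'
#' @param frames Stack of one scan cycle (`[ny, nx, P]`, frame count must
#'   equal the scan positions of the reference).
#' @param reference A [record_reference()] pattern.
#' @param lut A [build_calibration()] LUT.
#' @param pinhole_radius_px Digital pinhole radius (pixels); default 1.5x
#'   the in-focus PSF half-width is a good choice.
#' @param window_halfwidth_px Fit window half-width (pixels).
#' @param search_radius_px,threshold_k Spot-localization settings.
#' @return Object of class `compounded_volume`: `intensity`, `depth_um`
#'   (NA where no signal), `weight` (depth-weight map), `n_spots`, and
#'   per-spot `spot_table`.
#' @export
compound_volume <- function(frames, reference, lut, pinhole_radius_px = 4,
                            window_halfwidth_px = 10, search_radius_px = 4,
                            threshold_k = 4) {
  frames <- as_stack(frames)
  P <- n_scan_positions(reference$scan)
  if (dim(frames)[3] != P) {
    stop("scan cycle must contain exactly ", P, " frames, got ",
         dim(frames)[3], call. = FALSE)
  }
  px <- reference$pixel_size_um
  ny <- dim(frames)[1]; nx <- dim(frames)[2]
  intensity <- matrix(0, ny, nx)
  zw <- matrix(0, ny, nx)  # sum of weight * z
  wsum <- matrix(0, ny, nx)
  hw <- as.integer(window_halfwidth_px)
  spot_rows <- list()

  for (k in seq_len(P)) {
    fr <- frames[, , k]
    bg <- median(fr)
    fr0 <- fr - bg
    refk <- reference$spots[reference$spots$position == k, , drop = FALSE]
    spots <- localize_spots(fr, refk, px, search_radius_px, threshold_k)
    spots <- spots[spots$present, , drop = FALSE]
    if (nrow(spots) == 0) next
    for (i in seq_len(nrow(spots))) {
      r <- round(spots$y_px[i]); c <- round(spots$x_px[i])
      r0 <- max(1, r - hw); r1 <- min(ny, r + hw)
      c0 <- max(1, c - hw); c1 <- min(nx, c + hw)
      if (r1 - r0 < 4 || c1 - c0 < 4) next
      sub <- fr0[r0:r1, c0:c1]
      fit <- fit_elliptical_gaussian(sub, px)
      if (!fit$converged) next
      value <- metric_from_widths(lut$metric, fit$wx_um, fit$wy_um)
      xg <- fit$x0_um + (c0 - 1) * px
      yg <- fit$y0_um + (r0 - 1) * px
      zl <- lookup_depth(lut, value, xg, yg)
      pin <- apply_digital_pinhole(
        sub, c(fit$y0_um / px + 1, fit$x0_um / px + 1), pinhole_radius_px)
      pin[pin < 0] <- 0
      intensity[r0:r1, c0:c1] <- intensity[r0:r1, c0:c1] + pin
      zw[r0:r1, c0:c1] <- zw[r0:r1, c0:c1] + pin * zl$z_um
      wsum[r0:r1, c0:c1] <- wsum[r0:r1, c0:c1] + pin
      spot_rows[[length(spot_rows) + 1]] <- tibble::tibble(
        position = k, spot_id = spots$spot_id[i], x_um = xg, y_um = yg,
        z_um = zl$z_um, amplitude = fit$a,
        ellipticity = fit$ellipticity, out_of_range = zl$out_of_range)
    }
  }
  depth <- ifelse(wsum > 0, zw / wsum, NA_real_)
  dim(depth) <- c(ny, nx)
  structure(list(intensity = intensity, depth_um = depth, weight = wsum,
                 n_spots = length(spot_rows),
                 spot_table = dplyr::bind_rows(spot_rows),
                 pixel_size_um = px),
            class = "compounded_volume")
}

#' @export
print.compounded_volume <- function(x, ...) {
  cat(sprintf("<compounded volume %d x %d px, %d spots, depth defined on %d px>\n",
              nrow(x$intensity), ncol(x$intensity), x$n_spots,
              sum(!is.na(x$depth_um))))
  invisible(x)
}

#' Compound a multi-volume acquisition
#'
#' Splits the stack into complete scan cycles (any remainder frames are
#' reported, never silently dropped) and compounds each cycle.
#'
#' @param stack Full acquisition stack.
#' @param reference A [record_reference()] pattern.
#' @param lut Depth LUT.
#' @param ... Passed to [compound_volume()].
#' @return List: `volumes` (list of `compounded_volume`),
#'   `remainder_frames`.
#' @export
compound_series <- function(stack, reference, lut, ...) {
  stack <- as_stack(stack)
  P <- n_scan_positions(reference$scan)
  nf <- dim(stack)[3]
  n_vol <- nf %/% P
  remainder <- nf %% P
  if (remainder > 0) {
    message(remainder, " trailing frame(s) do not fill a scan cycle and were left uncompounded")
  }
  volumes <- purrr::map(seq_len(n_vol), function(v) {
    compound_volume(stack[, , ((v - 1) * P + 1):(v * P), drop = FALSE],
                    reference, lut, ...)
  })
  list(volumes = volumes, remainder_frames = remainder)
}

#' Time-to-peak map from a volume series
#'
#' Per pixel, TTP is the time (seconds from the series start) of the
#' maximum of the moving-average-smoothed intensity curve, ties broken to
#' the earliest frame. Pixels whose peak prominence (smoothed maximum minus
#' smoothed minimum) is below `prominence_min` are masked.
#'
#' @param volumes List of `compounded_volume` objects, or a 3D array
#'   `[ny, nx, n_volumes]` of intensities; at least 3 volumes.
#' @param volume_rate_hz Effective volume rate (Hz).
#' @param smoothing_window Moving-average window (volumes).
#' @param prominence_min Minimum peak prominence (counts).
#' @return Object of class `ttp_map`: `ttp_s` (NA where masked), `valid`.
#' @export
compute_ttp <- function(volumes, volume_rate_hz, smoothing_window = 3,
                        prominence_min = 0) {
  series <- if (is.list(volumes) && inherits(volumes[[1]], "compounded_volume")) {
    as_stack(purrr::map(volumes, "intensity"))
  } else {
    as_stack(volumes)
  }
  nt <- dim(series)[3]
  if (nt < 3) stop("TTP needs at least 3 volumes", call. = FALSE)
  ny <- dim(series)[1]; nx <- dim(series)[2]
  mat <- matrix(series, ny * nx, nt)  # pixels x time
  if (smoothing_window > 1) {
    k <- rep(1 / smoothing_window, smoothing_window)
    sm <- t(apply(mat, 1, function(v) {
      as.numeric(stats::filter(v, k, sides = 2))
    }))
    # moving average is NA at the edges; fall back to the raw values there
    sm[is.na(sm)] <- mat[is.na(sm)]
  } else {
    sm <- mat
  }
  peak_idx <- max.col(sm, ties.method = "first")
  prom <- apply(sm, 1, max) - apply(sm, 1, min)
  valid <- prom > prominence_min & prom > 0
  ttp <- (peak_idx - 1) / volume_rate_hz
  ttp[!valid] <- NA_real_
  structure(list(ttp_s = matrix(ttp, ny, nx), valid = matrix(valid, ny, nx),
                 volume_rate_hz = volume_rate_hz,
                 duration_s = (nt - 1) / volume_rate_hz),
            class = "ttp_map")
}

#' @export
print.ttp_map <- function(x, ...) {
  cat(sprintf("<TTP map %d x %d px, %d valid px, %.2f s series at %.2f Hz>\n",
              nrow(x$ttp_s), ncol(x$ttp_s), sum(x$valid),
              x$duration_s, x$volume_rate_hz))
  invisible(x)
}

#' Per-ROI perfusion statistics
#'
#' Mean and SD of the time-to-peak over the valid pixels of each ROI
#' (by convention small, e.g. 5 x 5 pixel, regions). ROIs whose pixels are
#' all masked are reported as undefined (NA), not zero.
#'
#' @param ttp A [compute_ttp()] map.
#' @param rois Tibble with `label`, `row0`, `col0`, `height`, `width`
#'   (1-based pixel rectangles).
#' @return Tibble: `label`, `mean_ttp_s`, `sd_ttp_s`, `n_valid`.
#' @export
roi_perfusion_stats <- function(ttp, rois) {
  stopifnot(inherits(ttp, "ttp_map"))
  purrr::map(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    if (r$row0 < 1 || r$col0 < 1 ||
        r$row0 + r$height - 1 > nrow(ttp$ttp_s) ||
        r$col0 + r$width - 1 > ncol(ttp$ttp_s)) {
      stop("ROI '", r$label, "' extends outside the map", call. = FALSE)
    }
    vals <- ttp$ttp_s[r$row0:(r$row0 + r$height - 1),
                      r$col0:(r$col0 + r$width - 1)]
    vals <- vals[!is.na(vals)]
    tibble::tibble(
      label = r$label,
      mean_ttp_s = if (length(vals)) mean(vals) else NA_real_,
      sd_ttp_s = if (length(vals) > 1) sd(vals) else
        if (length(vals) == 1) 0 else NA_real_,
      n_valid = length(vals)
    )
  }) |> dplyr::bind_rows()
}
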