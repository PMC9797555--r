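# Emitter localization: background subtraction, candidate detection by
# adaptive thresholding + connected components, and iterative elliptical
# Gaussian fitting of the astigmatic PSF. Shared by the SL and MI pipelines.

#' Subtract the temporal-mean background from a stack
#'
#' Each output frame is the input minus the pixelwise mean over all frames,
#' clipped at zero - moving emitters survive, static structure and constant
#' background cancel.
#'
#' @param stack 3D array `[ny, nx, frames]` (or a single matrix).
#' @return Array of the same dimensions.
#' @export
subtract_background <- function(stack) {
  stack <- as_stack(stack)
  bg <- rowMeans(stack, dims = 2)
  out <- sweep(stack, c(1, 2), bg)
  out[out < 0] <- 0
  out
}

# Adaptive detection threshold: median + k * robust SD (scaled MAD).
# When the MAD is degenerate relative to the frame's dynamic range (e.g.
# noiseless synthetic frames whose background spread vanishes), the
# background statistics are instead estimated from the sub-threshold pixels
# of a plain-SD first pass.
adaptive_threshold <- function(frame, threshold_k) {
  med <- median(frame)
  thr <- med + threshold_k * mad(frame)
  if (!is.finite(thr) || thr - med <= 1e-6 * (max(frame) - med)) {
    bg <- frame[frame < med + threshold_k * sd(frame)]
    thr <- median(bg) + threshold_k * sd(bg)
    if (!is.finite(thr) || thr <= med) thr <- med
  }
  thr
}

#' Detect candidate emitters in one frame
#'
#' Adaptive threshold `median + k * robust SD` (robust SD via the scaled
#' median absolute deviation), 8-connected components of the suprathreshold
#' mask, intensity-weighted centroids. Components touching the frame border
#' are flagged `edge`.
#'
#' @param frame Background-subtracted numeric matrix.
#' @param pixel_size_um Pixel pitch (um).
#' @param threshold_k Threshold in robust SDs above the median.
#' @param min_area Minimum component area (pixels).
#' @return Tibble: `x_um`, `y_um`, `x_px`, `y_px` (1-based, fractional),
#'   `area_px`, `peak`, `edge`.
#' @export
detect_candidates <- function(frame, pixel_size_um = 1, threshold_k = 4,
                              min_area = 4) {
  thr <- adaptive_threshold(frame, threshold_k)
  mask <- frame > thr
  empty <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          x_px = numeric(), y_px = numeric(),
                          area_px = integer(), peak = numeric(),
                          edge = logical())
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  ny <- nrow(frame); nx <- ncol(frame)
  idx <- which(lab > 0)
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  df <- tibble::tibble(lab = lab[idx], r = rows, c = cols, w = frame[idx])
  out <- df |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      x_px = sum(.data$c * .data$w) / sum(.data$w),
      y_px = sum(.data$r * .data$w) / sum(.data$w),
      area_px = dplyr::n(),
      peak = max(.data$w),
      edge = any(.data$r == 1 | .data$r == ny | .data$c == 1 | .data$c == nx),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$area_px >= min_area) |>
    dplyr::mutate(x_um = (.data$x_px - 1) * pixel_size_um,
                  y_um = (.data$y_px - 1) * pixel_size_um) |>
    dplyr::select("x_um", "y_um", "x_px", "y_px", "area_px", "peak", "edge")
  out
}

# Moment-based initial guess on a subimage (local pixel coordinates, um).
moment_init <- function(sub, pixel_size_um) {
  c0 <- median(sub)
  a0 <- max(sub) - c0
  w <- pmax(sub - c0, 0)
  if (sum(w) == 0) w[] <- 1
  x_um <- px_to_um(seq_len(ncol(sub)), pixel_size_um)
  y_um <- px_to_um(seq_len(nrow(sub)), pixel_size_um)
  wx_col <- colSums(w); wy_row <- rowSums(w)
  x0 <- sum(x_um * wx_col) / sum(wx_col)
  y0 <- sum(y_um * wy_row) / sum(wy_row)
  varx <- sum(wx_col * (x_um - x0)^2) / sum(wx_col)
  vary <- sum(wy_row * (y_um - y0)^2) / sum(wy_row)
  list(a = max(a0, .Machine$double.eps), x0 = x0, y0 = y0,
       wx = max(2 * sqrt(varx), pixel_size_um / 2),
       wy = max(2 * sqrt(vary), pixel_size_um / 2),
       c = max(c0, 0))
}

#' Fit the elliptical Gaussian PSF model to a subimage
#'
#' Levenberg-Marquardt least squares of
#' `a * exp(-2 (x-x0)^2 / wx^2 - 2 (y-y0)^2 / wy^2) + c` with an analytic
#' Jacobian, initialised from image moments (amplitude = max - median,
#' offset = median, centre = intensity-weighted centroid, widths = twice
#' the second central moments). Iteration cap 100.
#'
#' @param sub Numeric matrix (at least 5 x 5) containing one dominant peak.
#' @param pixel_size_um Pixel pitch (um).
#' @param init Optional list overriding the moment initialisation
#'   (`a`, `x0`, `y0`, `wx`, `wy`, `c`, local um coordinates).
#' @return A one-row tibble: `a`, `x0_um`, `y0_um`, `wx_um`, `wy_um`, `c`,
#'   `ellipticity`, `converged`, `rss`, `niter`. Coordinates are local to
#'   the subimage (top-left pixel centre = 0).
#' @export
fit_elliptical_gaussian <- function(sub, pixel_size_um = 1, init = NULL) {
  if (!is.matrix(sub) || nrow(sub) < 5 || ncol(sub) < 5) {
    stop("subimage must be a matrix of at least 5 x 5 pixels", call. = FALSE)
  }
  x_um <- px_to_um(seq_len(ncol(sub)), pixel_size_um)
  y_um <- px_to_um(seq_len(nrow(sub)), pixel_size_um)
  X <- matrix(x_um, nrow(sub), ncol(sub), byrow = TRUE)
  Y <- matrix(y_um, nrow(sub), ncol(sub))
  xv <- as.vector(X); yv <- as.vector(Y); dv <- as.vector(sub)

  start <- moment_init(sub, pixel_size_um)
  if (!is.null(init)) start[names(init)] <- init
  par0 <- unlist(start[c("a", "x0", "y0", "wx", "wy", "c")])

  resid_fn <- function(p) {
    E <- exp(-2 * (xv - p[2])^2 / p[4]^2 - 2 * (yv - p[3])^2 / p[5]^2)
    p[1] * E + p[6] - dv
  }
  jac_fn <- function(p) {
    dx <- xv - p[2]; dy <- yv - p[3]
    E <- exp(-2 * dx^2 / p[4]^2 - 2 * dy^2 / p[5]^2)
    aE <- p[1] * E
    cbind(E,
          aE * 4 * dx / p[4]^2,
          aE * 4 * dy / p[5]^2,
          aE * 4 * dx^2 / p[4]^3,
          aE * 4 * dy^2 / p[5]^3,
          1)
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-12, ptol = 1e-12))),
    error = function(e) NULL
  )
  ok <- !is.null(fit) && fit$info %in% 1:4
  p <- unname(if (is.null(fit)) par0 else fit$par)
  p[4] <- abs(p[4]); p[5] <- abs(p[5])  # model is even in the widths
  ok <- ok && p[1] > 0 && p[4] > 0 && p[5] > 0
  tibble::tibble(
    a = p[1], x0_um = p[2], y0_um = p[3], wx_um = p[4], wy_um = p[5], c = p[6],
    ellipticity = if (ok) (p[4] - p[5]) / (p[4] + p[5]) else NA_real_,
    converged = ok,
    rss = if (is.null(fit)) NA_real_ else fit$deviance,
    niter = if (is.null(fit)) NA_integer_ else fit$niter
  )
}

#' Detect and fit all emitters in one frame
#'
#' Composition of [detect_candidates()] and [fit_elliptical_gaussian()]
#' on square windows centred on each candidate. Candidates closer together
#' than the window width, or whose window is clipped by the frame border,
#' are flagged `edge` and not fitted (overlapping PSFs carry no reliable
#' depth). Non-converged fits are flagged `fit_failed`.
#'
#' @param frame Background-subtracted matrix.
#' @param pixel_size_um Pixel pitch (um).
#' @param window_halfwidth_px Half-width of the fit window (pixels);
#'   choose about 3x the largest expected PSF width.
#' @param threshold_k,min_area Passed to [detect_candidates()].
#' @param frame_index 0-based frame index recorded in the output.
#' @return Detection tibble: `frame`, `x_um`, `y_um`, `wx_um`, `wy_um`,
#'   `amplitude`, `offset`, `ellipticity`, `flag` ("ok", "edge",
#'   "fit_failed").
#' @export
localize_frame <- function(frame, pixel_size_um = 1, window_halfwidth_px = 10,
                           threshold_k = 4, min_area = 4, frame_index = 0L) {
  cand <- detect_candidates(frame, pixel_size_um, threshold_k, min_area)
  empty <- tibble::tibble(frame = integer(), x_um = numeric(), y_um = numeric(),
                          wx_um = numeric(), wy_um = numeric(),
                          amplitude = numeric(), offset = numeric(),
                          ellipticity = numeric(), flag = character())
  if (nrow(cand) == 0) return(empty)
  hw <- as.integer(window_halfwidth_px)
  ny <- nrow(frame); nx <- ncol(frame)

  # overlap gating: windows that would contain a second candidate
  if (nrow(cand) > 1) {
    d <- as.matrix(stats::dist(cbind(cand$x_px, cand$y_px)))
    diag(d) <- Inf
    overlap <- apply(d, 1, min) < 2 * hw
  } else {
    overlap <- FALSE
  }

  rows <- purrr::map(seq_len(nrow(cand)), function(i) {
    r0 <- round(cand$y_px[i]) - hw; r1 <- round(cand$y_px[i]) + hw
    c0 <- round(cand$x_px[i]) - hw; c1 <- round(cand$x_px[i]) + hw
    clipped <- r0 < 1 || c0 < 1 || r1 > ny || c1 > nx
    if (cand$edge[i] || overlap[i] || clipped) {
      return(tibble::tibble(frame = frame_index,
                            x_um = cand$x_um[i], y_um = cand$y_um[i],
                            wx_um = NA_real_, wy_um = NA_real_,
                            amplitude = NA_real_, offset = NA_real_,
                            ellipticity = NA_real_, flag = "edge"))
    }
    sub <- frame[r0:r1, c0:c1]
    fit <- fit_elliptical_gaussian(sub, pixel_size_um)
    tibble::tibble(
      frame = frame_index,
      x_um = fit$x0_um + (c0 - 1) * pixel_size_um,
      y_um = fit$y0_um + (r0 - 1) * pixel_size_um,
      wx_um = fit$wx_um, wy_um = fit$wy_um,
      amplitude = fit$a, offset = fit$c,
      ellipticity = fit$ellipticity,
      flag = if (fit$converged) "ok" else "fit_failed"
    )
  })
  dplyr::bind_rows(rows)
}

#' Localize emitters in every frame of a stack
#'
#' @param stack 3D array of background-subtracted frames.
#' @param ... Passed to [localize_frame()].
#' @return Row-bound detection tibble over all frames (0-based `frame`).
#' @export
localize_stack <- function(stack, ...) {
  stack <- as_stack(stack)
  purrr::map(seq_len(dim(stack)[3]), function(f) {
    localize_frame(stack[, , f], ..., frame_index = f - 1L)
  }) |> dplyr::bind_rows()
}

#' Assign depths to detections through a calibration LUT
#'
#' Each unflagged detection gains `z_um = lookup_depth(lut, ellipticity,
#' position)`; lookups outside the valid calibration range keep their
#' clamped depth but are flagged `out_of_range`. Flagged detections
#' (edge, fit_failed) carry no depth claim (`z_um = NA`).
#'
#' @param detections A [localize_stack()] tibble.
#' @param lut A [build_calibration()] LUT.
#' @return The detections with columns `z_um` and updated `flag`.
#' @export
assign_depth <- function(detections, lut) {
  detections$z_um <- NA_real_
  ok <- detections$flag == "ok" & !is.na(detections$ellipticity)
  if (any(ok)) {
    metric_value <- switch(lut$metric,
      ellipticity = detections$ellipticity[ok],
      axis_difference = detections$wx_um[ok] - detections$wy_um[ok],
      single_axis = detections$wx_um[ok]
    )
    looked <- lookup_depth(lut, metric_value,
                           detections$x_um[ok], detections$y_um[ok])
    detections$z_um[ok] <- looked$z_um
    oor <- which(ok)[looked$out_of_range]
    detections$flag[oor] <- "out_of_range"
  }
  detections
}

#' Write detections to CSV
#'
#' Columns carry unit suffixes; flags are kept verbatim.
#'
#' @param detections Detection tibble (optionally depth-assigned).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
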