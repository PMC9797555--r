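# Spatially variant depth calibration: per-subregion monotone mapping
# between a PSF-shape metric (ellipticity by default) and depth, built from
# a fluorescent-slide z-stack with known axial step.

lut_metrics <- c("ellipticity", "axis_difference", "single_axis")

metric_from_widths <- function(metric, wx, wy) {
  switch(metric,
    ellipticity = (wx - wy) / (wx + wy),
    axis_difference = wx - wy,
    single_axis = wx,
    stop("unknown PSF-shape metric: ", metric, call. = FALSE)
  )
}

# subregion indices (row, col) for physical positions
subregion_of <- function(x_um, y_um, grid, img_dim_px, pixel_size_um) {
  fov <- rev(img_dim_px) * pixel_size_um  # c(x, y)
  col <- pmin(pmax(floor(x_um / fov[1] * grid[2]) + 1, 1), grid[2])
  row <- pmin(pmax(floor(y_um / fov[2] * grid[1]) + 1, 1), grid[1])
  list(row = row, col = col)
}

# longest strictly monotone run (by sign of successive differences)
longest_monotone_run <- function(v) {
  n <- length(v)
  if (n < 2) return(c(1, n))
  s <- sign(diff(v))
  best <- c(1, 1); cur_start <- 1
  for (i in seq_along(s)) {
    if (s[i] == 0 || (i > cur_start && s[i] != s[cur_start])) cur_start <- i
    if (s[i] != 0 && (i - cur_start + 2) > (best[2] - best[1] + 1)) {
      best <- c(cur_start, i + 1)
    }
  }
  best
}

#' Build a spatially variant depth look-up table
#'
#' Localizes the calibration spots in every plane of a fluorescent-slide
#' z-stack, averages the chosen PSF-shape metric per plane within each
#' subregion of the FOV, and fits a monotone interpolant over the largest
#' strictly monotone sub-interval of each subregion's curve - that interval
#' is the subregion's valid depth range. Subregions without detected spots
#' are flagged empty and fall back to the nearest populated subregion at
#' lookup time.
#'
#' @param stack 3D array, one frame per z plane.
#' @param z_um Depth of each plane (um); at least 3 distinct values.
#' @param subregions `c(rows, cols)` subdivision of the FOV (e.g. `c(5, 5)`
#'   for the 25-subregion calibration; `c(1, 1)` for a global curve).
#' @param metric One of `"ellipticity"`, `"axis_difference"`,
#'   `"single_axis"`.
#' @param pixel_size_um Pixel pitch (um).
#' @param threshold_k,min_area,window_halfwidth_px Localization settings,
#'   see [localize_frame()].
#' @return An object of class `depth_lut`.
#' @export
build_calibration <- function(stack, z_um, subregions = c(5, 5),
                              metric = "ellipticity", pixel_size_um = 5.56,
                              threshold_k = 4, min_area = 4,
                              window_halfwidth_px = 10) {
  stack <- as_stack(stack)
  metric <- match.arg(metric, lut_metrics)
  if (length(z_um) != dim(stack)[3]) {
    stop("`z_um` must give one depth per frame", call. = FALSE)
  }
  if (length(unique(z_um)) < 3) {
    stop("calibration needs at least 3 distinct z planes", call. = FALSE)
  }
  grid <- as.integer(rep(subregions, length.out = 2))
  img_dim_px <- dim(stack)[1:2]

  det <- purrr::map(seq_along(z_um), function(f) {
    d <- localize_frame(stack[, , f], pixel_size_um, window_halfwidth_px,
                        threshold_k, min_area, frame_index = f - 1L)
    d$z_um <- z_um[f]
    d
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$flag == "ok")

  if (nrow(det) == 0) stop("no calibration spots detected", call. = FALSE)
  sub <- subregion_of(det$x_um, det$y_um, grid, img_dim_px, pixel_size_um)
  det$sub_row <- sub$row; det$sub_col <- sub$col
  det$value <- metric_from_widths(metric, det$wx_um, det$wy_um)

  samples <- det |>
    dplyr::group_by(.data$sub_row, .data$sub_col, .data$z_um) |>
    dplyr::summarise(value = mean(.data$value), n_spots = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$sub_row, .data$sub_col, .data$z_um)

  valid <- samples |>
    dplyr::group_by(.data$sub_row, .data$sub_col) |>
    dplyr::group_modify(function(g, key) {
      run <- longest_monotone_run(g$value)
      tibble::tibble(z_min = g$z_um[run[1]], z_max = g$z_um[run[2]],
                     n_planes = run[2] - run[1] + 1)
    }) |>
    dplyr::ungroup()

  all_subs <- tidyr::expand_grid(sub_row = seq_len(grid[1]),
                                 sub_col = seq_len(grid[2]))
  valid <- dplyr::left_join(all_subs, valid, by = c("sub_row", "sub_col")) |>
    dplyr::mutate(empty = is.na(.data$z_min) | .data$n_planes < 3)
  if (any(valid$empty)) {
    warning(sum(valid$empty),
            " subregion(s) without a usable calibration curve; ",
            "lookups there fall back to the nearest populated subregion",
            call. = FALSE)
  }

  structure(list(grid = grid, img_dim_px = as.integer(img_dim_px),
                 pixel_size_um = pixel_size_um, metric = metric,
                 samples = samples, valid = valid),
            class = "depth_lut")
}

#' @export
print.depth_lut <- function(x, ...) {
  cat(sprintf("<depth LUT: %d x %d subregions, metric '%s', %d empty>\n",
              x$grid[1], x$grid[2], x$metric, sum(x$valid$empty)))
  rng <- range(x$samples$z_um)
  cat(sprintf("  sampled depths: %.0f .. %.0f um (%d planes)\n",
              rng[1], rng[2], length(unique(x$samples$z_um))))
  invisible(x)
}

# monotone samples of one subregion restricted to its valid run
lut_curve <- function(lut, row, col) {
  g <- lut$samples[lut$samples$sub_row == row & lut$samples$sub_col == col, ]
  v <- lut$valid[lut$valid$sub_row == row & lut$valid$sub_col == col, ]
  if (nrow(v) == 0 || v$empty) return(NULL)
  g <- g[g$z_um >= v$z_min & g$z_um <= v$z_max, ]
  g[order(g$z_um), ]
}

# nearest populated subregion for each (row, col)
nearest_populated <- function(lut, row, col) {
  pop <- lut$valid[!lut$valid$empty, ]
  if (nrow(pop) == 0) stop("depth LUT has no populated subregion", call. = FALSE)
  d2 <- (pop$sub_row - row)^2 + (pop$sub_col - col)^2
  i <- which.min(d2)
  c(pop$sub_row[i], pop$sub_col[i])
}

#' Invert the calibration: PSF-shape metric to depth
#'
#' Looks up each metric value in the monotone interpolant (monotone
#' piecewise-cubic, Hyman-filtered) of the subregion containing the lateral
#' position. Values outside the curve's range clamp to the nearest endpoint
#' and are flagged out-of-range.
#'
#' @param lut A [build_calibration()] LUT.
#' @param values PSF-shape metric values (vectorised).
#' @param x_um,y_um Lateral positions (um), recycled against `values`.
#' @return Tibble: `z_um`, `out_of_range`, `sub_row`, `sub_col`.
#' @export
lookup_depth <- function(lut, values, x_um, y_um) {
  stopifnot(inherits(lut, "depth_lut"))
  n <- length(values)
  x_um <- rep(x_um, length.out = n); y_um <- rep(y_um, length.out = n)
  sub <- subregion_of(x_um, y_um, lut$grid, lut$img_dim_px, lut$pixel_size_um)
  out <- tibble::tibble(z_um = rep(NA_real_, n),
                        out_of_range = rep(FALSE, n),
                        sub_row = sub$row, sub_col = sub$col)
  key <- paste(sub$row, sub$col)
  for (k in unique(key)) {
    i <- which(key == k)
    rc <- c(sub$row[i[1]], sub$col[i[1]])
    curve <- lut_curve(lut, rc[1], rc[2])
    if (is.null(curve)) {
      rc <- nearest_populated(lut, rc[1], rc[2])
      curve <- lut_curve(lut, rc[1], rc[2])
    }
    vr <- range(curve$value)
    v <- values[i]
    oor <- v < vr[1] | v > vr[2]
    vcl <- clamp(v, vr[1], vr[2])
    o <- order(curve$value)
    inv <- stats::splinefun(curve$value[o], curve$z_um[o], method = "hyman")
    out$z_um[i] <- inv(vcl)
    out$out_of_range[i] <- oor
  }
  out
}

#' Serialise a depth LUT to JSON
#' @param lut A `depth_lut`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "depth_lut"))
  payload <- list(grid = lut$grid, img_dim_px = lut$img_dim_px,
                  pixel_size_um = lut$pixel_size_um, metric = lut$metric,
                  samples = as.list(lut$samples),
                  valid = as.list(lut$valid))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a depth LUT from JSON
#' @param path File written by [write_lut()].
#' @return A `depth_lut` object.
#' @export
read_lut <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(grid = as.integer(p$grid),
                 img_dim_px = as.integer(p$img_dim_px),
                 pixel_size_um = p$pixel_size_um, metric = p$metric,
                 samples = tibble::as_tibble(p$samples),
                 valid = tibble::as_tibble(p$valid)),
            class = "depth_lut")
}

#' Compare PSF-shape metrics for robustness to scattering blur
#'
#' Builds an unblurred global calibration curve per metric, then re-images
#' the same z-stack under increasing isotropic Gaussian blur and reports,
#' for each metric and blur level, the largest absolute depth error
#' incurred by re-using the unblurred curve on the blurred data. Because
#' isotropic blur inflates both PSF axes together, the quotient-based
#' ellipticity largely cancels it, while single-axis and axis-difference
#' curves shift.
#'
#' @param stack Calibration z-stack (unblurred).
#' @param z_um Depth per plane (um).
#' @param blur_levels_um Gaussian blur SDs (um); must include 0.
#' @param metrics Character vector of metrics to compare.
#' @param pixel_size_um Pixel pitch (um).
#' @param ... Passed to [build_calibration()] / [localize_frame()].
#' @return Tibble: `metric`, `blur_um`, `max_abs_dz_um`.
#' @export
compare_depth_metrics <- function(stack, z_um, blur_levels_um = c(0, 5, 10),
                                  metrics = lut_metrics,
                                  pixel_size_um = 5.56, ...) {
  stack <- as_stack(stack)
  if (length(blur_levels_um) < 2 || !any(blur_levels_um == 0)) {
    stop("`blur_levels_um` needs at least two levels including 0", call. = FALSE)
  }
  luts <- purrr::map(metrics, function(m) {
    build_calibration(stack, z_um, subregions = c(1, 1), metric = m,
                      pixel_size_um = pixel_size_um, ...)
  })
  names(luts) <- metrics

  purrr::map(blur_levels_um, function(b) {
    blurred <- stack
    if (b > 0) {
      for (f in seq_len(dim(stack)[3])) {
        blurred[, , f] <- blur_matrix(stack[, , f], b / pixel_size_um)
      }
    }
    det <- purrr::map(seq_along(z_um), function(f) {
      d <- localize_frame(blurred[, , f], pixel_size_um, ...)
      d$z_true <- z_um[f]
      d
    }) |>
      dplyr::bind_rows() |>
      dplyr::filter(.data$flag == "ok")
    purrr::map(metrics, function(m) {
      lut <- luts[[m]]
      vals <- det |>
        dplyr::mutate(value = metric_from_widths(m, .data$wx_um, .data$wy_um)) |>
        dplyr::group_by(.data$z_true) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop")
      looked <- lookup_depth(lut, vals$value,
                             rep(0, nrow(vals)), rep(0, nrow(vals)))
      # clamped out-of-range lookups count with their full depth error:
      # a metric whose curve drifts off-range has not become more robust
      err <- max(abs(looked$z_um - vals$z_true))
      tibble::tibble(metric = m, blur_um = b, max_abs_dz_um = err)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
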