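# Sparse-localization reconstruction: link depth-assigned detections into
# trajectories frame by frame (optimal bipartite assignment with gap
# closing), convert link displacements to speeds, and render compounded
# localization / depth / velocity maps.

#' Link detections into trajectories
#'
#' Frame-sequential optimal bipartite (Hungarian) assignment between active
#' track heads and the detections of each frame, with cost = lateral
#' Euclidean distance, gated at `max_disp_um` per link. Track heads
#' unmatched in a frame stay active for up to `max_gap` missing frames.
#' Flagged detections (`edge`, `fit_failed`) are never linked.
#'
#' @param detections Depth-assigned detection tibble (`frame`, `x_um`,
#'   `y_um`, `z_um`, `flag`).
#' @param max_disp_um Maximum lateral displacement per link (um).
#' @param max_gap Maximum number of bridged missing frames (0 = none).
#' @return The linkable detections with a `track_id` column (NA for
#'   orphaned detections), ordered by track and frame.
#' @export
link_tracks <- function(detections, max_disp_um, max_gap = 0) {
  det <- detections[detections$flag %in% c("ok", "out_of_range"), , drop = FALSE]
  det$track_id <- NA_integer_
  if (nrow(det) == 0) return(det)
  det <- det[order(det$frame), ]
  frames <- sort(unique(det$frame))
  # active track heads: track id, last frame, last position
  heads <- tibble::tibble(track_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric())
  next_id <- 1L
  for (f in frames) {
    idx <- which(det$frame == f)
    heads <- heads[f - heads$frame <= max_gap + 1L, , drop = FALSE]
    assigned <- rep(NA_integer_, length(idx))
    if (nrow(heads) > 0 && length(idx) > 0) {
      cost <- outer(seq_len(nrow(heads)), seq_along(idx),
                    Vectorize(function(i, j) {
                      sqrt((heads$x_um[i] - det$x_um[idx[j]])^2 +
                           (heads$y_um[i] - det$y_um[idx[j]])^2)
                    }))
      cost[cost > max_disp_um] <- Inf
      match_col <- solve_assignment(cost)
      for (i in seq_along(match_col)) {
        j <- match_col[i]
        if (!is.na(j) && is.finite(cost[i, j])) {
          assigned[j] <- heads$track_id[i]
        }
      }
    }
    new_heads <- list()
    for (j in seq_along(idx)) {
      if (is.na(assigned[j])) {
        assigned[j] <- next_id
        next_id <- next_id + 1L
      }
      det$track_id[idx[j]] <- assigned[j]
    }
    kept <- heads[!heads$track_id %in% assigned, , drop = FALSE]
    heads <- dplyr::bind_rows(kept, tibble::tibble(
      track_id = assigned, frame = f,
      x_um = det$x_um[idx], y_um = det$y_um[idx]))
  }
  det[order(det$track_id, det$frame), ]
}

#' Per-link speeds along tracks
#'
#' Speed of each link is `|displacement| * frame_rate / gap_frames`,
#' converted to mm/s. Displacement is 3D (x, y, z) by default; set
#' `use_3d = FALSE` for lateral-only speeds (links whose depth is NA also
#' fall back to lateral displacement).
#'
#' @param tracks Output of [link_tracks()].
#' @param frame_rate_hz Acquisition frame rate (Hz).
#' @param use_3d Include the depth component of the displacement.
#' @return Tibble of links: `track_id`, `frame0`, `frame1`, endpoint
#'   coordinates, `gap_frames`, `speed_mm_s`.
#' @export
compute_velocities <- function(tracks, frame_rate_hz, use_3d = TRUE) {
  tracks |>
    dplyr::filter(!is.na(.data$track_id)) |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::reframe(
      frame0 = .data$frame[-dplyr::n()], frame1 = .data$frame[-1],
      x0_um = .data$x_um[-dplyr::n()], x1_um = .data$x_um[-1],
      y0_um = .data$y_um[-dplyr::n()], y1_um = .data$y_um[-1],
      z0_um = .data$z_um[-dplyr::n()], z1_um = .data$z_um[-1]
    ) |>
    dplyr::mutate(
      gap_frames = .data$frame1 - .data$frame0,
      dz = dplyr::if_else(use_3d & !is.na(.data$z0_um) & !is.na(.data$z1_um),
                          .data$z1_um - .data$z0_um, 0),
      disp_um = sqrt((.data$x1_um - .data$x0_um)^2 +
                     (.data$y1_um - .data$y0_um)^2 + .data$dz^2),
      speed_mm_s = .data$disp_um * frame_rate_hz / .data$gap_frames / 1000
    ) |>
    dplyr::select(-"dz")
}

#' Render compounded localization, depth and velocity maps
#'
#' Rasterizes every track link as a 2D line segment; each touched pixel
#' accumulates a count, the locally interpolated depth, and the link speed.
#' Maps are per-pixel means; pixels with no contributions are NA (empty,
#' not zero). Rendering is order-independent.
#'
#' @param links Output of [compute_velocities()].
#' @param ny_px,nx_px Output raster size (pixels).
#' @param pixel_size_um Pixel pitch (um).
#' @param min_track_length Minimum detections per track for a track's links
#'   to be rendered (suppresses spurious two-point links).
#' @return Object of class `rendered_maps`: matrices `counts`, `depth_um`,
#'   `speed_mm_s`.
#' @export
render_localization_maps <- function(links, ny_px, nx_px, pixel_size_um,
                                     min_track_length = 3) {
  counts <- matrix(0, ny_px, nx_px)
  zsum <- matrix(0, ny_px, nx_px)
  zcnt <- matrix(0, ny_px, nx_px)
  vsum <- matrix(0, ny_px, nx_px)
  if (nrow(links) > 0) {
    keep_ids <- links |>
      dplyr::count(.data$track_id) |>
      dplyr::filter(.data$n >= min_track_length - 1) |>
      dplyr::pull("track_id")
    links <- links[links$track_id %in% keep_ids, , drop = FALSE]
    for (i in seq_len(nrow(links))) {
      c0 <- links$x0_um[i] / pixel_size_um + 1
      c1 <- links$x1_um[i] / pixel_size_um + 1
      r0 <- links$y0_um[i] / pixel_size_um + 1
      r1 <- links$y1_um[i] / pixel_size_um + 1
      nstep <- max(2, ceiling(max(abs(c1 - c0), abs(r1 - r0))) * 2)
      t <- seq(0, 1, length.out = nstep)
      rr <- round(r0 + t * (r1 - r0)); cc <- round(c0 + t * (c1 - c0))
      zz <- if (!is.na(links$z0_um[i]) && !is.na(links$z1_um[i])) {
        links$z0_um[i] + t * (links$z1_um[i] - links$z0_um[i])
      } else {
        rep(NA_real_, nstep)
      }
      keep <- !duplicated(cbind(rr, cc)) & rr >= 1 & rr <= ny_px &
        cc >= 1 & cc <= nx_px
      for (k in which(keep)) {
        counts[rr[k], cc[k]] <- counts[rr[k], cc[k]] + 1
        vsum[rr[k], cc[k]] <- vsum[rr[k], cc[k]] + links$speed_mm_s[i]
        if (!is.na(zz[k])) {
          zsum[rr[k], cc[k]] <- zsum[rr[k], cc[k]] + zz[k]
          zcnt[rr[k], cc[k]] <- zcnt[rr[k], cc[k]] + 1
        }
      }
    }
  }
  depth <- ifelse(zcnt > 0, zsum / zcnt, NA_real_)
  speed <- ifelse(counts > 0, vsum / counts, NA_real_)
  dim(depth) <- dim(speed) <- c(ny_px, nx_px)
  structure(list(counts = counts, depth_um = depth, speed_mm_s = speed,
                 pixel_size_um = pixel_size_um),
            class = "rendered_maps")
}

#' @export
print.rendered_maps <- function(x, ...) {
  cat(sprintf("<rendered maps %d x %d px: %d occupied pixels>\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Full sparse-localization reconstruction
#'
#' Composition of the SL stages: background subtraction, per-frame
#' candidate detection and elliptical-Gaussian fitting, depth assignment
#' through the calibration LUT, trajectory linking, velocimetry, and map
#' rendering. Deterministic for fixed input.
#'
#' @param stack Raw acquisition stack `[ny, nx, frames]`.
#' @param lut A [build_calibration()] LUT for the same optics/FOV.
#' @param frame_rate_hz Acquisition frame rate (Hz).
#' @param pixel_size_um Pixel pitch (um).
#' @param max_disp_um Link gating distance (um); defaults to the expected
#'   maximum speed of 10 mm/s over one frame interval.
#' @param max_gap Bridged missing frames.
#' @param window_halfwidth_px,threshold_k,min_area Localization settings.
#' @param use_3d 3D (default) or lateral-only speeds.
#' @param min_track_length Minimum track length for rendering.
#' @return List: `maps` (`rendered_maps`), `tracks`, `links`, `detections`.
#' @export
reconstruct_sl <- function(stack, lut, frame_rate_hz, pixel_size_um = 5.56,
                           max_disp_um = 10000 / frame_rate_hz, max_gap = 1,
                           window_halfwidth_px = 10, threshold_k = 4,
                           min_area = 4, use_3d = TRUE, min_track_length = 3) {
  stack <- as_stack(stack)
  enhanced <- subtract_background(stack)
  detections <- localize_stack(enhanced, pixel_size_um = pixel_size_um,
                               window_halfwidth_px = window_halfwidth_px,
                               threshold_k = threshold_k, min_area = min_area)
  detections <- assign_depth(detections, lut)
  tracks <- link_tracks(detections, max_disp_um, max_gap)
  links <- compute_velocities(tracks, frame_rate_hz, use_3d)
  maps <- render_localization_maps(links, dim(stack)[1], dim(stack)[2],
                                   pixel_size_um, min_track_length)
  list(maps = maps, tracks = tracks, links = links, detections = detections)
}
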