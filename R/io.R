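# Shared I/O: multi-page TIFF stacks (16-bit acquisitions, 32-bit float
# maps), YAML configuration, JSON run logs, and the run_pipeline()
# dispatcher behind the command-line entry point.

#' Write an image stack as multi-page TIFF
#'
#' 16-bit integer for acquisition stacks (values clamped to 0..65535), or
#' 32-bit for real-valued maps. 32-bit maps are stored affinely rescaled to
#' the full sample range with the scaling recorded in a `<path>.range.json`
#' sidecar (read transparently by [read_stack()]); NA/NaN pixels use a
#' reserved code and reappear as NaN.
#'
#' @param stack 3D array `[ny, nx, frames]` or a single matrix.
#' @param path Output path.
#' @param bits 16 (integer counts) or 32 (rescaled real values).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  stack <- as_stack(stack)
  if (bits == 32) {
    fin <- stack[is.finite(stack)]
    lo <- if (length(fin)) min(fin) else 0
    hi <- if (length(fin)) max(fin) else 0
    span <- if (hi > lo) hi - lo else 1
    eps <- 1e-3  # codes below eps are reserved for NA
    jsonlite::write_json(list(lo = lo, hi = hi, span = span, eps = eps),
                         paste0(path, ".range.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  pages <- purrr::map(seq_len(dim(stack)[3]), function(f) {
    fr <- stack[, , f]
    if (bits == 16) {
      fr <- round(clamp(fr, 0, 65535)) / 65535
    } else {
      enc <- eps + (1 - eps) * (fr - lo) / span
      enc[!is.finite(fr)] <- 0
      fr <- enc
    }
    fr
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read a multi-page grayscale TIFF stack
#'
#' Integer stacks are returned on their native count scale; float pages
#' are returned as stored.
#'
#' @param path TIFF file path.
#' @return 3D array `[ny, nx, frames]` with attribute `n_pages`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".range.json")
  scaled <- file.exists(sidecar)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = !scaled),
                    error = function(e) {
                      stop("cannot read '", path, "' as TIFF: ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (!is.matrix(pages[[i]])) {
      stop("page ", i, " of '", path, "' is not single-channel grayscale",
           call. = FALSE)
    }
  }
  out <- as_stack(pages)
  if (scaled) {
    rng <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dec <- rng$lo + (out - rng$eps) / (1 - rng$eps) * rng$span
    dec[out < rng$eps / 2] <- NaN
    out <- dec
  }
  attr(out, "n_pages") <- length(pages)
  out
}

#' Read a YAML configuration file
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Build a scan pattern from a configuration list
#' @param cfg List with `lattice_dim`, `scan_dim`, `fov_um`,
#'   `frame_rate_hz`.
#' @return A [make_scan_pattern()] object.
#' @export
scan_from_config <- function(cfg) {
  make_scan_pattern(lattice_dim = unlist(cfg$lattice_dim),
                    scan_dim = unlist(cfg$scan_dim),
                    fov_um = unlist(cfg$fov_um),
                    frame_rate_hz = cfg$frame_rate_hz %||% 2250)
}

run_log <- function(command, config, inputs, timings) {
  list(
    package = "astivol",
    version = as.character(utils::packageVersion("astivol")),
    command = command,
    config = config,
    input_hashes = purrr::map(inputs, function(p) {
      if (is.character(p) && file.exists(p)) {
        unname(tools::md5sum(p))
      } else {
        rlang::hash(p)
      }
    }),
    timings_s = timings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Run one reconstruction command from a configuration
#'
#' Dispatcher behind the command-line interface. Supported commands:
#' `simulate` (synthetic bead-flow acquisition + calibration z-stack +
#' ground-truth CSV from a scene description),
#' `calibrate` (slide z-stack + z sidecar -> LUT JSON),
#' `reconstruct-sl` (stack + LUT -> depth/velocity/density maps + tracks
#' CSV), `reconstruct-mi` (stack + reference + scan + LUT -> compounded
#' intensity/depth maps), `ttp-map` (intensity volume stack -> TTP map),
#' `vessel-quant` (intensity map + ROI rectangles -> metrics CSV).
#' Every run writes a JSON log (parameters, input hashes, per-stage
#' timings) into the output directory; outputs are deterministic given
#' inputs and seed.
#'
#' @param config Named list (usually from [read_config()]). Common fields:
#'   `stack`, `lut`, `out_dir`, `pixel_size_um`, `frame_rate_hz`, `seed`;
#'   see the command implementations for specifics.
#' @param command One of the commands above.
#' @return Named list of output paths, invisibly.
#' @export
run_pipeline <- function(config, command) {
  command <- match.arg(command, c("simulate", "calibrate", "reconstruct-sl",
                                  "reconstruct-mi", "ttp-map", "vessel-quant"))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  px <- config$pixel_size_um %||% 5.56
  t0 <- proc.time()[["elapsed"]]
  inputs <- list()
  outputs <- list()

  if (command == "simulate") {
    for (f in c("n_frames", "frame_rate_hz")) {
      if (is.null(config[[f]])) stop("simulate: config needs `", f, "`", call. = FALSE)
    }
    seed <- config$seed %||% 1L
    npx <- config$image_size_px %||% 162
    psf <- default_psf_params()
    cfg <- acquisition_config(npx, npx, pixel_size_um = px,
                              frame_rate_hz = config$frame_rate_hz,
                              seed = seed)
    if (isTRUE(config$reference_noise %||% TRUE)) cfg <- reference_noise(cfg)
    ph <- make_crossing_channels(
      separation_um = config$separation_um %||% 260,
      diameter_um = config$diameter_um %||% 50,
      fov_mm = npx * px / 1000)
    em <- simulate_bead_flow(ph,
                             linear_density_per_mm = config$bead_density_per_mm %||% 2,
                             speed_range_mm_s = unlist(config$speed_range_mm_s %||% c(1, 3)),
                             n_frames = config$n_frames,
                             frame_rate_hz = config$frame_rate_hz,
                             seed = seed + 1L)
    stack <- simulate_widefield_acquisition(em, psf, cfg,
                                            n_frames = config$n_frames)
    cal <- simulate_calibration_stack(seq(-300, 300, by = 50), psf,
                                      acquisition_config(npx, npx,
                                                         pixel_size_um = px,
                                                         seed = seed + 2L),
                                      spot_grid = c(6, 6))
    outputs$stack <- file.path(out_dir, "acquisition.tif")
    outputs$truth <- file.path(out_dir, "emitters_truth.csv")
    outputs$phantom <- file.path(out_dir, "phantom.json")
    outputs$cal_stack <- file.path(out_dir, "calibration.tif")
    outputs$cal_z <- file.path(out_dir, "calibration_z.yaml")
    write_stack(stack, outputs$stack, bits = 16)
    utils::write.csv(em, outputs$truth, row.names = FALSE)
    write_phantom_json(ph, outputs$phantom)
    write_stack(cal$stack, outputs$cal_stack, bits = 16)
    yaml::write_yaml(list(z_um = cal$z_um), outputs$cal_z)
    inputs <- list(config = config)
  } else if (command == "calibrate") {
    for (f in c("stack", "z_sidecar")) {
      if (is.null(config[[f]])) stop("calibrate: config needs `", f, "`", call. = FALSE)
    }
    stack <- read_stack(config$stack)
    z_um <- unlist(read_config(config$z_sidecar)$z_um)
    lut <- build_calibration(stack, z_um,
                             subregions = unlist(config$subregions %||% c(5, 5)),
                             metric = config$metric %||% "ellipticity",
                             pixel_size_um = px)
    outputs$lut <- file.path(out_dir, "lut.json")
    write_lut(lut, outputs$lut)
    inputs <- list(stack = config$stack, z_sidecar = config$z_sidecar)
  } else if (command == "reconstruct-sl") {
    for (f in c("stack", "lut", "frame_rate_hz")) {
      if (is.null(config[[f]])) stop("reconstruct-sl: config needs `", f, "`", call. = FALSE)
    }
    lut <- read_lut(config$lut)
    stack <- read_stack(config$stack)
    res <- reconstruct_sl(stack, lut, frame_rate_hz = config$frame_rate_hz,
                          pixel_size_um = px,
                          max_disp_um = config$max_disp_um %||%
                            (10000 / config$frame_rate_hz),
                          max_gap = config$max_gap %||% 1)
    outputs$depth_map <- file.path(out_dir, "depth_um.tif")
    outputs$velocity_map <- file.path(out_dir, "velocity_mm_s.tif")
    outputs$density_map <- file.path(out_dir, "density_counts.tif")
    outputs$tracks <- file.path(out_dir, "tracks.csv")
    write_stack(res$maps$depth_um, outputs$depth_map, bits = 32)
    write_stack(res$maps$speed_mm_s, outputs$velocity_map, bits = 32)
    write_stack(res$maps$counts, outputs$density_map, bits = 32)
    utils::write.csv(res$tracks, outputs$tracks, row.names = FALSE)
    inputs <- list(stack = config$stack, lut = config$lut)
  } else if (command == "reconstruct-mi") {
    for (f in c("stack", "reference", "scan", "lut")) {
      if (is.null(config[[f]])) stop("reconstruct-mi: config needs `", f, "`", call. = FALSE)
    }
    scan <- scan_from_config(read_config(config$scan))
    lut <- read_lut(config$lut)
    ref <- record_reference(read_stack(config$reference), scan, px)
    res <- compound_series(read_stack(config$stack), ref, lut,
                           pinhole_radius_px = config$pinhole_radius_px %||% 4)
    for (v in seq_along(res$volumes)) {
      outputs[[paste0("intensity_v", v)]] <-
        file.path(out_dir, sprintf("intensity_v%03d.tif", v))
      outputs[[paste0("depth_v", v)]] <-
        file.path(out_dir, sprintf("depth_um_v%03d.tif", v))
      write_stack(res$volumes[[v]]$intensity, outputs[[paste0("intensity_v", v)]], 32)
      write_stack(res$volumes[[v]]$depth_um, outputs[[paste0("depth_v", v)]], 32)
    }
    inputs <- list(stack = config$stack, reference = config$reference,
                   scan = config$scan, lut = config$lut)
  } else if (command == "ttp-map") {
    for (f in c("volumes", "volume_rate_hz")) {
      if (is.null(config[[f]])) stop("ttp-map: config needs `", f, "`", call. = FALSE)
    }
    series <- read_stack(config$volumes)
    ttp <- compute_ttp(series, config$volume_rate_hz,
                       smoothing_window = config$smoothing_window %||% 3,
                       prominence_min = config$prominence_min %||% 0)
    outputs$ttp <- file.path(out_dir, "ttp_s.tif")
    write_stack(ttp$ttp_s, outputs$ttp, bits = 32)
    inputs <- list(volumes = config$volumes)
  } else if (command == "vessel-quant") {
    for (f in c("map", "rois")) {
      if (is.null(config[[f]])) stop("vessel-quant: config needs `", f, "`", call. = FALSE)
    }
    img <- read_stack(config$map)[, , 1]
    rois <- read_config(config$rois)$rois
    stats <- purrr::map(rois, function(r) {
      roi <- img[r$row0:(r$row0 + r$height - 1), r$col0:(r$col0 + r$width - 1)]
      dplyr::mutate(quantify_roi(roi)$metrics, label = r$label, .before = 1)
    }) |> dplyr::bind_rows()
    outputs$stats <- file.path(out_dir, "vessel_stats.csv")
    utils::write.csv(stats, outputs$stats, row.names = FALSE)
    inputs <- list(map = config$map, rois = config$rois)
  }

  log <- run_log(command, config, inputs,
                 list(total = proc.time()[["elapsed"]] - t0))
  log_path <- file.path(out_dir, paste0(command, "_log.json"))
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  outputs$log <- log_path
  invisible(outputs)
}
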