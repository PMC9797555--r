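# Astigmatic PSF model: each lateral axis of the PSF focuses at its own
# axial plane, so the width pair (wx, wy) encodes emitter depth.

#' Astigmatic PSF parameter set
#'
#' Defines the closed-form defocus law of an astigmatic wide-field system in
#' which a weak cylindrical lens splits the focus into two axially separated
#' planes, one per lateral axis. Each axis follows the Gaussian-beam
#' hyperbola `w(z) = w0 * sqrt(1 + ((z - zf)/zR)^2)`.
#'
#' The depth convention places `z = 0` midway between the two focal planes,
#' with z increasing away from the objective; for symmetric parameters the
#' PSF is round (ellipticity 0) at `z = 0`. All lengths are in micrometres.
#'
#' @param w0x,w0y In-focus 1/e^2 half-widths of the x and y axes (um).
#' @param zfx,zfy Focal-plane depths of the x and y axes (um); must differ.
#' @param zRx,zRy Defocus scales (um): the depth offset at which an axis
#'   width grows by sqrt(2).
#' @return An object of class `psf_params`.
#' @seealso [default_psf_params()], [psf_widths()], [ellipticity()]
#' @export
psf_params <- function(w0x, w0y, zfx, zfy, zRx, zRy) {
  vals <- c(w0x = w0x, w0y = w0y, zRx = zRx, zRy = zRy)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("widths `w0x`, `w0y` and defocus scales `zRx`, `zRy` must be strictly positive", call. = FALSE)
  }
  if (!is.finite(zfx) || !is.finite(zfy) || zfx == zfy) {
    stop("astigmatism requires two separated focal planes: `zfx` must differ from `zfy`", call. = FALSE)
  }
  structure(
    list(w0x = w0x, w0y = w0y, zfx = zfx, zfy = zfy, zRx = zRx, zRy = zRy),
    class = "psf_params"
  )
}

#' Default optics matching the reference system
#'
#' In-focus width chosen so the lateral FWHM is 12.6 um; focal planes at
#' -300 and +300 um give the ~600 um usable depth range.
#'
#' @param focal_separation_um Axial distance between the two focal planes (um).
#' @param fwhm_um In-focus lateral FWHM (um).
#' @param zR_um Defocus scale shared by both axes (um).
#' @return A [psf_params()] object.
#' @export
default_psf_params <- function(focal_separation_um = 600, fwhm_um = 12.6, zR_um = 300) {
  w0 <- fwhm_um / sqrt(2 * log(2))
  psf_params(
    w0x = w0, w0y = w0,
    zfx = -focal_separation_um / 2, zfy = focal_separation_um / 2,
    zRx = zR_um, zRy = zR_um
  )
}

#' @export
print.psf_params <- function(x, ...) {
  cat("<astigmatic PSF>\n")
  cat(sprintf("  w0 (um):  x %.3f  y %.3f\n", x$w0x, x$w0y))
  cat(sprintf("  zf (um):  x %.1f  y %.1f  (separation %.1f)\n",
              x$zfx, x$zfy, abs(x$zfx - x$zfy)))
  cat(sprintf("  zR (um):  x %.1f  y %.1f\n", x$zRx, x$zRy))
  invisible(x)
}

#' PSF axis widths at a given depth
#'
#' @param params A [psf_params()] object.
#' @param z Depth(s) in micrometres (vectorised).
#' @return A tibble with columns `z_um`, `wx_um`, `wy_um`.
#' @export
psf_widths <- function(params, z) {
  stopifnot(inherits(params, "psf_params"))
  tibble::tibble(
    z_um = z,
    wx_um = params$w0x * sqrt(1 + ((z - params$zfx) / params$zRx)^2),
    wy_um = params$w0y * sqrt(1 + ((z - params$zfy) / params$zRy)^2)
  )
}

#' PSF ellipticity
#'
#' The depth-encoding scalar `(wx - wy) / (wx + wy)`: zero for a round PSF,
#' odd under exchange of the axes, and strictly inside (-1, 1).
#'
#' @param wx,wy Axis widths (um), strictly positive; vectorised.
#' @return Numeric vector of ellipticities.
#' @export
ellipticity <- function(wx, wy) {
  if (any(!is.finite(wx)) || any(!is.finite(wy)) || any(wx <= 0) || any(wy <= 0)) {
    stop("PSF widths must be strictly positive and finite", call. = FALSE)
  }
  (wx - wy) / (wx + wy)
}

#' FWHM of one PSF axis
#'
#' For the intensity profile `a * exp(-2 r^2 / w^2)` the full width at half
#' maximum is `w * sqrt(2 * log(2))`.
#'
#' @param w 1/e^2 half-width (um), strictly positive; vectorised.
#' @return FWHM in the same units.
#' @export
fwhm_from_width <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("width must be strictly positive", call. = FALSE)
  }
  w * sqrt(2 * log(2))
}

#' A single elliptical-Gaussian PSF realisation
#'
#' Parameter vector of the image-formation model
#' `f(x, y) = a * exp(-2 (x - x0)^2 / wx^2 - 2 (y - y0)^2 / wy^2) + c`.
#'
#' @param a Peak amplitude above offset (counts), > 0.
#' @param x0,y0 Centre position (um).
#' @param wx,wy Axis 1/e^2 half-widths (um), > 0.
#' @param c Constant offset (counts), >= 0.
#' @return An object of class `psf_sample`.
#' @export
psf_sample <- function(a, x0, y0, wx, wy, c = 0) {
  if (!is.finite(a) || a <= 0) stop("amplitude `a` must be > 0", call. = FALSE)
  if (any(c(wx, wy) <= 0) || any(!is.finite(c(wx, wy)))) {
    stop("widths `wx`, `wy` must be > 0", call. = FALSE)
  }
  if (!is.finite(c) || c < 0) stop("offset `c` must be >= 0", call. = FALSE)
  structure(list(a = a, x0 = x0, y0 = y0, wx = wx, wy = wy, c = c),
            class = "psf_sample")
}

# Evaluate the elliptical Gaussian on physical coordinate vectors (um).
# Returns the outer-product image as a matrix [length(y), length(x)].
eval_elliptical_gaussian <- function(a, x0, y0, wx, wy, c, x_um, y_um) {
  gx <- exp(-2 * (x_um - x0)^2 / wx^2)
  gy <- exp(-2 * (y_um - y0)^2 / wy^2)
  a * (gy %o% gx) + c
}

#' Render a PSF onto a pixel raster
#'
#' Evaluates the elliptical Gaussian at pixel centres. The raster follows
#' the package convention: pixel (row, col) has physical centre
#' `((col - 1) * pixel_size, (row - 1) * pixel_size)` so the top-left pixel
#' centre is the origin.
#'
#' @param sample A [psf_sample()].
#' @param ny,nx Raster size in pixels (> 0).
#' @param pixel_size_um Pixel pitch at the object plane (um).
#' @return Numeric matrix `ny x nx` of counts.
#' @export
render_psf <- function(sample, ny, nx, pixel_size_um) {
  stopifnot(inherits(sample, "psf_sample"))
  if (ny < 1 || nx < 1) stop("raster must contain at least one pixel", call. = FALSE)
  x_um <- (seq_len(nx) - 1) * pixel_size_um
  y_um <- (seq_len(ny) - 1) * pixel_size_um
  eval_elliptical_gaussian(sample$a, sample$x0, sample$y0,
                           sample$wx, sample$wy, sample$c, x_um, y_um)
}

#' Serialise PSF parameters to JSON
#'
#' @param params A [psf_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psf_params <- function(params, path) {
  stopifnot(inherits(params, "psf_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read PSF parameters from JSON
#'
#' @param path File written by [write_psf_params()].
#' @return A [psf_params()] object.
#' @export
read_psf_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  psf_params(as.numeric(p$w0x), as.numeric(p$w0y),
             as.numeric(p$zfx), as.numeric(p$zfy),
             as.numeric(p$zRx), as.numeric(p$zRy))
}

# Smooth field-dependent aberration of the optics across the FOV, used to
# exercise the sub-region calibration. The perturbation is a fixed smooth
# surface of the normalised lateral position (u, v in [0, 1]):
#   zfx -> zfx + amp * sin(pi u) cos(pi v),  zfy -> zfy - amp * cos(pi u) sin(pi v)
#   w0  -> w0 * (1 + rel * (u - 0.5) * (v - 0.5))
psf_at_position <- function(params, x_um, y_um, fov_um,
                            aberration = NULL) {
  if (is.null(aberration)) return(params)
  u <- min(max(x_um / fov_um[1], 0), 1)
  v <- min(max(y_um / fov_um[2], 0), 1)
  amp <- aberration$zf_amp_um %||% 0
  rel <- aberration$w0_rel %||% 0
  scale <- 1 + rel * (u - 0.5) * (v - 0.5)
  psf_params(
    w0x = params$w0x * scale,
    w0y = params$w0y * scale,
    zfx = params$zfx + amp * sin(pi * u) * cos(pi * v),
    zfy = params$zfy - amp * cos(pi * u) * sin(pi * v),
    zRx = params$zRx, zRy = params$zRy
  )
}
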