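#' Optical recording configuration
#'
#' Describes the off-axis digital holographic recording geometry shared by
#' the simulator and the reconstructor: illumination wavelength, camera
#' pixel pitch and sensor size, and the spatial carrier frequency introduced
#' by the tilted reference beam.
#'
#' The carrier can be given directly as `(carrier_fx, carrier_fy)` in
#' cycles/metre, or implicitly through `tilt_angle` (radians), in which case
#' the carrier magnitude is `sin(tilt_angle)/wavelength` split equally over
#' both axes (a diagonal fringe pattern). When neither is supplied the
#' default puts a quarter of the sampling frequency on each axis,
#' `fx = fy = 1/(4 * pixel_pitch)` — the classic off-axis choice that keeps
#' the +1 order, the -1 order and the DC term separated, and aligns the
#' carrier with an integer number of fringe cycles across the frame whenever
#' the sensor size is divisible by 4.
#'
#' @param wavelength Illumination wavelength in metres. Default 532e-9
#'   (green solid-state laser).
#' @param pixel_pitch Camera pixel size in metres. Default 5.5e-6.
#' @param sensor_ny,sensor_nx Sensor dimensions in pixels (rows, columns).
#'   Default 2048 each; set smaller for desk-scale work.
#' @param carrier_fx,carrier_fy Spatial carrier frequency in cycles/metre
#'   along image x (columns) and y (rows). Ignored when `tilt_angle` is
#'   given.
#' @param tilt_angle Optional reference-beam tilt in radians; implies a
#'   carrier of magnitude `sin(tilt_angle)/wavelength` on the diagonal.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(sensor_ny = 256, sensor_nx = 256)
#' cfg$carrier_fx * cfg$pixel_pitch  # cycles per pixel
#' @export
optical_config <- function(wavelength = 532e-9,
                           pixel_pitch = 5.5e-6,
                           sensor_ny = 2048L,
                           sensor_nx = 2048L,
                           carrier_fx = NULL,
                           carrier_fy = NULL,
                           tilt_angle = NULL) {
  stopifnot(wavelength > 0, pixel_pitch > 0,
            sensor_ny >= 8, sensor_nx >= 8)
  if (!is.null(tilt_angle)) {
    f_mag <- sin(tilt_angle) / wavelength
    carrier_fx <- f_mag / sqrt(2)
    carrier_fy <- f_mag / sqrt(2)
  } else if (is.null(carrier_fx) || is.null(carrier_fy)) {
    carrier_fx <- 1 / (4 * pixel_pitch)
    carrier_fy <- 1 / (4 * pixel_pitch)
  }
  cfg <- structure(
    list(wavelength = wavelength,
         pixel_pitch = pixel_pitch,
         sensor_ny = as.integer(sensor_ny),
         sensor_nx = as.integer(sensor_nx),
         carrier_fx = carrier_fx,
         carrier_fy = carrier_fy,
         tilt_angle = tilt_angle),
    class = "optical_config")
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  f_mag <- sqrt(cfg$carrier_fx^2 + cfg$carrier_fy^2)
  nyq <- 1 / (2 * cfg$pixel_pitch)
  if (f_mag >= nyq) {
    stop("carrier frequency magnitude ", format(f_mag),
         " cycles/m violates the Nyquist limit 1/(2*pixel_pitch) = ",
         format(nyq), call. = FALSE)
  }
  if (!is.null(cfg$tilt_angle)) {
    expect <- sin(cfg$tilt_angle) / cfg$wavelength
    if (abs(f_mag - expect) > 1e-12 * max(abs(expect), 1)) {
      stop("carrier magnitude inconsistent with tilt_angle", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength : %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  pixel pitch: %.2f um\n", x$pixel_pitch * 1e6))
  cat(sprintf("  sensor     : %d x %d px\n", x$sensor_ny, x$sensor_nx))
  cat(sprintf("  carrier    : (%.3g, %.3g) cycles/m  (%.3f, %.3f) cycles/px\n",
              x$carrier_fx, x$carrier_fy,
              x$carrier_fx * x$pixel_pitch, x$carrier_fy * x$pixel_pitch))
  invisible(x)
}

# Spatial coordinate grids in metres. Pixel (1,1) sits at (x,y) = (0,0),
# x grows along columns, y along rows.
coord_grids <- function(ny, nx, pitch) {
  x <- matrix((seq_len(nx) - 1) * pitch, ny, nx, byrow = TRUE)
  y <- matrix((seq_len(ny) - 1) * pitch, ny, nx, byrow = FALSE)
  list(x = x, y = y)
}

# FFT frequency axis in cycles/metre (DC first, then positive, then
# negative frequencies), matching stats::fft ordering.
fft_freq <- function(n, pitch) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * pitch)
}

freq_grids <- function(ny, nx, pitch) {
  fx <- fft_freq(nx, pitch)
  fy <- fft_freq(ny, pitch)
  list(fx = matrix(fx, ny, nx, byrow = TRUE),
       fy = matrix(fy, ny, nx, byrow = FALSE))
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Complex optical field at a stated axial position
#'
#' A thin container for a reconstructed complex amplitude: the 2D complex
#' array, the axial position `z` (metres, relative to the hologram plane)
#' and the [optical_config()] it was recorded with.
#'
#' @param field 2D complex (or real) matrix matching the sensor dimensions.
#' @param z Axial position in metres.
#' @param config An [optical_config()].
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(field, z, config) {
  stopifnot(is.matrix(field), is.finite(z),
            inherits(config, "optical_config"))
  if (!all(dim(field) == c(config$sensor_ny, config$sensor_nx))) {
    # fields cropped out of a larger reconstruction keep their own geometry
    config$sensor_ny <- nrow(field)
    config$sensor_nx <- ncol(field)
  }
  structure(list(field = field + 0i, z = z, config = config),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d at z = %.4g m\n",
              nrow(x$field), ncol(x$field), x$z))
  invisible(x)
}
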