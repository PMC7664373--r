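#' Demodulate an off-axis hologram
#'
#' Recovers the baseband complex object wave from the recorded intensity.
#' The spectrum of an off-axis hologram contains the object term riding on
#' the carrier (+1 order), its conjugate (-1 order) and the DC
#' autocorrelation. Demodulation multiplies the intensity by the conjugate
#' carrier wave — which translates the +1 order to the spectral origin —
#' and then applies a circular low-pass of radius `filter_radius`,
#' rejecting the DC term and the -1 order. This is the textbook "select a
#' bandpass around the carrier peak and shift it to baseband", implemented
#' in a form that is exact for carriers that do not sit on an integer
#' Fourier bin.
#'
#' @param hologram A `hologram` (see [form_hologram()] or
#'   [read_hologram()]).
#' @param filter_radius Bandpass radius in cycles/metre. Default: half the
#'   carrier magnitude, the largest radius guaranteed not to touch the DC
#'   peak while leaving room for the autocorrelation skirt.
#' @param phi_r Reference-beam phase offset assumed during recording.
#' @return A [complex_field()] at `z = 0` approximating
#'   `|O| exp(i psi_o)`.
#' @examples
#' cfg <- optical_config(sensor_ny = 128, sensor_nx = 128)
#' sl <- make_phantom_slide(1, c(128, 128),
#'                          phantom_morphology(radius_range_px = c(12, 16)),
#'                          seed = 3)
#' fld <- demodulate(form_hologram(sl, cfg))
#' @export
demodulate <- function(hologram, filter_radius = NULL, phi_r = 0) {
  stopifnot(inherits(hologram, "hologram"))
  cfg <- hologram$config
  validate_optical_config(cfg)
  f_mag <- sqrt(cfg$carrier_fx^2 + cfg$carrier_fy^2)
  if (is.null(filter_radius)) filter_radius <- f_mag / 2
  if (filter_radius >= f_mag) {
    stop("filter_radius (", format(filter_radius),
         ") reaches the DC term: must be < carrier magnitude ",
         format(f_mag), call. = FALSE)
  }
  g <- coord_grids(cfg$sensor_ny, cfg$sensor_nx, cfg$pixel_pitch)
  carrier <- exp(-1i * (2 * pi * (cfg$carrier_fx * g$x + cfg$carrier_fy * g$y)
                        - phi_r))
  shifted <- hologram$intensity * carrier
  fr <- freq_grids(cfg$sensor_ny, cfg$sensor_nx, cfg$pixel_pitch)
  mask <- (fr$fx^2 + fr$fy^2) <= filter_radius^2
  spec <- fft2(shifted)
  spec[!mask] <- 0i
  complex_field(ifft2(spec), z = 0, config = cfg)
}

# Angular spectrum propagation on a bare complex matrix.
propagate_matrix <- function(m, dz, cfg) {
  if (dz == 0) return(m)
  fr <- freq_grids(nrow(m), ncol(m), cfg$pixel_pitch)
  f2 <- fr$fx^2 + fr$fy^2
  k2 <- 1 / cfg$wavelength^2
  prop <- f2 <= k2
  kz <- sqrt(pmax(k2 - f2, 0))
  transfer <- matrix(0i, nrow(m), ncol(m))
  transfer[prop] <- exp(1i * 2 * pi * dz * kz[prop])
  ifft2(fft2(m) * transfer)
}

#' Propagate a complex field by the angular spectrum method
#'
#' Applies the exact scalar-diffraction transfer function
#' `exp(i 2 pi dz sqrt(1/lambda^2 - fx^2 - fy^2))` in the Fourier domain.
#' Evanescent components (`fx^2 + fy^2 > 1/lambda^2`) are set to zero,
#' which avoids exponential blow-up when propagating backwards. For
#' band-limited fields the operator is unitary, so energy is conserved and
#' `propagate(propagate(u, dz), -dz)` returns `u`.
#'
#' @param field A [complex_field()].
#' @param dz Propagation distance in metres (signed).
#' @return A [complex_field()] at `z + dz`.
#' @export
propagate <- function(field, dz) {
  stopifnot(inherits(field, "complex_field"), is.finite(dz))
  complex_field(propagate_matrix(field$field, dz, field$config),
                z = field$z + dz, config = field$config)
}

#' Tamura coefficient of an amplitude image
#'
#' The contrast statistic `sqrt(sd(a) / mean(a))` with the population
#' standard deviation. For a pure phase object the reconstructed amplitude
#' is flattest — and the Tamura coefficient smallest — at best focus, which
#' is why [autofocus()] minimizes it.
#'
#' @param amplitude Non-negative numeric matrix or vector.
#' @return A single non-negative number.
#' @examples
#' tamura(c(1, 3))  # sqrt(1 / 2)
#' @export
tamura <- function(amplitude) {
  if (length(amplitude) == 0) stop("empty amplitude", call. = FALSE)
  if (any(amplitude < 0)) stop("amplitude must be >= 0", call. = FALSE)
  mu <- mean(amplitude)
  if (mu == 0) stop("tamura undefined for zero-mean amplitude", call. = FALSE)
  sdev <- sqrt(mean((amplitude - mu)^2))
  sqrt(sdev / mu)
}

#' Autofocus by Tamura-coefficient minimization
#'
#' Scans propagation distance, evaluating the Tamura coefficient of the
#' propagated amplitude on a uniform coarse grid over `[z_min, z_max]`,
#' then refines around the running minimum by successive step halving:
#' each refinement level evaluates the two midpoints flanking the current
#' best at half the previous step. After `n_refine_levels` rounds the best
#' focus is bracketed to within
#' `(z_max - z_min) / (n_coarse - 1) / 2^n_refine_levels`.
#'
#' @param field A [complex_field()] (typically the demodulated hologram at
#'   `z = 0`).
#' @param z_min,z_max Search interval in metres.
#' @param n_coarse Number of coarse grid points (>= 3).
#' @param n_refine_levels Number of step-halving refinement rounds.
#' @return An object of class `focus_scan`: `scan` (tibble of all `(z, tamura,
#'   stage)` evaluations), `z_best`, `t_best`, `bracket` (final half-width).
#'   Warns, without failing, when the coarse minimum sits on the search
#'   boundary.
#' @export
autofocus <- function(field, z_min, z_max, n_coarse = 21L,
                      n_refine_levels = 3L) {
  stopifnot(inherits(field, "complex_field"), z_min < z_max, n_coarse >= 3)
  z_grid <- seq(z_min, z_max, length.out = n_coarse)
  step <- z_grid[2] - z_grid[1]
  tam_at <- function(z) tamura(Mod(propagate_matrix(field$field, z,
                                                    field$config)))
  t_coarse <- vapply(z_grid, tam_at, numeric(1))
  evals <- tibble::tibble(z = z_grid, tamura = t_coarse, stage = "coarse")
  i_best <- which.min(t_coarse)
  if (i_best == 1L || i_best == n_coarse) {
    warning("autofocus minimum on search boundary; ",
            "consider widening [z_min, z_max]", call. = FALSE)
  }
  z_best <- z_grid[i_best]; t_best <- t_coarse[i_best]
  for (lev in seq_len(n_refine_levels)) {
    step <- step / 2
    for (z in c(z_best - step, z_best + step)) {
      tv <- tam_at(z)
      evals <- dplyr::bind_rows(
        evals, tibble::tibble(z = z, tamura = tv,
                              stage = paste0("refine", lev)))
      if (tv < t_best) { t_best <- tv; z_best <- z }
    }
  }
  structure(list(scan = evals, z_best = z_best, t_best = t_best,
                 bracket = step),
            class = "focus_scan")
}

#' @export
print.focus_scan <- function(x, ...) {
  cat(sprintf("<focus_scan> z_best = %.5g m (T = %.4f), %d evaluations, bracket %.3g m\n",
              x$z_best, x$t_best, nrow(x$scan), x$bracket))
  invisible(x)
}

#' @export
#' @rdname autofocus
#' @param x A `focus_scan`.
#' @param ... Unused.
tidy.focus_scan <- function(x, ...) x$scan

#' Plot a focus scan
#'
#' @param object A `focus_scan` from [autofocus()].
#' @param ... Unused.
#' @return A ggplot of the Tamura coefficient against propagation distance,
#'   refinement evaluations overlaid, best focus marked.
#' @export
autoplot.focus_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$z, y = .data$tamura,
                               colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = dplyr::filter(object$scan,
                                            .data$stage == "coarse")) +
    ggplot2::geom_vline(xintercept = object$z_best, linetype = 2) +
    ggplot2::labs(x = "propagation distance z (m)",
                  y = "Tamura coefficient", colour = NULL)
}

#' Extract the wrapped quantitative phase image of a field
#'
#' Per-pixel argument of the complex field, wrapped to `[-pi, pi)` (the
#' half-open convention: a field value of -1 maps to `-pi`).
#'
#' @param field A [complex_field()].
#' @param class_id Optional class label to attach.
#' @return A [wqpi()].
#' @export
extract_wqpi <- function(field, class_id = NA_integer_) {
  stopifnot(inherits(field, "complex_field"))
  wqpi(wrap_phase(Arg(field$field)), class_id = class_id,
       pixel_pitch = field$config$pixel_pitch)
}

#' Compensate a constant phase offset
#'
#' Estimates the global phase offset of a wrapped phase image from the
#' mode of its phase histogram (the flat background concentrates there;
#' the estimate is then refined by a circular mean over pixels within
#' 0.3 rad of the mode) and subtracts it. This is the constant-offset
#' residual-aberration compensation step: offsets introduced by the
#' reference beam or the reconstruction shift every pixel equally and are
#' removed before segmentation; anything left over is what the phase-bias
#' augmentation teaches classifiers to tolerate.
#'
#' @param x A [wqpi()].
#' @return A list with `wqpi` (compensated image) and `offset` (estimated
#'   radians).
#' @export
compensate_offset <- function(x) {
  stopifnot(inherits(x, "wqpi"))
  h <- graphics::hist(x$phase, breaks = seq(-pi, pi, length.out = 257),
                      plot = FALSE)
  mode0 <- h$mids[which.max(h$counts)]
  near <- Mod(exp(1i * (x$phase - mode0))) > 0 &
    abs(Arg(exp(1i * (x$phase - mode0)))) < 0.3
  offset <- Arg(mean(exp(1i * x$phase[near])))
  list(wqpi = wqpi(wrap_phase(x$phase - offset), class_id = x$class_id,
                   pixel_pitch = x$pixel_pitch),
       offset = offset)
}

#' Write a focus scan as CSV
#'
#' @param x A `focus_scan`.
#' @param path CSV path (columns `z`, `tamura`, `stage`).
#' @return `path`, invisibly.
#' @export
write_focus_scan <- function(x, path) {
  utils::write.csv(x$scan, path, row.names = FALSE)
  invisible(path)
}
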