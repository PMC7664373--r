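#' Morphology settings for phantom slides
#'
#' Parameters controlling the parametric phase-object families used by
#' [make_phantom_slide()]. Each class is assigned one of five families
#' (elliptic with longitudinal striae, pennate-like with transverse striae,
#' centric with radial arms, annular, ringed dome) together with
#' class-specific texture frequencies, aspect ratios and peak phase, so
#' that classes are morphologically distinct the way diatom species are.
#'
#' @param radius_range_px Range of object radii in pixels.
#' @param peak_phase_range Range of peak optical phase in radians. The
#'   default exceeds 2*pi so that the wrapped phase image genuinely wraps.
#' @param edge_taper Fraction of the radius over which the phase profile is
#'   smoothly tapered to zero (raised-cosine edge).
#' @param margin_px Minimum clearance, in pixels, between object supports
#'   and between an object and the frame border.
#' @param max_attempts Placement attempts per object before
#'   [make_phantom_slide()] gives up with an error.
#' @return A list of class `phantom_morphology`.
#' @export
phantom_morphology <- function(radius_range_px = c(22, 38),
                               peak_phase_range = c(2.2 * pi, 3.2 * pi),
                               edge_taper = 0.35,
                               margin_px = 12,
                               max_attempts = 2000L) {
  stopifnot(length(radius_range_px) == 2, all(radius_range_px > 2),
            diff(radius_range_px) >= 0,
            length(peak_phase_range) == 2, all(peak_phase_range > 0),
            edge_taper > 0, edge_taper < 1, max_attempts >= 1)
  structure(list(radius_range_px = radius_range_px,
                 peak_phase_range = peak_phase_range,
                 edge_taper = edge_taper,
                 margin_px = margin_px,
                 max_attempts = as.integer(max_attempts)),
            class = "phantom_morphology")
}

# Deterministic per-class morphology parameters. Classes cycle through the
# five families; texture frequency, aspect and arm count walk with the
# class index so neighbouring classes stay distinguishable.
class_params <- function(class_id, morph_seed, morphology) {
  withr::with_seed((morph_seed %% 100000L) * 101L + class_id, {
    list(
      family = (class_id - 1L) %% 5L,
      aspect = stats::runif(1, 1.3, 2.4),
      stria_freq = 1 + (class_id %% 3) + stats::runif(1, 0, 0.5),
      stria_amp = stats::runif(1, 0.4, 0.7),
      n_arms = 3L + (class_id %% 4L),
      peak_phase = stats::runif(1, morphology$peak_phase_range[1],
                                morphology$peak_phase_range[2]),
      base_orientation = stats::runif(1, 0, pi)
    )
  })
}

# Render one phase object on a (2r+1)^2 patch. Returns a non-negative
# matrix that tapers smoothly to zero at the support boundary.
render_object <- function(params, radius_px, orientation, taper) {
  n <- 2L * ceiling(radius_px) + 1L
  c0 <- (n + 1) / 2
  u0 <- outer(rep(1, n), (seq_len(n) - c0) / radius_px)   # along columns
  v0 <- outer((seq_len(n) - c0) / radius_px, rep(1, n))   # along rows
  co <- cos(orientation); si <- sin(orientation)
  u <- co * u0 + si * v0
  v <- -si * u0 + co * v0
  a <- params$aspect
  k <- params$stria_freq
  ta <- params$stria_amp
  fam <- params$family
  # striae are additive with fixed (sub-radian) amplitude so that texture
  # gradients stay inside the demodulation passband regardless of the
  # object's peak phase
  if (fam == 0L) {              # elliptic, striae along the major axis
    rho <- sqrt(u^2 + (a * v)^2)
    tex <- ta * cos(2 * pi * k * u)
    prof <- pmax(1 - rho^2, 0)
  } else if (fam == 1L) {       # pennate-like superellipse, transverse striae
    rho <- (abs(u)^1.6 + abs(a * v)^1.6)^(1 / 1.6)
    tex <- ta * cos(2 * pi * k * v * a)
    prof <- pmax(1 - rho^2, 0)
  } else if (fam == 2L) {       # centric with radial arms
    rho <- sqrt(u^2 + v^2)
    th <- atan2(v, u)
    tex <- ta * cos(params$n_arms * th) * pmin(rho * 3, 1)
    prof <- pmax(1 - rho^2, 0)
  } else if (fam == 3L) {       # annulus with ring texture
    rho <- sqrt(u^2 + v^2)
    tex <- ta * cos(2 * pi * k * rho)
    prof <- exp(-((rho - 0.55) / 0.35)^2)
  } else {                      # dome with concentric rings
    rho <- sqrt(u^2 + v^2)
    tex <- ta * cos(2 * pi * k * rho^2)
    prof <- pmax(1 - rho^2, 0)
  }
  win <- edge_window(rho, taper)
  phase <- (params$peak_phase * prof + tex) * win
  phase[rho >= 1] <- 0
  pmax(phase, 0)
}

# Raised-cosine window: 1 inside rho <= 1 - taper, cosine roll-off to 0 at 1.
edge_window <- function(rho, taper) {
  w <- matrix(0, nrow(rho), ncol(rho))
  inner <- rho <= 1 - taper
  edge <- rho > 1 - taper & rho < 1
  w[inner] <- 1
  w[edge] <- 0.5 * (1 + cos(pi * (rho[edge] - (1 - taper)) / taper))
  w
}

#' Generate a phantom slide of labeled phase objects
#'
#' Builds a synthetic "test slide": `n_classes` disjoint pure-phase objects,
#' one per class, placed without overlap on a zero-phase background. Each
#' class has a distinct parametric morphology (see [phantom_morphology()])
#' and a peak phase that by default exceeds 2*pi, so that the wrapped phase
#' image wraps inside objects. Output is deterministic for a fixed seed.
#'
#' @param n_classes Number of classes (= number of objects placed).
#' @param image_shape Integer pair `(ny, nx)` giving the canvas in pixels.
#' @param morphology A [phantom_morphology()] configuration.
#' @param seed Integer seed controlling placement and per-class parameters.
#' @return An object of class `phantom_slide`: `true_phase` (radians,
#'   unwrapped ground truth), `label_map` (0 background, k inside object of
#'   class k), and `objects`, a tibble with one row per object (class id,
#'   centroid, radius, defocus).
#' @examples
#' sl <- make_phantom_slide(3, c(256, 256), seed = 1)
#' sl$objects
#' @export
make_phantom_slide <- function(n_classes,
                               image_shape = c(1024L, 1024L),
                               morphology = phantom_morphology(),
                               seed = 1L) {
  stopifnot(n_classes >= 1, length(image_shape) == 2)
  ny <- as.integer(image_shape[1]); nx <- as.integer(image_shape[2])
  phase <- matrix(0, ny, nx)
  labels <- matrix(0L, ny, nx)
  margin <- morphology$margin_px

  placed <- withr::with_seed(seed, {
    rows <- numeric(n_classes); cols <- numeric(n_classes)
    radii <- numeric(n_classes); orient <- numeric(n_classes)
    for (k in seq_len(n_classes)) {
      r <- stats::runif(1, morphology$radius_range_px[1],
                        morphology$radius_range_px[2])
      if (2 * r + 2 * margin >= min(ny, nx)) {
        stop("object radius too large for image_shape", call. = FALSE)
      }
      ok <- FALSE
      for (att in seq_len(morphology$max_attempts)) {
        cy <- stats::runif(1, r + margin + 1, ny - r - margin)
        cx <- stats::runif(1, r + margin + 1, nx - r - margin)
        if (k == 1L) { ok <- TRUE }
        else {
          d <- sqrt((rows[seq_len(k - 1)] - cy)^2 +
                    (cols[seq_len(k - 1)] - cx)^2)
          ok <- all(d >= radii[seq_len(k - 1)] + r + margin)
        }
        if (ok) break
      }
      if (!ok) {
        stop("could not place ", n_classes, " disjoint objects in a ",
             ny, "x", nx, " canvas after ", morphology$max_attempts,
             " attempts per object", call. = FALSE)
      }
      rows[k] <- cy; cols[k] <- cx; radii[k] <- r
      orient[k] <- stats::runif(1, 0, pi)
    }
    list(rows = rows, cols = cols, radii = radii, orient = orient)
  })

  for (k in seq_len(n_classes)) {
    params <- class_params(k, seed, morphology)
    patch <- render_object(params, placed$radii[k],
                           params$base_orientation + placed$orient[k],
                           morphology$edge_taper)
    np <- nrow(patch)
    r0 <- round(placed$rows[k]) - (np - 1L) %/% 2L
    c0 <- round(placed$cols[k]) - (np - 1L) %/% 2L
    rr <- r0:(r0 + np - 1L); cc <- c0:(c0 + np - 1L)
    sup <- patch > 1e-9
    phase[rr, cc][sup] <- patch[sup]
    labels[rr, cc][sup] <- k
  }

  objects <- tibble::tibble(
    class_id = seq_len(n_classes),
    centroid_row = placed$rows,
    centroid_col = placed$cols,
    radius_px = placed$radii,
    defocus_z = 0
  )
  structure(list(true_phase = phase, label_map = labels, objects = objects,
                 image_shape = c(ny, nx), seed = as.integer(seed)),
            class = "phantom_slide")
}

#' @export
print.phantom_slide <- function(x, ...) {
  cat(sprintf("<phantom_slide> %d x %d px, %d objects, seed %d\n",
              x$image_shape[1], x$image_shape[2], nrow(x$objects), x$seed))
  invisible(x)
}

#' Form an off-axis hologram of a phantom slide
#'
#' Computes the recorded intensity `|R + O|^2` of the interference between
#' a unit-amplitude tilted plane reference wave
#' `R = exp(i[2 pi (fx x + fy y) - phi_r])` and the object wave
#' `O = A exp(i psi_o)` carrying the slide's phase. With zero defocus, zero
#' noise and `A = 1` this is exactly
#' `2 + 2 cos(2 pi (fx x + fy y) - phi_r + psi_o)` pointwise. A nonzero
#' `defocus_z` propagates the object wave by the angular spectrum method
#' before interference, emulating recording away from the focal plane.
#'
#' @param slide A [make_phantom_slide()] result (its canvas must match the
#'   sensor dimensions in `config`).
#' @param config An [optical_config()].
#' @param defocus_z Object-to-hologram-plane distance in metres (0 = in
#'   focus at the sensor).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise;
#'   the noisy intensity is clipped at 0.
#' @param seed Seed for the noise draw (required when `noise_sd > 0`).
#' @param object_amplitude Amplitude of the object wave (0 suppresses the
#'   object beam entirely; default 1, a pure phase object).
#' @param phi_r Constant reference-beam phase offset in radians.
#' @return An object of class `hologram` with fields `intensity`, `config`
#'   and `true_defocus`.
#' @examples
#' cfg <- optical_config(sensor_ny = 128, sensor_nx = 128)
#' sl <- make_phantom_slide(1, c(128, 128),
#'                          phantom_morphology(radius_range_px = c(14, 18)),
#'                          seed = 2)
#' h <- form_hologram(sl, cfg)
#' range(h$intensity)
#' @export
form_hologram <- function(slide, config, defocus_z = 0, noise_sd = 0,
                          seed = NULL, object_amplitude = 1, phi_r = 0) {
  stopifnot(inherits(slide, "phantom_slide"),
            inherits(config, "optical_config"),
            noise_sd >= 0, is.finite(defocus_z))
  validate_optical_config(config)
  if (!all(slide$image_shape == c(config$sensor_ny, config$sensor_nx))) {
    stop("slide canvas does not match sensor dimensions", call. = FALSE)
  }
  obj <- object_amplitude * exp(1i * slide$true_phase)
  if (defocus_z != 0) {
    obj <- propagate_matrix(obj, defocus_z, config)
  }
  g <- coord_grids(config$sensor_ny, config$sensor_nx, config$pixel_pitch)
  # reference with phase -(2 pi f.r - phi_r): the interference cross term
  # is then 2|R||O| cos(2 pi (fx x + fy y) - phi_r + psi_o)
  ref <- exp(-1i * (2 * pi * (config$carrier_fx * g$x + config$carrier_fy * g$y)
                    - phi_r))
  intensity <- Mod(ref + obj)^2
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    noise <- withr::with_seed(seed, {
      matrix(stats::rnorm(length(intensity), sd = noise_sd),
             nrow(intensity), ncol(intensity))
    })
    intensity <- pmax(intensity + noise, 0)
  }
  structure(list(intensity = intensity, config = config,
                 true_defocus = defocus_z),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, true defocus %.4g m\n",
              nrow(x$intensity), ncol(x$intensity), x$true_defocus))
  invisible(x)
}

#' Simulate a "wet" single-object hologram
#'
#' Emulates recording a live, suspended specimen: one object of a known
#' class (sharing the morphology of that class on the training slide via
#' `morph_seed`, with fresh instance jitter in size and orientation), a
#' random defocus drawn uniformly from `defocus_range`, a random residual
#' phase offset on the object support drawn from `bias_range`, and additive
#' intensity noise. The returned hologram carries the true class and true
#' defocus for evaluation.
#'
#' @param class_id Class whose morphology to instantiate.
#' @param config An [optical_config()]; its sensor dimensions set the
#'   canvas.
#' @param morph_seed Seed tying class morphologies to a training slide
#'   (pass the slide's seed).
#' @param seed Per-object seed for instance jitter, defocus, bias, noise.
#' @param defocus_range Length-2 range (metres) for the true defocus.
#' @param noise_sd Intensity noise standard deviation.
#' @param bias_range Length-2 range (radians) for the residual phase offset.
#' @param radius_px Nominal object radius in pixels, typically the radius
#'   the class has on the training slide (live specimens of a species
#'   share its size up to a few percent); defaults to the midpoint of the
#'   morphology's radius range. Instance jitter of +/- 8% is applied.
#' @param morphology A [phantom_morphology()].
#' @return A `hologram` with extra fields `true_class` and `true_defocus`.
#' @export
simulate_wet_object <- function(class_id, config, morph_seed, seed,
                                defocus_range = c(-2e-3, 2e-3),
                                noise_sd = 0.02,
                                bias_range = c(0, pi),
                                radius_px = NULL,
                                morphology = phantom_morphology()) {
  ny <- config$sensor_ny; nx <- config$sensor_nx
  draws <- withr::with_seed(seed, {
    list(defocus = stats::runif(1, defocus_range[1], defocus_range[2]),
         bias = stats::runif(1, bias_range[1], bias_range[2]),
         rad_jit = stats::runif(1, 0.92, 1.08),
         orient = stats::runif(1, 0, 2 * pi),
         noise_seed = sample.int(.Machine$integer.max - 1L, 1))
  })
  params <- class_params(class_id, morph_seed, morphology)
  if (is.null(radius_px)) radius_px <- mean(morphology$radius_range_px)
  r <- radius_px * draws$rad_jit
  patch <- render_object(params, r, draws$orient, morphology$edge_taper)
  sup <- patch > 1e-9
  np <- nrow(patch)
  if (np > min(ny, nx)) stop("object larger than canvas", call. = FALSE)
  phase <- matrix(0, ny, nx)
  labels <- matrix(0L, ny, nx)
  r0 <- (ny - np) %/% 2L + 1L; c0 <- (nx - np) %/% 2L + 1L
  rr <- r0:(r0 + np - 1L); cc <- c0:(c0 + np - 1L)
  phase[rr, cc][sup] <- patch[sup]
  labels[rr, cc][sup] <- class_id
  slide <- structure(
    list(true_phase = phase, label_map = labels,
         objects = tibble::tibble(class_id = class_id,
                                  centroid_row = (ny + 1) / 2,
                                  centroid_col = (nx + 1) / 2,
                                  radius_px = r,
                                  defocus_z = draws$defocus),
         image_shape = c(ny, nx), seed = as.integer(seed)),
    class = "phantom_slide")
  # the residual phase offset is carried by the reference beam: the
  # demodulated reconstruction then shows psi_o + bias over the whole
  # field, the situation the bias augmentation models
  holo <- form_hologram(slide, config, defocus_z = draws$defocus,
                        noise_sd = noise_sd, seed = draws$noise_seed,
                        phi_r = -draws$bias)
  holo$true_class <- class_id
  holo$true_bias <- draws$bias
  holo
}

#' Write / read a hologram with its optics sidecar
#'
#' The intensity is stored as 32-bit float TIFF rescaled to `[0, 1]`; the
#' linear rescaling (offset, scale), the [optical_config()] and the ground
#' truth (true defocus, class if known) go to a YAML sidecar next to the
#' TIFF, so the pair round-trips losslessly up to float precision.
#'
#' @param hologram A `hologram`.
#' @param path Path of the TIFF to write; the sidecar is `<path>.yaml`.
#' @return `write_hologram()` returns `path` invisibly; `read_hologram()`
#'   returns a `hologram`.
#' @export
write_hologram <- function(hologram, path) {
  stopifnot(inherits(hologram, "hologram"))
  sc <- write_scaled_tiff(hologram$intensity, path)
  cfg <- hologram$config
  meta <- list(
    optics = list(wavelength = cfg$wavelength, pixel_pitch = cfg$pixel_pitch,
                  sensor_ny = cfg$sensor_ny, sensor_nx = cfg$sensor_nx,
                  carrier_fx = cfg$carrier_fx, carrier_fy = cfg$carrier_fy),
    scale = sc,
    true_defocus = hologram$true_defocus,
    true_class = if (is.null(hologram$true_class)) NA else hologram$true_class
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- read_scaled_tiff(path, meta$scale)
  cfg <- optical_config(wavelength = meta$optics$wavelength,
                        pixel_pitch = meta$optics$pixel_pitch,
                        sensor_ny = meta$optics$sensor_ny,
                        sensor_nx = meta$optics$sensor_nx,
                        carrier_fx = meta$optics$carrier_fx,
                        carrier_fy = meta$optics$carrier_fy)
  h <- structure(list(intensity = m, config = cfg,
                      true_defocus = meta$true_defocus),
                 class = "hologram")
  if (!is.na(meta$true_class)) h$true_class <- meta$true_class
  h
}

# 32-bit float TIFF with linear [0,1] rescaling; returns the mapping.
write_scaled_tiff <- function(m, path) {
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32L,
                  compression = "none")
  list(offset = lo, scale = scale)
}

read_scaled_tiff <- function(path, sc) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * sc$scale + sc$offset
}
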