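# Shared fixture builders. Everything is generated in code at test time.

tiny_config <- function(n = 128L) {
  optical_config(sensor_ny = n, sensor_nx = n)
}

# Hand-built single-object slide with an arbitrary phase patch, centred.
manual_slide <- function(phase_fn, n = 256L) {
  ctr <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - ctr)^2, rep(1, n)) +
            outer(rep(1, n), (seq_len(n) - ctr)^2))
  phase <- phase_fn(r)
  lab <- matrix(0L, n, n)
  lab[phase > 1e-9] <- 1L
  structure(list(
    true_phase = phase, label_map = lab,
    objects = tibble::tibble(class_id = 1L, centroid_row = ctr,
                             centroid_col = ctr, radius_px = n / 4,
                             defocus_z = 0),
    image_shape = c(n, n), seed = 0L), class = "phantom_slide")
}

# Smooth gaussian phase dome: band-limited enough that demodulation is
# exact to ~1e-7 even at a 3*pi peak.
gaussian_dome_slide <- function(n = 256L, peak = 3 * pi, sigma = 20) {
  manual_slide(function(r) peak * exp(-r^2 / (2 * sigma^2)), n = n)
}

# Wide flat-top plateau with a raised-cosine skirt.
flat_top_slide <- function(n = 256L, peak = 1.2, r_in = 30, r_out = 60) {
  manual_slide(function(r) {
    peak * ifelse(r <= r_in, 1,
                  ifelse(r < r_out,
                         0.5 * (1 + cos(pi * (r - r_in) / (r_out - r_in))),
                         0))
  }, n = n)
}

# Morphology used by the autofocus-recovery suites: spatially smooth,
# weakly scattering objects for which amplitude-contrast autofocus is
# unbiased (see the methods vignette).
focus_suite_morphology <- function() {
  phantom_morphology(radius_range_px = c(40, 60), edge_taper = 0.45,
                     peak_phase_range = c(0.5, 1.5))
}

# Small random wqpi for augmentation tests.
random_wqpi <- function(n = 48L, seed = 1L, class_id = 1L) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n, -pi, pi * 0.999), n, n)
    wqpi(m, class_id = class_id)
  })
}
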