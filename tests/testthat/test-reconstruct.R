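test_that("demodulating a reference-only hologram yields a null field", {
  cfg <- tiny_config(128)
  sl <- manual_slide(function(r) 0 * r, n = 128)
  h <- form_hologram(sl, cfg, object_amplitude = 0)
  fld <- demodulate(h)
  expect_lt(max(Mod(fld$field)), 1e-9)
})

test_that("demodulation recovers the wrapped phase of smooth objects", {
  cfg <- tiny_config(256)
  # band-limited flat-top: plateau of 1.2 rad, wide raised-cosine skirt
  sl <- flat_top_slide(n = 256)
  wq <- extract_wqpi(demodulate(form_hologram(sl, cfg)))
  ctr <- (256 + 1) / 2
  r <- sqrt(outer((1:256 - ctr)^2, rep(1, 256)) +
            outer(rep(1, 256), (1:256 - ctr)^2))
  err <- abs(wrap_phase(wq$phase - wrap_phase(sl$true_phase)))
  expect_lt(max(err[r <= 24]), 1e-3)

  # gaussian dome with peak 3*pi: wrapping occurs, recovery stays ~1e-6
  sl2 <- gaussian_dome_slide(n = 256)
  wq2 <- extract_wqpi(demodulate(form_hologram(sl2, cfg)))
  err2 <- abs(wrap_phase(wq2$phase - wrap_phase(sl2$true_phase)))
  expect_lt(max(err2[r <= 40]), 1e-6)
  expect_gt(max(sl2$true_phase), 2 * pi)
})

test_that("demodulation filter must not reach the DC term", {
  cfg <- tiny_config(64)
  sl <- manual_slide(function(r) 0 * r, n = 64)
  h <- form_hologram(sl, cfg)
  f_mag <- sqrt(cfg$carrier_fx^2 + cfg$carrier_fy^2)
  expect_error(demodulate(h, filter_radius = f_mag * 1.01), "DC")
})

test_that("zero-distance propagation is the identity", {
  cfg <- tiny_config(64)
  u <- withr::with_seed(1, matrix(stats::rnorm(64^2), 64, 64) +
                           1i * matrix(stats::rnorm(64^2), 64, 64))
  fld <- complex_field(u, 0, cfg)
  out <- propagate(fld, 0)
  expect_lt(max(Mod(out$field - u)) / max(Mod(u)), 1e-12)
})

test_that("propagation round trips, composes and conserves energy", {
  cfg <- tiny_config(128)
  # band-limited random field: restrict the spectrum to low frequencies
  make_field <- function(seed) {
    withr::with_seed(seed, {
      spec <- matrix(0i, 128, 128)
      spec[1:16, 1:16] <- matrix(stats::rnorm(256) +
                                 1i * stats::rnorm(256), 16, 16)
      complex_field(stats::fft(spec, inverse = TRUE) / 128^2, 0, cfg)
    })
  }
  for (seed in 1:5) {
    u <- make_field(seed)
    dz <- 1e-3 * seed
    back <- propagate(propagate(u, dz), -dz)
    rel <- sqrt(sum(Mod(back$field - u$field)^2) / sum(Mod(u$field)^2))
    expect_lt(rel, 1e-10)
    # composition
    two <- propagate(propagate(u, dz / 3), 2 * dz / 3)
    one <- propagate(u, dz)
    relc <- sqrt(sum(Mod(two$field - one$field)^2) /
                 sum(Mod(one$field)^2))
    expect_lt(relc, 1e-10)
    # unitary on the propagating band
    e0 <- sum(Mod(u$field)^2)
    e1 <- sum(Mod(propagate(u, dz)$field)^2)
    expect_lt(abs(e1 - e0) / e0, 1e-9)
  }
})

test_that("a uniform field propagates as a plane wave", {
  cfg <- tiny_config(32)
  u <- complex_field(matrix(3 + 0i, 32, 32), 0, cfg)
  dz <- 2.5e-4
  out <- propagate(u, dz)
  expected <- 3 * exp(1i * 2 * pi * dz / cfg$wavelength)
  expect_lt(max(Mod(out$field - expected)), 1e-9 * 3)
})

test_that("tamura matches its definition and invariances", {
  expect_equal(tamura(matrix(2, 5, 5)), 0)
  expect_equal(tamura(c(1, 3)), sqrt(1 / 2), tolerance = 1e-12)
  a <- withr::with_seed(2, matrix(stats::runif(100, 0.1, 2), 10, 10))
  expect_equal(tamura(5.7 * a), tamura(a), tolerance = 1e-12)
  expect_error(tamura(matrix(0, 3, 3)), "zero")
  expect_error(tamura(matrix(-1, 2, 2)))
})

test_that("defocus raises the amplitude contrast of a phase object", {
  cfg <- tiny_config(256)
  sl <- make_phantom_slide(1, c(256, 256), focus_suite_morphology(),
                           seed = 21)
  fld <- demodulate(form_hologram(sl, cfg))
  t_focus <- tamura(Mod(fld$field))
  # ~5 depth-of-field units for the passband NA
  t_out1 <- tamura(Mod(propagate(fld, 5e-3)$field))
  t_out2 <- tamura(Mod(propagate(fld, -5e-3)$field))
  expect_lt(t_focus, t_out1)
  expect_lt(t_focus, t_out2)
})

test_that("autofocus localizes an already-focused field near zero", {
  cfg <- tiny_config(256)
  sl <- make_phantom_slide(1, c(256, 256), focus_suite_morphology(),
                           seed = 31)
  fld <- demodulate(form_hologram(sl, cfg))
  af <- autofocus(fld, -2e-3, 2e-3, n_coarse = 21, n_refine_levels = 3)
  bracket <- (4e-3 / 20) / 2^3
  expect_lte(abs(af$z_best), bracket)
  expect_equal(af$bracket, bracket, tolerance = 1e-12)
  expect_equal(min(af$scan$tamura), af$t_best)
})

test_that("autofocus recovers known defocus within the final bracket", {
  cfg <- tiny_config(256)
  hits <- 0L; n_draws <- 6L
  for (i in seq_len(n_draws)) {
    d <- withr::with_seed(600 + i, stats::runif(1, 0.5e-3, 2.5e-3))
    sl <- make_phantom_slide(1, c(256, 256), focus_suite_morphology(),
                             seed = 300 + i)
    fld <- demodulate(form_hologram(sl, cfg, defocus_z = d))
    af <- suppressWarnings(autofocus(fld, -3.2e-3, -0.1e-3, 21, 3))
    if (abs(af$z_best + d) <= af$bracket) hits <- hits + 1L
  }
  expect_gte(hits, n_draws - 1L)
})

test_that("a boundary minimum triggers a warning, not an error", {
  cfg <- tiny_config(256)
  sl <- make_phantom_slide(1, c(256, 256), focus_suite_morphology(),
                           seed = 41)
  fld <- demodulate(form_hologram(sl, cfg, defocus_z = 2e-3))
  # true refocus at -2 mm lies outside [+1, +3] mm: metric is monotone
  expect_warning(autofocus(fld, 1e-3, 3e-3, n_coarse = 7,
                           n_refine_levels = 1),
                 "boundary")
})

test_that("extract_wqpi applies the half-open wrap convention", {
  cfg <- tiny_config(16)
  fld <- complex_field(matrix(exp(0.5i), 16, 16), 0, cfg)
  expect_equal(extract_wqpi(fld)$phase, matrix(0.5, 16, 16),
               tolerance = 1e-12)
  fld2 <- complex_field(matrix(-1 + 0i, 16, 16), 0, cfg)
  expect_equal(extract_wqpi(fld2)$phase, matrix(-pi, 16, 16),
               tolerance = 1e-12)
})

test_that("constant offsets are estimated and removed", {
  cfg <- tiny_config(256)
  sl <- flat_top_slide(n = 256, peak = 1.2)
  wq <- extract_wqpi(demodulate(form_hologram(sl, cfg, phi_r = -0.9)))
  comp <- compensate_offset(wq)
  expect_equal(comp$offset, 0.9, tolerance = 0.05)
  bg <- sl$label_map == 0
  expect_lt(stats::median(abs(comp$wqpi$phase[bg])), 0.02)
})
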