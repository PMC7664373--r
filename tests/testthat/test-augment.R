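test_that("wrap_phase implements the half-open 2*pi modulation", {
  expect_equal(wrap_phase(0), 0)
  expect_equal(wrap_phase(pi), -pi)
  expect_equal(wrap_phase(2.5 * pi), 0.5 * pi, tolerance = 1e-12)
  expect_equal(wrap_phase(-pi), -pi)
  expect_equal(wrap_phase(c(-3 * pi, 7 * pi)), c(-pi, -pi),
               tolerance = 1e-12)
  expect_error(wrap_phase(c(1, NA)), "finite")
  v <- withr::with_seed(1, stats::runif(1000, -50, 50))
  w <- wrap_phase(v)
  expect_true(all(w >= -pi & w < pi))
  expect_equal(exp(1i * w), exp(1i * v), tolerance = 1e-9)
})

test_that("the default augmentation lattice matches the study design", {
  g <- build_grid()
  expect_length(g$scales_x, 21)
  expect_length(g$scales_y, 21)
  expect_length(g$angles_deg, 36)
  expect_length(g$biases_rad, 11)
  expect_equal(range(g$scales_x), c(-0.2, 0.2))
  expect_equal(g$angles_deg, seq(0, 350, by = 10))
  expect_equal(g$biases_rad, seq(0, pi, length.out = 11))
  expect_equal(grid_cardinality(g), 174636L)
  expect_equal(grid_cardinality(build_grid(n_scales = 1, angle_step = 360,
                                           n_biases = 1)), 1L)
})

test_that("lattice cardinality is the product of its dimension lengths", {
  for (seed in 1:6) {
    dims <- withr::with_seed(seed, sample(1:7, 3, replace = TRUE))
    g <- build_grid(n_scales = dims[1], angle_step = 360 / dims[2],
                    n_biases = dims[3])
    expect_equal(grid_cardinality(g), dims[1]^2 * dims[2] * dims[3])
  }
  expect_error(build_grid(angle_step = 400))
})

test_that("identity parameters reproduce the generator exactly", {
  gen <- random_wqpi(32, seed = 4)
  out <- apply_transform(gen, 0, 0, 0, 0, out_shape = c(64, 64))
  r0 <- (64 - 32) %/% 2
  expect_identical(out$phase[r0 + 1:32, r0 + 1:32], gen$phase)
  expect_true(all(out$phase[1:r0, ] == 0))
})

test_that("a bias shifts a constant disc by exactly that wrapped amount", {
  ph <- matrix(0, 32, 32)
  r <- sqrt(outer((1:32 - 16.5)^2, rep(1, 32)) +
            outer(rep(1, 32), (1:32 - 16.5)^2))
  ph[r < 10] <- 1.2
  gen <- wqpi(ph)
  out <- apply_transform(gen, 0, 0, 0, 2.5, out_shape = c(32, 32))
  expect_equal(out$phase[r < 8], rep(wrap_phase(1.2 + 2.5), sum(r < 8)),
               tolerance = 1e-12)
})

test_that("every augmented image respects the wrapped-phase range", {
  gen <- random_wqpi(40, seed = 6)
  g <- build_grid()
  idx <- withr::with_seed(8, sample.int(grid_cardinality(g), 50))
  tuples <- holoplankton:::decode_tuple(idx, g)
  for (i in seq_len(nrow(tuples))) {
    out <- apply_transform(gen, tuples$scale_x[i], tuples$scale_y[i],
                           tuples$angle_deg[i], tuples$bias_rad[i],
                           out_shape = c(96, 96))
    expect_true(all(out$phase >= -pi & out$phase < pi))
  }
})

test_that("two half-turns approximately reproduce the original", {
  # smooth generator: interpolation error bound applies on its support
  ph <- matrix(0, 48, 48)
  r <- sqrt(outer((1:48 - 24.5)^2, rep(1, 48)) +
            outer(rep(1, 48), (1:48 - 24.5)^2))
  ph[r < 18] <- 1.5 * cos(r[r < 18] / 4)
  gen <- wqpi(wrap_phase(ph))
  once <- apply_transform(gen, 0, 0, 180, 0, out_shape = c(64, 64))
  twice <- apply_transform(once, 0, 0, 180, 0, out_shape = c(64, 64))
  ref <- apply_transform(gen, 0, 0, 0, 0, out_shape = c(64, 64))
  sup <- abs(ref$phase) > 1e-9
  expect_lt(mean(abs(wrap_phase(twice$phase[sup] - ref$phase[sup]))), 0.02)
})

test_that("oversized transforms are rejected", {
  gen <- random_wqpi(60, seed = 2)
  expect_error(apply_transform(gen, 0.2, 0.2, 45, 0,
                               out_shape = c(64, 64)),
               "exceeds")
})

test_that("dataset plans sample without replacement, deterministically", {
  g <- build_grid(n_scales = 3, angle_step = 90, n_biases = 2)  # K = 72
  p1 <- plan_dataset(c(1L, 2L, 5L), g, per_class = 20, seed = 3)
  p2 <- plan_dataset(c(1L, 2L, 5L), g, per_class = 20, seed = 3)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 60)
  expect_equal(unname(table(p1$class_id)), rep(20L, 3), ignore_attr = TRUE)
  for (k in c(1, 2, 5)) {
    expect_false(anyDuplicated(p1$tuple_index[p1$class_id == k]) > 0)
  }
  expect_error(plan_dataset(1L, g, per_class = 73, seed = 1), "cardinality")
  # exhaustive sampling of a single-tuple lattice
  g1 <- build_grid(n_scales = 1, angle_step = 360, n_biases = 1)
  expect_equal(nrow(plan_dataset(1:4, g1, 1, seed = 1)), 4)
})

test_that("decoded tuples cover the lattice bijectively", {
  g <- build_grid(n_scales = 2, angle_step = 120, n_biases = 3)  # K = 36
  tup <- holoplankton:::decode_tuple(seq_len(grid_cardinality(g)), g)
  expect_equal(nrow(dplyr::distinct(tup[, c("scale_x", "scale_y",
                                            "angle_deg", "bias_rad")])),
               grid_cardinality(g))
})

test_that("generated datasets land on disk with a faithful manifest", {
  gens <- list("1" = random_wqpi(24, seed = 1, class_id = 1L),
               "2" = random_wqpi(24, seed = 2, class_id = 2L))
  g <- build_grid(n_scales = 2, angle_step = 180, n_biases = 2)
  dir <- withr::local_tempdir()
  man <- generate_dataset(gens, g, per_class = 3, seed = 9, out_dir = dir,
                          out_shape = c(48, 48))
  expect_equal(nrow(man), 6)
  expect_true(all(file.exists(man$path)))
  img <- read_wqpi(man$path[1])
  ref <- realize_augmentation(man[1, ], gens, out_shape = c(48, 48))
  expect_equal(img$phase, ref$phase, tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "grid.yaml")))
})

test_that("stratified splits are exact partitions with per-class rounding", {
  man <- tibble::tibble(class_id = rep(1:3, each = 10), i = 1:30)
  sp <- split_train_val(man, 0.8, seed = 5)
  expect_equal(unname(table(sp$train$class_id)), rep(8L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$val$class_id)), rep(2L, 3),
               ignore_attr = TRUE)
  expect_setequal(c(sp$train$i, sp$val$i), man$i)
  expect_length(intersect(sp$train$i, sp$val$i), 0)
  sp2 <- split_train_val(man, 0.8, seed = 5)
  expect_identical(sp$train, sp2$train)
  expect_error(split_train_val(tibble::tibble(class_id = 1, i = 1), 0.5),
               "empty")
})
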