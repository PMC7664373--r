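#' Build the deterministic augmentation lattice
#'
#' The training set for each class is generated from a single wrapped phase
#' image by three nested transformations: anisotropic resizing, rotation,
#' and a constant phase bias, with the 2*pi-modulation operator applied
#' after every step. This function enumerates the lattice of transform
#' parameters. The default lattice is 21 scales per axis spanning -20%..+20%
#' in 2% steps, 36 rotations in 10-degree steps, and 11 phase biases evenly
#' spaced on `[0, pi]` — 21 x 21 x 36 x 11 = 174,636 tuples per class.
#'
#' @param n_scales Scale values per axis.
#' @param scale_range Relative scale span (`-0.2, 0.2` means -20%..+20%).
#' @param angle_step Rotation step in degrees (angles are
#'   `seq(0, 360 - angle_step, by = angle_step)`).
#' @param n_biases Number of phase biases.
#' @param bias_range Bias span in radians, inclusive.
#' @param random_biases If `TRUE`, draw the biases uniformly at random from
#'   `bias_range` instead of spacing them evenly (`seed` controls the
#'   draw). Even spacing is the default for reproducibility.
#' @param seed Seed for `random_biases`.
#' @return An object of class `augmentation_grid` with ordered fields
#'   `scales_x`, `scales_y`, `angles_deg`, `biases_rad`.
#' @examples
#' grid_cardinality(build_grid())  # 174636
#' @export
build_grid <- function(n_scales = 21L, scale_range = c(-0.2, 0.2),
                       angle_step = 10, n_biases = 11L,
                       bias_range = c(0, pi), random_biases = FALSE,
                       seed = 1L) {
  stopifnot(n_scales >= 1, n_biases >= 1, angle_step > 0,
            angle_step <= 360)
  scales <- if (n_scales == 1L) mean(scale_range) else
    seq(scale_range[1], scale_range[2], length.out = n_scales)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  biases <- if (random_biases) {
    withr::with_seed(seed, sort(stats::runif(n_biases, bias_range[1],
                                             bias_range[2])))
  } else if (n_biases == 1L) mean(bias_range) else {
    seq(bias_range[1], bias_range[2], length.out = n_biases)
  }
  if (length(scales) == 0 || length(angles) == 0 || length(biases) == 0) {
    stop("empty augmentation grid dimension", call. = FALSE)
  }
  structure(list(scales_x = scales, scales_y = scales,
                 angles_deg = angles, biases_rad = biases),
            class = "augmentation_grid")
}

#' @rdname build_grid
#' @param grid An `augmentation_grid`.
#' @return `grid_cardinality()`: the number of parameter tuples in the
#'   lattice.
#' @export
grid_cardinality <- function(grid) {
  stopifnot(inherits(grid, "augmentation_grid"))
  length(grid$scales_x) * length(grid$scales_y) *
    length(grid$angles_deg) * length(grid$biases_rad)
}

#' @export
print.augmentation_grid <- function(x, ...) {
  cat(sprintf("<augmentation_grid> %d x %d scales, %d angles, %d biases = %s tuples\n",
              length(x$scales_x), length(x$scales_y), length(x$angles_deg),
              length(x$biases_rad),
              format(grid_cardinality(x), big.mark = ",")))
  invisible(x)
}

# Decode linear tuple indices (1-based) into the four lattice coordinates.
# scales_x varies fastest, then scales_y, then angle, then bias.
decode_tuple <- function(index, grid) {
  n1 <- length(grid$scales_x); n2 <- length(grid$scales_y)
  n3 <- length(grid$angles_deg)
  i <- index - 1
  i1 <- i %% n1
  i2 <- (i %/% n1) %% n2
  i3 <- (i %/% (n1 * n2)) %% n3
  i4 <- i %/% (n1 * n2 * n3)
  tibble::tibble(
    tuple_index = index,
    scale_x = grid$scales_x[i1 + 1], scale_y = grid$scales_y[i2 + 1],
    angle_deg = grid$angles_deg[i3 + 1], bias_rad = grid$biases_rad[i4 + 1]
  )
}

#' Apply one augmentation transform to a generator WQPI
#'
#' The three nested steps, each followed by the 2*pi-modulation operator:
#' (1) resize by `(1 + scale_y, 1 + scale_x)` (rows, columns) with bilinear
#' interpolation; (2) rotate by `angle_deg` about the image centre with
#' bilinear interpolation and zero-phase background; (3) add `bias_rad` to
#' every pixel. The result is centre-placed on a zero-phase canvas of
#' `out_shape`. Interpolation acts on the wrapped values directly, so
#' pixels straddling a wrap discontinuity produce localized artifacts —
#' the same behaviour a classifier trained on these images must tolerate
#' at test time. Identity parameters reproduce the input exactly.
#'
#' @param gen Generator [wqpi()].
#' @param scale_x,scale_y Relative scale changes (e.g. `-0.2` .. `0.2`).
#' @param angle_deg Rotation in degrees.
#' @param bias_rad Phase bias in radians.
#' @param out_shape Output canvas `(ny, nx)`.
#' @param complex_interp If `TRUE`, resize and rotate interpolate
#'   `exp(i phase)` and take the argument, avoiding wrap-discontinuity
#'   artifacts. Off by default.
#' @return A [wqpi()] of shape `out_shape` carrying `gen`'s class id.
#' @export
apply_transform <- function(gen, scale_x, scale_y, angle_deg, bias_rad,
                            out_shape = c(256L, 256L),
                            complex_interp = FALSE) {
  stopifnot(inherits(gen, "wqpi"),
            scale_x > -0.5, scale_x < 1, scale_y > -0.5, scale_y < 1)
  interp2 <- function(m, fun) {
    if (complex_interp) {
      re <- fun(cos(m)); im <- fun(sin(m))
      atan2(im, re)
    } else {
      fun(m)
    }
  }
  m <- gen$phase
  if (scale_x != 0 || scale_y != 0) {
    new_r <- max(2L, round(nrow(m) * (1 + scale_y)))
    new_c <- max(2L, round(ncol(m) * (1 + scale_x)))
    m <- interp2(m, function(z)
      EBImage::resize(z, w = new_r, h = new_c, filter = "bilinear"))
    m <- wrap_phase(m)
  }
  if (angle_deg %% 360 != 0) {
    m <- interp2(m, function(z)
      EBImage::rotate(z, angle_deg, filter = "bilinear", bg.col = 0))
    m <- wrap_phase(m)
  }
  if (bias_rad != 0) m <- wrap_phase(m + bias_rad)
  if (nrow(m) > out_shape[1] || ncol(m) > out_shape[2]) {
    stop("transformed image (", nrow(m), "x", ncol(m),
         ") exceeds out_shape (", out_shape[1], "x", out_shape[2], ")",
         call. = FALSE)
  }
  canvas <- matrix(0, out_shape[1], out_shape[2])
  r0 <- (out_shape[1] - nrow(m)) %/% 2L
  c0 <- (out_shape[2] - ncol(m)) %/% 2L
  canvas[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  wqpi(canvas, class_id = gen$class_id, pixel_pitch = gen$pixel_pitch)
}

#' Plan a sampled augmented dataset
#'
#' For each class, samples `per_class` parameter tuples uniformly without
#' replacement from the augmentation lattice (deterministically for a
#' fixed seed) and returns the manifest plan as a tibble — no images are
#' materialized. [realize_augmentation()] turns any manifest row into its
#' image; [generate_dataset()] materializes the whole plan to disk.
#'
#' @param class_ids Integer vector of class labels (one generator each).
#' @param grid An [build_grid()] lattice.
#' @param per_class Images per class (must not exceed the lattice
#'   cardinality).
#' @param seed Sampling seed.
#' @return A tibble with columns `class_id`, `tuple_index`, `scale_x`,
#'   `scale_y`, `angle_deg`, `bias_rad`; exactly `per_class` rows per
#'   class.
#' @export
plan_dataset <- function(class_ids, grid, per_class, seed = 1L) {
  K <- grid_cardinality(grid)
  if (per_class > K) {
    stop("per_class (", per_class, ") exceeds grid cardinality (", K, ")",
         call. = FALSE)
  }
  stopifnot(!anyDuplicated(class_ids))
  withr::with_seed(seed, {
    purrr::map_dfr(sort(class_ids), function(k) {
      idx <- sort(sample.int(K, per_class))
      dplyr::mutate(decode_tuple(idx, grid), class_id = as.integer(k),
                    .before = 1)
    })
  })
}

#' Materialize one manifest row
#'
#' @param row One-row manifest (from [plan_dataset()]).
#' @param generators Named list of generator [wqpi()]s, names =
#'   class ids.
#' @param out_shape Canvas shape passed to [apply_transform()].
#' @return The augmented [wqpi()].
#' @export
realize_augmentation <- function(row, generators, out_shape = c(256L, 256L)) {
  gen <- generators[[as.character(row$class_id)]]
  if (is.null(gen)) stop("no generator for class ", row$class_id,
                         call. = FALSE)
  apply_transform(gen, row$scale_x, row$scale_y, row$angle_deg,
                  row$bias_rad, out_shape = out_shape)
}

#' Generate an augmented dataset on disk
#'
#' Materializes a [plan_dataset()] plan: one float TIFF (and optionally an
#' 8-bit PNG-style gray TIFF mapping `[-pi, pi)` to 0..255) per augmented
#' image, under per-class directories, plus `manifest.csv` and the grid as
#' `grid.yaml`.
#'
#' @param generators Named list of generator [wqpi()]s (names = class
#'   ids).
#' @param grid An [build_grid()] lattice.
#' @param per_class Images per class.
#' @param seed Sampling seed.
#' @param out_dir Output directory.
#' @param out_shape Canvas shape.
#' @param eight_bit Also write 8-bit gray companions.
#' @return The manifest tibble with a `path` column, invisibly.
#' @export
generate_dataset <- function(generators, grid, per_class, seed, out_dir,
                             out_shape = c(256L, 256L), eight_bit = FALSE) {
  class_ids <- as.integer(names(generators))
  man <- plan_dataset(class_ids, grid, per_class, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man$path <- file.path(out_dir, sprintf("class_%02d", man$class_id),
                        sprintf("aug_%07d.tif", man$tuple_index))
  for (d in unique(dirname(man$path))) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  for (i in seq_len(nrow(man))) {
    img <- realize_augmentation(man[i, ], generators, out_shape)
    write_wqpi(img, man$path[i])
    if (eight_bit) {
      g <- floor((img$phase + pi) / (2 * pi) * 256)
      g[g > 255] <- 255
      tiff::writeTIFF(g / 255, sub("\\.tif$", "_8bit.tif", man$path[i]),
                      bits.per.sample = 8L)
    }
  }
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(scales_x = grid$scales_x, scales_y = grid$scales_y,
                        angles_deg = grid$angles_deg,
                        biases_rad = grid$biases_rad),
                   file.path(out_dir, "grid.yaml"))
  invisible(man)
}

#' Stratified train/validation split of a manifest
#'
#' Splits per class: for each class, `round(train_frac * n)` rows are drawn
#' at random (deterministically for a fixed seed) into the training side,
#' the rest into validation. The two sides partition the input exactly and
#' class balance is preserved by construction.
#'
#' @param manifest A manifest tibble with a `class_id` column.
#' @param train_frac Training fraction, strictly between 0 and 1.
#' @param seed Split seed.
#' @return A list with elements `train` and `val`.
#' @examples
#' man <- tibble::tibble(class_id = rep(1:2, each = 10), i = 1:20)
#' sp <- split_train_val(man, 0.8, seed = 7)
#' table(sp$train$class_id)
#' @export
split_train_val <- function(manifest, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, "class_id" %in% names(manifest))
  withr::with_seed(seed, {
    idx_tr <- unlist(lapply(split(seq_len(nrow(manifest)),
                                  manifest$class_id), function(ix) {
      n_tr <- round(train_frac * length(ix))
      if (n_tr == 0 || n_tr == length(ix)) {
        stop("split leaves an empty side for some class", call. = FALSE)
      }
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(train = manifest[sort(idx_tr), , drop = FALSE],
       val = manifest[setdiff(seq_len(nrow(manifest)), sort(idx_tr)), ,
                      drop = FALSE])
}
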