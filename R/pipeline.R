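#' Assemble a full-run configuration
#'
#' One nested configuration drives the whole chain:
#' simulate -> reconstruct -> segment -> augment -> train -> ensemble.
#' Defaults reproduce the full-scale study conditions (50 classes on a
#' 2048 x 2048 sensor, the 174,636-tuple augmentation lattice, 21,000
#' sampled images per class, 80/20 stratified split, SGD protocol);
#' desk-scale work passes smaller values. The object serializes to YAML
#' and back losslessly via [write_run_config()] / [read_run_config()].
#'
#' @param seed Global seed; all per-stage seeds are derived from it by
#'   fixed offsets.
#' @param n_classes Number of classes on the phantom slide.
#' @param image_shape Slide/sensor canvas `(ny, nx)`.
#' @param wavelength,pixel_pitch Optics (metres).
#' @param radius_range_px,peak_phase_range Morphology settings (see
#'   [phantom_morphology()]).
#' @param dry_noise_sd Intensity noise when recording the dry slide.
#' @param min_area_px,pad_px,close_px Segmentation settings (see
#'   [segment_slide()]).
#' @param n_scales,scale_range,angle_step,n_biases,bias_range Augmentation
#'   lattice settings (see [build_grid()]).
#' @param per_class Augmented images sampled per class.
#' @param train_frac Training fraction of the stratified split.
#' @param aug_out_shape Augmentation canvas `(ny, nx)`.
#' @param members Character vector of architecture names; each entry is
#'   trained with its own derived seed, so repeating a name trains
#'   independent replicates for the ensemble.
#' @param learning_rate,momentum,weight_decay,patience_epochs,max_epochs,
#'   crop_px,input_px,batch_size,encoding Training protocol (see
#'   [train_config()]).
#' @param wet_n_per_class,wet_classes,wet_image_shape,wet_defocus_range,
#'   wet_noise_sd,wet_bias_range Wet-test fixture settings (see
#'   [simulate_wet_object()]); `wet_classes = NULL` tests every class.
#' @param autofocus_n_coarse,autofocus_refine_levels Focus search
#'   settings.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_classes = 50L,
                       image_shape = c(2048L, 2048L),
                       wavelength = 532e-9, pixel_pitch = 5.5e-6,
                       radius_range_px = c(22, 38),
                       peak_phase_range = c(2.2 * pi, 3.2 * pi),
                       dry_noise_sd = 0,
                       min_area_px = 100L, pad_px = 8L, close_px = 5L,
                       n_scales = 21L, scale_range = c(-0.2, 0.2),
                       angle_step = 10, n_biases = 11L,
                       bias_range = c(0, pi),
                       per_class = 21000L, train_frac = 0.8,
                       aug_out_shape = c(256L, 256L),
                       members = c("mlp32", "mlp64", "mlp128"),
                       learning_rate = 0.001, momentum = 0.9,
                       weight_decay = 0.001, patience_epochs = 5L,
                       max_epochs = 200L, crop_px = 224L, input_px = 32L,
                       batch_size = 32L, encoding = "cossin",
                       wet_n_per_class = 20L, wet_classes = NULL,
                       wet_image_shape = c(256L, 256L),
                       wet_defocus_range = c(0.5e-3, 2.5e-3),
                       wet_noise_sd = 0.02,
                       wet_bias_range = c(0, pi),
                       autofocus_n_coarse = 21L,
                       autofocus_refine_levels = 3L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_classes = as.integer(n_classes),
                    image_shape = as.integer(image_shape),
                    radius_range_px = radius_range_px,
                    peak_phase_range = peak_phase_range,
                    dry_noise_sd = dry_noise_sd),
    optics = list(wavelength = wavelength, pixel_pitch = pixel_pitch),
    segment = list(min_area_px = as.integer(min_area_px),
                   pad_px = as.integer(pad_px),
                   close_px = as.integer(close_px)),
    augment = list(n_scales = as.integer(n_scales),
                   scale_range = scale_range, angle_step = angle_step,
                   n_biases = as.integer(n_biases),
                   bias_range = bias_range,
                   per_class = as.integer(per_class),
                   train_frac = train_frac,
                   out_shape = as.integer(aug_out_shape)),
    classify = list(members = members, learning_rate = learning_rate,
                    momentum = momentum, weight_decay = weight_decay,
                    patience_epochs = as.integer(patience_epochs),
                    max_epochs = as.integer(max_epochs),
                    crop_px = as.integer(crop_px),
                    input_px = as.integer(input_px),
                    batch_size = as.integer(batch_size),
                    encoding = encoding),
    wet = list(n_per_class = as.integer(wet_n_per_class),
               classes = if (is.null(wet_classes)) NULL else
                 as.integer(wet_classes),
               image_shape = as.integer(wet_image_shape),
               defocus_range = wet_defocus_range,
               noise_sd = wet_noise_sd, bias_range = wet_bias_range,
               autofocus_n_coarse = as.integer(autofocus_n_coarse),
               autofocus_refine_levels = as.integer(autofocus_refine_levels))
  ), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- structure(raw, class = "run_config")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Centre-place (or centre-crop) a matrix on a zero canvas of given shape.
place_center <- function(m, shape) {
  if (nrow(m) > shape[1]) {
    s <- (nrow(m) - shape[1]) %/% 2L
    m <- m[s + seq_len(shape[1]), , drop = FALSE]
  }
  if (ncol(m) > shape[2]) {
    s <- (ncol(m) - shape[2]) %/% 2L
    m <- m[, s + seq_len(shape[2]), drop = FALSE]
  }
  out <- matrix(0, shape[1], shape[2])
  r0 <- (shape[1] - nrow(m)) %/% 2L
  c0 <- (shape[2] - ncol(m)) %/% 2L
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

slide_morphology <- function(cfg) {
  phantom_morphology(radius_range_px = cfg$simulate$radius_range_px,
                     peak_phase_range = cfg$simulate$peak_phase_range)
}

slide_optics <- function(cfg, shape = NULL) {
  if (is.null(shape)) shape <- cfg$simulate$image_shape
  optical_config(wavelength = cfg$optics$wavelength,
                 pixel_pitch = cfg$optics$pixel_pitch,
                 sensor_ny = shape[1], sensor_nx = shape[2])
}

pipeline_train_config <- function(cfg, member_index) {
  cc <- cfg$classify
  train_config(learning_rate = cc$learning_rate, momentum = cc$momentum,
               weight_decay = cc$weight_decay,
               patience_epochs = cc$patience_epochs,
               max_epochs = cc$max_epochs, crop_px = cc$crop_px,
               input_px = cc$input_px, batch_size = cc$batch_size,
               encoding = cc$encoding,
               seed = cfg$seed + 101L * member_index)
}

#' Run the dry-slide training chain
#'
#' Executes simulate -> record -> demodulate -> extract -> segment ->
#' augment -> split -> train on synthetic data, end to end, with all
#' randomness derived from the configuration's global seed. Any stage
#' failure propagates with the stage name attached. The returned report is
#' free of timestamps, so two runs with the same configuration are
#' identical.
#'
#' @param config A [run_config()].
#' @return Object of class `dry_run`: `report` (nested list of per-stage
#'   counts, lattice cardinality, split sizes and per-member validation
#'   metrics), `models`, `generators`, `grid`, `slide`, `config`.
#' @export
run_dry_slide_training <- function(config) {
  stopifnot(inherits(config, "run_config"))
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  t0 <- Sys.time()
  slide <- with_stage("simulate", {
    make_phantom_slide(config$simulate$n_classes,
                       config$simulate$image_shape,
                       slide_morphology(config),
                       seed = config$seed + 11L)
  })
  stage_msg("simulate", "%d objects on %dx%d canvas (%.1fs)",
            nrow(slide$objects), slide$image_shape[1], slide$image_shape[2],
            as.numeric(Sys.time() - t0, units = "secs"))

  wq <- with_stage("reconstruct", {
    cfg_o <- slide_optics(config)
    holo <- form_hologram(slide, cfg_o,
                          noise_sd = config$simulate$dry_noise_sd,
                          seed = config$seed + 13L)
    extract_wqpi(demodulate(holo))
  })
  objs <- with_stage("segment", {
    o <- segment_slide(wq, config$segment$min_area_px,
                       config$segment$pad_px, config$segment$close_px)
    assign_classes(o, slide)
  })
  stage_msg("segment", "%d objects segmented", length(objs))
  if (length(objs) != config$simulate$n_classes) {
    warning("segmented ", length(objs), " objects, expected ",
            config$simulate$n_classes, call. = FALSE)
  }
  generators <- stats::setNames(
    lapply(objs, function(o) {
      g <- o$wqpi_crop; g$class_id <- o$class_id; g
    }),
    vapply(objs, function(o) as.character(o$class_id), character(1)))

  grid <- with_stage("augment", {
    build_grid(n_scales = config$augment$n_scales,
               scale_range = config$augment$scale_range,
               angle_step = config$augment$angle_step,
               n_biases = config$augment$n_biases,
               bias_range = config$augment$bias_range)
  })
  plan <- with_stage("augment", {
    plan_dataset(as.integer(names(generators)), grid,
                 config$augment$per_class, seed = config$seed + 23L)
  })
  split <- with_stage("augment", {
    split_train_val(plan, config$augment$train_frac,
                    seed = config$seed + 37L)
  })
  stage_msg("augment", "lattice %d tuples/class; plan %d rows (%d train / %d val)",
            grid_cardinality(grid), nrow(plan), nrow(split$train),
            nrow(split$val))

  tr_counts <- table(split$train$class_id)
  va_counts <- table(split$val$class_id)

  models <- list(); member_glance <- list()
  for (i in seq_along(config$classify$members)) {
    arch <- config$classify$members[i]
    tc <- pipeline_train_config(config, i)
    t1 <- Sys.time()
    feats_tr <- with_stage("train", {
      manifest_features(split$train, generators,
                        out_shape = config$augment$out_shape, config = tc)
    })
    feats_va <- with_stage("train", {
      manifest_features(split$val, generators,
                        out_shape = config$augment$out_shape, config = tc)
    })
    m <- with_stage("train", {
      train_model(feats_tr$x, feats_tr$y, feats_va$x, feats_va$y,
                  architecture = arch, config = tc)
    })
    stage_msg("train", "member %d (%s): best epoch %d, val acc %.3f (%.1fs)",
              i, arch, m$best_epoch,
              m$log$val_accuracy[m$best_epoch],
              as.numeric(Sys.time() - t1, units = "secs"))
    models[[i]] <- m
    member_glance[[i]] <- glance(m)
  }
  member_tbl <- dplyr::bind_rows(member_glance)
  member_tbl$member <- seq_along(config$classify$members)

  report <- list(
    seed = config$seed,
    n_classes = config$simulate$n_classes,
    n_true_objects = nrow(slide$objects),
    n_segmented = length(objs),
    grid_cardinality = grid_cardinality(grid),
    total_plan_rows = nrow(plan),
    per_class_planned = as.integer(config$augment$per_class),
    train_rows = nrow(split$train),
    val_rows = nrow(split$val),
    train_per_class = stats::setNames(as.integer(tr_counts),
                                      names(tr_counts)),
    val_per_class = stats::setNames(as.integer(va_counts),
                                    names(va_counts)),
    members = lapply(seq_len(nrow(member_tbl)), function(i)
      as.list(member_tbl[i, ]))
  )
  structure(list(report = report, models = models, generators = generators,
                 grid = grid, slide = slide, config = config),
            class = "dry_run")
}

#' @export
print.dry_run <- function(x, ...) {
  cat(sprintf("<dry_run> %d classes, %d generators, %d models; lattice %s\n",
              x$report$n_classes, x$report$n_segmented,
              length(x$models),
              format(x$report$grid_cardinality, big.mark = ",")))
  invisible(x)
}

#' Run the wet test phase
#'
#' Simulates out-of-focus "wet" holograms of classes present in training,
#' demodulates each, locates the focus plane with [autofocus()], extracts
#' and segments the refocused wrapped phase image, classifies every object
#' with the max-voting ensemble, and reports accuracy together with the
#' full and test-class-restricted confusion matrices.
#'
#' @param config A [run_config()].
#' @param trained A `dry_run` from [run_dry_slide_training()] (models and
#'   slide seed are taken from it).
#' @return Object of class `wet_run`: `accuracy`, `confusion_full`,
#'   `confusion_restricted`, `objects` (per-object tibble with true class,
#'   true defocus, recovered `z_best`, predicted class), `ensemble`.
#' @export
run_wet_test <- function(config, trained) {
  stopifnot(inherits(config, "run_config"), inherits(trained, "dry_run"))
  classes <- config$wet$classes
  if (is.null(classes)) classes <- as.integer(names(trained$generators))
  if (!all(classes %in% as.integer(names(trained$generators)))) {
    stop("wet test classes must be a subset of the trained classes",
         call. = FALSE)
  }
  cfg_o <- slide_optics(config, config$wet$image_shape)
  dz <- config$wet$defocus_range
  # the demodulated field needs back-propagation, so search negative z
  z_search <- sort(-dz)
  pad <- 0.15 * diff(z_search)
  z_search <- c(z_search[1] - pad, z_search[2] + pad)
  morph <- slide_morphology(config)
  tc <- pipeline_train_config(config, 1L)
  slide_radius <- stats::setNames(trained$slide$objects$radius_px,
                                  trained$slide$objects$class_id)

  rows <- list(); feats <- list()
  k <- 0L
  for (cl in classes) {
    for (j in seq_len(config$wet$n_per_class)) {
      k <- k + 1L
      seed_k <- config$seed + 499L * cl + j
      holo <- simulate_wet_object(cl, cfg_o,
                                  morph_seed = trained$slide$seed,
                                  seed = seed_k,
                                  defocus_range = dz,
                                  noise_sd = config$wet$noise_sd,
                                  bias_range = config$wet$bias_range,
                                  radius_px = slide_radius[[as.character(cl)]],
                                  morphology = morph)
      fld <- demodulate(holo)
      af <- withCallingHandlers(
        autofocus(fld, z_search[1], z_search[2],
                  n_coarse = config$wet$autofocus_n_coarse,
                  n_refine_levels = config$wet$autofocus_refine_levels),
        warning = function(w) invokeRestart("muffleWarning"))
      foc <- propagate(fld, af$z_best)
      comp <- compensate_offset(extract_wqpi(foc))
      wq <- comp$wqpi
      objs <- segment_slide(wq, config$segment$min_area_px,
                            config$segment$pad_px,
                            config$segment$close_px)
      if (length(objs) > 0) {
        areas <- vapply(objs, function(o) o$area_px, integer(1))
        crop <- objs[[which.max(areas)]]$wqpi_crop$phase
      } else {
        crop <- wq$phase  # fall back to the full field
      }
      # centre the segmented object on the augmentation canvas so train
      # and test images share geometry before feature extraction
      canvas <- place_center(crop, config$augment$out_shape)
      feats[[k]] <- wqpi_feature_vector(canvas, tc$crop_px, tc$input_px,
                                        tc$encoding)
      rows[[k]] <- tibble::tibble(
        class_id = cl, instance = j, true_defocus = holo$true_defocus,
        z_best = af$z_best, n_segmented = length(objs),
        focus_error = abs(af$z_best + holo$true_defocus))
    }
  }
  obj_tbl <- dplyr::bind_rows(rows)
  x <- do.call(rbind, feats)
  y <- obj_tbl$class_id
  ens <- evaluate_ensemble(trained$models, x, y)
  obj_tbl$predicted <- ens$voted
  stage_msg("wet", "%d objects, ensemble accuracy %.3f", nrow(obj_tbl),
            ens$accuracy)
  structure(list(
    accuracy = ens$accuracy,
    confusion_full = ens$confusion,
    confusion_restricted = restrict_confusion(ens$confusion, classes),
    objects = obj_tbl,
    ensemble = ens
  ), class = "wet_run")
}

#' @export
print.wet_run <- function(x, ...) {
  cat(sprintf("<wet_run> accuracy %.3f over %d objects (%d classes)\n",
              x$accuracy, nrow(x$objects),
              length(unique(x$objects$class_id))))
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report The `report` element of a `dry_run`, or any
#'   JSON-serializable list.
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
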