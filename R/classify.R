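#' Training protocol configuration
#'
#' The optimization protocol: stochastic gradient descent with momentum and
#' weight decay, per-epoch validation loss, early stopping after
#' `patience_epochs` epochs without a new validation-loss minimum, and
#' retention of the minimum-validation-loss checkpoint. Defaults are
#' lr 0.001, momentum 0.9, weight decay 0.001, patience 5, at most 200
#' epochs, with inputs centre-cropped to `crop_px` pixels.
#'
#' @param learning_rate SGD learning rate (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param weight_decay L2 penalty coefficient.
#' @param patience_epochs Early-stopping patience (epochs without
#'   validation-loss improvement); must be below `max_epochs`.
#' @param max_epochs Hard epoch cap.
#' @param crop_px Centre-crop size in pixels applied before the network.
#' @param input_px Side length the crop is resampled to before entering
#'   the network (desk-scale networks are small; 32 px retains the striae
#'   and outline structure that separates classes).
#' @param channel_replicate Replicate the gray channel to 3 channels
#'   (only meaningful for architectures expecting RGB; the built-in
#'   networks are single-channel).
#' @param encoding Input encoding, `"cossin"` (cosine and sine channels of
#'   the wrapped phase; default) or `"gray"` (wrapped phase mapped to
#'   `[0, 1]`).
#' @param batch_size Minibatch size.
#' @param seed Seed controlling weight initialization and epoch shuffles.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         weight_decay = 0.001, patience_epochs = 5L,
                         max_epochs = 200L, crop_px = 224L, input_px = 32L,
                         channel_replicate = TRUE, batch_size = 32L,
                         encoding = c("cossin", "gray"), seed = 1L) {
  encoding <- match.arg(encoding)
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            weight_decay >= 0, patience_epochs >= 1,
            patience_epochs < max_epochs, crop_px >= 8, input_px >= 4,
            batch_size >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 crop_px = as.integer(crop_px),
                 input_px = as.integer(input_px),
                 channel_replicate = isTRUE(channel_replicate),
                 batch_size = as.integer(batch_size),
                 encoding = encoding,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Available desk-scale architectures
#'
#' Small fully-connected softmax networks (one tanh hidden layer) trained
#' from scratch; the registry name fixes the hidden width. These stand in
#' for large pretrained convolutional families at desk scale — the
#' training protocol (SGD, early stopping, min-loss checkpoint) is
#' identical.
#'
#' @return Named list of architecture descriptors.
#' @export
architectures <- function() {
  list(mlp32 = list(hidden = 32L), mlp64 = list(hidden = 64L),
       mlp128 = list(hidden = 128L))
}

# Centre-crop (zero-pad if smaller) to crop_px, then bilinear-resample to
# input_px. Encoding "cossin" maps the wrapped phase to its cosine and
# sine channels before resampling — both are continuous across the wrap
# seam, so downsampling does not manufacture edge artifacts and a phase
# bias acts as a smooth rotation of the (cos, sin) pair. Encoding "gray"
# resamples the wrapped phase directly and maps [-pi, pi) to [0, 1], the
# 8-bit-gray convention used when exporting for external classifiers.
wqpi_feature_vector <- function(phase, crop_px, input_px,
                                encoding = c("cossin", "gray")) {
  encoding <- match.arg(encoding)
  ny <- nrow(phase); nx <- ncol(phase)
  cp <- min(crop_px, max(ny, nx))
  out <- matrix(0, cp, cp)
  sr <- max(1L, (ny - cp) %/% 2L + 1L); er <- min(ny, sr + cp - 1L)
  sc <- max(1L, (nx - cp) %/% 2L + 1L); ec <- min(nx, sc + cp - 1L)
  dr <- (cp - (er - sr + 1L)) %/% 2L
  dc <- (cp - (ec - sc + 1L)) %/% 2L
  out[dr + seq_len(er - sr + 1L), dc + seq_len(ec - sc + 1L)] <-
    phase[sr:er, sc:ec]
  shrink <- function(m) EBImage::resize(m, w = input_px, h = input_px,
                                        filter = "bilinear")
  if (encoding == "cossin") {
    c(as.vector(shrink(cos(out))), as.vector(shrink(sin(out))))
  } else {
    as.vector((shrink(out) + pi) / (2 * pi))
  }
}

feature_length <- function(config) {
  if (config$encoding == "cossin") 2L * config$input_px^2 else
    config$input_px^2
}

#' Build a feature matrix from WQPIs
#'
#' @param images List of [wqpi()]s (or bare phase matrices).
#' @param config A [train_config()] (crop and input sizes).
#' @return Numeric matrix, one row per image.
#' @export
wqpi_features <- function(images, config = train_config()) {
  t(vapply(images, function(im) {
    ph <- if (inherits(im, "wqpi")) im$phase else im
    wqpi_feature_vector(ph, config$crop_px, config$input_px,
                        config$encoding)
  }, numeric(feature_length(config))))
}

#' Realize manifest rows into a feature matrix
#'
#' Materializes each row of an augmentation manifest (see
#' [plan_dataset()]) through [realize_augmentation()] and converts it to
#' the classifier's input features.
#'
#' @param manifest Manifest tibble.
#' @param generators Named list of generator [wqpi()]s.
#' @param out_shape Augmentation canvas shape.
#' @param config A [train_config()].
#' @return List with `x` (feature matrix) and `y` (integer labels).
#' @export
manifest_features <- function(manifest, generators,
                              out_shape = c(256L, 256L),
                              config = train_config()) {
  x <- matrix(0, nrow(manifest), feature_length(config))
  for (i in seq_len(nrow(manifest))) {
    img <- realize_augmentation(manifest[i, ], generators, out_shape)
    x[i, ] <- wqpi_feature_vector(img$phase, config$crop_px,
                                  config$input_px, config$encoding)
  }
  list(x = x, y = as.integer(manifest$class_id))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(w, x) {
  h <- tanh(sweep(x %*% w$W1, 2, w$b1, "+"))
  p <- softmax_rows(sweep(h %*% w$W2, 2, w$b2, "+"))
  list(h = h, p = p)
}

mlp_loss <- function(w, x, y_onehot, weight_decay) {
  p <- mlp_forward(w, x)$p
  ce <- -mean(log(pmax(rowSums(p * y_onehot), 1e-12)))
  ce + 0.5 * weight_decay * (sum(w$W1^2) + sum(w$W2^2))
}

#' Train a classifier on augmented WQPIs
#'
#' Minibatch SGD with momentum and weight decay on cross-entropy loss.
#' After each epoch the validation loss is computed; training stops when
#' `patience_epochs` epochs pass without a new validation-loss minimum (or
#' at `max_epochs`), and the weights from the minimum-validation-loss
#' epoch are retained. Fully deterministic for a fixed `config$seed`.
#'
#' @param x_train,y_train Training features (rows = samples) and integer
#'   labels.
#' @param x_val,y_val Validation features and labels.
#' @param architecture Name from [architectures()].
#' @param config A [train_config()].
#' @return An object of class `holo_model`: best weights, the class set,
#'   the per-epoch `log` tibble (train loss, validation loss, validation
#'   accuracy) and `best_epoch`.
#' @export
train_model <- function(x_train, y_train, x_val, y_val,
                        architecture = "mlp64", config = train_config()) {
  arch <- architectures()[[architecture]]
  if (is.null(arch)) stop("unknown architecture: ", architecture,
                          call. = FALSE)
  classes <- sort(unique(as.integer(y_train)))
  if (!all(y_val %in% classes)) {
    stop("validation labels outside the training class set", call. = FALSE)
  }
  n_class <- length(classes)
  d <- ncol(x_train); h <- arch$hidden
  y_tr <- match(as.integer(y_train), classes)
  y_va <- match(as.integer(y_val), classes)
  onehot <- function(idx) {
    m <- matrix(0, length(idx), n_class)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  yt1 <- onehot(y_tr); yv1 <- onehot(y_va)

  fit <- withr::with_seed(config$seed, {
    s1 <- sqrt(6 / (d + h)); s2 <- sqrt(6 / (h + n_class))
    w <- list(W1 = matrix(stats::runif(d * h, -s1, s1), d, h),
              b1 = rep(0, h),
              W2 = matrix(stats::runif(h * n_class, -s2, s2), h, n_class),
              b2 = rep(0, n_class))
    v <- lapply(w, function(z) z * 0)
    best <- list(loss = Inf, w = w, epoch = 0L)
    log <- list()
    n <- nrow(x_train)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tr_loss_sum <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x_train[ix, , drop = FALSE]
        yb <- yt1[ix, , drop = FALSE]
        fw <- mlp_forward(w, xb)
        nb <- length(ix)
        delta2 <- (fw$p - yb) / nb
        gW2 <- crossprod(fw$h, delta2) + config$weight_decay * w$W2
        gb2 <- colSums(delta2)
        dh <- tcrossprod(delta2, w$W2) * (1 - fw$h^2)
        gW1 <- crossprod(xb, dh) + config$weight_decay * w$W1
        gb1 <- colSums(dh)
        g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        for (nm in names(w)) {
          v[[nm]] <- config$momentum * v[[nm]] -
            config$learning_rate * g[[nm]]
          w[[nm]] <- w[[nm]] + v[[nm]]
        }
        tr_loss_sum <- tr_loss_sum -
          sum(log(pmax(rowSums(fw$p * yb), 1e-12)))
      }
      val_fw <- mlp_forward(w, x_val)
      val_ce <- -mean(log(pmax(rowSums(val_fw$p * yv1), 1e-12)))
      val_loss <- val_ce + 0.5 * config$weight_decay *
        (sum(w$W1^2) + sum(w$W2^2))
      val_acc <- mean(max.col(val_fw$p) == y_va)
      log[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr_loss_sum / n,
        val_loss = val_loss, val_accuracy = val_acc)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, w = w, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience_epochs) {
        break
      }
    }
    list(w = best$w, best_epoch = best$epoch,
         log = dplyr::bind_rows(log))
  })

  structure(list(weights = fit$w, architecture = architecture,
                 hidden = h, classes = classes, config = config,
                 log = fit$log, best_epoch = fit$best_epoch),
            class = "holo_model")
}

#' @export
print.holo_model <- function(x, ...) {
  cat(sprintf("<holo_model> %s (%d hidden), %d classes, best epoch %d (val loss %.4f)\n",
              x$architecture, x$hidden, length(x$classes), x$best_epoch,
              x$log$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
#' @rdname train_model
#' @param x A `holo_model`.
#' @param ... Unused.
tidy.holo_model <- function(x, ...) x$log

#' @export
#' @rdname train_model
glance.holo_model <- function(x, ...) {
  tibble::tibble(architecture = x$architecture, hidden = x$hidden,
                 n_classes = length(x$classes),
                 epochs_run = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_loss = x$log$val_loss[x$best_epoch],
                 best_val_accuracy = x$log$val_accuracy[x$best_epoch])
}

#' Predict classes for new WQPI features
#'
#' @param object A `holo_model`.
#' @param newdata Feature matrix (rows = samples).
#' @param ... Unused.
#' @return Tibble with `.pred` (integer class), `.confidence` (winning
#'   softmax probability); the full probability matrix is attached as the
#'   `"prob"` attribute.
#' @export
predict.holo_model <- function(object, newdata, ...) {
  p <- mlp_forward(object$weights, newdata)$p
  j <- max.col(p, ties.method = "first")
  out <- tibble::tibble(.pred = object$classes[j],
                        .confidence = p[cbind(seq_len(nrow(p)), j)])
  attr(out, "prob") <- p
  out
}

#' Confusion matrix over a fixed class set
#'
#' @param true,pred Integer label vectors.
#' @param class_ids Ordered label set indexing rows (true) and columns
#'   (predicted). Defaults to the union of observed labels.
#' @return An object of class `confusion_matrix` (integer counts plus the
#'   label vector).
#' @export
confusion_matrix <- function(true, pred, class_ids = NULL) {
  if (is.null(class_ids)) class_ids <- sort(unique(c(true, pred)))
  if (!all(true %in% class_ids) || !all(pred %in% class_ids)) {
    stop("labels outside class_ids", call. = FALSE)
  }
  counts <- table(factor(true, levels = class_ids),
                  factor(pred, levels = class_ids))
  structure(list(counts = unclass(counts), class_ids = class_ids),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d samples\n",
              length(x$class_ids), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Restrict a confusion matrix to a class subset
#'
#' Keeps the rows (true classes) in `classes`; predicted labels outside
#' the subset are collapsed into an `other` column so that total counts
#' are conserved. Rows for true classes outside the subset must be empty.
#'
#' @param cm A [confusion_matrix()].
#' @param classes Class ids to keep.
#' @return A `confusion_matrix` over `classes` (plus an `other` column
#'   when any prediction fell outside).
#' @export
restrict_confusion <- function(cm, classes) {
  stopifnot(inherits(cm, "confusion_matrix"))
  keep <- cm$class_ids %in% classes
  drop_rows <- cm$counts[!keep, , drop = FALSE]
  if (sum(drop_rows) > 0) {
    stop("true labels outside the restriction subset", call. = FALSE)
  }
  counts <- cm$counts[keep, , drop = FALSE]
  inside <- counts[, keep, drop = FALSE]
  outside <- rowSums(counts[, !keep, drop = FALSE])
  if (sum(outside) > 0) {
    inside <- cbind(inside, other = outside)
  }
  structure(list(counts = inside, class_ids = cm$class_ids[keep]),
            class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(df) <- c("true", "predicted", "n")
  tibble::as_tibble(df)
}

#' @rdname confusion_matrix
#' @param object A `confusion_matrix`.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "count")
}

#' Evaluate a model on labeled features
#'
#' @param model A `holo_model`.
#' @param x Feature matrix.
#' @param y True integer labels (must be a subset of the trained class
#'   set).
#' @return Object of class `holo_eval`: `accuracy`, `confusion`
#'   (over the full trained class set), `predictions` tibble.
#' @export
evaluate <- function(model, x, y) {
  y <- as.integer(y)
  if (!all(y %in% model$classes)) {
    stop("test labels outside the trained class set", call. = FALSE)
  }
  pr <- predict(model, x)
  structure(list(
    accuracy = mean(pr$.pred == y),
    confusion = confusion_matrix(y, pr$.pred, class_ids = model$classes),
    predictions = dplyr::mutate(pr, .true = y)
  ), class = "holo_eval")
}

#' @export
print.holo_eval <- function(x, ...) {
  cat(sprintf("<holo_eval> accuracy %.3f over %d samples\n",
              x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' @rdname evaluate
#' @export
glance.holo_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = nrow(x$predictions))
}

#' Max-voting label fusion
#'
#' Per sample, the modal label across models. Ties are broken by the
#' highest mean confidence among the tied labels, then by the lowest class
#' id — a deterministic rule. With a single model the labels pass through
#' unchanged.
#'
#' @param labels Integer matrix, `n_models x n_samples`.
#' @param confidences Optional matrix of the same shape with values in
#'   `[0, 1]`; defaults to all-equal confidences (ties then fall through
#'   to the lowest-id rule).
#' @return Integer vector of voted labels, one per sample.
#' @examples
#' max_vote(matrix(c(27, 27, 41), 3, 1))
#' @export
max_vote <- function(labels, confidences = NULL) {
  stopifnot(is.matrix(labels), nrow(labels) >= 1)
  if (is.null(confidences)) {
    confidences <- matrix(1, nrow(labels), ncol(labels))
  }
  if (!all(dim(labels) == dim(confidences))) {
    stop("labels and confidences shapes differ", call. = FALSE)
  }
  vapply(seq_len(ncol(labels)), function(j) {
    lab <- labels[, j]; conf <- confidences[, j]
    votes <- table(lab)
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1L) return(top)
    mc <- vapply(top, function(l) mean(conf[lab == l]), numeric(1))
    cand <- top[mc == max(mc)]
    min(cand)
  }, integer(1))
}

#' Select ensemble members by accuracy threshold
#'
#' @param results Tibble or data frame with columns `name` and `accuracy`
#'   (one row per trained model).
#' @param threshold Strict lower bound on accuracy (default 0.9).
#' @return The qualifying rows; warns when none qualify.
#' @examples
#' select_ensemble(tibble::tibble(
#'   name = c("a", "b", "c", "d"),
#'   accuracy = c(0.91, 0.94, 0.88, 0.95)))
#' @export
select_ensemble <- function(results, threshold = 0.9) {
  stopifnot(nrow(results) >= 1, all(c("name", "accuracy") %in%
                                    names(results)))
  sel <- dplyr::filter(results, .data$accuracy > threshold)
  if (nrow(sel) == 0) {
    warning("no model exceeds accuracy threshold ", threshold,
            call. = FALSE)
  }
  sel
}

#' Evaluate a max-voting ensemble
#'
#' Runs each model on the same samples, fuses labels with [max_vote()],
#' and scores the fused prediction.
#'
#' @param models List of `holo_model`s trained over the same class set.
#' @param x Feature matrix.
#' @param y True integer labels.
#' @return Object of class `holo_ensemble_eval`: `accuracy`, `confusion`,
#'   `per_model` (labels matrix), `voted` labels.
#' @export
evaluate_ensemble <- function(models, x, y) {
  stopifnot(length(models) >= 1)
  y <- as.integer(y)
  classes <- models[[1]]$classes
  for (m in models) stopifnot(identical(m$classes, classes))
  preds <- lapply(models, function(m) predict(m, x))
  labels <- do.call(rbind, lapply(preds, function(p) p$.pred))
  confs <- do.call(rbind, lapply(preds, function(p) p$.confidence))
  voted <- max_vote(labels, confs)
  structure(list(
    accuracy = mean(voted == y),
    confusion = confusion_matrix(y, voted, class_ids = classes),
    per_model = labels, per_model_confidence = confs, voted = voted,
    true = y
  ), class = "holo_ensemble_eval")
}

#' @export
print.holo_ensemble_eval <- function(x, ...) {
  cat(sprintf("<holo_ensemble_eval> %d models, accuracy %.3f over %d samples\n",
              nrow(x$per_model), x$accuracy, length(x$voted)))
  invisible(x)
}

#' @rdname evaluate_ensemble
#' @param x A `holo_ensemble_eval`.
#' @param ... Unused.
#' @export
glance.holo_ensemble_eval <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$per_model), accuracy = x$accuracy,
                 n = length(x$voted))
}
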