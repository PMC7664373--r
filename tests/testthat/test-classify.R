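# Tiny separable feature sets built directly in feature space.
toy_features <- function(n_per_class, d = 16, gap = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * d, 0, 0.3), ncol = d),
               matrix(stats::rnorm(n_per_class * d, gap, 0.3), ncol = d))
    y <- rep(c(1L, 2L), each = n_per_class)
    list(x = x, y = y)
  })
}

test_that("feature extraction produces the expected geometry", {
  ph <- matrix(0.5, 40, 40)
  cfgs <- list(train_config(crop_px = 32, input_px = 8),
               train_config(crop_px = 32, input_px = 8,
                            encoding = "gray"))
  f1 <- wqpi_features(list(wqpi(ph)), cfgs[[1]])
  expect_equal(dim(f1), c(1, 2 * 64))
  expect_equal(unname(f1[1, 1]), cos(0.5), tolerance = 1e-9)
  f2 <- wqpi_features(list(wqpi(ph)), cfgs[[2]])
  expect_equal(dim(f2), c(1, 64))
  expect_equal(unname(f2[1, 1]), (0.5 + pi) / (2 * pi), tolerance = 1e-9)
})

test_that("a separable two-class toy is learned to perfect validation accuracy", {
  tr <- toy_features(40); va <- toy_features(10, seed = 2)
  m <- train_model(tr$x, tr$y, va$x, va$y, architecture = "mlp32",
                   config = train_config(max_epochs = 40, seed = 3,
                                         learning_rate = 0.05,
                                         crop_px = 8, input_px = 4))
  expect_s3_class(m, "holo_model")
  expect_equal(m$log$val_accuracy[m$best_epoch], 1)
  ev <- evaluate(m, va$x, va$y)
  expect_equal(ev$accuracy, 1)
})

test_that("training stops patience epochs after the last improvement", {
  tr <- toy_features(30); va <- toy_features(8, seed = 4)
  cfg <- train_config(max_epochs = 100, patience_epochs = 5, seed = 7,
                      crop_px = 8, input_px = 4)
  m <- train_model(tr$x, tr$y, va$x, va$y, "mlp32", cfg)
  if (nrow(m$log) < cfg$max_epochs) {
    expect_equal(nrow(m$log), m$best_epoch + cfg$patience_epochs)
  }
  # best epoch attains the minimum recorded validation loss
  expect_equal(m$log$val_loss[m$best_epoch], min(m$log$val_loss))
})

test_that("training is deterministic for a fixed seed", {
  tr <- toy_features(30); va <- toy_features(8, seed = 5)
  cfg <- train_config(max_epochs = 10, seed = 11, crop_px = 8,
                      input_px = 4)
  m1 <- train_model(tr$x, tr$y, va$x, va$y, "mlp32", cfg)
  m2 <- train_model(tr$x, tr$y, va$x, va$y, "mlp32", cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$weights, m2$weights)
})

test_that("unknown architectures and label mismatches are rejected", {
  tr <- toy_features(10)
  expect_error(train_model(tr$x, tr$y, tr$x, tr$y, "resnet50"),
               "unknown architecture")
  expect_error(train_model(tr$x, tr$y, tr$x, rep(9L, length(tr$y)),
                           "mlp32"),
               "class set")
})

test_that("tidiers expose the training log and summary", {
  tr <- toy_features(20); va <- toy_features(5, seed = 6)
  m <- train_model(tr$x, tr$y, va$x, va$y, "mlp32",
                   train_config(max_epochs = 8, seed = 1, crop_px = 8,
                                input_px = 4))
  expect_s3_class(tidy(m), "tbl_df")
  expect_named(glance(m),
               c("architecture", "hidden", "n_classes", "epochs_run",
                 "best_epoch", "best_val_loss", "best_val_accuracy"))
})

test_that("max voting returns the mode with documented tie-breaking", {
  expect_equal(max_vote(matrix(c(27L, 27L, 41L), 3, 1)), 27L)
  one <- matrix(c(3L, 9L, 5L), 1, 3)
  expect_equal(max_vote(one), as.integer(one))
  labs <- matrix(c(4L, 7L, 2L), 3, 1)
  confs <- matrix(c(0.5, 0.9, 0.4), 3, 1)
  expect_equal(max_vote(labs, confs), 7L)
  # all-tied confidences fall through to the lowest class id
  expect_equal(max_vote(labs, matrix(0.5, 3, 1)), 2L)
  expect_error(max_vote(labs, matrix(0.5, 2, 1)), "shape")
})

test_that("max voting equals brute-force per-sample mode computation", {
  brute <- function(labels, confs) {
    vapply(seq_len(ncol(labels)), function(j) {
      lab <- labels[, j]
      tab <- sort(table(lab), decreasing = TRUE)
      top <- as.integer(names(tab)[tab == tab[1]])
      if (length(top) == 1) return(top)
      mc <- sapply(top, function(l) mean(confs[, j][lab == l]))
      cand <- top[abs(mc - max(mc)) < 1e-15]
      min(cand)
    }, integer(1))
  }
  for (seed in 1:25) {
    withr::with_seed(seed, {
      k <- sample(1:5, 1); n <- sample(1:40, 1)
      labels <- matrix(sample(1:6, k * n, replace = TRUE), k, n)
      confs <- matrix(stats::runif(k * n), k, n)
      expect_identical(max_vote(labels, confs), brute(labels, confs))
    })
  }
})

test_that("ensemble selection applies a strict accuracy threshold", {
  res <- tibble::tibble(name = c("a", "b", "c", "d"),
                        accuracy = c(0.91, 0.94, 0.88, 0.95))
  expect_equal(nrow(select_ensemble(res, 0.90)), 3)
  expect_setequal(select_ensemble(res, 0.90)$name, c("a", "b", "d"))
  expect_warning(sel <- select_ensemble(res, 1.0), "threshold")
  expect_equal(nrow(sel), 0)
  expect_equal(nrow(select_ensemble(res, 0)), 4)
})

test_that("confusion matrices conserve counts and project to subsets", {
  truth <- rep(1:3, each = 4)
  pred <- c(1, 1, 1, 2,  2, 2, 2, 2,  3, 3, 1, 3)
  cm <- confusion_matrix(truth, pred, class_ids = 1:5)
  expect_equal(dim(cm$counts), c(5, 5))
  expect_equal(unname(rowSums(cm$counts)), c(4, 4, 4, 0, 0))
  expect_equal(sum(cm$counts), 12)
  sub <- restrict_confusion(cm, 1:3)
  expect_equal(sum(sub$counts), 12)
  expect_equal(dim(sub$counts), c(3, 3))
  # predictions escaping the subset go to an explicit "other" column
  pred2 <- c(1, 1, 5, 2,  2, 2, 2, 2,  3, 3, 1, 3)
  cm2 <- confusion_matrix(truth, pred2, class_ids = 1:5)
  sub2 <- restrict_confusion(cm2, 1:3)
  expect_equal(sum(sub2$counts), 12)
  expect_true("other" %in% colnames(sub2$counts))
  expect_error(restrict_confusion(cm, 2:3), "outside")
})

test_that("a perfect predictor scores one with a diagonal confusion matrix", {
  tr <- toy_features(40, gap = 4)
  m <- train_model(tr$x, tr$y, tr$x, tr$y, "mlp32",
                   train_config(max_epochs = 40, seed = 2,
                                learning_rate = 0.05, crop_px = 8,
                                input_px = 4))
  ev <- evaluate(m, tr$x, tr$y)
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(ev$confusion$counts) - sum(diag(ev$confusion$counts)),
               0)
  expect_equal(unname(rowSums(ev$confusion$counts)),
               unname(as.integer(table(tr$y))))
  expect_error(evaluate(m, tr$x, rep(99L, nrow(tr$x))), "class set")
})

test_that("ensembles vote among member predictions and beat disagreement", {
  tr <- toy_features(40); va <- toy_features(12, seed = 8)
  models <- lapply(1:3, function(s) {
    train_model(tr$x, tr$y, va$x, va$y, "mlp32",
                train_config(max_epochs = 15, seed = s, crop_px = 8,
                             input_px = 4))
  })
  ens <- evaluate_ensemble(models, va$x, va$y)
  # voted label always among the member labels for that sample
  for (j in seq_along(ens$voted)) {
    expect_true(ens$voted[j] %in% ens$per_model[, j])
  }
  # where all members agree, the ensemble returns that label
  agree <- apply(ens$per_model, 2, function(col) length(unique(col)) == 1)
  expect_equal(ens$voted[agree], ens$per_model[1, agree])
})
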