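# Small training problems: 1-s segments, separable by construction.
tiny_dataset <- function(n_per_class = 15, k = 3, seed = 53,
                         n_channels = 23) {
  cfg <- synth_config(n_channels = n_channels, segment_seconds = 1,
                      n_segments_per_class = n_per_class,
                      ictal_amplitude_gain = 3, seed = seed)
  synthetic_dataset(cfg, k = k)
}

tiny_config <- function(variant = "DCAE_BiLSTM", epochs = 3, ...) {
  train_config(variant, segment_seconds = 1, learning_rate = 1e-3,
               batch_size = 8, epochs = epochs, seed = 60, ...)
}

test_that("training reduces the joint loss on separable synthetic data", {
  ds <- tiny_dataset()
  config <- tiny_config()
  model <- init_model(ictalcae:::config_spec(config), seed = 60)
  fit <- train_fold(model, ds$x, ds$labels, config)
  expect_equal(nrow(fit$history), config$epochs)  # one row per epoch
  expect_lt(fit$history$tl[config$epochs], fit$history$tl[1])
  expect_true(all(is.finite(fit$history$tl)))
  # classifier-only variants have no reconstruction loss
  cfg2 <- tiny_config("DCNN_MLP", epochs = 2)
  m2 <- init_model(ictalcae:::config_spec(cfg2), seed = 60)
  fit2 <- train_fold(m2, ds$x, ds$labels, cfg2)
  expect_true(all(is.na(fit2$history$rcl)))
  expect_equal(fit2$history$tl, fit2$history$cl)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- tiny_dataset(n_per_class = 10)
  config <- tiny_config(epochs = 2)
  run <- function() {
    model <- init_model(ictalcae:::config_spec(config), seed = 61)
    train_fold(model, ds$x, ds$labels, config, shuffle_seed = 62)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
})

test_that("a weightless reconstruction branch recovers the classifier-only
          training dynamics", {
  ds <- tiny_dataset(n_per_class = 10)
  # DCNN reference run
  cfg_dcnn <- tiny_config("DCNN_BiLSTM", epochs = 2)
  m_dcnn <- init_model(ictalcae:::config_spec(cfg_dcnn), seed = 63)
  fit_dcnn <- train_fold(m_dcnn, ds$x, ds$labels, cfg_dcnn, shuffle_seed = 64)
  # DCAE with a vanishing reconstruction weight and full classification
  # weight, sharing the DCNN's encoder and head initialization
  cfg_dcae <- tiny_config("DCAE_BiLSTM", epochs = 2,
                          weights = loss_weights(1, 1e-9))
  m_dcae <- init_model(ictalcae:::config_spec(cfg_dcae), seed = 63)
  for (nm in names(m_dcnn$params)) m_dcae$params[[nm]] <- m_dcnn$params[[nm]]
  fit_dcae <- train_fold(m_dcae, ds$x, ds$labels, cfg_dcae, shuffle_seed = 64)
  expect_equal(fit_dcae$history$cl, fit_dcnn$history$cl, tolerance = 1e-3)
})

test_that("cross-validation partitions segments and aggregates fold metrics", {
  ds <- tiny_dataset()
  config <- tiny_config(epochs = 2)
  res <- suppressWarnings(cross_validate(ds, config))
  expect_s3_class(res, "cv_result")
  expect_length(res$fold_metrics, ds$k)
  # every segment is tested exactly once across the folds
  expect_equal(sort(unlist(lapply(0:(ds$k - 1),
                                  function(f) which(ds$fold_ids == f)))),
               seq_along(ds$labels))
  # the aggregate mean is the arithmetic mean of the fold metrics
  mm <- do.call(rbind, lapply(res$fold_metrics, unclass))
  expect_equal(res$mean, colMeans(mm), tolerance = 1e-12)
  expect_equal(res$sd, apply(mm, 2, sd), tolerance = 1e-12)
  # a fold missing one class is rejected
  ds_bad <- ds
  ds_bad$fold_ids[ds_bad$labels == 1] <- 0L
  ds_bad$fold_ids[ds_bad$labels == 0] <- 1L
  expect_error(cross_validate(ds_bad, config), "missing a class")
})

test_that("per-fold normalization mode recomputes statistics from training
          folds only", {
  cfg <- synth_config(n_channels = 6, segment_seconds = 1,
                      n_segments_per_class = 12, seed = 65)
  ds <- synthetic_dataset(cfg, k = 3, keep_raw = TRUE)
  config <- tiny_config(epochs = 1)
  res <- suppressWarnings(
    cross_validate(ds, config, folds = 0, per_fold_normalization = TRUE))
  expect_s3_class(res, "cv_result")
  ds_noraw <- synthetic_dataset(cfg, k = 3)
  expect_error(cross_validate(ds_noraw, config, folds = 0,
                              per_fold_normalization = TRUE), "keep_raw")
})

test_that("the evaluation grid reports mean +/- sd rows per variant/length", {
  ds <- tiny_dataset(n_per_class = 9, k = 3)
  config <- tiny_config(epochs = 1)
  grid <- suppressWarnings(run_grid(list("1" = ds), config,
                   variants = c("DCAE_MLP", "DCNN_BiLSTM")))
  expect_equal(nrow(grid$table), 2)
  expect_equal(grid$table$segment_length, rep("1 s", 2))
  expect_true(all(grepl("^\\d+\\.\\d{2} ± \\d+\\.\\d{2}$", grid$table$Se)))
  expect_named(grid$table, c("segment_length", "method", "Se", "Sp", "Acc",
                             "Pr", "F_score"))
  # same seed reproduces the table bit-identically
  grid2 <- suppressWarnings(run_grid(list("1" = ds), config,
                    variants = c("DCAE_MLP", "DCNN_BiLSTM")))
  expect_identical(grid$table, grid2$table)
})

test_that("history plots are written once per fold and empty input warns", {
  ds <- tiny_dataset(n_per_class = 10, k = 2)
  res <- suppressWarnings(cross_validate(ds, tiny_config(epochs = 2)))
  dir <- file.path(tempdir(), "ictalcae-hist")
  on.exit(unlink(dir, recursive = TRUE))
  paths <- plot_histories(res, dir = dir)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))
  res$histories <- list()
  expect_warning(plot_histories(res, dir = dir), "no training histories")
})

test_that("non-adam optimizers step without diverging", {
  ds <- tiny_dataset(n_per_class = 8, k = 2)
  for (opt in c("sgd", "rmsprop", "adadelta")) {
    config <- tiny_config(epochs = 1)
    config$optimizer <- opt
    model <- init_model(ictalcae:::config_spec(config), seed = 66)
    fit <- train_fold(model, ds$x, ds$labels, config)
    expect_true(all(is.finite(fit$history$tl)))
  }
})
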