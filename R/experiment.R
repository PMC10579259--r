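#' Training configuration
#'
#' Defaults reproduce the reference protocol: Adam with learning rate 0.0001,
#' batches of 32, joint loss weights (0.5, 1.0). The epoch count is not fixed
#' by the protocol and defaults to 100; scaled-down runs use far fewer (see
#' the package vignette for the desk-scale settings).
#'
#' @param variant Model variant (see [model_spec()]).
#' @param segment_seconds Segment length in seconds.
#' @param optimizer One of `"adam"`, `"sgd"`, `"rmsprop"`, `"adadelta"`.
#' @param learning_rate Positive step size.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param weights A [loss_weights()].
#' @param dropout Dropout rate on the Bi-LSTM head.
#' @param seed Master seed: weight initialization, batch shuffling and any
#'   dropout all derive from it.
#' @param ... Extra arguments passed to [model_spec()].
#' @return Object of class `train_config`.
#' @export
train_config <- function(variant = "DCAE_BiLSTM", segment_seconds = 4,
                         optimizer = c("adam", "sgd", "rmsprop", "adadelta"),
                         learning_rate = 1e-4, batch_size = 32, epochs = 100,
                         weights = loss_weights(), dropout = 0, seed = 1,
                         ...) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(variant = variant, segment_seconds = segment_seconds,
                 optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weights = weights,
                 dropout = dropout, seed = as.integer(seed),
                 spec_args = list(...)), class = "train_config")
}

config_spec <- function(config) {
  do.call(model_spec, c(list(variant = config$variant,
                             segment_seconds = config$segment_seconds,
                             dropout = config$dropout), config$spec_args))
}

# --- optimizers -------------------------------------------------------------

opt_state_new <- function() new.env(parent = emptyenv())

opt_update <- function(params, grads, state, config, step) {
  lr <- config$learning_rate
  for (nm in names(grads)) {
    g <- grads[[nm]]
    p <- params[[nm]]
    upd <- switch(config$optimizer,
      sgd = -lr * g,
      adam = {
        m <- state[[paste0(nm, ".m")]] %||% 0
        v <- state[[paste0(nm, ".v")]] %||% 0
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g^2
        state[[paste0(nm, ".m")]] <- m
        state[[paste0(nm, ".v")]] <- v
        mhat <- m / (1 - 0.9^step)
        vhat <- v / (1 - 0.999^step)
        -lr * mhat / (sqrt(vhat) + 1e-7)
      },
      rmsprop = {
        v <- state[[paste0(nm, ".v")]] %||% 0
        v <- 0.9 * v + 0.1 * g^2
        state[[paste0(nm, ".v")]] <- v
        -lr * g / (sqrt(v) + 1e-7)
      },
      adadelta = {
        v <- state[[paste0(nm, ".v")]] %||% 0
        u <- state[[paste0(nm, ".u")]] %||% 0
        v <- 0.95 * v + 0.05 * g^2
        dx <- -sqrt(u + 1e-6) / sqrt(v + 1e-6) * g
        u <- 0.95 * u + 0.05 * dx^2
        state[[paste0(nm, ".v")]] <- v
        state[[paste0(nm, ".u")]] <- u
        lr * dx   # adadelta is near scale-free; lr acts as a multiplier
      })
    params[[nm]] <- p + upd
  }
  params
}

# --- training ---------------------------------------------------------------

#' Train a model on one training split
#'
#' Mini-batch training with per-epoch seeded shuffling (the last partial
#' batch is kept). Autoencoder variants minimize the weighted total loss
#' `weight_cl * CL + weight_rlc * RC_L`; classifier-only variants minimize
#' the cross-entropy alone. A non-finite loss aborts with a diagnostic.
#'
#' @param model A `cae_model` (see [assemble()]).
#' @param x Training segments `(N, I, J, 1)`.
#' @param y Binary labels.
#' @param config A [train_config()].
#' @param shuffle_seed Seed for the batch shuffling (defaults to
#'   `config$seed`).
#' @return List with the trained `model` and `history` (a data frame with
#'   per-epoch mean `cl`, `rcl`, `tl` and training `accuracy`).
#' @export
train_fold <- function(model, x, y, config, shuffle_seed = config$seed) {
  stopifnot(inherits(model, "cae_model"), inherits(config, "train_config"))
  x <- as_batch(x)
  n <- dim(x)[1]
  params <- model$params
  state <- opt_state_new()
  history <- data.frame(epoch = seq_len(config$epochs), cl = NA_real_,
                        rcl = NA_real_, tl = NA_real_, accuracy = NA_real_)
  step <- 0L
  with_seed(shuffle_seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      cl_s <- rcl_s <- tl_s <- 0; correct <- 0L
      for (s in starts) {
        b <- idx[s:min(n, s + config$batch_size - 1L)]
        cspec <- spec_to_cpp(model$spec, config$weights,
                             drop_seed = sample.int(.Machine$integer.max, 1))
        res <- cpp_model_grad(x[b, , , , drop = FALSE], as.double(y[b]),
                              params, cspec)
        if (!is.finite(res$tl))
          stop(sprintf("training diverged (non-finite loss at epoch %d)",
                       epoch))
        step <- step + 1L
        params <- opt_update(params, res$grads, state, config, step)
        for (nm in names(res$bn_updates)) params[[nm]] <- res$bn_updates[[nm]]
        w <- length(b)
        cl_s <- cl_s + res$cl * w
        rcl_s <- rcl_s + (if (is.na(res$rcl)) 0 else res$rcl) * w
        tl_s <- tl_s + res$tl * w
        correct <- correct + sum((res$prob >= 0.5) == (y[b] == 1))
      }
      history$cl[epoch] <- cl_s / n
      history$rcl[epoch] <- if (model$spec$has_decoder) rcl_s / n else NA_real_
      history$tl[epoch] <- tl_s / n
      history$accuracy[epoch] <- correct / n
    }
  })
  model$params <- params
  list(model = model, history = history)
}

#' Evaluate a model on held-out segments
#'
#' @param model A trained `cae_model`.
#' @param x Segments `(N, I, J, 1)`.
#' @param y Binary labels.
#' @param tau Decision threshold.
#' @param chunk Batch size for the forward passes.
#' @return List with `metrics` (a `metrics_record`), `counts`, `prob`.
#' @export
evaluate_model <- function(model, x, y, tau = 0.5, chunk = 64L) {
  x <- as_batch(x)
  n <- dim(x)[1]
  prob <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    b <- s:min(n, s + chunk - 1L)
    prob[b] <- model_forward(model, x[b, , , , drop = FALSE],
                             reconstruct = FALSE)$prob
  }
  thr <- threshold_predictions(prob, y, tau)
  list(metrics = compute_metrics(thr$counts), counts = thr$counts,
       prob = prob)
}

#' Stratified k-fold cross-validation
#'
#' Each fold serves once as the held-out test set while a freshly initialized
#' model trains on the remaining folds; per-fold metrics are computed on the
#' held-out fold only and aggregated as mean and standard deviation. Under a
#' fixed configuration seed the whole procedure (initialization, shuffling,
#' evaluation) is deterministic.
#'
#' @param dataset An `eeg_dataset` with fold assignments.
#' @param config A [train_config()].
#' @param folds Folds to run (default: all). Running a subset is useful for
#'   quick checks; aggregation then covers the subset.
#' @param per_fold_normalization Recompute z-score and min-max statistics
#'   from the training folds only (requires a dataset built with
#'   `keep_raw = TRUE`); the default reuses the merged-dataset normalization
#'   the preparation pipeline applied.
#' @param verbose Print per-fold progress.
#' @return Object of class `cv_result`: per-fold `metrics` and `histories`,
#'   aggregated `mean` and `sd` per metric, and the `config`.
#' @export
cross_validate <- function(dataset, config, folds = NULL,
                           per_fold_normalization = FALSE, verbose = FALSE) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  folds <- folds %||% sort(unique(dataset$fold_ids))
  if (per_fold_normalization && is.null(dataset$x_raw))
    stop("per-fold normalization requires a dataset prepared with keep_raw = TRUE")
  fold_metrics <- list()
  histories <- list()
  for (f in folds) {
    test <- dataset$fold_ids == f
    if (length(unique(dataset$labels[test])) < 2 ||
        length(unique(dataset$labels[!test])) < 2)
      stop(sprintf("fold %d is missing a class", f))
    if (per_fold_normalization) {
      stats <- channel_stats(dataset$x_raw[!test, , , drop = FALSE])
      z_tr <- zscore_channels(dataset$x_raw[!test, , , drop = FALSE], stats)
      mm <- minmax_scale(z_tr)
      z_te <- zscore_channels(dataset$x_raw[test, , , drop = FALSE], stats)
      te <- minmax_scale(z_te, mm$bounds)$values
      x_tr <- array(mm$values, c(dim(z_tr), 1))
      x_te <- array(pmin(pmax(te, 0), 1), c(dim(z_te), 1))
    } else {
      x_tr <- dataset$x[!test, , , , drop = FALSE]
      x_te <- dataset$x[test, , , , drop = FALSE]
    }
    model <- init_model(config_spec(config), seed = config$seed + 1000L * f)
    fit <- train_fold(model, x_tr, dataset$labels[!test], config,
                      shuffle_seed = config$seed + 1000L * f + 1L)
    ev <- evaluate_model(fit$model, x_te, dataset$labels[test])
    fold_metrics[[as.character(f)]] <- ev$metrics
    histories[[as.character(f)]] <- fit$history
    if (verbose)
      message(sprintf("fold %d: acc %.2f%%", f, ev$metrics[["accuracy"]]))
  }
  mm <- do.call(rbind, lapply(fold_metrics, unclass))
  structure(list(
    fold_metrics = fold_metrics, histories = histories,
    mean = colMeans(mm), sd = apply(mm, 2, sd), folds = folds,
    config = config
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %g-s segments, %d folds\n", x$config$variant,
              x$config$segment_seconds, length(x$folds)))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Run the variant-by-length evaluation grid
#'
#' Cross-validates every model variant at every provided segment length and
#' collects the results in the conventional reporting layout (segment
#' length, method, then Se, Sp, Acc, Pr and F-score as "mean +/- sd" with two
#' decimals).
#'
#' @param datasets Named list of `eeg_dataset`s keyed by segment length
#'   (e.g. `list("1" = ..., "2" = ..., "4" = ...)`).
#' @param config A [train_config()]; its variant/length fields are overridden
#'   by the grid.
#' @param variants Variants to run (default: all four).
#' @return Object of class `grid_result` with `results` (list of
#'   `cv_result`) and `table` (formatted data frame).
#' @export
run_grid <- function(datasets, config, variants = VARIANTS) {
  rows <- list()
  results <- list()
  full <- length(datasets) * length(variants)
  for (len in names(datasets)) {
    for (v in variants) {
      cfg <- config
      cfg$variant <- v
      cfg$segment_seconds <- as.numeric(len)
      key <- paste0(v, "@", len, "s")
      res <- tryCatch(cross_validate(datasets[[len]], cfg),
                      error = function(e) {
                        warning(sprintf("grid cell %s failed: %s", key,
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
      if (is.null(res)) next
      results[[key]] <- res
      fmt <- function(m) sprintf("%.2f ± %.2f", res$mean[[m]], res$sd[[m]])
      rows[[key]] <- data.frame(
        segment_length = paste0(len, " s"), method = v,
        Se = fmt("sensitivity"), Sp = fmt("specificity"),
        Acc = fmt("accuracy"), Pr = fmt("precision"), F_score = fmt("f1"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) < full)
    warning(sprintf("grid incomplete: %d of %d cells", length(rows), full),
            call. = FALSE)
  structure(list(results = results,
                 table = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Plot training histories of a cross-validation run
#'
#' Writes one figure per requested fold with the training accuracy and the
#' loss components (classification, reconstruction, total) against epoch.
#'
#' @param result A `cv_result`.
#' @param dir Output directory for the PNG files.
#' @param folds Folds to plot (default: all available).
#' @return Invisibly, the written file paths (empty with a warning when no
#'   histories are present).
#' @export
plot_histories <- function(result, dir = ".", folds = NULL) {
  stopifnot(inherits(result, "cv_result"))
  folds <- as.character(folds %||% names(result$histories))
  folds <- intersect(folds, names(result$histories))
  if (length(folds) == 0 ||
      all(vapply(result$histories[folds], nrow, integer(1)) == 0)) {
    warning("no training histories to plot", call. = FALSE)
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (f in folds) {
    h <- result$histories[[f]]
    long <- rbind(
      data.frame(epoch = h$epoch, value = h$cl, curve = "classification loss"),
      if (!all(is.na(h$rcl)))
        data.frame(epoch = h$epoch, value = h$rcl, curve = "reconstruction loss"),
      data.frame(epoch = h$epoch, value = h$tl, curve = "total loss"),
      data.frame(epoch = h$epoch, value = h$accuracy, curve = "train accuracy"))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~curve, scales = "free_y") +
      ggplot2::labs(title = sprintf("%s, fold %s", result$config$variant, f),
                    x = "epoch", y = NULL) +
      ggplot2::theme_minimal()
    path <- file.path(dir, sprintf("history_fold%s.png", f))
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)
    paths <- c(paths, path)
  }
  invisible(paths)
}
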