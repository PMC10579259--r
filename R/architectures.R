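VARIANTS <- c("DCAE_MLP", "DCAE_BiLSTM", "DCNN_MLP", "DCNN_BiLSTM")

#' Declarative description of one model architecture
#'
#' Four variants are supported: the joint reconstruction-classification
#' autoencoders (`DCAE_MLP`, `DCAE_BiLSTM`) and the classifier-only networks
#' (`DCNN_MLP`, `DCNN_BiLSTM`) obtained by removing the decoder. All share an
#' encoder of four (conv -> ReLU -> batch norm -> max pool) stages with 32 and
#' 64 filters in alternating order, 3 x 2 same-padded kernels, stride 1,
#' pooling windows (2,2) except (2,3) at the last stage. The decoder mirrors
#' this with four (conv -> activation -> upsample) stages, filters
#' 64, 32, 32, 1, the last with a sigmoid activation, upsampling factors
#' (2,3) then (2,2); its output is cropped back to the input grid.
#'
#' @param variant One of `"DCAE_MLP"`, `"DCAE_BiLSTM"`, `"DCNN_MLP"`,
#'   `"DCNN_BiLSTM"`.
#' @param segment_seconds EEG segment length in seconds, one of 1, 2, 4.
#' @param n_channels Number of EEG channels (default 23).
#' @param sampling_rate_hz Sampling rate in Hz (default 256).
#' @param encoder_filters,decoder_filters Filter counts per stage.
#' @param kernel Convolution kernel extent `(rows, cols)`.
#' @param pool_plan,upsample_plan Lists of per-stage window/factor pairs.
#' @param mlp_hidden Hidden layer widths of the MLP head.
#' @param lstm_units Hidden units per LSTM direction (default 50).
#' @param dropout Dropout rate on the Bi-LSTM head features, in `[0, 1)`.
#'   Default 0; around 0.2 is a reasonable setting when overfitting shows.
#' @param bn_eps,bn_momentum Batch-normalization stability constant and
#'   running-statistics momentum.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' spec <- model_spec("DCAE_BiLSTM", segment_seconds = 4)
#' latent_shape(spec)  # 64 x 1 x 64
model_spec <- function(variant = VARIANTS, segment_seconds = 4,
                       n_channels = 23, sampling_rate_hz = 256,
                       encoder_filters = c(32, 64, 32, 64),
                       decoder_filters = c(64, 32, 32, 1),
                       kernel = c(3, 2),
                       pool_plan = list(c(2, 2), c(2, 2), c(2, 2), c(2, 3)),
                       upsample_plan = list(c(2, 3), c(2, 2), c(2, 2), c(2, 2)),
                       mlp_hidden = c(50, 32), lstm_units = 50, dropout = 0,
                       bn_eps = 1e-3, bn_momentum = 0.9) {
  variant <- match.arg(variant)
  if (!segment_seconds %in% c(1, 2, 4))
    stop("segment_seconds must be one of 1, 2, 4")
  stopifnot(length(encoder_filters) == 4, length(decoder_filters) == 4,
            length(pool_plan) == 4, length(upsample_plan) == 4,
            dropout >= 0, dropout < 1, bn_eps > 0)
  if (decoder_filters[4] != 1)
    stop("the final decoder convolution must have a single filter")
  spec <- structure(list(
    variant = variant, segment_seconds = segment_seconds,
    n_channels = n_channels, sampling_rate_hz = sampling_rate_hz,
    encoder_filters = encoder_filters, decoder_filters = decoder_filters,
    kernel = kernel, pool_plan = pool_plan, upsample_plan = upsample_plan,
    mlp_hidden = mlp_hidden, lstm_units = lstm_units, dropout = dropout,
    bn_eps = bn_eps, bn_momentum = bn_momentum,
    has_decoder = grepl("^DCAE", variant),
    head = if (grepl("MLP$", variant)) "mlp" else "bilstm"
  ), class = "model_spec")
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  ls <- latent_shape(x)
  cat(sprintf("<model_spec> %s, %g-s segments (%d x %d x 1) -> latent %s\n",
              x$variant, x$segment_seconds,
              x$sampling_rate_hz * x$segment_seconds, x$n_channels,
              paste(ls, collapse = " x ")))
  invisible(x)
}

#' Latent representation shape of an encoder
#'
#' Traces the input grid through the four pooling stages (ceil-mode), e.g.
#' a 4-s segment (1024 x 23 x 1) maps to a latent of 64 x 1 x 64.
#'
#' @param spec A [model_spec()].
#' @return Integer vector `(time steps, channel extent, feature maps)`.
#' @export
latent_shape <- function(spec) {
  h <- spec$sampling_rate_hz * spec$segment_seconds
  w <- spec$n_channels
  for (p in spec$pool_plan) {
    h <- ceiling(h / p[1])
    w <- ceiling(w / p[2])
  }
  as.integer(c(h, w, spec$encoder_filters[4]))
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights (seeded), zero biases, batch-norm scale 1 / shift 0
#' with running mean 0 and variance 1.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the weight draws.
#' @return An object of class `cae_model` holding `spec` and `params`.
#' @export
init_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  params <- with_seed(seed, {
    p <- list()
    cin <- 1
    for (i in 1:4) {
      f <- spec$encoder_filters[i]
      p[[paste0("ec", i, "_W")]] <- glorot(kh * kw * cin, kh * kw * f,
                                           c(kh, kw, cin, f))
      p[[paste0("ec", i, "_b")]] <- numeric(f)
      p[[paste0("bn", i, "_gamma")]] <- rep(1, f)
      p[[paste0("bn", i, "_beta")]] <- numeric(f)
      p[[paste0("bn", i, "_mean")]] <- numeric(f)
      p[[paste0("bn", i, "_var")]] <- rep(1, f)
      cin <- f
    }
    if (spec$has_decoder) {
      for (i in 1:4) {
        f <- spec$decoder_filters[i]
        p[[paste0("dc", i, "_W")]] <- glorot(kh * kw * cin, kh * kw * f,
                                             c(kh, kw, cin, f))
        p[[paste0("dc", i, "_b")]] <- numeric(f)
        cin <- f
      }
    }
    ls <- latent_shape(spec)
    if (spec$head == "mlp") {
      d <- prod(ls)
      widths <- c(d, spec$mlp_hidden, 1)
      for (i in seq_len(length(widths) - 1)) {
        p[[paste0("fc", i, "_W")]] <- glorot(widths[i], widths[i + 1],
                                             c(widths[i], widths[i + 1]))
        p[[paste0("fc", i, "_b")]] <- numeric(widths[i + 1])
      }
    } else {
      f <- ls[2] * ls[3]
      u <- spec$lstm_units
      for (dir in c("fw", "bw")) {
        p[[paste0("lstm_", dir, "_W")]] <- glorot(f + u, 4 * u,
                                                  c(f + u, 4 * u))
        p[[paste0("lstm_", dir, "_b")]] <- numeric(4 * u)
      }
      p[["out_W"]] <- glorot(2 * u, 1, c(2 * u, 1))
      p[["out_b"]] <- numeric(1)
    }
    p
  })
  structure(list(spec = spec, params = params), class = "cae_model")
}

#' Assemble one of the four model variants
#'
#' Convenience wrapper: `model_spec()` + `init_model()`. The encoder stack is
#' structurally identical between the autoencoder and classifier-only variants
#' of the same segment length, and identical seeds give identical encoder
#' initializations, which enables controlled comparisons.
#'
#' @inheritParams model_spec
#' @param seed Seed for weight initialization.
#' @param ... Passed to [model_spec()].
#' @return A `cae_model`.
#' @export
assemble <- function(variant, segment_seconds, seed = 1, ...) {
  init_model(model_spec(variant = variant, segment_seconds = segment_seconds,
                        ...), seed = seed)
}

#' @export
print.cae_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %s trainable parameters\n",
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Batch-norm running statistics are state, not parameters, and are excluded.
#'
#' @param model A `cae_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  nm <- trainable_names(model$params)
  sum(vapply(model$params[nm], length, integer(1)))
}

trainable_names <- function(params) {
  nm <- names(params)
  nm[!grepl("_(mean|var)$", nm)]
}

# Spec fields in the form the C++ engine consumes.
spec_to_cpp <- function(spec, weights = NULL, drop_seed = 0L) {
  list(
    has_decoder = spec$has_decoder, head = spec$head,
    pool_h = vapply(spec$pool_plan, `[`, numeric(1), 1) |> as.integer(),
    pool_w = vapply(spec$pool_plan, `[`, numeric(1), 2) |> as.integer(),
    up_h = vapply(spec$upsample_plan, `[`, numeric(1), 1) |> as.integer(),
    up_w = vapply(spec$upsample_plan, `[`, numeric(1), 2) |> as.integer(),
    bn_eps = spec$bn_eps, bn_momentum = spec$bn_momentum,
    weight_cl = if (is.null(weights)) 0.5 else weights$weight_cl,
    weight_rlc = if (is.null(weights)) 1.0 else weights$weight_rlc,
    dropout = spec$dropout, drop_seed = as.integer(drop_seed)
  )
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("x must be an array")
  if (length(d) == 2) array(x, c(1, d, 1))
  else if (length(d) == 3) array(x, c(d, 1))
  else if (length(d) == 4) x
  else stop("x must have 2 to 4 dimensions")
}

#' Forward pass through a model
#'
#' Runs the encoder (batch norm in inference mode, using running statistics),
#' the classification head, and -- for autoencoder variants -- the decoder.
#'
#' @param model A `cae_model`.
#' @param x Segment batch: `(N, I, J, 1)` array (a single `(I, J)` matrix or
#'   `(I, J, 1)` array is promoted to a batch of one).
#' @param reconstruct Return the reconstruction for autoencoder variants?
#' @return List with `prob` (length-N class probabilities), `latent_dim`, and
#'   `recon` (`(N, I, J, 1)`, values in `(0, 1)`) when applicable.
#' @export
model_forward <- function(model, x, reconstruct = TRUE) {
  x <- as_batch(x)
  cpp_model_forward(x, model$params, spec_to_cpp(model$spec), reconstruct)
}

#' Save / load a model checkpoint
#'
#' Serializes the spec and all parameters (including batch-norm running
#' statistics), so a reloaded model evaluates identically.
#'
#' @param model A `cae_model`.
#' @param path File path (RDS).
#' @return `path` (write) or the restored `cae_model` (read).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cae_model"))
  model
}

#' Encoder output (latent representation) for a batch
#'
#' @param model A `cae_model`.
#' @param x Segment batch as in [model_forward()].
#' @return Array `(N, time steps, channel extent, feature maps)`.
#' @export
model_latent <- function(model, x) {
  cpp_model_latent(as_batch(x), model$params, spec_to_cpp(model$spec))$latent
}
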