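#' Rectified linear unit
#'
#' Elementwise `max(0, y)`, the activation used by every convolutional and
#' fully connected layer except the final sigmoid outputs.
#'
#' @param y Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries clamped to zero.
#' @export
#' @examples
#' nn_relu(c(-3, 0, 2))
nn_relu <- function(y) {
  out <- pmax(y, 0)
  attributes(out) <- attributes(y)
  out
}

#' Logistic sigmoid
#'
#' Overflow-safe `1 / (1 + exp(-y))`, used by the classification outputs and
#' the reconstruction layer so that outputs live in (0, 1).
#'
#' @param y Numeric vector, matrix or array.
#' @return Object of the same shape with values in (0, 1).
#' @export
#' @examples
#' nn_sigmoid(0)        # 0.5
#' nn_sigmoid(log(3))   # 0.75
nn_sigmoid <- function(y) {
  out <- ifelse(y >= 0, 1 / (1 + exp(-y)), exp(y) / (1 + exp(y)))
  attributes(out) <- attributes(y)
  out
}

#' 2-D convolution over (time, channel) grids
#'
#' Same-padded, stride-1 convolution. Input tensors carry a trailing feature
#' axis: either `(time, channel, features)` for a single segment or
#' `(batch, time, channel, features)` for a batch. For even kernel extents the
#' "same" padding puts `floor((k-1)/2)` zeros before and the remainder after,
#' so the default 3 x 2 kernel pads one row above/below and one column on the
#' right. No activation is applied; callers compose with [nn_relu()] or
#' [nn_sigmoid()].
#'
#' @param x Input array, `(I, J, C)` or `(N, I, J, C)`.
#' @param weights Kernel array `(kh, kw, C, F)`.
#' @param bias Numeric vector of length `F` (default zeros).
#' @return Array with the same spatial shape and `F` feature maps.
#' @export
nn_conv2d <- function(x, weights, bias = NULL) {
  stopifnot(is.array(x), is.array(weights), length(dim(weights)) == 4)
  if (is.null(bias)) bias <- numeric(dim(weights)[4])
  cpp_conv2d(as.double(x) |> array(dim(x)),
             as.double(weights) |> array(dim(weights)),
             as.double(bias))
}

#' Max pooling with boundary-preserving (ceil) windows
#'
#' Non-overlapping max pooling. Output dimensions are `ceiling(input/window)`:
#' partial windows at the boundary are kept, which is what lets the 23-channel
#' axis survive four pooling stages (23 -> 12 -> 6 -> 3 -> 1).
#'
#' @param x Input array, `(I, J, C)` or `(N, I, J, C)`.
#' @param window Integer pair `(ph, pw)`; the architectures use `(2, 2)` for
#'   the first three stages and `(2, 3)` for the last.
#' @return Downsampled array.
#' @export
nn_max_pool <- function(x, window = c(2, 2)) {
  stopifnot(is.array(x), length(window) == 2, all(window >= 1))
  cpp_max_pool(as.double(x) |> array(dim(x)), as.integer(window[1]),
               as.integer(window[2]))
}

#' Nearest-neighbour upsampling
#'
#' Each cell is repeated `factor` times along the time and channel axes, so
#' output dimensions are exactly `input * factor`. With equal factors,
#' `nn_max_pool(nn_upsample(x, f), f)` recovers `x`.
#'
#' @param x Input array, `(I, J, C)` or `(N, I, J, C)`.
#' @param factor Integer pair `(fh, fw)`; the decoder uses `(2, 3)` at its
#'   first stage and `(2, 2)` afterwards.
#' @return Enlarged array.
#' @export
nn_upsample <- function(x, factor = c(2, 2)) {
  stopifnot(is.array(x), length(factor) == 2, all(factor >= 1))
  cpp_upsample(as.double(x) |> array(dim(x)), as.integer(factor[1]),
               as.integer(factor[2]))
}

#' Batch normalization
#'
#' Per-feature standardization followed by the learned affine transform
#' `gamma * xhat + beta`. In `"train"` mode the batch's own (biased) mean and
#' variance are used; in `"infer"` mode the supplied running statistics are.
#'
#' @param x Matrix `(batch, features)` or array `(N, I, J, C)` (features =
#'   feature maps, statistics pooled over batch and spatial axes).
#' @param gamma,beta Learned scale and shift, one value per feature.
#' @param mode `"train"` or `"infer"`.
#' @param running_mean,running_var Running statistics, required for `"infer"`.
#' @param eps Stability constant added to the variance (default 1e-3).
#' @return List with `values` (same shape as `x`) and, in train mode, the
#'   `batch_mean` and `batch_var` used.
#' @export
nn_batch_norm <- function(x, gamma, beta, mode = c("train", "infer"),
                          running_mean = NULL, running_var = NULL,
                          eps = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(eps > 0)
  dm <- dim(x)
  if (is.null(dm)) stop("x must be a matrix or array")
  nf <- dm[length(dm)]
  stopifnot(length(gamma) == nf, length(beta) == nf)
  xm <- matrix(as.double(x), ncol = nf)
  if (mode == "train") {
    if (nrow(xm) < 2) stop("train-mode batch normalization needs at least 2 items")
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
  } else {
    if (is.null(running_mean) || is.null(running_var))
      stop("infer mode requires running_mean and running_var")
    mu <- running_mean
    v <- running_var
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  values <- array(out, dm)
  if (mode == "train") list(values = values, batch_mean = mu, batch_var = v)
  else list(values = values)
}

#' One step of the LSTM memory-cell recurrence
#'
#' The cell combines the previous hidden state `h_prev` and the input `y`
#' through four gates: forget `j = sigmoid(Xj [h, y] + aj)` decides what to
#' drop from the cell state, input `k` what to write, output `l` what to
#' expose, and the candidate `tanh(Xb [h, y] + ab)` supplies the new content.
#' The state updates are `c = j * c_prev + k * cand` and `h = l * tanh(c)`.
#'
#' @param params List with weight matrices `Xj`, `Xk`, `Xl`, `Xb`, each
#'   `(units, units + n_features)` acting on the concatenation `[h_prev, y]`,
#'   and bias vectors `aj`, `ak`, `al`, `ab` of length `units`.
#' @param y Input vector at this time step.
#' @param h_prev,c_prev Previous hidden and cell state vectors (default zero).
#' @return List with the new hidden state `h` and cell state `c`.
#' @export
nn_lstm_step <- function(params, y, h_prev = NULL, c_prev = NULL) {
  units <- length(params$aj)
  if (is.null(h_prev)) h_prev <- numeric(units)
  if (is.null(c_prev)) c_prev <- numeric(units)
  z <- c(h_prev, y)
  for (w in c("Xj", "Xk", "Xl", "Xb"))
    if (ncol(params[[w]]) != length(z))
      stop(sprintf("weight %s has %d columns but [h, y] has length %d",
                   w, ncol(params[[w]]), length(z)))
  j <- nn_sigmoid(drop(params$Xj %*% z) + params$aj)
  k <- nn_sigmoid(drop(params$Xk %*% z) + params$ak)
  l <- nn_sigmoid(drop(params$Xl %*% z) + params$al)
  cand <- tanh(drop(params$Xb %*% z) + params$ab)
  cstate <- j * c_prev + k * cand
  h <- l * tanh(cstate)
  list(h = h, c = cstate)
}

#' Bidirectional LSTM layer with time-averaged output
#'
#' Runs two independent LSTM cells over a feature sequence, one forward in
#' time and one backward, concatenates their hidden states at every step, and
#' averages the concatenated outputs over all time steps. Reversing the input
#' sequence therefore swaps the forward/backward halves of the result.
#'
#' @param sequence Matrix `(time steps, features)`.
#' @param fw_params,bw_params Cell parameter lists as in [nn_lstm_step()].
#' @return List with `average` (length `2 * units`) and `outputs`
#'   (`time steps x 2 * units`, forward half first).
#' @export
nn_bilstm <- function(sequence, fw_params, bw_params) {
  if (NROW(sequence) == 0) stop("empty sequence")
  sequence <- rbind(sequence)
  n <- nrow(sequence)
  units <- length(fw_params$aj)
  run <- function(params, idx) {
    h <- NULL; cs <- NULL
    out <- matrix(0, n, units)
    for (t in seq_len(n)) {
      st <- nn_lstm_step(params, sequence[idx[t], ], h, cs)
      h <- st$h; cs <- st$c
      out[idx[t], ] <- h
    }
    out
  }
  fw <- run(fw_params, seq_len(n))
  bw <- run(bw_params, rev(seq_len(n)))
  outputs <- cbind(fw, bw)
  list(average = colMeans(outputs), outputs = outputs)
}
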