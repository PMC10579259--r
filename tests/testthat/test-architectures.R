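test_that("latent shapes follow the pooling arithmetic for every length", {
  expect_equal(latent_shape(model_spec("DCAE_MLP", 4)), c(64L, 1L, 64L))
  expect_equal(latent_shape(model_spec("DCAE_MLP", 2)), c(32L, 1L, 64L))
  expect_equal(latent_shape(model_spec("DCAE_MLP", 1)), c(16L, 1L, 64L))
})

test_that("model spec validates its structural invariants", {
  expect_error(model_spec("DCAE_MLP", segment_seconds = 3), "1, 2, 4")
  expect_error(model_spec("NOPE", 4))
  expect_error(model_spec("DCAE_MLP", 4, decoder_filters = c(64, 32, 32, 2)),
               "single filter")
  sp <- model_spec("DCNN_BiLSTM", 2)
  expect_false(sp$has_decoder)
  expect_equal(sp$head, "bilstm")
})

test_that("every variant/length builds and forwards with coherent shapes", {
  set.seed(41)
  for (len in c(1, 2, 4)) {
    x <- array(runif(2 * 256 * len * 23), c(2, 256 * len, 23, 1))
    for (v in c("DCAE_MLP", "DCAE_BiLSTM", "DCNN_MLP", "DCNN_BiLSTM")) {
      model <- assemble(v, len, seed = 8)
      out <- model_forward(model, x)
      expect_length(out$prob, 2)
      expect_true(all(out$prob > 0 & out$prob < 1))
      if (grepl("^DCAE", v)) {
        expect_equal(dim(out$recon), dim(x))
        expect_true(all(out$recon >= 0 & out$recon <= 1))
      } else {
        expect_null(out$recon)
      }
    }
  }
})

test_that("the MLP head flattens a 4-s latent to 4096 inputs", {
  model <- assemble("DCAE_MLP", 4, seed = 2)
  expect_equal(dim(model$params$fc1_W), c(4096, 50))
  expect_equal(dim(model$params$fc2_W), c(50, 32))
  expect_equal(dim(model$params$fc3_W), c(32, 1))
})

test_that("the Bi-LSTM head sees 100 concatenated features per step", {
  model <- assemble("DCAE_BiLSTM", 4, seed = 2)
  expect_equal(dim(model$params$out_W), c(100, 1))
  expect_equal(dim(model$params$lstm_fw_W), c(64 + 50, 200))
})

test_that("a zero-weight head outputs probability one half", {
  model <- assemble("DCNN_MLP", 1, seed = 3)
  for (nm in grep("^fc", names(model$params), value = TRUE))
    model$params[[nm]][] <- 0
  x <- array(runif(3 * 256 * 23), c(3, 256, 23, 1))
  expect_equal(model_forward(model, x)$prob, rep(0.5, 3))
  model2 <- assemble("DCNN_BiLSTM", 1, seed = 3)
  for (nm in c("lstm_fw_W", "lstm_fw_b", "lstm_bw_W", "lstm_bw_b",
               "out_W", "out_b"))
    model2$params[[nm]][] <- 0
  expect_equal(model_forward(model2, x)$prob, rep(0.5, 3))
})

test_that("removing the decoder reduces the parameter count only", {
  dcae <- assemble("DCAE_BiLSTM", 2, seed = 9)
  dcnn <- assemble("DCNN_BiLSTM", 2, seed = 9)
  expect_lt(n_params(dcnn), n_params(dcae))
  # identical seed gives bit-identical encoder initializations
  enc <- grep("^(ec|bn)", names(dcae$params), value = TRUE)
  expect_identical(dcae$params[enc], dcnn$params[enc])
  # parameter count is independent of segment length (no dense encoder layers)
  enc_n <- function(m) sum(vapply(m$params[grep("^ec", names(m$params))],
                                  length, integer(1)))
  expect_equal(enc_n(assemble("DCAE_MLP", 1)), enc_n(assemble("DCAE_MLP", 4)))
})

# The float training engine must agree with a forward pass composed from the
# double-precision layer primitives.
compose_forward <- function(model, xb) {
  spec <- model$spec
  p <- model$params
  n <- dim(xb)[1]
  probs <- numeric(n)
  recons <- array(0, dim(xb))
  for (i in seq_len(n)) {
    a <- array(xb[i, , , ], c(dim(xb)[2], dim(xb)[3], 1))
    for (s in 1:4) {
      a <- nn_relu(nn_conv2d(a, p[[paste0("ec", s, "_W")]],
                             p[[paste0("ec", s, "_b")]]))
      a <- nn_batch_norm(a, p[[paste0("bn", s, "_gamma")]],
                         p[[paste0("bn", s, "_beta")]], mode = "infer",
                         running_mean = p[[paste0("bn", s, "_mean")]],
                         running_var = p[[paste0("bn", s, "_var")]],
                         eps = spec$bn_eps)$values
      a <- nn_max_pool(a, spec$pool_plan[[s]])
    }
    latent <- a
    if (spec$head == "mlp") {
      flat <- as.numeric(latent)
      h1 <- nn_relu(drop(flat %*% p$fc1_W) + p$fc1_b)
      h2 <- nn_relu(drop(h1 %*% p$fc2_W) + p$fc2_b)
      probs[i] <- nn_sigmoid(drop(h2 %*% p$fc3_W) + p$fc3_b)
    } else {
      u <- spec$lstm_units
      Tn <- dim(latent)[1]
      seq_x <- matrix(aperm(latent, c(2, 3, 1)), nrow = Tn, byrow = TRUE)
      unpack <- function(W, b) list(
        Xj = t(W[, 1:u]), Xk = t(W[, (u + 1):(2 * u)]),
        Xl = t(W[, (2 * u + 1):(3 * u)]), Xb = t(W[, (3 * u + 1):(4 * u)]),
        aj = b[1:u], ak = b[(u + 1):(2 * u)], al = b[(2 * u + 1):(3 * u)],
        ab = b[(3 * u + 1):(4 * u)])
      bl <- nn_bilstm(seq_x, unpack(p$lstm_fw_W, p$lstm_fw_b),
                      unpack(p$lstm_bw_W, p$lstm_bw_b))
      probs[i] <- nn_sigmoid(drop(bl$average %*% p$out_W) + p$out_b)
    }
    if (spec$has_decoder) {
      d <- latent
      for (s in 1:4) {
        d <- nn_conv2d(d, p[[paste0("dc", s, "_W")]],
                       p[[paste0("dc", s, "_b")]])
        d <- if (s < 4) nn_relu(d) else nn_sigmoid(d)
        d <- nn_upsample(d, spec$upsample_plan[[s]])
      }
      recons[i, , , 1] <- d[seq_len(dim(xb)[2]), seq_len(dim(xb)[3]), 1]
    }
  }
  list(prob = probs, recon = recons)
}

test_that("the training engine matches the composed double primitives", {
  set.seed(43)
  for (v in c("DCAE_MLP", "DCAE_BiLSTM")) {
    model <- assemble(v, 1, seed = 12, n_channels = 5)
    # non-trivial running stats so inference-mode batch norm is exercised
    for (s in 1:4) {
      f <- length(model$params[[paste0("bn", s, "_mean")]])
      model$params[[paste0("bn", s, "_mean")]] <- rnorm(f, sd = 0.1)
      model$params[[paste0("bn", s, "_var")]] <- runif(f, 0.5, 1.5)
    }
    xb <- array(runif(2 * 256 * 5), c(2, 256, 5, 1))
    fast <- model_forward(model, xb)
    ref <- compose_forward(model, xb)
    expect_equal(fast$prob, ref$prob, tolerance = 1e-4)
    expect_equal(fast$recon, ref$recon, tolerance = 1e-4)
  }
})

test_that("latent sequence mapping exposes time steps x features", {
  model <- assemble("DCAE_BiLSTM", 1, seed = 4)
  x <- array(runif(2 * 256 * 23), c(2, 256, 23, 1))
  lat <- model_latent(model, x)
  expect_equal(dim(lat), c(2, 16, 1, 64))
})

test_that("model checkpoints round-trip through save/load", {
  model <- assemble("DCNN_MLP", 1, seed = 5)
  x <- array(runif(2 * 256 * 23), c(2, 256, 23, 1))
  p1 <- model_forward(model, x)$prob
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_model(model, path)
  expect_identical(model_forward(load_model(path), x)$prob, p1)
})
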