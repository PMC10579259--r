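test_that("relu clips negatives and passes positives and zero", {
  expect_identical(nn_relu(c(-3, 0, 2)), c(0, 0, 2))
  x <- matrix(c(-1.5, 2.5, 0, -0.1), 2)
  expect_equal(nn_relu(x), matrix(c(0, 2.5, 0, 0), 2))
})

test_that("sigmoid hits its closed-form values and satisfies symmetry", {
  expect_equal(nn_sigmoid(0), 0.5)
  expect_equal(nn_sigmoid(log(3)), 0.75)
  y <- seq(-8, 8, by = 0.7)
  expect_equal(nn_sigmoid(-y), 1 - nn_sigmoid(y), tolerance = 1e-12)
  expect_equal(nn_sigmoid(c(-1e4, 1e4)), c(0, 1))
  expect_true(all(is.finite(nn_sigmoid(c(-1e4, 1e4)))))
})

test_that("conv2d matches the brute-force sliding-window oracle", {
  set.seed(11)
  cases <- list(
    list(d = c(6, 4, 1), k = c(3, 2), f = 2),
    list(d = c(5, 5, 3), k = c(3, 2), f = 4),
    list(d = c(8, 3, 2), k = c(1, 1), f = 3),
    list(d = c(4, 6, 2), k = c(3, 3), f = 2),
    list(d = c(7, 2, 4), k = c(2, 2), f = 5)
  )
  for (cs in cases) {
    x <- rand_tensor(cs$d)
    w <- rand_tensor(c(cs$k, cs$d[3], cs$f))
    b <- rnorm(cs$f)
    expect_equal(nn_conv2d(x, w, b), oracle_conv2d(x, w, b),
                 tolerance = 1e-10)
  }
})

test_that("conv2d special cases: all-ones kernel, identity, filter count", {
  x <- array(1, c(6, 4, 1))
  w <- array(1, c(3, 2, 1, 1))
  out <- nn_conv2d(x, w)
  expect_equal(out[3, 2, 1], 6)  # interior position covers the full kernel
  # 1x1 identity kernel reproduces the input
  xi <- rand_tensor(c(5, 3, 1))
  wi <- array(1, c(1, 1, 1, 1))
  expect_equal(nn_conv2d(xi, wi), xi)
  # filter count sets the feature-map count
  x2 <- rand_tensor(c(8, 5, 1))
  w32 <- rand_tensor(c(3, 2, 1, 32))
  expect_equal(dim(nn_conv2d(x2, w32)), c(8, 5, 32))
  # batched input keeps the batch axis
  xb <- rand_tensor(c(3, 8, 5, 1))
  expect_equal(dim(nn_conv2d(xb, w32)), c(3, 8, 5, 32))
})

test_that("max pooling uses ceil-mode windows and matches the oracle", {
  # the 23-channel axis survives the architecture's four pooling stages
  widths <- 23
  for (win in list(c(2, 2), c(2, 2), c(2, 2), c(2, 3))) {
    x <- rand_tensor(c(16, widths[length(widths)], 1))
    widths <- c(widths, dim(nn_max_pool(x, win))[2])
  }
  expect_equal(widths, c(23, 12, 6, 3, 1))
  set.seed(21)
  for (i in 1:5) {
    d <- c(sample(3:9, 1), sample(3:9, 1), sample(1:3, 1))
    win <- sample(list(c(2, 2), c(2, 3), c(3, 2)), 1)[[1]]
    x <- rand_tensor(d)
    expect_equal(nn_max_pool(x, win), oracle_max_pool(x, win[1], win[2]))
  }
  # constant input stays constant, and pooling never exceeds the input max
  xc <- array(2.5, c(6, 6, 2))
  expect_true(all(nn_max_pool(xc, c(2, 2)) == 2.5))
  xr <- rand_tensor(c(7, 5, 2))
  expect_lte(max(nn_max_pool(xr, c(2, 3))), max(xr))
})

test_that("upsampling repeats cells and inverts pooling", {
  x <- rand_tensor(c(64, 1, 2))
  expect_equal(dim(nn_upsample(x, c(2, 3))), c(128, 3, 2))
  set.seed(31)
  for (i in 1:4) {
    d <- c(sample(2:6, 1), sample(2:6, 1), sample(1:3, 1))
    f <- sample(list(c(2, 2), c(2, 3)), 1)[[1]]
    x <- rand_tensor(d)
    up <- nn_upsample(x, f)
    expect_equal(up, oracle_upsample(x, f[1], f[2]))
    # max-pooling an upsampled grid with the same factor recovers it
    expect_equal(nn_max_pool(up, f), x)
  }
  xc <- array(1.2, c(3, 3, 1))
  expect_true(all(nn_upsample(xc, c(2, 2)) == 1.2))
})

test_that("batch normalization standardizes then applies the affine pair", {
  set.seed(41)
  xm <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  eps <- 1e-3
  out <- nn_batch_norm(xm, gamma = rep(1, 4), beta = rep(0, 4), eps = eps)
  mu <- colMeans(out$values)
  v <- apply(out$values, 2, function(z) mean((z - mean(z))^2))
  expect_true(all(abs(mu) < 1e-12))
  expect_true(all(abs(v - 1) < 2 * eps))
  # gamma/beta shift a standardized batch to sd 2, mean 3
  xs <- scale(matrix(rnorm(300), 100, 3))[, ]
  out2 <- nn_batch_norm(xs, gamma = rep(2, 3), beta = rep(3, 3), eps = eps)
  expect_equal(unname(colMeans(out2$values)), rep(3, 3), tolerance = 1e-6)
  # constant feature collapses to beta
  xc <- cbind(rep(5, 10), rnorm(10))
  outc <- nn_batch_norm(xc, gamma = c(1, 1), beta = c(7, 0), eps = eps)
  expect_true(all(outc$values[, 1] == 7))
  # matches the oracle on random input
  expect_equal(nn_batch_norm(xm, gamma = c(1, 2, 3, 4),
                             beta = c(0, -1, 2, 0.5), eps = eps)$values,
               oracle_batch_norm(xm, c(1, 2, 3, 4), c(0, -1, 2, 0.5), eps))
  expect_error(nn_batch_norm(matrix(1, 1, 2), c(1, 1), c(0, 0)),
               "at least 2")
  # inference mode uses the supplied running statistics
  outi <- nn_batch_norm(xm, rep(1, 4), rep(0, 4), mode = "infer",
                        running_mean = rep(0, 4), running_var = rep(1, 4),
                        eps = 1e-12)
  expect_equal(outi$values, xm, tolerance = 1e-9)
})

test_that("lstm_step follows the gated recurrence", {
  # zero weights: gates 0.5, candidate 0 => state and output stay at zero
  p0 <- rand_lstm_params(3, 2, scale = 0)
  st <- nn_lstm_step(p0, y = c(1, -1))
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$c, rep(0, 3))
  # saturated forget gate carries the previous cell state through
  ps <- rand_lstm_params(1, 1, scale = 0)
  ps$aj <- 20; ps$ak <- -20
  st2 <- nn_lstm_step(ps, y = 0.7, h_prev = 0, c_prev = 1)
  expect_equal(st2$c, 1, tolerance = 1e-6)
  expect_equal(st2$h, 0.5 * tanh(st2$c), tolerance = 1e-9)
  # random weights over several steps match the independent recurrence
  set.seed(51)
  p <- rand_lstm_params(4, 3)
  y <- matrix(rnorm(9), 3, 3)
  h <- NULL; cs <- NULL
  outs <- matrix(0, 3, 4)
  for (t in 1:3) {
    st <- nn_lstm_step(p, y[t, ], h, cs)
    h <- st$h; cs <- st$c
    outs[t, ] <- h
  }
  expect_equal(outs, oracle_lstm_seq(y, p), tolerance = 1e-12)
  expect_error(nn_lstm_step(p, y = rnorm(7)), "columns")
})

test_that("bilstm concatenates both directions and averages over time", {
  set.seed(61)
  fw <- rand_lstm_params(3, 2)
  bw <- rand_lstm_params(3, 2)
  # zero-weight cells give an all-zero average
  z <- nn_bilstm(matrix(rnorm(8), 4, 2), rand_lstm_params(3, 2, 0),
                 rand_lstm_params(3, 2, 0))
  expect_equal(z$average, rep(0, 6))
  # a single step's average is that step's concatenated output
  y1 <- matrix(rnorm(2), 1, 2)
  one <- nn_bilstm(y1, fw, bw)
  expect_equal(one$average, drop(one$outputs))
  # reversing the sequence swaps the forward and backward halves
  y <- matrix(rnorm(10), 5, 2)
  a <- nn_bilstm(y, fw, bw)
  b <- nn_bilstm(y[5:1, , drop = FALSE], bw, fw)
  expect_equal(a$average[1:3], b$average[4:6], tolerance = 1e-12)
  expect_equal(a$average[4:6], b$average[1:3], tolerance = 1e-12)
  expect_error(nn_bilstm(matrix(0, 0, 2), fw, bw), "empty")
})
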