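# Independent brute-force reference implementations used to check the layer
# primitives and objectives. These deliberately share no code with the
# package: plain loops over the defining formulas.

oracle_conv2d <- function(x, w, b = NULL) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; nf <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  if (is.null(b)) b <- numeric(nf)
  pt <- (kh - 1) %/% 2
  pl <- (kw - 1) %/% 2
  out <- array(0, c(H, W, nf))
  for (f in seq_len(nf)) {
    for (h in seq_len(H)) {
      for (ww in seq_len(W)) {
        acc <- b[f]
        for (dh in seq_len(kh)) {
          for (dw in seq_len(kw)) {
            hs <- h + dh - 1 - pt
            ws <- ww + dw - 1 - pl
            if (hs >= 1 && hs <= H && ws >= 1 && ws <= W)
              for (c in seq_len(cin))
                acc <- acc + x[hs, ws, c] * w[dh, dw, c, f]
          }
        }
        out[h, ww, f] <- acc
      }
    }
  }
  out
}

oracle_max_pool <- function(x, ph, pw) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Ho <- ceiling(H / ph); Wo <- ceiling(W / pw)
  out <- array(0, c(Ho, Wo, C))
  for (c in seq_len(C))
    for (ho in seq_len(Ho))
      for (wo in seq_len(Wo)) {
        hs <- ((ho - 1) * ph + 1):min(H, ho * ph)
        ws <- ((wo - 1) * pw + 1):min(W, wo * pw)
        out[ho, wo, c] <- max(x[hs, ws, c])
      }
  out
}

oracle_upsample <- function(x, fh, fw) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(H * fh, W * fw, C))
  for (c in seq_len(C))
    for (h in seq_len(H * fh))
      for (w in seq_len(W * fw))
        out[h, w, c] <- x[ceiling(h / fh), ceiling(w / fw), c]
  out
}

oracle_batch_norm <- function(xm, gamma, beta, eps = 1e-3) {
  out <- xm
  for (j in seq_len(ncol(xm))) {
    mu <- sum(xm[, j]) / nrow(xm)
    v <- sum((xm[, j] - mu)^2) / nrow(xm)
    out[, j] <- gamma[j] * (xm[, j] - mu) / sqrt(v + eps) + beta[j]
  }
  out
}

# LSTM recurrence over a (T x F) sequence; params as four weight matrices on
# [h, y] plus biases. Returns the T x units hidden-state sequence.
oracle_lstm_seq <- function(seq_x, params) {
  units <- length(params$aj)
  n <- nrow(seq_x)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(units); cs <- numeric(units)
  out <- matrix(0, n, units)
  for (t in seq_len(n)) {
    z <- c(h, seq_x[t, ])
    j <- sig(as.numeric(params$Xj %*% z) + params$aj)
    k <- sig(as.numeric(params$Xk %*% z) + params$ak)
    l <- sig(as.numeric(params$Xl %*% z) + params$al)
    cand <- tanh(as.numeric(params$Xb %*% z) + params$ab)
    cs <- j * cs + k * cand
    h <- l * tanh(cs)
    out[t, ] <- h
  }
  out
}

oracle_bce <- function(p, y, clamp = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pc <- min(max(p[i], clamp), 1 - clamp)
    s <- s + y[i] * log(pc) + (1 - y[i]) * log(1 - pc)
  }
  -s / length(p)
}

oracle_mse <- function(x, xhat) {
  m <- dim(x)[1]
  s <- 0
  for (i in seq_len(m)) {
    xi <- x[i, , ]; ri <- xhat[i, , ]
    s <- s + sum((xi - ri)^2) / length(xi)
  }
  s / m
}

oracle_metrics <- function(pred, truth) {
  a <- sum(pred == 1 & truth == 1)
  b <- sum(pred == 0 & truth == 0)
  d <- sum(pred == 1 & truth == 0)
  m <- sum(pred == 0 & truth == 1)
  acc <- (a + b) / (a + b + d + m) * 100
  se <- if (a + m > 0) a / (a + m) * 100 else 0
  sp <- if (b + d > 0) b / (b + d) * 100 else 0
  pr <- if (a + d > 0) a / (a + d) * 100 else 0
  f1 <- if (pr + se > 0) 2 * (pr / 100) * (se / 100) / (pr / 100 + se / 100) * 100 else 0
  c(accuracy = acc, sensitivity = se, specificity = sp, precision = pr,
    f1 = f1)
}

# Random LSTM cell parameters in the spec's four-matrix form.
rand_lstm_params <- function(units, nf, scale = 0.3) {
  m <- function() matrix(runif(units * (units + nf), -scale, scale), units)
  list(Xj = m(), Xk = m(), Xl = m(), Xb = m(),
       aj = runif(units, -scale, scale), ak = runif(units, -scale, scale),
       al = runif(units, -scale, scale), ab = runif(units, -scale, scale))
}

rand_tensor <- function(dims) array(rnorm(prod(dims)), dims)

rel_err <- function(a, b) {
  den <- pmax(abs(a), abs(b), 1e-8)
  max(abs(a - b) / den)
}
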