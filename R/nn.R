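# Minimal neural window embedders, written in base R with manual
# backpropagation and Adam. Two variants feed the ensemble's top layer:
#   conv:      [conv -> batchnorm -> relu -> maxpool] x2 -> MLP(16, 5, 1)
#   recurrent: bidirectional tanh RNN (hidden 32)     -> MLP(16, 5, 1)
# After training, the final layer is dropped and the 5-unit penultimate
# activations become the learned features.

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr = 2e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# ---- conv pieces (x: B x T x C arrays; time in dim 2) ----------------------

im2col <- function(x, K) {
  B <- dim(x)[1]; T <- dim(x)[2]; C <- dim(x)[3]
  L <- T - K + 1L
  out <- matrix(0, B * L, C * K)
  for (c in seq_len(C)) {
    for (k in seq_len(K)) {
      out[, (c - 1L) * K + k] <- as.vector(x[, k:(k + L - 1L), c])
    }
  }
  out
}

col2im <- function(dcols, B, T, C, K) {
  L <- T - K + 1L
  dx <- array(0, c(B, T, C))
  for (c in seq_len(C)) {
    for (k in seq_len(K)) {
      dx[, k:(k + L - 1L), c] <- dx[, k:(k + L - 1L), c] +
        array(dcols[, (c - 1L) * K + k], c(B, L))
    }
  }
  dx
}

bn_forward <- function(x2, gamma, beta, run_mean, run_var, train, momentum = 0.9) {
  # x2: N x F matrix (batch*length flattened rows)
  eps <- 1e-5
  if (train) {
    mu <- colMeans(x2)
    va <- colMeans(sweep(x2, 2, mu)^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * va
  } else {
    mu <- run_mean; va <- run_var
  }
  xhat <- sweep(sweep(x2, 2, mu), 2, sqrt(va + eps), "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, inv_sd = 1 / sqrt(va + eps),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2, m1) - xhat * matrix(m2, nrow(xhat), ncol(xhat), byrow = TRUE)
  dx <- sweep(dx, 2, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool2 <- function(x) {
  # x: B x L x F with even L; pool width/stride 2 along time
  a <- x[, seq(1, dim(x)[2], by = 2), , drop = FALSE]
  b <- x[, seq(2, dim(x)[2], by = 2), , drop = FALSE]
  take_a <- a >= b
  list(y = ifelse(take_a, a, b), take_a = take_a)
}

maxpool2_backward <- function(dy, take_a, L) {
  B <- dim(dy)[1]; F <- dim(dy)[3]
  dx <- array(0, c(B, L, F))
  dx[, seq(1, L, by = 2), ] <- ifelse(take_a, dy, 0)
  dx[, seq(2, L, by = 2), ] <- ifelse(take_a, 0, dy)
  dx
}

conv_init <- function(C, T, F1 = 16, F2 = 32, K = 5, H = 16, P = 5) {
  L1 <- (T - K + 1L) / 2L
  L2 <- (L1 - K + 1L) / 2L
  flat <- L2 * F2
  list(W1 = he_init(C * K, F1, C * K), b1 = rep(0, F1),
       g1 = rep(1, F1), be1 = rep(0, F1),
       W2 = he_init(F1 * K, F2, F1 * K), b2 = rep(0, F2),
       g2 = rep(1, F2), be2 = rep(0, F2),
       W3 = he_init(flat, H, flat), b3 = rep(0, H),
       W4 = he_init(H, P, H), b4 = rep(0, P),
       W5 = he_init(P, 1, P), b5 = 0)
}

conv_forward <- function(pm, bn, x, K = 5, train = TRUE) {
  B <- dim(x)[1]; T <- dim(x)[2]
  L1 <- T - K + 1L
  c1 <- im2col(x, K)
  z1 <- sweep(c1 %*% pm$W1, 2, pm$b1, "+")
  n1 <- bn_forward(z1, pm$g1, pm$be1, bn$m1, bn$v1, train)
  r1 <- pmax(n1$y, 0)
  a1 <- array(r1, c(B, L1, ncol(r1)))
  p1 <- maxpool2(a1)
  T2 <- L1 / 2L
  L2 <- T2 - K + 1L
  c2 <- im2col(p1$y, K)
  z2 <- sweep(c2 %*% pm$W2, 2, pm$b2, "+")
  n2 <- bn_forward(z2, pm$g2, pm$be2, bn$m2, bn$v2, train)
  r2 <- pmax(n2$y, 0)
  a2 <- array(r2, c(B, L2, ncol(r2)))
  p2 <- maxpool2(a2)
  flat <- matrix(p2$y, B)           # B x (L2/2 * F2)
  h3 <- pmax(sweep(flat %*% pm$W3, 2, pm$b3, "+"), 0)
  h4 <- pmax(sweep(h3 %*% pm$W4, 2, pm$b4, "+"), 0)   # penultimate, dim 5
  logit <- as.numeric(h4 %*% pm$W5 + pm$b5)
  bn_new <- list(m1 = n1$run_mean, v1 = n1$run_var,
                 m2 = n2$run_mean, v2 = n2$run_var)
  list(logit = logit, pen = h4, bn = bn_new,
       cache = list(x = x, c1 = c1, n1 = n1, r1 = r1, p1 = p1,
                    c2 = c2, n2 = n2, r2 = r2, p2 = p2,
                    flat = flat, h3 = h3, h4 = h4,
                    B = B, T = T, L1 = L1, T2 = T2, L2 = L2))
}

conv_backward <- function(pm, cache, dlogit, K = 5) {
  B <- cache$B
  dW5 <- t(cache$h4) %*% matrix(dlogit, ncol = 1)
  db5 <- sum(dlogit)
  dh4 <- matrix(dlogit, ncol = 1) %*% t(pm$W5)
  dh4 <- dh4 * (cache$h4 > 0)
  dW4 <- t(cache$h3) %*% dh4
  db4 <- colSums(dh4)
  dh3 <- dh4 %*% t(pm$W4)
  dh3 <- dh3 * (cache$h3 > 0)
  dW3 <- t(cache$flat) %*% dh3
  db3 <- colSums(dh3)
  dflat <- dh3 %*% t(pm$W3)
  F2 <- length(pm$b2)
  dp2 <- array(dflat, c(B, cache$L2 / 2L, F2))
  da2 <- maxpool2_backward(dp2, cache$p2$take_a, cache$L2)
  dr2 <- matrix(da2, B * cache$L2, F2)
  dr2 <- dr2 * (cache$r2 > 0)
  bb2 <- bn_backward(dr2, cache$n2, pm$g2)
  dz2 <- bb2$dx
  dW2 <- t(cache$c2) %*% dz2
  db2 <- colSums(dz2)
  dc2 <- dz2 %*% t(pm$W2)
  F1 <- length(pm$b1)
  dp1y <- col2im(dc2, B, cache$T2, F1, K)
  da1 <- maxpool2_backward(dp1y, cache$p1$take_a, cache$L1)
  dr1 <- matrix(da1, B * cache$L1, F1)
  dr1 <- dr1 * (cache$r1 > 0)
  bb1 <- bn_backward(dr1, cache$n1, pm$g1)
  dz1 <- bb1$dx
  dW1 <- t(cache$c1) %*% dz1
  db1 <- colSums(dz1)
  list(W1 = dW1, b1 = db1, g1 = bb1$dgamma, be1 = bb1$dbeta,
       W2 = dW2, b2 = db2, g2 = bb2$dgamma, be2 = bb2$dbeta,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4, W5 = dW5, b5 = db5)
}

# ---- bidirectional tanh RNN ------------------------------------------------

rnn_init <- function(C, H = 32, Hd = 16, P = 5) {
  list(Wxf = he_init(C, H, C), Whf = he_init(H, H, H) * 0.5, bf = rep(0, H),
       Wxb = he_init(C, H, C), Whb = he_init(H, H, H) * 0.5, bb = rep(0, H),
       W3 = he_init(2 * H, Hd, 2 * H), b3 = rep(0, Hd),
       W4 = he_init(Hd, P, Hd), b4 = rep(0, P),
       W5 = he_init(P, 1, P), b5 = 0)
}

time_slice <- function(x, t) matrix(x[, t, ], dim(x)[1], dim(x)[3])

rnn_direction <- function(x, Wx, Wh, b, idx) {
  B <- dim(x)[1]; H <- ncol(Wx)
  hs <- array(0, c(B, length(idx) + 1L, H))
  h <- matrix(0, B, H)
  for (j in seq_along(idx)) {
    h <- tanh(sweep(time_slice(x, idx[j]) %*% Wx + h %*% Wh, 2, b, "+"))
    hs[, j + 1L, ] <- h
  }
  hs
}

rnn_direction_backward <- function(x, Wx, Wh, b, idx, hs, dh_last) {
  B <- dim(x)[1]
  dWx <- Wx * 0; dWh <- Wh * 0; db <- b * 0
  dh <- dh_last
  H <- ncol(Wx)
  for (j in rev(seq_along(idx))) {
    h <- matrix(hs[, j + 1L, ], B, H)
    dz <- dh * (1 - h^2)
    dWx <- dWx + t(time_slice(x, idx[j])) %*% dz
    dWh <- dWh + t(matrix(hs[, j, ], B, H)) %*% dz
    db <- db + colSums(dz)
    dh <- dz %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

rnn_forward <- function(pm, x) {
  B <- dim(x)[1]; T <- dim(x)[2]; H <- ncol(pm$Wxf)
  hf <- rnn_direction(x, pm$Wxf, pm$Whf, pm$bf, seq_len(T))
  hb <- rnn_direction(x, pm$Wxb, pm$Whb, pm$bb, rev(seq_len(T)))
  feat <- cbind(matrix(hf[, T + 1L, ], B, H), matrix(hb[, T + 1L, ], B, H))
  h3 <- pmax(sweep(feat %*% pm$W3, 2, pm$b3, "+"), 0)
  h4 <- pmax(sweep(h3 %*% pm$W4, 2, pm$b4, "+"), 0)
  logit <- as.numeric(h4 %*% pm$W5 + pm$b5)
  list(logit = logit, pen = h4,
       cache = list(x = x, hf = hf, hb = hb, feat = feat, h3 = h3, h4 = h4, T = T))
}

rnn_backward <- function(pm, cache, dlogit) {
  T <- cache$T
  H <- ncol(pm$Wxf)
  dW5 <- t(cache$h4) %*% matrix(dlogit, ncol = 1)
  db5 <- sum(dlogit)
  dh4 <- (matrix(dlogit, ncol = 1) %*% t(pm$W5)) * (cache$h4 > 0)
  dW4 <- t(cache$h3) %*% dh4
  db4 <- colSums(dh4)
  dh3 <- (dh4 %*% t(pm$W4)) * (cache$h3 > 0)
  dW3 <- t(cache$feat) %*% dh3
  db3 <- colSums(dh3)
  dfeat <- dh3 %*% t(pm$W3)
  gf <- rnn_direction_backward(cache$x, pm$Wxf, pm$Whf, pm$bf, seq_len(T),
                               cache$hf, dfeat[, seq_len(H), drop = FALSE])
  gb <- rnn_direction_backward(cache$x, pm$Wxb, pm$Whb, pm$bb, rev(seq_len(T)),
                               cache$hb, dfeat[, H + seq_len(H), drop = FALSE])
  list(Wxf = gf$dWx, Whf = gf$dWh, bf = gf$db,
       Wxb = gb$dWx, Whb = gb$dWh, bb = gb$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4, W5 = dW5, b5 = db5)
}

# ---- input assembly and training -------------------------------------------

extractor_channels <- function(sensors) {
  if (sensors == "accel") c("aX", "aY", "aZ", "aVM")
  else c("aX", "aY", "aZ", "aVM", "gX", "gY", "gZ", "gVM")
}

windows_to_array <- function(windows, sensors) {
  B <- nrow(windows)
  T <- nrow(windows$accel[[1]])
  chans <- extractor_channels(sensors)
  x <- array(0, c(B, T, length(chans)))
  for (i in seq_len(B)) {
    a <- windows$accel[[i]]
    x[i, , 1] <- a[, 1]; x[i, , 2] <- a[, 2]; x[i, , 3] <- a[, 3]
    x[i, , 4] <- vm3(a)
    if (sensors == "both") {
      g <- windows$gyro[[i]]
      if (is.null(g)) ns_abort("gyroscope requested but absent from windows",
                               "ns_error_schema")
      x[i, , 5] <- g[, 1]; x[i, , 6] <- g[, 2]; x[i, , 7] <- g[, 3]
      x[i, , 8] <- vm3(g)
    }
  }
  x
}

#' Train a learned window-feature extractor
#'
#' Trains a small binary scratch classifier on labeled 3-s windows -- either a
#' two-block 1-D convolutional network or a bidirectional recurrent network,
#' both ending in a dense head with output dimensions (16, 5, 1) -- by
#' binary cross-entropy, then keeps everything up to the 5-unit penultimate
#' layer as a fixed feature map.
#'
#' @param kind `"conv"` or `"recurrent"`.
#' @param windows A labeled `ns_windows` set (training subjects only).
#' @param sensors `"accel"` (4 input channels: axes + VM) or `"both"` (8).
#' @param epochs Training epochs.
#' @param seed RNG seed (weights and batch shuffling).
#' @param lr,batch Adam learning rate (`NULL` = 2e-3 conv, 8e-3 recurrent)
#'   and minibatch size.
#' @return A `ns_extractor` object with `penultimate_dim = 5`.
#' @export
train_extractor <- function(kind = c("conv", "recurrent"), windows,
                            sensors = c("accel", "both"), epochs = 12,
                            seed = 1L, lr = NULL, batch = 64L) {
  kind <- match.arg(kind)
  lr <- lr %||% if (kind == "conv") 2e-3 else 8e-3
  sensors <- match.arg(sensors)
  if (anyNA(windows$label)) ns_abort("windows must be labeled", "ns_error_label")
  y <- as.numeric(windows$label == "scratch")
  if (length(unique(y)) < 2L) {
    ns_abort("training windows contain a single class", "ns_error_degenerate")
  }
  x <- windows_to_array(windows, sensors)
  mu <- apply(x, 3, mean)
  sdv <- pmax(apply(x, 3, stats::sd), 1e-8)
  for (c in seq_len(dim(x)[3])) x[, , c] <- (x[, , c] - mu[c]) / sdv[c]
  B <- dim(x)[1]; T <- dim(x)[2]; C <- dim(x)[3]
  with_seed(seed, {
    if (kind == "conv") {
      pm <- conv_init(C, T)
      bn <- list(m1 = rep(0, 16), v1 = rep(1, 16),
                 m2 = rep(0, 32), v2 = rep(1, 32))
    } else {
      pm <- rnn_init(C)
      bn <- NULL
    }
    st <- adam_new(pm)
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(B)
      tot <- 0
      for (s in seq(1, B, by = batch)) {
        ids <- ord[s:min(B, s + batch - 1L)]
        if (length(ids) < 2L) next
        xb <- x[ids, , , drop = FALSE]
        yb <- y[ids]
        if (kind == "conv") {
          fw <- conv_forward(pm, bn, xb, train = TRUE)
          bn <- fw$bn
        } else {
          fw <- rnn_forward(pm, xb)
        }
        p <- 1 / (1 + exp(-fw$logit))
        tot <- tot + sum(-(yb * log(pmax(p, 1e-12)) +
                             (1 - yb) * log(pmax(1 - p, 1e-12))))
        dlogit <- (p - yb) / length(ids)
        gr <- if (kind == "conv") conv_backward(pm, fw$cache, dlogit)
              else rnn_backward(pm, fw$cache, dlogit)
        upd <- adam_step(pm, gr, st, lr = lr)
        pm <- upd$params
        st <- upd$state
      }
      losses[ep] <- tot / B
    }
    structure(list(kind = kind, sensors = sensors, params = pm, bn = bn,
                   norm = list(mu = mu, sd = sdv), penultimate_dim = 5L,
                   loss = losses, seed = seed),
              class = "ns_extractor")
  })
}

#' Penultimate-layer embedding of windows
#'
#' @param extractor A trained `ns_extractor`.
#' @param windows A `ns_windows` set.
#' @return B x 5 numeric matrix.
#' @export
extract_embedding <- function(extractor, windows) {
  if (!inherits(extractor, "ns_extractor")) {
    ns_abort("extractor is not trained (expected a ns_extractor)", "ns_error_schema")
  }
  x <- windows_to_array(windows, extractor$sensors)
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- (x[, , c] - extractor$norm$mu[c]) / extractor$norm$sd[c]
  }
  if (extractor$kind == "conv") {
    conv_forward(extractor$params, extractor$bn, x, train = FALSE)$pen
  } else {
    rnn_forward(extractor$params, x)$pen
  }
}

#' Classifier probabilities straight from an extractor (training diagnostics)
#' @keywords internal
extractor_predict <- function(extractor, windows) {
  x <- windows_to_array(windows, extractor$sensors)
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- (x[, , c] - extractor$norm$mu[c]) / extractor$norm$sd[c]
  }
  lg <- if (extractor$kind == "conv") {
    conv_forward(extractor$params, extractor$bn, x, train = FALSE)$logit
  } else rnn_forward(extractor$params, x)$logit
  1 / (1 + exp(-lg))
}

#' Append the ten learned features to a feature matrix
#'
#' Five penultimate activations from the convolutional extractor and five
#' from the recurrent extractor, bringing an accelerometer-only matrix to 348
#' columns and a two-sensor matrix to 686.
#'
#' @param extractors List with elements `conv` and `recurrent`
#'   (`ns_extractor`s).
#' @param features A `ns_features` tibble (interpretable columns).
#' @param windows The matching `ns_windows` set.
#' @return `features` with `dl_conv_1..5`, `dl_rnn_1..5` appended.
#' @export
derive_dl_features <- function(extractors, features, windows) {
  pc <- extract_embedding(extractors$conv, windows)
  pr <- extract_embedding(extractors$recurrent, windows)
  colnames(pc) <- paste0("dl_conv_", 1:5)
  colnames(pr) <- paste0("dl_rnn_", 1:5)
  out <- dplyr::bind_cols(features, tibble::as_tibble(pc), tibble::as_tibble(pr))
  attr(out, "feature_cols") <- c(attr(features, "feature_cols"),
                                 colnames(pc), colnames(pr))
  class(out) <- class(features)
  out
}
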