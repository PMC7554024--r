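# Minimal CNN engine used by the segmentation network.
#
# Activations are numeric arrays [H, W, C, N] (column-major). Convolutions
# are same-padded (zero padding) and computed as one im2col matrix
# multiplication per batch, which hands the heavy lifting to BLAS. All
# backward passes are validated against numerical differentiation in the
# test suite.

.im2col_cache <- new.env(parent = emptyenv())

# index matrix [H*W, k*k] into the zero-padded (H+2p)x(W+2p) plane
im2col_idx <- function(h, w, k) {
  key <- paste(h, w, k, sep = "x")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p
  g_i <- rep(seq_len(h), times = w)
  g_j <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k)
  o <- 0L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      o <- o + 1L
      idx[, o] <- (g_j + dj - 1L) * hp + (g_i + di)
    }
  }
  .im2col_cache[[key]] <- idx
  idx
}

pad_zero <- function(x, p) {
  if (p == 0L) return(x)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h + 2L * p, w + 2L * p)
  out[(p + 1):(p + h), (p + 1):(p + w)] <- x
  out
}

# x: [H, W, C, N]; W_mat: [k*k*C, F]; returns list(out = [H, W, F, N], cache)
conv_forward <- function(x, W_mat, b, k) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  p <- (k - 1L) %/% 2L
  idx <- im2col_idx(h, w, k)
  hw <- h * w
  cols <- matrix(0, n * hw, k * k * cin)
  for (s in seq_len(n)) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    for (c in seq_len(cin)) {
      xp <- pad_zero(x[, , c, s], p)
      cols[rows, ((c - 1L) * k * k + 1L):(c * k * k)] <- xp[idx]
    }
  }
  outmat <- cols %*% W_mat
  outmat <- sweep(outmat, 2L, b, "+")
  f <- ncol(W_mat)
  out <- array(0, c(h, w, f, n))
  for (s in seq_len(n)) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    out[, , , s] <- array(outmat[rows, ], c(h, w, f))
  }
  list(out = out, cache = list(cols = cols, x_dim = d, k = k, W = W_mat))
}

conv_backward <- function(cache, dout) {
  d <- cache$x_dim; h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  k <- cache$k; p <- (k - 1L) %/% 2L
  hw <- h * w; f <- ncol(cache$W)
  doutmat <- matrix(0, n * hw, f)
  for (s in seq_len(n)) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    doutmat[rows, ] <- matrix(dout[, , , s], hw, f)
  }
  dW <- crossprod(cache$cols, doutmat)
  db <- colSums(doutmat)
  dcols <- doutmat %*% t(cache$W)
  idx <- im2col_idx(h, w, k)
  hp <- h + 2L * p; wp <- w + 2L * p
  dx <- array(0, d)
  for (s in seq_len(n)) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    for (c in seq_len(cin)) {
      dxp <- numeric(hp * wp)
      block <- dcols[rows, ((c - 1L) * k * k + 1L):(c * k * k), drop = FALSE]
      for (o in seq_len(k * k)) {
        dxp[idx[, o]] <- dxp[idx[, o]] + block[, o]
      }
      dxp <- matrix(dxp, hp, wp)
      dx[, , c, s] <- dxp[(p + 1):(p + h), (p + 1):(p + w)]
    }
  }
  list(dx = dx, dW = dW, db = db)
}

# batch normalization over (H, W, N) per channel
bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); cn <- d[3]
  xhat <- array(0, d)
  mu <- numeric(cn); iv <- numeric(cn)
  for (c in seq_len(cn)) {
    xc <- x[, , c, , drop = FALSE]
    if (train) {
      m <- mean(xc); v <- mean((xc - m)^2)
      run_mean[c] <- momentum * run_mean[c] + (1 - momentum) * m
      run_var[c] <- momentum * run_var[c] + (1 - momentum) * v
    } else {
      m <- run_mean[c]; v <- run_var[c]
    }
    mu[c] <- m; iv[c] <- 1 / sqrt(v + eps)
    xhat[, , c, ] <- (xc - m) * iv[c]
  }
  out <- xhat
  for (c in seq_len(cn)) out[, , c, ] <- gamma[c] * xhat[, , c, ] + beta[c]
  list(out = out,
       cache = list(xhat = xhat, ivar = iv, gamma = gamma, train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(cache, dout) {
  d <- dim(dout); cn <- d[3]
  m_el <- prod(d[-3]) # elements per channel
  dx <- array(0, d)
  dgamma <- numeric(cn); dbeta <- numeric(cn)
  for (c in seq_len(cn)) {
    dy <- dout[, , c, , drop = FALSE]
    xh <- cache$xhat[, , c, , drop = FALSE]
    dgamma[c] <- sum(dy * xh)
    dbeta[c] <- sum(dy)
    if (cache$train) {
      dx[, , c, ] <- cache$gamma[c] * cache$ivar[c] / m_el *
        (m_el * dy - dbeta[c] - xh * dgamma[c])
    } else {
      dx[, , c, ] <- cache$gamma[c] * cache$ivar[c] * dy
    }
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(cache, dout) dout * cache

# 2x2 max pooling, stride 2
pool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  ro <- seq(1L, h, 2L); re <- seq(2L, h, 2L)
  co <- seq(1L, w, 2L); ce <- seq(2L, w, 2L)
  a <- x[ro, co, , , drop = FALSE]; b <- x[re, co, , , drop = FALSE]
  cc <- x[ro, ce, , , drop = FALSE]; dd <- x[re, ce, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  s1 <- a == m; s2 <- (b == m) & !s1
  s3 <- (cc == m) & !s1 & !s2; s4 <- (dd == m) & !s1 & !s2 & !s3
  list(out = m, cache = list(s = list(s1, s2, s3, s4), in_dim = d))
}

pool_backward <- function(cache, dout) {
  d <- cache$in_dim; h <- d[1]; w <- d[2]
  ro <- seq(1L, h, 2L); re <- seq(2L, h, 2L)
  co <- seq(1L, w, 2L); ce <- seq(2L, w, 2L)
  dx <- array(0, d)
  s <- cache$s
  dx[ro, co, , ] <- dout * s[[1]]
  dx[re, co, , ] <- dx[re, co, , , drop = FALSE] + dout * s[[2]]
  dx[ro, ce, , ] <- dx[ro, ce, , , drop = FALSE] + dout * s[[3]]
  dx[re, ce, , ] <- dx[re, ce, , , drop = FALSE] + dout * s[[4]]
  dx
}

# nearest-neighbor 2x upsampling
upsample_forward <- function(x) {
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
           drop = FALSE]
  list(out = out, cache = d)
}

upsample_backward <- function(cache, dout) {
  h2 <- dim(dout)[1]; w2 <- dim(dout)[2]
  ro <- seq(1L, h2, 2L); re <- seq(2L, h2, 2L)
  co <- seq(1L, w2, 2L); ce <- seq(2L, w2, 2L)
  dout[ro, co, , , drop = FALSE] + dout[re, co, , , drop = FALSE] +
    dout[ro, ce, , , drop = FALSE] + dout[re, ce, , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable weighted binary cross-entropy on logits; returns the
# loss and its gradient wrt the logits
wbce_logits <- function(z, y, wts) {
  loss <- mean(wts * (pmax(z, 0) - z * y + log1p(exp(-abs(z)))))
  dz <- wts * (sigmoid(z) - y) / length(z)
  list(loss = loss, dz = dz)
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
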