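# Minimal reverse-mode neural-network kernels.
#
# Conventions:
#  * sequence tensors are 3-d arrays (batch, time/tokens, channels);
#    dim(x) <- c(B*T, C) is a free reshape because of column-major layout
#  * every layer has <name>_fwd(x, p, ...) -> list(out, cache) and
#    <name>_bwd(g, cache) -> list(dx, grads); grads mirror the param list
#  * parameters are nested named lists of numeric arrays; environments inside
#    a param list (batch-norm running statistics) are ignored by the
#    optimizer and the tree utilities

## ---- tensor helpers ---------------------------------------------------

as_mat <- function(x) {           # (B,T,C) -> (B*T, C)
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_arr <- function(x, B, T_) {    # (B*T, C) -> (B,T,C)
  dim(x) <- c(B, T_, ncol_or_last(x))
  x
}

ncol_or_last <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d[length(d)]
}

## ---- parameter-tree utilities -----------------------------------------

is_param_leaf <- function(x) is.numeric(x)

tree_map <- function(f, p) {
  if (is_param_leaf(p)) return(f(p))
  if (is.list(p)) return(lapply(p, function(q) tree_map(f, q)))
  p  # environments and other state pass through untouched
}

tree_map2 <- function(f, a, b) {
  if (is_param_leaf(a)) {
    if (is.null(b)) stop("parameter tree mismatch: missing counterpart leaf")
    return(f(a, b))
  }
  if (is.list(a)) {
    out <- a
    # match by name when both sides are named, else by position; a silent
    # NULL lookup here would corrupt the optimizer state
    keys <- names(a)
    by_name <- !is.null(keys) && !is.null(names(b))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[keys[i]]] else b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    return(out)
  }
  a
}

tree_zero <- function(p) tree_map(function(x) x * 0, p)

tree_axpy <- function(acc, g) {   # acc + g, treating NULL grads as zero
  if (is.null(g)) return(acc)
  if (is.null(acc)) return(g)
  tree_map2(`+`, acc, g)
}

## ---- initialisers ------------------------------------------------------

init_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

init_conv <- function(K, c_in, c_out) {
  array(stats::rnorm(K * c_in * c_out, sd = sqrt(2 / (K * c_in + c_out))),
        dim = c(K, c_in, c_out))
}

init_linear <- function(n_in, n_out) {
  list(W = init_mat(n_in, n_out), b = numeric(n_out))
}

## ---- dense / activations ----------------------------------------------

linear_fwd <- function(x, p) {
  out <- x %*% p$W
  out <- out + rep(p$b, each = nrow(out))
  list(out = out, cache = list(x = x, p = p))
}

linear_bwd <- function(g, cache) {
  list(dx = g %*% t(cache$p$W),
       grads = list(W = crossprod(cache$x, g), b = colSums(g)))
}

elu_fwd <- function(x) {
  out <- .elu_fwd_cpp(x)$out
  list(out = out, cache = out)
}

elu_bwd <- function(g, cache) {
  .elu_bwd_cpp(g, cache)
}

gelu_fwd <- function(x) {
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  th <- tanh(inner)
  out <- 0.5 * x * (1 + th)
  list(out = out, cache = list(x = x, th = th, c0 = c0))
}

gelu_bwd <- function(g, cache) {
  x <- cache$x; th <- cache$th; c0 <- cache$c0
  sech2 <- 1 - th^2
  d <- 0.5 * (1 + th) + 0.5 * x * sech2 * c0 * (1 + 3 * 0.044715 * x^2)
  g * d
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  keep <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(keep) <- dim(x)
  list(out = x * keep, cache = keep)
}

dropout_bwd <- function(g, cache) {
  if (is.null(cache)) g else g * cache
}

softmax_rows <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)          # mx recycles down columns = per-row shift
  e / rowSums(e)
}

## ---- normalisation -----------------------------------------------------

new_bn_state <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mu <- numeric(C); e$var <- rep(1, C); e$initialized <- FALSE
  e
}

# x: (B,T,C); statistics over batch x time per channel
batchnorm_fwd <- function(x, p, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  x2 <- as_mat(x)
  n <- nrow(x2)
  if (train) {
    mu <- colMeans(x2)
    xc <- x2 - rep(mu, each = n)
    v <- colMeans(xc^2)
    st <- p$state
    if (!st$initialized) {
      st$mu <- mu; st$var <- v; st$initialized <- TRUE
    } else {
      st$mu <- (1 - momentum) * st$mu + momentum * mu
      st$var <- (1 - momentum) * st$var + momentum * v
    }
  } else {
    mu <- p$state$mu; v <- p$state$var
    xc <- x2 - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  sc <- .bn_scale_cpp(x2, mu, inv, p$gamma, p$beta)
  out <- sc$out
  dim(out) <- d
  list(out = out, cache = list(xhat = sc$xhat, inv = inv, d = d, p = p, train = train))
}

batchnorm_bwd <- function(g, cache) {
  d <- cache$d
  g2 <- g; dim(g2) <- c(d[1] * d[2], d[3])
  r <- .bn_bwd_cpp(g2, cache$xhat, cache$p$gamma, cache$inv, cache$train)
  dx2 <- r$dx
  dim(dx2) <- d
  list(dx = dx2, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

init_batchnorm <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C), state = new_bn_state(C))
}

# layer norm over the last axis; x is (N, C)
layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(p$gamma, each = nrow(x)) + rep(p$beta, each = nrow(x))
  list(out = out, cache = list(xhat = xhat, inv = inv, p = p))
}

layernorm_bwd <- function(g, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dgamma <- colSums(g * xhat)
  dbeta <- colSums(g)
  gx <- g * rep(cache$p$gamma, each = nrow(g))
  dx <- (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)) * inv
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

init_layernorm <- function(C) list(gamma = rep(1, C), beta = numeric(C))

## ---- temporal max pooling ----------------------------------------------

# x: (B,T,C); non-overlapping temporal max pooling of width `pool`
# (ragged tail allowed, output length ceil(T / pool))
maxpool_time_fwd <- function(x, pool = 2L) {
  d <- dim(x)
  r <- .maxpool_fwd_cpp(x, d[1], d[2], d[3], as.integer(pool))
  list(out = r$out, cache = list(arg = r$arg, pool = pool, d = d))
}

maxpool_time_bwd <- function(g, cache) {
  d <- cache$d
  .maxpool_bwd_cpp(g, cache$arg, d[1], d[2], d[3], as.integer(cache$pool))
}

# mean over the time axis of (B,T,C) -> (B,C), via one matmul against a
# block-structured averaging matrix (cheaper than apply() at these sizes)
mean_over_time <- function(x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1], d[2] * d[3])
  M <- matrix(0, d[2] * d[3], d[3])
  M[cbind(seq_len(d[2] * d[3]), rep(seq_len(d[3]), each = d[2]))] <- 1 / d[2]
  m %*% M
}

# gradient of mean_over_time: (B,C) -> (B,T,C)
mean_over_time_bwd <- function(g, T_) {
  d <- dim(g)
  out <- g[, rep(seq_len(d[2]), each = T_), drop = FALSE] / T_
  dim(out) <- c(d[1], T_, d[2])
  out
}

## ---- 1-d convolution over time (im2col) --------------------------------

conv_pad_lengths <- function(K, dilation, padding) {
  span <- (K - 1L) * dilation
  switch(padding,
    valid  = c(0L, 0L),
    same   = c(span %/% 2L, span - span %/% 2L),
    causal = c(span, 0L),
    stop("unknown padding: ", padding))
}

conv_out_len <- function(T_, K, stride, dilation, padding) {
  pl <- conv_pad_lengths(K, dilation, padding)
  Tp <- T_ + pl[1] + pl[2]
  span <- (K - 1L) * dilation
  ((Tp - span - 1L) %/% stride) + 1L
}

# Build the im2col matrix (B*T_out, K*C_in) for x (B,T,C_in).
conv_im2col <- function(x, K, stride = 1L, dilation = 1L, padding = "same") {
  d <- dim(x)
  pl <- conv_pad_lengths(K, dilation, padding)
  Tp <- d[2] + pl[1] + pl[2]
  xp <- array(0, dim = c(d[1], Tp, d[3]))
  xp[, pl[1] + seq_len(d[2]), ] <- x
  span <- (K - 1L) * dilation
  T_out <- ((Tp - span - 1L) %/% stride) + 1L
  starts <- (seq_len(T_out) - 1L) * stride + 1L
  tidx <- as.vector(outer(starts, (seq_len(K) - 1L) * dilation, "+"))
  cols <- xp[, tidx, , drop = FALSE]        # (B, T_out*K, C_in)
  dim(cols) <- c(d[1] * T_out, K * d[3])
  list(X2 = cols, T_out = T_out, Tp = Tp, pl = pl, d = d,
       K = K, stride = stride, dilation = dilation)
}

conv1d_fwd <- function(x, p, stride = 1L, dilation = 1L, padding = "same",
                       im2col = NULL) {
  K <- dim(p$W)[1]; c_in <- dim(p$W)[2]; c_out <- dim(p$W)[3]
  ic <- if (is.null(im2col)) conv_im2col(x, K, stride, dilation, padding) else im2col
  Wm <- p$W; dim(Wm) <- c(K * c_in, c_out)
  out <- ic$X2 %*% Wm
  out <- out + rep(p$b, each = nrow(out))
  dim(out) <- c(ic$d[1], ic$T_out, c_out)
  list(out = out, cache = list(ic = ic, p = p))
}

conv1d_bwd <- function(g, cache, need_dx = TRUE) {
  ic <- cache$ic; p <- cache$p
  K <- dim(p$W)[1]; c_in <- dim(p$W)[2]; c_out <- dim(p$W)[3]
  g2 <- g; dim(g2) <- c(ic$d[1] * ic$T_out, c_out)
  dW <- crossprod(ic$X2, g2)
  dim(dW) <- dim(p$W)
  db <- colSums(g2)
  dx <- NULL
  if (need_dx) {
    Wm <- p$W; dim(Wm) <- c(K * c_in, c_out)
    dX2 <- g2 %*% t(Wm)                      # (B*T_out, K*C_in)
    dim(dX2) <- c(ic$d[1], ic$T_out, K, c_in)
    dxp <- array(0, dim = c(ic$d[1], ic$Tp, c_in))
    starts <- (seq_len(ic$T_out) - 1L) * ic$stride + 1L
    for (k in seq_len(K)) {
      tt <- starts + (k - 1L) * ic$dilation
      dk_ <- dX2[, , k, ]
      dim(dk_) <- c(ic$d[1], ic$T_out, c_in)
      dxp[, tt, ] <- dxp[, tt, , drop = FALSE] + dk_
    }
    dx <- dxp[, ic$pl[1] + seq_len(ic$d[2]), , drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

## ---- multi-head scaled-dot-product self-attention ----------------------

init_msa <- function(C, heads, d_k) {
  hd <- heads * d_k
  list(Wq = init_mat(C, hd), bq = numeric(hd),
       Wk = init_mat(C, hd), bk = numeric(hd),
       Wv = init_mat(C, hd), bv = numeric(hd),
       Wo = init_mat(hd, C), bo = numeric(C))
}

# x: (B, n, C). Standard multi-head self-attention over the token axis,
# batched across B (token counts are small, so per-token loops over vectors
# of length B are cheaper than per-batch-element matrix products).
# Returns the per-head attention weights (B, heads, n, n) for inspection.
msa_fwd <- function(x, p, heads, d_k) {
  d <- dim(x); B <- d[1]; n <- d[2]; C <- d[3]
  hd <- heads * d_k
  x2 <- as_mat(x)
  nr <- B * n
  Q2 <- x2 %*% p$Wq + rep(p$bq, each = nr)
  K2 <- x2 %*% p$Wk + rep(p$bk, each = nr)
  V2 <- x2 %*% p$Wv + rep(p$bv, each = nr)
  att <- .attn_fwd_cpp(Q2, K2, V2, B, n, heads, d_k)
  O2 <- att$O2
  A <- att$A
  out2 <- O2 %*% p$Wo + rep(p$bo, each = nr)
  out <- out2; dim(out) <- c(B, n, C)
  list(out = out,
       cache = list(x2 = x2, Q2 = Q2, K2 = K2, V2 = V2, O2 = O2, A = A,
                    B = B, n = n, heads = heads, d_k = d_k, p = p),
       alpha = A)
}

msa_bwd <- function(g, cache) {
  B <- cache$B; n <- cache$n; heads <- cache$heads; d_k <- cache$d_k
  p <- cache$p
  hd <- heads * d_k
  nr <- B * n
  g2 <- g; dim(g2) <- c(nr, ncol(p$Wo))
  dWo <- crossprod(cache$O2, g2)
  dbo <- colSums(g2)
  dO2 <- g2 %*% t(p$Wo)
  r <- .attn_bwd_cpp(dO2, cache$Q2, cache$K2, cache$V2, cache$A, B, n, heads, d_k)
  dQ2 <- r$dQ2; dK2 <- r$dK2; dV2 <- r$dV2
  x2 <- cache$x2
  grads <- list(
    Wq = crossprod(x2, dQ2), bq = colSums(dQ2),
    Wk = crossprod(x2, dK2), bk = colSums(dK2),
    Wv = crossprod(x2, dV2), bv = colSums(dV2),
    Wo = dWo, bo = dbo)
  dx2 <- dQ2 %*% t(p$Wq) + dK2 %*% t(p$Wk) + dV2 %*% t(p$Wv)
  dx <- dx2; dim(dx) <- c(B, n, nrow(p$Wq))
  list(dx = dx, grads = grads)
}

## ---- sinusoidal positional encoding ------------------------------------

positional_encoding <- function(n, d) {
  pos <- seq_len(n) - 1L
  i <- seq_len(d) - 1L
  angle <- outer(pos, 1 / 10000^(2 * (i %/% 2) / d))
  pe <- matrix(0, n, d)
  even <- (i %% 2) == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

## ---- Adam optimizer -----------------------------------------------------

adam_state <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- tree_zero(params)
  e$v <- tree_zero(params)
  e$t <- 0L
  e
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  st$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, st$v, grads)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), st$m, st$v)
  if (weight_decay > 0) {
    params <- tree_map(function(w) w * (1 - lr * weight_decay), params)
  }
  tree_map2(function(w, u) w - lr * u, params, upd)
}

## ---- numeric utilities used by tests and training ----------------------

cross_entropy_fwd <- function(logits, y) {
  # logits: (N, n_classes); y: integer labels 0-based
  prob <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(prob[idx], 1e-12)))
  dlogits <- prob
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n
  list(loss = loss, prob = prob, dlogits = dlogits)
}
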