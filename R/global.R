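#' Stack the nine per-cluster feature vectors
#'
#' @param vectors list of exactly 9 numeric vectors of equal length d, in
#'   canonical cluster order.
#' @return Numeric matrix 9 x d (row l = cluster l).
#' @export
stack_cluster_features <- function(vectors) {
  if (length(vectors) != 9L) {
    stop(sprintf("expected 9 cluster vectors, got %d", length(vectors)))
  }
  lens <- vapply(vectors, length, 1L)
  if (length(unique(lens)) != 1L) stop("cluster vectors have ragged lengths")
  m <- do.call(rbind, vectors)
  rownames(m) <- cluster_order()
  m
}

#' Bidirectional cross-attention configuration
#'
#' @param n_layers stacked BCA layers.
#' @param heads,d_k attention heads and per-head dimension.
#' @param conv_kernel kernel of the depthwise temporal convolution applied
#'   across the window axis inside each layer.
#' @param dilations per-layer dilation of that convolution (recycled).
#' @param ffn_hidden hidden width of the per-layer feed-forward network
#'   (GELU activation).
#' @param dropout dropout rate.
#' @return A `bca_config` list.
#' @export
bca_config <- function(n_layers = 4L, heads = 16L, d_k = 16L,
                       conv_kernel = 13L, dilations = c(1L, 2L, 4L, 8L),
                       ffn_hidden = 128L, dropout = 0.2) {
  if (n_layers < 1) stop("need at least one BCA layer")
  structure(list(n_layers = as.integer(n_layers), heads = as.integer(heads),
                 d_k = as.integer(d_k), conv_kernel = as.integer(conv_kernel),
                 dilations = as.integer(rep_len(dilations, n_layers)),
                 ffn_hidden = as.integer(ffn_hidden), dropout = dropout),
            class = "bca_config")
}

init_bca_layer <- function(d, cfg) {
  p <- list(msa = init_msa(d, cfg$heads, cfg$d_k),
            ln1 = init_layernorm(d),
            conv = list(W = matrix(0, cfg$conv_kernel, 9 * d),
                        b = numeric(9 * d)),
            ln2 = init_layernorm(d),
            ffn1 = init_linear(d, cfg$ffn_hidden),
            ffn2 = init_linear(cfg$ffn_hidden, d),
            ln3 = init_layernorm(d))
  # residual-friendly start: the attention / temporal-conv / FFN branches are
  # zero-initialised at their output projections, so a fresh BCA layer is a
  # near-identity map and stacking it can only refine the cluster features
  p$msa$Wo[] <- 0
  p$ffn2$W[] <- 0
  p
}

init_bca_stack <- function(d, cfg) {
  lapply(seq_len(cfg$n_layers), function(i) init_bca_layer(d, cfg))
}

## depthwise convolution over the window axis --------------------------------
## x: (T, B, C) where T = windows per trial, B = trials; weights (K, C)

depthconv_fwd <- function(x, p, dilation = 1L) {
  d <- dim(x); T_ <- d[1]
  K <- nrow(p$W)
  span <- (K - 1L) * dilation
  pl <- span %/% 2L; prr <- span - pl
  xp <- array(0, dim = c(T_ + span, d[2], d[3]))
  xp[pl + seq_len(T_), , ] <- x
  out <- array(0, dim = d)
  for (k in seq_len(K)) {
    wk <- p$W[k, ]
    seg <- xp[(k - 1L) * dilation + seq_len(T_), , , drop = FALSE]
    out <- out + seg * rep(wk, each = T_ * d[2])
  }
  out <- out + rep(p$b, each = T_ * d[2])
  list(out = out, cache = list(xp = xp, d = d, K = K, dilation = dilation, pl = pl, p = p))
}

depthconv_bwd <- function(g, cache) {
  d <- cache$d; T_ <- d[1]; K <- cache$K; dilation <- cache$dilation
  span <- (K - 1L) * dilation
  dxp <- array(0, dim = dim(cache$xp))
  dW <- matrix(0, K, d[3])
  for (k in seq_len(K)) {
    tt <- (k - 1L) * dilation + seq_len(T_)
    seg <- cache$xp[tt, , , drop = FALSE]
    dW[k, ] <- colSums(matrix(seg * g, T_ * d[2], d[3]))
    dxp[tt, , ] <- dxp[tt, , , drop = FALSE] +
      g * rep(cache$p$W[k, ], each = T_ * d[2])
  }
  db <- colSums(matrix(g, T_ * d[2], d[3]))
  dx <- dxp[cache$pl + seq_len(T_), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

## one model-grade BCA layer --------------------------------------------------
## x: (B_win, 9, d) with window index w = (trial-1)*T + t (t fastest);
## the depthwise temporal convolution runs across the T windows of a trial.

bca_layer_fwd <- function(x, p, cfg, dilation, T_, train = FALSE) {
  d <- dim(x); B <- d[1]; dm <- d[3]
  att <- msa_fwd(x, p$msa, cfg$heads, cfg$d_k)
  r1 <- x + att$out
  r1m <- as_mat(r1)
  ln1 <- layernorm_fwd(r1m, p$ln1)
  h1 <- ln1$out; dim(h1) <- d
  # windows of one trial form the temporal axis for the depthwise conv
  n_trials <- B %/% T_
  hseq <- h1; dim(hseq) <- c(T_, n_trials, 9L * dm)
  cv <- depthconv_fwd(hseq, p$conv, dilation)
  cvout <- cv$out; dim(cvout) <- d
  r2 <- h1 + cvout
  ln2 <- layernorm_fwd(as_mat(r2), p$ln2)
  h2 <- ln2$out
  f1 <- linear_fwd(h2, p$ffn1)
  a1 <- gelu_fwd(f1$out)
  dr <- dropout_fwd(a1$out, cfg$dropout, train)
  f2 <- linear_fwd(dr$out, p$ffn2)
  r3 <- h2 + f2$out
  ln3 <- layernorm_fwd(r3, p$ln3)
  out <- ln3$out; dim(out) <- d
  list(out = out, alpha = att$alpha,
       cache = list(att = att, ln1 = ln1, cv = cv, ln2 = ln2, f1 = f1,
                    a1 = a1, dr = dr, f2 = f2, ln3 = ln3, d = d, T_ = T_))
}

bca_layer_bwd <- function(g, cache) {
  d <- cache$d; B <- d[1]; dm <- d[3]; T_ <- cache$T_
  g3 <- g; dim(g3) <- c(B * 9L, dm)
  dln3 <- layernorm_bwd(g3, cache$ln3$cache)
  dh2 <- dln3$dx
  df2 <- linear_bwd(dh2, cache$f2$cache)
  ddr <- dropout_bwd(df2$dx, cache$dr$cache)
  da1 <- gelu_bwd(ddr, cache$a1$cache)
  df1 <- linear_bwd(da1, cache$f1$cache)
  dh2 <- dh2 + df1$dx
  dln2 <- layernorm_bwd(dh2, cache$ln2$cache)
  dr2 <- dln2$dx; dim(dr2) <- d
  dcvout <- dr2; dim(dcvout) <- c(T_, B %/% T_, 9L * dm)
  dcv <- depthconv_bwd(dcvout, cache$cv$cache)
  dh1 <- dcv$dx; dim(dh1) <- d
  dh1 <- dh1 + dr2
  dh1m <- as_mat(dh1)
  dln1 <- layernorm_bwd(dh1m, cache$ln1$cache)
  dr1 <- dln1$dx; dim(dr1) <- d
  datt <- msa_bwd(dr1, cache$att$cache)
  dx <- dr1 + datt$dx
  list(dx = dx,
       grads = list(msa = datt$grads, ln1 = dln1$grads, conv = dcv$grads,
                    ln2 = dln2$grads, ffn1 = df1$grads, ffn2 = df2$grads,
                    ln3 = dln3$grads))
}

bca_stack_fwd <- function(x, params, cfg, T_, train = FALSE) {
  alphas <- list()
  caches <- list()
  for (i in seq_along(params)) {
    r <- bca_layer_fwd(x, params[[i]], cfg, cfg$dilations[i], T_, train)
    x <- r$out
    alphas[[i]] <- r$alpha
    caches[[i]] <- r$cache
  }
  list(out = x, alphas = alphas, caches = caches)
}

bca_stack_bwd <- function(g, caches) {
  grads <- vector("list", length(caches))
  for (i in rev(seq_along(caches))) {
    r <- bca_layer_bwd(g, caches[[i]])
    g <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = g, grads = grads)
}

## ---- user-facing BCA wrappers -------------------------------------------

#' Single bidirectional cross-attention pass over the cluster matrix
#'
#' The Eq-level attention core: the 9 x d cluster matrix is projected into
#' query/key/value, pairwise similarities are scaled by `1/sqrt(d_k)`,
#' softmax-normalized row-wise, and applied to the values. `alpha[i, j]` is
#' the attention cluster i pays to cluster j; `alpha[j, i]` the reverse
#' direction, so both directions of every pair are produced in one pass.
#'
#' @param F_mat numeric matrix `n_clusters x d` (normally 9 x d).
#' @param params list with `Wq`, `Wk`, `Wv` (each `d x d_k`); optional biases
#'   `bq`, `bk`, `bv`.
#' @return List (attention state): `Q`, `K`, `V`, `S` (scores), `alpha`
#'   (row-stochastic weights) and `O = alpha %*% V`.
#' @export
bca_layer_forward <- function(F_mat, params) {
  if (any(!is.finite(F_mat))) {
    stop("non-finite cluster feature in row ", which(!is.finite(rowSums(F_mat)))[1])
  }
  d_k <- ncol(params$Wq)
  Q <- F_mat %*% params$Wq
  K <- F_mat %*% params$Wk
  V <- F_mat %*% params$Wv
  if (!is.null(params$bq)) Q <- sweep(Q, 2L, params$bq, "+")
  if (!is.null(params$bk)) K <- sweep(K, 2L, params$bk, "+")
  if (!is.null(params$bv)) V <- sweep(V, 2L, params$bv, "+")
  S <- tcrossprod(Q, K) / sqrt(d_k)
  alpha <- softmax_rows(S)
  list(Q = Q, K = K, V = V, S = S, alpha = alpha, O = alpha %*% V)
}

#' Stacked bidirectional cross-attention (full layers)
#'
#' Applies `n_layers` full BCA layers (multi-head attention, depthwise
#' temporal convolution, GELU feed-forward, each with residual connection and
#' LayerNorm) to one cluster matrix, retaining every layer's head-wise
#' attention weights.
#'
#' @param F_mat numeric matrix `9 x d`.
#' @param params list of layer parameter lists from `init_bca_layer`
#'   (length `n_layers`).
#' @param config a [bca_config()].
#' @param n_layers number of layers to apply (defaults to `length(params)`).
#' @return List with `O` (9 x d refined matrix) and `alphas` (list of
#'   `heads x 9 x 9` arrays per layer).
#' @export
bca_stack_forward <- function(F_mat, params, config, n_layers = length(params)) {
  x <- array(F_mat, dim = c(1L, nrow(F_mat), ncol(F_mat)))
  r <- bca_stack_fwd(x, params[seq_len(n_layers)], config, T_ = 1L, train = FALSE)
  O <- r$out[1L, , ]
  alphas <- lapply(r$alphas, function(a) {
    out <- array(a[1L, , , ], dim = dim(a)[2:4])
    out
  })
  list(O = O, alphas = alphas)
}

## ---- temporal convolutional network -------------------------------------

#' TCN configuration
#'
#' @param n_blocks residual blocks.
#' @param kernel_sizes odd kernel lengths, one per block.
#' @param dilations dilation factors, one per block.
#' @param filters convolutional channels per layer.
#' @param dropout dropout rate.
#' @return A `tcn_config` list.
#' @export
tcn_config <- function(n_blocks = 3L, kernel_sizes = c(3L, 5L, 7L),
                       dilations = c(1L, 2L, 4L), filters = 64L, dropout = 0.2) {
  if (length(kernel_sizes) != n_blocks || length(dilations) != n_blocks) {
    stop("kernel_sizes and dilations must have length n_blocks")
  }
  if (any(kernel_sizes %% 2 == 0)) stop("TCN kernels must be odd")
  structure(list(n_blocks = as.integer(n_blocks),
                 kernel_sizes = as.integer(kernel_sizes),
                 dilations = as.integer(dilations),
                 filters = as.integer(filters), dropout = dropout),
            class = "tcn_config")
}

#' Receptive field of a TCN
#'
#' Each block contributes two causal convolutions of kernel `k_b` and
#' dilation `d_b`: `1 + sum_b 2 * (k_b - 1) * d_b` time steps.
#'
#' @param config a [tcn_config()].
#' @return Integer receptive field in time steps.
#' @export
tcn_receptive_field <- function(config) {
  as.integer(1L + sum(2L * (config$kernel_sizes - 1L) * config$dilations))
}

init_tcn <- function(c_in, cfg) {
  blocks <- list()
  for (b in seq_len(cfg$n_blocks)) {
    k <- cfg$kernel_sizes[b]
    blk <- list(conv1 = list(W = init_conv(k, c_in, cfg$filters), b = numeric(cfg$filters)),
                conv2 = list(W = init_conv(k, cfg$filters, cfg$filters), b = numeric(cfg$filters)))
    if (c_in != cfg$filters) blk$proj <- init_linear(c_in, cfg$filters)
    blocks[[b]] <- blk
    c_in <- cfg$filters
  }
  blocks
}

# x: (B, T, C). Causal residual blocks; output length equals input length
# and H_t depends only on inputs at times <= t.
tcn_fwd <- function(x, params, cfg, train = FALSE) {
  caches <- list()
  for (b in seq_along(params)) {
    p <- params[[b]]
    dl <- cfg$dilations[b]
    c1 <- conv1d_fwd(x, p$conv1, dilation = dl, padding = "causal")
    e1 <- elu_fwd(c1$out)
    d1 <- dropout_fwd(e1$out, cfg$dropout, train)
    c2 <- conv1d_fwd(d1$out, p$conv2, dilation = dl, padding = "causal")
    e2 <- elu_fwd(c2$out)
    d2 <- dropout_fwd(e2$out, cfg$dropout, train)
    if (!is.null(p$proj)) {
      x2 <- as_mat(x)
      pj <- linear_fwd(x2, p$proj)
      res <- pj$out; dim(res) <- dim(d2$out)
    } else {
      pj <- NULL
      res <- x
    }
    out <- d2$out + res
    caches[[b]] <- list(c1 = c1, e1 = e1, d1 = d1, c2 = c2, e2 = e2, d2 = d2,
                        pj = pj, din = dim(x))
    x <- out
  }
  list(out = x, caches = caches)
}

tcn_bwd <- function(g, caches) {
  grads <- vector("list", length(caches))
  for (b in rev(seq_along(caches))) {
    ca <- caches[[b]]
    gres <- g
    gd2 <- dropout_bwd(g, ca$d2$cache)
    ge2 <- elu_bwd(gd2, ca$e2$cache)
    gc2 <- conv1d_bwd(ge2, ca$c2$cache)
    gd1 <- dropout_bwd(gc2$dx, ca$d1$cache)
    ge1 <- elu_bwd(gd1, ca$e1$cache)
    gc1 <- conv1d_bwd(ge1, ca$c1$cache)
    gb <- list(conv1 = gc1$grads, conv2 = gc2$grads)
    if (!is.null(ca$pj)) {
      gres2 <- gres; dim(gres2) <- c(dim(g)[1] * dim(g)[2], dim(g)[3])
      gpj <- linear_bwd(gres2, ca$pj$cache)
      gb$proj <- gpj$grads
      dres <- gpj$dx; dim(dres) <- ca$din
    } else {
      dres <- gres
    }
    g <- gc1$dx + dres
    grads[[b]] <- gb
  }
  list(dx = g, grads = grads)
}

#' TCN forward pass over a global window sequence
#'
#' @param seq numeric matrix `T x features` (one trial's window sequence) or
#'   array `batch x T x features`.
#' @param config a [tcn_config()].
#' @param params parameters from `init_tcn` (built for `ncol(seq)` inputs).
#' @return Matrix `T x filters` (or batch array).
#' @export
tcn_forward <- function(seq, config, params) {
  single <- is.matrix(seq)
  x <- if (single) array(seq, dim = c(1L, nrow(seq), ncol(seq))) else seq
  out <- tcn_fwd(x, params, config, train = FALSE)$out
  if (single) {
    m <- matrix(out, dim(out)[2], dim(out)[3])
    m
  } else out
}

#' Temporal average pooling
#'
#' @param H matrix `T x features` or array `batch x T x features`.
#' @return Feature vector (or `batch x features` matrix): the mean over time.
#' @export
temporal_average_pool <- function(H) {
  if (is.matrix(H)) return(colMeans(H))
  mean_over_time(H)
}

## ---- recurrent integrators (ablation variants) ---------------------------

init_lstm_layer <- function(c_in, hidden) {
  list(Wx = init_mat(c_in, 4L * hidden), Wh = init_mat(hidden, 4L * hidden),
       b = numeric(4L * hidden))
}

# x: (B, T, C) -> per-step hidden states hs (B, T, H) plus cache
lstm_fwd <- function(x, p, hidden) {
  d <- dim(x); B <- d[1]; T_ <- d[2]
  h <- matrix(0, B, hidden); cc <- matrix(0, B, hidden)
  hs <- array(0, dim = c(B, T_, hidden))
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, ], B)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2L, p$b, "+")
    i_ <- plogis_mat(z[, seq_len(hidden), drop = FALSE])
    f_ <- plogis_mat(z[, hidden + seq_len(hidden), drop = FALSE])
    g_ <- tanh(z[, 2L * hidden + seq_len(hidden), drop = FALSE])
    o_ <- plogis_mat(z[, 3L * hidden + seq_len(hidden), drop = FALSE])
    c_prev <- cc
    cc <- f_ * c_prev + i_ * g_
    tc <- tanh(cc)
    h_prev <- h
    h <- o_ * tc
    hs[, t, ] <- h
    steps[[t]] <- list(xt = xt, i = i_, f = f_, g = g_, o = o_,
                       c_prev = c_prev, c = cc, tc = tc, h_prev = h_prev)
  }
  list(hs = hs, h_last = h, cache = list(steps = steps, p = p, hidden = hidden, d = d))
}

# ghs: per-step gradients (B, T, H)
lstm_bwd <- function(ghs, cache) {
  p <- cache$p; H <- cache$hidden; d <- cache$d
  B <- d[1]; T_ <- d[2]
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(length(p$b))
  dx <- array(0, dim = d)
  dc <- matrix(0, B, H)
  gh <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    gh <- gh + matrix(ghs[, t, ], B)
    s <- cache$steps[[t]]
    do_ <- gh * s$tc
    dc <- dc + gh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dz <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(p$Wx)
    gh <- dz %*% t(p$Wh)
    dc <- dc * s$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

plogis_mat <- function(x) 1 / (1 + exp(-x))

init_gru_layer <- function(c_in, hidden) {
  list(Wx = init_mat(c_in, 3L * hidden), Wh = init_mat(hidden, 3L * hidden),
       b = numeric(3L * hidden))
}

# GRU step: z,r gates then candidate n = tanh(Wxn x + r * (Whn h)).
# hs holds the hidden state at the absolute time index of each step, so a
# reverse pass still yields hs[, t, ] for time t.
gru_fwd <- function(x, p, hidden, reverse = FALSE) {
  d <- dim(x); B <- d[1]; T_ <- d[2]
  h <- matrix(0, B, hidden)
  order_t <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  hs <- array(0, dim = c(B, T_, hidden))
  steps <- vector("list", T_)
  for (ti in seq_along(order_t)) {
    t <- order_t[ti]
    xt <- matrix(x[, t, ], B)
    zx <- sweep(xt %*% p$Wx, 2L, p$b, "+")
    zh <- h %*% p$Wh
    z_ <- plogis_mat(zx[, seq_len(hidden), drop = FALSE] +
                     zh[, seq_len(hidden), drop = FALSE])
    r_ <- plogis_mat(zx[, hidden + seq_len(hidden), drop = FALSE] +
                     zh[, hidden + seq_len(hidden), drop = FALSE])
    hn <- zh[, 2L * hidden + seq_len(hidden), drop = FALSE]
    n_ <- tanh(zx[, 2L * hidden + seq_len(hidden), drop = FALSE] + r_ * hn)
    h_prev <- h
    h <- (1 - z_) * n_ + z_ * h_prev
    hs[, t, ] <- h
    steps[[ti]] <- list(xt = xt, z = z_, r = r_, n = n_, hn = hn, h_prev = h_prev, t = t)
  }
  list(hs = hs, h_last = h, cache = list(steps = steps, p = p, hidden = hidden, d = d))
}

gru_bwd <- function(ghs, cache) {
  p <- cache$p; H <- cache$hidden; d <- cache$d
  B <- d[1]; T_ <- length(cache$steps)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(length(p$b))
  dx <- array(0, dim = d)
  gh <- matrix(0, B, H)
  for (ti in rev(seq_len(T_))) {
    s <- cache$steps[[ti]]
    gh <- gh + matrix(ghs[, s$t, ], B)
    dz <- gh * (s$h_prev - s$n)
    dn <- gh * (1 - s$z)
    dh_prev <- gh * s$z
    dpre_n <- dn * (1 - s$n^2)
    dr <- dpre_n * s$hn
    dhn <- dpre_n * s$r
    dpre_z <- dz * s$z * (1 - s$z)
    dpre_r <- dr * s$r * (1 - s$r)
    dzx <- cbind(dpre_z, dpre_r, dpre_n)
    dzh <- cbind(dpre_z, dpre_r, dhn)
    dWx <- dWx + crossprod(s$xt, dzx)
    dWh <- dWh + crossprod(s$h_prev, dzh)
    db <- db + colSums(dzx)
    dx[, s$t, ] <- dx[, s$t, ] + dzx %*% t(p$Wx)
    gh <- dh_prev + dzh %*% t(p$Wh)
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- MLP classifier ------------------------------------------------------

init_mlp <- function(c_in, hidden, n_classes) {
  list(fc1 = init_linear(c_in, hidden), fc2 = init_linear(hidden, n_classes))
}

mlp_fwd <- function(h, p, dropout = 0, train = FALSE) {
  f1 <- linear_fwd(h, p$fc1)
  a1 <- elu_fwd(f1$out)
  dr <- dropout_fwd(a1$out, dropout, train)
  f2 <- linear_fwd(dr$out, p$fc2)
  list(logits = f2$out,
       cache = list(f1 = f1, a1 = a1, dr = dr, f2 = f2))
}

mlp_bwd <- function(g, cache) {
  df2 <- linear_bwd(g, cache$f2$cache)
  ddr <- dropout_bwd(df2$dx, cache$dr$cache)
  da1 <- elu_bwd(ddr, cache$a1$cache)
  df1 <- linear_bwd(da1, cache$f1$cache)
  list(dx = df1$dx, grads = list(fc1 = df1$grads, fc2 = df2$grads))
}

#' MLP classification head
#'
#' One hidden layer (ELU) followed by a linear map and softmax; components of
#' the returned vector lie in (0, 1) and sum to one.
#'
#' @param h feature vector or `batch x features` matrix.
#' @param params parameters from `init_mlp`.
#' @param n_classes number of classes (must match the parameter shapes).
#' @return Probability vector (or `batch x n_classes` matrix).
#' @export
mlp_classify <- function(h, params, n_classes) {
  if (n_classes < 2) stop("need at least 2 classes")
  if (ncol(params$fc2$W) != n_classes) {
    stop("params were built for ", ncol(params$fc2$W), " classes")
  }
  single <- is.null(dim(h))
  hm <- if (single) matrix(h, 1L) else h
  logits <- mlp_fwd(hm, params)$logits
  prob <- softmax_rows(logits)
  if (single) drop(prob) else prob
}
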