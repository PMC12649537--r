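#' Temporal kernel size rule
#'
#' The shallow encoder's temporal convolution kernel spans roughly 0.1 s:
#' `k = round(0.1 * fs)`, bumped to the next integer if even so the kernel is
#' always odd (symmetric support).
#'
#' @param fs sampling rate in Hz (>= 30; below that the kernel degenerates).
#' @return Odd positive integer kernel length in samples.
#' @export
temporal_kernel_size <- function(fs) {
  if (fs < 30) stop("fs must be >= 30 Hz for a usable temporal kernel")
  k <- round(0.1 * fs)
  if (k %% 2 == 0) k <- k + 1L
  as.integer(k)
}

#' Configuration of one per-cluster EEG Deformer
#'
#' @param fs sampling rate in Hz.
#' @param n_filters convolutional filters in the shallow feature encoder; the
#'   token feature dimension downstream.
#' @param n_hct_layers number of hierarchical coarse-to-fine transformer
#'   blocks (L).
#' @param n_heads,d_k attention heads and per-head dimension of the in-block
#'   self-attention.
#' @param mlp_hidden hidden width of the coarse-path feed-forward network.
#' @param dropout dropout rate in `[0, 1)` (fine path and FFN).
#' @param temporal_kernel odd temporal kernel length; defaults to
#'   [temporal_kernel_size()] of `fs`.
#' @param sfe_pool temporal max-pool width after the shallow encoder.
#' @param sfe_stride stride of the first temporal convolution.
#' @param fine_kernel kernel of the fine-path 1-d convolution.
#' @param out_dim output dimension d of the fused per-cluster feature vector.
#' @return A `deformer_config` list.
#' @export
deformer_config <- function(fs, n_filters = 64L, n_hct_layers = 3L,
                            n_heads = 16L, d_k = 16L, mlp_hidden = 16L,
                            dropout = 0.2, temporal_kernel = NULL,
                            sfe_pool = 4L, sfe_stride = 1L,
                            fine_kernel = 3L, out_dim = 64L) {
  if (is.null(temporal_kernel)) temporal_kernel <- temporal_kernel_size(fs)
  if (temporal_kernel %% 2 == 0 || temporal_kernel < 3) {
    stop("temporal_kernel must be odd and >= 3")
  }
  if (n_hct_layers < 1) stop("need at least one HCT layer")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(fs = fs, n_filters = as.integer(n_filters),
                 n_hct_layers = as.integer(n_hct_layers),
                 n_heads = as.integer(n_heads), d_k = as.integer(d_k),
                 mlp_hidden = as.integer(mlp_hidden), dropout = dropout,
                 temporal_kernel = as.integer(temporal_kernel),
                 sfe_pool = as.integer(sfe_pool),
                 sfe_stride = as.integer(sfe_stride),
                 fine_kernel = as.integer(fine_kernel),
                 out_dim = as.integer(out_dim)),
            class = "deformer_config")
}

#' Closed-form token counts through the Deformer
#'
#' The shallow encoder maps a window of `window_samples` samples to
#' `ceil(ceil(S / stride) / pool)` tokens; every HCT block halves the count on
#' each path (ceiling for odd counts) and concatenates the two halves, so the
#' count after block i is `2 * ceil(n_i / 2)`.
#'
#' @param config a [deformer_config()].
#' @param window_samples samples per analysis window.
#' @return List with `sfe` (token count after the encoder) and `hct` (vector
#'   of counts after each block).
#' @export
token_counts <- function(config, window_samples) {
  s1 <- conv_out_len(window_samples, config$temporal_kernel,
                     config$sfe_stride, 1L, "same")
  n <- ceiling(s1 / config$sfe_pool)
  hct <- integer(config$n_hct_layers)
  cur <- n
  for (i in seq_len(config$n_hct_layers)) {
    cur <- 2L * ceiling(cur / 2L)
    hct[i] <- cur
  }
  list(sfe = as.integer(n), hct = hct)
}

## ---- parameter construction -------------------------------------------

init_hct_layer <- function(cfg) {
  F_ <- cfg$n_filters
  list(
    proj = init_linear(F_, F_),
    msa = init_msa(F_, cfg$n_heads, cfg$d_k),
    ln = init_layernorm(F_),
    ffn1 = init_linear(F_, cfg$mlp_hidden),
    ffn2 = init_linear(cfg$mlp_hidden, F_),
    fine_conv = list(W = init_conv(cfg$fine_kernel, F_, F_), b = numeric(F_)),
    fine_bn = init_batchnorm(F_))
}

#' Initialize the parameters of one per-cluster Deformer
#'
#' @param config a [deformer_config()].
#' @param n_channels channels in the cluster this Deformer will encode.
#' @param use_hct,use_dip architectural switches used by the ablation
#'   variants: `use_hct = FALSE` routes shallow-encoder tokens straight to the
#'   fused head; `use_dip = FALSE` drops the dense log-power branch.
#' @return Parameter list (nested named lists of numeric arrays).
#' @export
deformer_init <- function(config, n_channels, use_hct = TRUE, use_dip = TRUE) {
  F_ <- config$n_filters
  k <- config$temporal_kernel
  p <- list(
    conv1 = list(W = init_conv(k, 1L, F_), b = numeric(F_)),
    conv2 = list(W = init_mat(n_channels * F_, F_), b = numeric(F_)),
    bn = init_batchnorm(F_))
  if (use_hct) {
    p$hct <- lapply(seq_len(config$n_hct_layers), function(i) init_hct_layer(config))
  }
  head_in <- F_ + if (use_hct && use_dip) config$n_hct_layers * F_ else 0L
  p$head <- init_linear(head_in, config$out_dim)
  # architectural switches ride along as non-numeric leaves so the optimizer
  # and gradient trees pass them through untouched
  p$use_hct <- isTRUE(use_hct)
  p$use_dip <- isTRUE(use_dip)
  p
}

## ---- shallow feature encoder -------------------------------------------

# x: (B, S, C). Temporal Conv (shared across channels) -> channel-mixing
# conv -> BatchNorm -> ELU -> MaxPool -> tokens + sinusoidal position code.
sfe_fwd <- function(x, p, cfg, train = FALSE, ic1 = NULL) {
  d <- dim(x); B <- d[1]; S <- d[2]; C <- d[3]
  if (C * cfg$n_filters != nrow(p$conv2$W)) {
    stop(sprintf("window has %d channels but the Deformer was built for %d",
                 C, nrow(p$conv2$W) / cfg$n_filters))
  }
  # fold channels into the batch axis for the shared temporal convolution;
  # when the im2col matrix is pre-built the rearranged input is not needed
  if (is.null(ic1)) {
    if (C == 1L) {
      xc <- x
    } else {
      xc <- aperm(x, c(1L, 3L, 2L))        # (B, C, S)
      dim(xc) <- c(B * C, S, 1L)
    }
  } else xc <- NULL
  cv1 <- conv1d_fwd(xc, p$conv1, stride = cfg$sfe_stride, padding = "same",
                    im2col = ic1)
  S1 <- dim(cv1$out)[2]
  h <- cv1$out                              # (B*C, S1, F)
  if (C == 1L) {
    dim(h) <- c(B * S1, cfg$n_filters)
  } else {
    dim(h) <- c(B, C, S1, cfg$n_filters)
    h <- aperm(h, c(1L, 3L, 2L, 4L))        # (B, S1, C, F)
    dim(h) <- c(B * S1, C * cfg$n_filters)
  }
  mix <- linear_fwd(h, p$conv2)             # channel-mixing (C x 1) conv
  h2 <- mix$out
  dim(h2) <- c(B, S1, cfg$n_filters)
  bn <- batchnorm_fwd(h2, p$bn, train)
  el <- elu_fwd(bn$out)
  mp <- maxpool_time_fwd(el$out, cfg$sfe_pool)
  n_tok <- dim(mp$out)[2]
  pe <- positional_encoding(n_tok, cfg$n_filters)
  tok <- mp$out + rep(pe, each = B)
  list(out = tok,
       cache = list(cv1 = cv1, mix = mix, bn = bn, el = el, mp = mp,
                    B = B, C = C, S1 = S1, cfg = cfg))
}

sfe_bwd <- function(g, cache, need_dx = FALSE) {
  cfg <- cache$cfg; B <- cache$B; C <- cache$C; S1 <- cache$S1
  dmp <- maxpool_time_bwd(g, cache$mp$cache)
  del <- elu_bwd(dmp, cache$el$cache)
  dbn <- batchnorm_bwd(del, cache$bn$cache)
  dh2 <- dbn$dx
  dim(dh2) <- c(B * S1, cfg$n_filters)
  dmix <- linear_bwd(dh2, cache$mix$cache)
  dh <- dmix$dx
  if (C == 1L) {
    dim(dh) <- c(B, S1, cfg$n_filters)
  } else {
    dim(dh) <- c(B, S1, C, cfg$n_filters)
    dh <- aperm(dh, c(1L, 3L, 2L, 4L))      # (B, C, S1, F)
    dim(dh) <- c(B * C, S1, cfg$n_filters)
  }
  dcv1 <- conv1d_bwd(dh, cache$cv1$cache, need_dx = need_dx)
  dx <- NULL
  if (need_dx) {
    dxc <- dcv1$dx                          # (B*C, S, 1)
    dim(dxc) <- c(B, C, dim(dxc)[2])
    dx <- aperm(dxc, c(1L, 3L, 2L))
  }
  list(dx = dx,
       grads = list(conv1 = dcv1$grads, conv2 = dmix$grads, bn = dbn$grads))
}

## ---- hierarchical coarse-to-fine block ---------------------------------

# Coarse path: MaxPool -> linear -> MSA -> residual(MaxPool) -> LayerNorm
# -> FFN. Fine path: Dropout -> Conv1D -> BatchNorm -> ELU -> MaxPool.
# Output: concat along tokens; the fine embedding is also returned for DIP.
hct_fwd <- function(tok, p, cfg, train = FALSE) {
  d <- dim(tok); B <- d[1]; n <- d[2]; F_ <- d[3]
  if (n < 2) stop("HCT block needs at least 2 tokens")
  # coarse-grained path
  mp <- maxpool_time_fwd(tok, 2L)
  ncg <- dim(mp$out)[2]
  pooled2 <- as_mat(mp$out)
  pr <- linear_fwd(pooled2, p$proj)
  pr3 <- pr$out; dim(pr3) <- c(B, ncg, F_)
  att <- msa_fwd(pr3, p$msa, cfg$n_heads, cfg$d_k)
  res <- att$out + mp$out
  res2 <- res; dim(res2) <- c(B * ncg, F_)
  ln <- layernorm_fwd(res2, p$ln)
  f1 <- linear_fwd(ln$out, p$ffn1)
  a1 <- elu_fwd(f1$out)
  dr1 <- dropout_fwd(a1$out, cfg$dropout, train)
  f2 <- linear_fwd(dr1$out, p$ffn2)
  cg <- f2$out; dim(cg) <- c(B, ncg, F_)
  # fine-grained path
  dr <- dropout_fwd(tok, cfg$dropout, train)
  cv <- conv1d_fwd(dr$out, p$fine_conv, padding = "same")
  bn <- batchnorm_fwd(cv$out, p$fine_bn, train)
  el <- elu_fwd(bn$out)
  fmp <- maxpool_time_fwd(el$out, 2L)
  nfg <- dim(fmp$out)[2]
  out <- array(0, dim = c(B, ncg + nfg, F_))
  out[, seq_len(ncg), ] <- cg
  out[, ncg + seq_len(nfg), ] <- fmp$out
  list(out = out, fine = fmp$out, alpha = att$alpha,
       cache = list(mp = mp, pr = pr, att = att, ln = ln, f1 = f1, a1 = a1,
                    dr1 = dr1, f2 = f2, dr = dr, cv = cv, bn = bn, el = el,
                    fmp = fmp, B = B, ncg = ncg, nfg = nfg, F_ = F_))
}

# g: gradient wrt the concatenated output; g_fine: extra gradient flowing
# into the fine embedding through the DIP tap (may be NULL).
hct_bwd <- function(g, g_fine, cache) {
  B <- cache$B; ncg <- cache$ncg; nfg <- cache$nfg; F_ <- cache$F_
  gcg <- g[, seq_len(ncg), , drop = FALSE]
  gfg <- g[, ncg + seq_len(nfg), , drop = FALSE]
  if (!is.null(g_fine)) gfg <- gfg + g_fine
  # coarse path
  gcg2 <- gcg; dim(gcg2) <- c(B * ncg, F_)
  df2 <- linear_bwd(gcg2, cache$f2$cache)
  ddr1 <- dropout_bwd(df2$dx, cache$dr1$cache)
  da1 <- elu_bwd(ddr1, cache$a1$cache)
  df1 <- linear_bwd(da1, cache$f1$cache)
  dln <- layernorm_bwd(df1$dx, cache$ln$cache)
  dres <- dln$dx; dim(dres) <- c(B, ncg, F_)
  datt <- msa_bwd(dres, cache$att$cache)
  dpr2 <- datt$dx; dim(dpr2) <- c(B * ncg, F_)
  dproj <- linear_bwd(dpr2, cache$pr$cache)
  dpooled <- dproj$dx; dim(dpooled) <- c(B, ncg, F_)
  dpooled <- dpooled + dres                 # residual branch
  dtok_c <- maxpool_time_bwd(dpooled, cache$mp$cache)
  # fine path
  dfmp <- maxpool_time_bwd(gfg, cache$fmp$cache)
  del <- elu_bwd(dfmp, cache$el$cache)
  dbn <- batchnorm_bwd(del, cache$bn$cache)
  dcv <- conv1d_bwd(dbn$dx, cache$cv$cache)
  dtok_f <- dropout_bwd(dcv$dx, cache$dr$cache)
  list(dx = dtok_c + dtok_f,
       grads = list(proj = dproj$grads, msa = datt$grads, ln = dln$grads,
                    ffn1 = df1$grads, ffn2 = df2$grads,
                    fine_conv = dcv$grads, fine_bn = dbn$grads))
}

## ---- dense information purification ------------------------------------

IP_EPS <- 1e-8

# log-power transform: per feature, log of the temporal mean square.
ip_fwd <- function(x) {
  d <- dim(x)
  ms <- mean_over_time(x^2)                  # (B, F)
  out <- log(ms + IP_EPS)
  list(out = out, cache = list(x = x, ms = ms, n = d[2]))
}

ip_bwd <- function(g, cache) {
  scale <- g / (cache$ms + IP_EPS)            # (B, F)
  2 * cache$x * mean_over_time_bwd(scale, cache$n)
}

## ---- full deformer ------------------------------------------------------

# x: (B, S, C) one cluster's windows. Returns (B, out_dim).
deformer_fwd <- function(x, p, cfg, train = FALSE, ic1 = NULL) {
  use_hct <- isTRUE(p$use_hct)
  use_dip <- isTRUE(p$use_dip)
  sfe <- sfe_fwd(x, p, cfg, train, ic1)
  tok <- sfe$out
  hct_caches <- list(); ip_caches <- list(); P_list <- list()
  alphas <- list()
  if (use_hct) {
    for (i in seq_len(cfg$n_hct_layers)) {
      blk <- hct_fwd(tok, p$hct[[i]], cfg, train)
      hct_caches[[i]] <- blk$cache
      alphas[[i]] <- blk$alpha
      if (use_dip) {
        ip <- ip_fwd(blk$fine)
        ip_caches[[i]] <- ip$cache
        P_list[[i]] <- ip$out
      }
      tok <- blk$out
    }
  }
  B <- dim(tok)[1]; n_fin <- dim(tok)[2]
  pooled <- mean_over_time(tok)               # temporal mean of F_concat
  feat <- if (use_hct && use_dip) cbind(pooled, do.call(cbind, P_list)) else pooled
  hd <- linear_fwd(feat, p$head)
  list(out = hd$out,
       cache = list(sfe = sfe$cache, hct = hct_caches, ip = ip_caches,
                    hd = hd$cache, n_fin = n_fin, B = B,
                    use_hct = use_hct, use_dip = use_dip,
                    F_ = cfg$n_filters, L = if (use_hct) cfg$n_hct_layers else 0L),
       alphas = alphas)
}

deformer_bwd <- function(g, cache) {
  F_ <- cache$F_; B <- cache$B; L <- cache$L
  dhd <- linear_bwd(g, cache$hd)
  dfeat <- dhd$dx
  dpooled <- dfeat[, seq_len(F_), drop = FALSE]
  dP <- list()
  if (cache$use_hct && cache$use_dip) {
    for (i in seq_len(L)) {
      dP[[i]] <- dfeat[, F_ * i + seq_len(F_), drop = FALSE]
    }
  }
  # gradient of the temporal mean back onto the final token sequence
  dtok <- mean_over_time_bwd(dpooled, cache$n_fin)
  grads <- list(head = dhd$grads)
  if (cache$use_hct) {
    hct_grads <- vector("list", L)
    for (i in rev(seq_len(L))) {
      g_fine <- if (cache$use_dip) ip_bwd(dP[[i]], cache$ip[[i]]) else NULL
      bk <- hct_bwd(dtok, g_fine, cache$hct[[i]])
      hct_grads[[i]] <- bk$grads
      dtok <- bk$dx
    }
    grads$hct <- hct_grads
  }
  dsfe <- sfe_bwd(dtok, cache$sfe)
  grads$conv1 <- dsfe$grads$conv1
  grads$conv2 <- dsfe$grads$conv2
  grads$bn <- dsfe$grads$bn
  list(dx = NULL, grads = grads)
}

## ---- user-facing wrappers (inference mode) ------------------------------

#' Shallow-feature-encoder forward pass
#'
#' Encodes one batch of cluster windows into a token sequence: two
#' convolutions (temporal then channel-mixing), batch normalization, ELU,
#' temporal max-pooling, token rearrangement and additive sinusoidal
#' positional encoding. Inference mode (no dropout, running-statistics
#' normalization).
#'
#' @param window numeric matrix `channels x samples` or array
#'   `batch x samples x channels`.
#' @param params Deformer parameters from [deformer_init()].
#' @param config a [deformer_config()].
#' @return Token array `batch x n_tokens x n_filters`.
#' @export
sfe_forward <- function(window, params, config) {
  x <- window_to_batch(window)
  sfe_fwd(x, params, config, train = FALSE)$out
}

#' Multi-head self-attention forward pass
#'
#' @param tokens array `batch x n_tokens x feature_dim` (a matrix is treated
#'   as a single-batch token sequence).
#' @param params attention parameters (see `init_msa`).
#' @param heads,d_k head count and per-head dimension.
#' @return List with `out` (same shape as input) and `alpha`
#'   (`batch x heads x n x n` attention weights; rows sum to one).
#' @export
msa_forward <- function(tokens, params, heads, d_k) {
  x <- tokens_to_batch(tokens)
  r <- msa_fwd(x, params, heads, d_k)
  list(out = r$out, alpha = r$alpha)
}

#' Coarse-grained HCT pathway
#'
#' MaxPool (stride 2) -> linear projection -> multi-head self-attention ->
#' residual add of the pooled tokens -> LayerNorm -> feed-forward network.
#'
#' @inheritParams msa_forward
#' @param params one HCT layer's parameters.
#' @param config a [deformer_config()].
#' @return Token array with `ceil(n/2)` tokens.
#' @export
hct_coarse_path <- function(tokens, params, config) {
  x <- tokens_to_batch(tokens)
  if (dim(x)[2] < 2) stop("coarse path needs at least 2 tokens")
  full <- hct_fwd(x, params, config, train = FALSE)
  ncg <- ceiling(dim(x)[2] / 2)
  full$out[, seq_len(ncg), , drop = FALSE]
}

#' Fine-grained HCT pathway
#'
#' Dropout -> 1-d convolution -> BatchNorm -> ELU -> MaxPool (stride 2).
#'
#' @inheritParams hct_coarse_path
#' @return Token array with `ceil(n/2)` tokens.
#' @export
hct_fine_path <- function(tokens, params, config) {
  x <- tokens_to_batch(tokens)
  if (dim(x)[2] < 2) stop("fine path needs at least 2 tokens")
  hct_fwd(x, params, config, train = FALSE)$fine
}

#' One full HCT block
#'
#' Runs both pathways and concatenates them along the token axis; the fine
#' embedding is returned separately for the dense-purification tap.
#'
#' @inheritParams hct_coarse_path
#' @return List with `out` (concatenated tokens) and `fine`.
#' @export
hct_block_forward <- function(tokens, params, config) {
  x <- tokens_to_batch(tokens)
  if (dim(x)[2] < 2) stop("HCT block needs at least 2 tokens")
  r <- hct_fwd(x, params, config, train = FALSE)
  list(out = r$out, fine = r$fine, alpha = r$alpha)
}

#' Log-power information-purification unit
#'
#' Per feature dimension, `log(mean_t(x^2) + eps)` with `eps = 1e-8`; the
#' output is bounded below by `log(eps)` and increases monotonically with the
#' temporal mean-square power.
#'
#' @inheritParams msa_forward
#' @return Matrix `batch x feature_dim` of log powers.
#' @export
ip_unit <- function(tokens) {
  x <- tokens_to_batch(tokens)
  ip_fwd(x)$out
}

#' Dense concatenation of purified block features
#'
#' @param P_list list of `batch x feature_dim` matrices (one per HCT block,
#'   in block order) or plain vectors.
#' @return Matrix `batch x (B * feature_dim)`.
#' @export
dip_aggregate <- function(P_list) {
  if (length(P_list) < 1) stop("need at least one purified block")
  P_list <- lapply(P_list, function(p) if (is.null(dim(p))) matrix(p, 1L) else p)
  lens <- vapply(P_list, ncol, 1L)
  if (length(unique(lens)) != 1) stop("per-block purified lengths differ")
  do.call(cbind, P_list)
}

#' Full per-cluster Deformer forward pass
#'
#' Shallow encoder, L HCT blocks (collecting the fine embeddings), dense
#' log-power purification, and the fused head: the temporal mean of the final
#' concatenated tokens is joined with the dense purified vector and linearly
#' projected to the configured output dimension.
#'
#' @inheritParams sfe_forward
#' @return Matrix `batch x out_dim` of fused cluster features.
#' @export
deformer_forward <- function(window, params, config) {
  x <- window_to_batch(window)
  deformer_fwd(x, params, config, train = FALSE)$out
}

window_to_batch <- function(window) {
  if (is.matrix(window)) {
    # channels x samples -> 1 x samples x channels
    array(t(window), dim = c(1L, ncol(window), nrow(window)))
  } else if (length(dim(window)) == 3L) {
    window
  } else stop("window must be a channels x samples matrix or a 3-d batch array")
}

tokens_to_batch <- function(tokens) {
  if (is.matrix(tokens)) array(tokens, dim = c(1L, nrow(tokens), ncol(tokens)))
  else if (length(dim(tokens)) == 3L) tokens
  else stop("tokens must be a matrix or 3-d array")
}
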