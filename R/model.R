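#' Architecture variants
#'
#' The full model is `"C2G-DF-BCA-TCN"`: nine per-cluster Deformers,
#' bidirectional cross-attention among the cluster features, a dilated TCN
#' over the window sequence, and an MLP head. The remaining names remove or
#' substitute one component: `"C2G-DF-TCN"` drops the BCA, `"C2G-DF-BCA"`
#' drops the TCN (temporal average pooling directly after the BCA),
#' `"C2G-DF-LSTM"` / `"C2G-DF-BGRU"` replace the TCN with two-layer
#' (bidirectional for BGRU) recurrent integrators, `"EEG-DF"` runs a single
#' Deformer over all channels with no clustering, `"DF-woDIP"` removes the
#' dense log-power branch from each Deformer, and `"DF-woHCTDIP"` routes
#' shallow-encoder features straight to the global stage.
#'
#' @return Character vector of known variant names.
#' @export
model_variants <- function() {
  c("C2G-DF-BCA-TCN", "C2G-DF-TCN", "C2G-DF-BCA", "C2G-DF-LSTM",
    "C2G-DF-BGRU", "EEG-DF", "DF-woDIP", "DF-woHCTDIP")
}

variant_flags <- function(name) {
  if (!name %in% model_variants()) {
    stop("unknown variant: ", name, " (known: ",
         paste(model_variants(), collapse = ", "), ")")
  }
  switch(name,
    "C2G-DF-BCA-TCN" = list(clustered = TRUE, bca = TRUE, integrator = "tcn",
                            hct = TRUE, dip = TRUE),
    "C2G-DF-TCN"     = list(clustered = TRUE, bca = FALSE, integrator = "tcn",
                            hct = TRUE, dip = TRUE),
    "C2G-DF-BCA"     = list(clustered = TRUE, bca = TRUE, integrator = "pool",
                            hct = TRUE, dip = TRUE),
    "C2G-DF-LSTM"    = list(clustered = TRUE, bca = FALSE, integrator = "lstm",
                            hct = TRUE, dip = TRUE),
    "C2G-DF-BGRU"    = list(clustered = TRUE, bca = FALSE, integrator = "bgru",
                            hct = TRUE, dip = TRUE),
    "EEG-DF"         = list(clustered = FALSE, bca = FALSE, integrator = "pool",
                            hct = TRUE, dip = TRUE),
    "DF-woDIP"       = list(clustered = TRUE, bca = TRUE, integrator = "tcn",
                            hct = TRUE, dip = FALSE),
    "DF-woHCTDIP"    = list(clustered = TRUE, bca = TRUE, integrator = "tcn",
                            hct = FALSE, dip = FALSE))
}

#' Build a variant constructor
#'
#' Returns a function with the same signature as [c2g_model()] minus
#' `variant`, pre-bound to the named architecture.
#'
#' @param name a variant name from [model_variants()].
#' @return A model-constructor function.
#' @export
build_variant <- function(name) {
  variant_flags(name)  # validates
  function(...) c2g_model(..., variant = name)
}

#' Construct a cluster-to-global emotion-recognition model
#'
#' @param cluster_sizes integer vector of channels per cluster (length 9 for
#'   clustered variants; for `"EEG-DF"` the total channel count is used).
#' @param n_classes number of emotion classes.
#' @param deformer a [deformer_config()].
#' @param bca a [bca_config()] (ignored by variants without BCA).
#' @param tcn a [tcn_config()] (ignored by variants without a TCN).
#' @param mlp_hidden hidden width of the classifier head.
#' @param rnn_hidden hidden width of the recurrent integrators.
#' @param dropout classifier dropout rate.
#' @param share_deformers if `TRUE` the nine clusters share one Deformer
#'   parameter set (requires equal cluster channel counts); default
#'   independent parameters per cluster.
#' @param variant architecture variant, see [model_variants()].
#' @return A `c2g_model` object holding configuration and parameters.
#' @export
c2g_model <- function(cluster_sizes, n_classes,
                      deformer = deformer_config(128),
                      bca = bca_config(),
                      tcn = tcn_config(),
                      mlp_hidden = 128L, rnn_hidden = 64L, dropout = 0.2,
                      share_deformers = FALSE,
                      variant = "C2G-DF-BCA-TCN") {
  fl <- variant_flags(variant)
  cluster_sizes <- unname(as.integer(cluster_sizes))
  d <- deformer$out_dim
  if (fl$clustered) {
    if (length(cluster_sizes) != 9L) stop("clustered variants need 9 cluster sizes")
    if (share_deformers && length(unique(cluster_sizes)) != 1L) {
      stop("shared Deformer weights require equal cluster sizes")
    }
    deformers <- if (share_deformers) {
      list(deformer_init(deformer, cluster_sizes[1], use_hct = fl$hct,
                         use_dip = fl$dip))
    } else {
      lapply(cluster_sizes, function(C)
        deformer_init(deformer, C, use_hct = fl$hct, use_dip = fl$dip))
    }
    feat_win <- 9L * d
  } else {
    total <- sum(cluster_sizes)
    deformers <- list(deformer_init(deformer, total, use_hct = fl$hct,
                                    use_dip = fl$dip))
    feat_win <- d
  }
  params <- list(deformers = deformers)
  if (fl$bca) params$bca <- init_bca_stack(d, bca)
  final_feat <- switch(fl$integrator,
    tcn = { params$tcn <- init_tcn(feat_win, tcn); tcn$filters },
    lstm = {
      params$rnn1 <- init_lstm_layer(feat_win, rnn_hidden)
      params$rnn2 <- init_lstm_layer(rnn_hidden, rnn_hidden)
      rnn_hidden
    },
    bgru = {
      params$rnn1f <- init_gru_layer(feat_win, rnn_hidden)
      params$rnn1b <- init_gru_layer(feat_win, rnn_hidden)
      params$rnn2f <- init_gru_layer(2L * rnn_hidden, rnn_hidden)
      params$rnn2b <- init_gru_layer(2L * rnn_hidden, rnn_hidden)
      2L * rnn_hidden
    },
    pool = feat_win)
  params$mlp <- init_mlp(final_feat, mlp_hidden, n_classes)
  structure(list(variant = variant, flags = fl, params = params,
                 share_deformers = isTRUE(share_deformers),
                 cluster_sizes = as.integer(cluster_sizes),
                 n_classes = as.integer(n_classes),
                 cfg = list(deformer = deformer, bca = bca, tcn = tcn,
                            mlp_hidden = as.integer(mlp_hidden),
                            rnn_hidden = as.integer(rnn_hidden),
                            dropout = dropout)),
            class = "c2g_model")
}

#' @export
print.c2g_model <- function(x, ...) {
  np <- 0
  count <- function(p) tree_map(function(w) np <<- np + length(w), p)
  count(x$params)
  cat(sprintf("<c2g_model> %s: %d classes, d = %d, %s parameters\n",
              x$variant, x$n_classes, x$cfg$deformer$out_dim,
              format(np, big.mark = ",")))
  invisible(x)
}

## ---- batched forward / backward ------------------------------------------
## A batch is list(x = list of per-cluster arrays (B_win, S, C_l), y = labels
## (0-based, one per trial), n_trials, T = windows per trial). Window order is
## trial-major with the window index running fastest: w = (trial-1)*T + t.

model_fwd <- function(model, batch, train = FALSE) {
  fl <- model$flags
  p <- model$params
  cfg <- model$cfg
  d <- cfg$deformer$out_dim
  n_def <- length(p$deformers)
  B_win <- dim(batch$x[[1]])[1]
  defc <- vector("list", n_def)
  alphas <- NULL
  if (fl$clustered) {
    Fstack <- array(0, dim = c(B_win, 9L, d))
    defc <- vector("list", 9L)
    for (l in seq_len(9L)) {
      ic1 <- if (!is.null(batch$ic1)) batch$ic1[[l]] else NULL
      pd <- p$deformers[[min(l, n_def)]]
      r <- deformer_fwd(batch$x[[l]], pd, cfg$deformer, train, ic1)
      Fstack[, l, ] <- r$out
      defc[[l]] <- r$cache
    }
    if (fl$bca) {
      bs <- bca_stack_fwd(Fstack, p$bca, cfg$bca, batch$T, train)
      alphas <- bs$alphas
      win_feat <- bs$out
      dim(win_feat) <- c(B_win, 9L * d)
      bca_cache <- bs$caches
    } else {
      win_feat <- Fstack
      dim(win_feat) <- c(B_win, 9L * d)
      bca_cache <- NULL
    }
  } else {
    ic1 <- if (!is.null(batch$ic1)) batch$ic1[[1]] else NULL
    r <- deformer_fwd(batch$x[[1]], p$deformers[[1]], cfg$deformer, train, ic1)
    win_feat <- r$out
    defc[[1]] <- r$cache
    bca_cache <- NULL
  }
  # (B_win, feat) -> (n_trials, T, feat)
  T_ <- batch$T; n_tr <- batch$n_trials
  feat <- ncol(win_feat)
  seq3 <- win_feat
  dim(seq3) <- c(T_, n_tr, feat)
  seq3 <- aperm(seq3, c(2L, 1L, 3L))
  int_cache <- NULL
  h <- switch(fl$integrator,
    tcn = {
      tc <- tcn_fwd(seq3, p$tcn, cfg$tcn, train)
      int_cache <- tc$caches
      temporal_average_pool(tc$out)
    },
    pool = temporal_average_pool(seq3),
    lstm = {
      l1 <- lstm_fwd(seq3, p$rnn1, cfg$rnn_hidden)
      l2 <- lstm_fwd(l1$hs, p$rnn2, cfg$rnn_hidden)
      int_cache <- list(l1 = l1, l2 = l2)
      l2$h_last
    },
    bgru = {
      g1f <- gru_fwd(seq3, p$rnn1f, cfg$rnn_hidden)
      g1b <- gru_fwd(seq3, p$rnn1b, cfg$rnn_hidden, reverse = TRUE)
      hs1 <- array(0, dim = c(n_tr, T_, 2L * cfg$rnn_hidden))
      hs1[, , seq_len(cfg$rnn_hidden)] <- g1f$hs
      hs1[, , cfg$rnn_hidden + seq_len(cfg$rnn_hidden)] <- g1b$hs
      g2f <- gru_fwd(hs1, p$rnn2f, cfg$rnn_hidden)
      g2b <- gru_fwd(hs1, p$rnn2b, cfg$rnn_hidden, reverse = TRUE)
      int_cache <- list(g1f = g1f, g1b = g1b, g2f = g2f, g2b = g2b)
      cbind(g2f$h_last, g2b$h_last)
    })
  mlp <- mlp_fwd(h, p$mlp, cfg$dropout, train)
  prob <- softmax_rows(mlp$logits)
  list(prob = prob, logits = mlp$logits, alphas = alphas,
       cache = list(defc = defc, bca = bca_cache, int = int_cache,
                    mlp = mlp$cache, T_ = T_, n_tr = n_tr, feat = feat,
                    B_win = B_win, d = d, fl = fl))
}

model_bwd <- function(model, dlogits, cache) {
  fl <- cache$fl
  p <- model$params
  grads <- list()
  gm <- mlp_bwd(dlogits, cache$mlp)
  grads$mlp <- gm$grads
  dh <- gm$dx
  T_ <- cache$T_; n_tr <- cache$n_tr; feat <- cache$feat
  H <- model$cfg$rnn_hidden
  dseq <- switch(fl$integrator,
    tcn = {
      tb <- tcn_bwd(mean_over_time_bwd(dh, T_), cache$int)
      grads$tcn <- tb$grads
      tb$dx
    },
    pool = mean_over_time_bwd(dh, T_),
    lstm = {
      ghs2 <- array(0, dim = c(n_tr, T_, H))
      ghs2[, T_, ] <- dh
      b2 <- lstm_bwd(ghs2, cache$int$l2$cache)
      grads$rnn2 <- b2$grads
      b1 <- lstm_bwd(b2$dx, cache$int$l1$cache)
      grads$rnn1 <- b1$grads
      b1$dx
    },
    bgru = {
      gf <- array(0, dim = c(n_tr, T_, H)); gf[, T_, ] <- dh[, seq_len(H)]
      gb <- array(0, dim = c(n_tr, T_, H)); gb[, 1L, ] <- dh[, H + seq_len(H)]
      b2f <- gru_bwd(gf, cache$int$g2f$cache)
      b2b <- gru_bwd(gb, cache$int$g2b$cache)
      grads$rnn2f <- b2f$grads
      grads$rnn2b <- b2b$grads
      dhs1 <- b2f$dx + b2b$dx
      b1f <- gru_bwd(dhs1[, , seq_len(H), drop = FALSE], cache$int$g1f$cache)
      b1b <- gru_bwd(dhs1[, , H + seq_len(H), drop = FALSE], cache$int$g1b$cache)
      grads$rnn1f <- b1f$grads
      grads$rnn1b <- b1b$grads
      b1f$dx + b1b$dx
    })
  # (n_trials, T, feat) -> (B_win, feat)
  dwin <- aperm(dseq, c(2L, 1L, 3L))
  dim(dwin) <- c(cache$B_win, feat)
  d <- cache$d
  if (fl$clustered) {
    if (fl$bca) {
      dstack3 <- dwin
      dim(dstack3) <- c(cache$B_win, 9L, d)
      bb <- bca_stack_bwd(dstack3, cache$bca)
      grads$bca <- bb$grads
      dF <- bb$dx
    } else {
      dF <- dwin
      dim(dF) <- c(cache$B_win, 9L, d)
    }
    n_def <- length(p$deformers)
    grads$deformers <- vector("list", n_def)
    for (l in seq_len(9L)) {
      gl <- matrix(dF[, l, ], cache$B_win, d)
      g_one <- deformer_bwd(gl, cache$defc[[l]])$grads
      slot <- min(l, n_def)
      grads$deformers[[slot]] <- tree_axpy(grads$deformers[[slot]], g_one)
    }
  } else {
    grads$deformers <- list(deformer_bwd(dwin, cache$defc[[1]])$grads)
  }
  grads
}

## ---- per-trial prediction --------------------------------------------------

#' Full-model forward pass for trials
#'
#' Runs the end-to-end pipeline in inference mode: per window, one Deformer
#' per cluster then (variant permitting) the BCA stack; per trial, the
#' window-ordered sequence through the temporal integrator, pooling and the
#' MLP head.
#'
#' @param model a [c2g_model()].
#' @param trials either one trial (list of 9 per-cluster window arrays
#'   `n_windows x samples x channels`) or a list of such trials with equal
#'   window counts.
#' @return List with `prob` (trials x classes), `pred` (0-based argmax
#'   labels) and `alphas` (per-BCA-layer attention arrays, or NULL).
#' @export
full_model_forward <- function(model, trials) {
  if (!is.null(dim(trials[[1]]))) trials <- list(trials)
  batch <- trials_to_batch(trials, model$flags$clustered)
  r <- model_fwd(model, batch, train = FALSE)
  list(prob = r$prob, pred = max.col(r$prob) - 1L, alphas = r$alphas)
}

# trials: list of per-trial cluster lists; all trials must share T.
trials_to_batch <- function(trials, clustered = TRUE, y = NULL) {
  Ts <- vapply(trials, function(tr) dim(tr[[1]])[1], 1L)
  if (length(unique(Ts)) != 1L) stop("trials in one batch must share the window count")
  T_ <- Ts[1]
  n_cl <- length(trials[[1]])
  x <- vector("list", n_cl)
  for (l in seq_len(n_cl)) {
    arrs <- lapply(trials, function(tr) tr[[l]])
    S <- dim(arrs[[1]])[2]; C <- dim(arrs[[1]])[3]
    out <- array(0, dim = c(T_ * length(trials), S, C))
    for (i in seq_along(arrs)) out[(i - 1L) * T_ + seq_len(T_), , ] <- arrs[[i]]
    x[[l]] <- out
  }
  list(x = x, y = y, n_trials = length(trials), T = T_)
}
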