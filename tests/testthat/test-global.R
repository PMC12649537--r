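ns <- asNamespace("c2geeg")

test_that("stacking cluster features preserves rows and rejects bad input", {
  vs <- lapply(1:9, function(i) { v <- numeric(9); v[i] <- 1; v })
  M <- stack_cluster_features(vs)
  expect_equal(unname(M), diag(9))
  expect_identical(rownames(M), cluster_order())
  set.seed(2)
  vs2 <- lapply(1:9, function(i) rnorm(5))
  M2 <- stack_cluster_features(vs2)
  for (i in 1:9) expect_identical(unname(M2[i, ]), vs2[[i]])
  expect_error(stack_cluster_features(vs2[1:8]), "expected 9")
  expect_error(stack_cluster_features(c(vs2[1:8], list(rnorm(3)))), "ragged")
})

test_that("single-layer cross-attention matches hand-computed and brute-force values", {
  # 2x2 toy: Q = K = I, V = I (via identity weights on identity features)
  Fm <- diag(2)
  p <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2))
  st <- bca_layer_forward(Fm, p)
  expect_equal(st$S, diag(2) / sqrt(2), tolerance = 1e-6)
  s <- 1 / sqrt(2)
  a11 <- exp(s) / (exp(s) + exp(0))
  expect_equal(st$alpha[1, ], c(a11, 1 - a11), tolerance = 1e-4)
  expect_equal(st$alpha[1, 1], 0.6698, tolerance = 1e-4)

  # identical rows -> uniform attention 1/9
  Fu <- matrix(1, 9, 4) * rep(c(1, -2, 0.5, 3), each = 9)
  pu <- list(Wq = matrix(rnorm(12), 4, 3), Wk = matrix(rnorm(12), 4, 3),
             Wv = matrix(rnorm(12), 4, 3))
  su <- bca_layer_forward(Fu, pu)
  expect_lt(max(abs(su$alpha - 1 / 9)), 1e-9)

  # random input vs brute-force double loop
  set.seed(44)
  for (rep in 1:5) {
    Fr <- matrix(rnorm(9 * 6), 9, 6)
    pr <- list(Wq = matrix(rnorm(6 * 4), 6, 4), Wk = matrix(rnorm(6 * 4), 6, 4),
               Wv = matrix(rnorm(6 * 4), 6, 4))
    st <- bca_layer_forward(Fr, pr)
    Q <- Fr %*% pr$Wq; K <- Fr %*% pr$Wk; V <- Fr %*% pr$Wv
    Sref <- matrix(0, 9, 9); Aref <- matrix(0, 9, 9)
    for (i in 1:9) for (j in 1:9) Sref[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(4)
    for (i in 1:9) Aref[i, ] <- exp(Sref[i, ]) / sum(exp(Sref[i, ]))
    expect_lt(max(abs(st$alpha - Aref)), 1e-6)
    expect_lt(max(abs(st$O - Aref %*% V)), 1e-6)
    expect_true(all(st$alpha > 0 & st$alpha < 1))
    Fbad <- Fr; Fbad[2, 1] <- NaN
    expect_error(bca_layer_forward(Fbad, pr), "non-finite")
  }
})

test_that("stacked BCA layers keep every alpha row-normalized and are deterministic", {
  set.seed(45)
  cfg <- tiny_bca_config()
  params <- ns$init_bca_stack(4L, cfg)
  Fm <- matrix(rnorm(9 * 4), 9, 4)
  r <- bca_stack_forward(Fm, params, cfg)
  expect_length(r$alphas, 2L)
  for (a in r$alphas) {
    sums <- apply(a, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
  r2 <- bca_stack_forward(Fm, params, cfg)
  expect_identical(r$O, r2$O)
  # n_layers = 1 applies exactly the first layer
  r1 <- bca_stack_forward(Fm, params, cfg, n_layers = 1)
  expect_length(r1$alphas, 1L)
  expect_identical(r1$alphas[[1]], r$alphas[[1]])
})

test_that("row-normalization holds across many random inputs (property)", {
  set.seed(46)
  cfg <- tiny_bca_config()
  params <- ns$init_bca_stack(4L, cfg)
  for (i in 1:100) {
    Fm <- matrix(rnorm(9 * 4, sd = runif(1, 0.1, 5)), 9, 4)
    r <- bca_stack_forward(Fm, params, cfg, n_layers = 1)
    expect_lt(max(abs(apply(r$alphas[[1]], c(1, 2), sum) - 1)), 1e-6)
  }
})

test_that("TCN is causal, length-preserving, and has the documented receptive field", {
  expect_identical(tcn_receptive_field(tcn_config()), 69L)
  expect_identical(tcn_receptive_field(tiny_tcn_config()), 13L)  # 1 + 2*2*1 + 2*2*2
  set.seed(47)
  cfg <- tiny_tcn_config()
  params <- ns$init_tcn(3L, cfg)
  # causality: impulse at t0 cannot influence outputs before t0
  T_ <- 12L
  base <- matrix(0, T_, 3)
  H0 <- tcn_forward(base, cfg, params)
  for (t0 in c(4L, 9L)) {
    x <- base; x[t0, ] <- 5
    H <- tcn_forward(x, cfg, params)
    expect_identical(nrow(H), T_)
    before <- abs(H[seq_len(t0 - 1L), , drop = FALSE] -
                  H0[seq_len(t0 - 1L), , drop = FALSE])
    expect_lt(max(before), 1e-12)
    expect_gt(max(abs(H[t0, ] - H0[t0, ])), 0)
  }
  # T = 1 degenerate sequence still works
  H1 <- tcn_forward(matrix(rnorm(3), 1, 3), cfg, params)
  expect_identical(dim(H1), c(1L, 4L))
  expect_error(tcn_config(n_blocks = 2, kernel_sizes = c(3, 4), dilations = c(1, 2)),
               "odd")
})

test_that("temporal average pooling is the time mean and permutation-invariant", {
  expect_equal(temporal_average_pool(matrix(7, 5, 3)), rep(7, 3))
  v <- c(2, -4, 6)
  expect_equal(temporal_average_pool(rbind(0 * v, v)), v / 2)
  set.seed(48)
  H <- matrix(rnorm(8 * 3), 8, 3)
  expect_equal(temporal_average_pool(H), temporal_average_pool(H[sample(8), ]))
  Hb <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
  pooled <- temporal_average_pool(Hb)
  expect_equal(pooled[1, ], colMeans(Hb[1, , ]))
})

test_that("MLP head emits a proper probability distribution", {
  set.seed(49)
  p <- ns$init_mlp(5L, 4L, 3L)
  h <- rnorm(5)
  y <- mlp_classify(h, p, 3L)
  expect_equal(sum(y), 1, tolerance = 1e-6)
  expect_true(all(y > 0 & y < 1))
  # zero weights -> uniform
  p0 <- p
  p0$fc1$W[] <- 0; p0$fc1$b[] <- 0; p0$fc2$W[] <- 0; p0$fc2$b[] <- 0
  expect_equal(unname(mlp_classify(h, p0, 3L)), rep(1 / 3, 3))
  # softmax shift invariance
  p_shift <- p; p_shift$fc2$b <- p$fc2$b + 10
  expect_equal(mlp_classify(h, p_shift, 3L), y, tolerance = 1e-9)
  expect_error(mlp_classify(h, p, 4L), "built for 3")
  expect_error(mlp_classify(h, p, 1L), "at least 2")
})

test_that("recurrent integrators backpropagate exact gradients", {
  set.seed(50)
  x <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
  pl <- ns$init_lstm_layer(3L, 2L)
  fl <- ns$lstm_fwd(x, pl, 2L)
  ghs <- array(rnorm(2 * 4 * 2), dim = c(2, 4, 2))
  al <- ns$lstm_bwd(ghs, fl$cache)
  ngl <- numeric_gradient(function(pp) sum(ns$lstm_fwd(x, pp, 2L)$hs * ghs), pl)
  expect_lt(max_tree_diff(al$grads, ngl), 1e-6)

  pg <- ns$init_gru_layer(3L, 2L)
  for (rev in c(FALSE, TRUE)) {
    fg <- ns$gru_fwd(x, pg, 2L, reverse = rev)
    ag <- ns$gru_bwd(ghs, fg$cache)
    ngg <- numeric_gradient(function(pp) sum(ns$gru_fwd(x, pp, 2L, reverse = rev)$hs * ghs), pg)
    expect_lt(max_tree_diff(ag$grads, ngg), 1e-6)
  }
})

test_that("full model forward yields valid probabilities for every variant", {
  set.seed(51)
  trial <- tiny_trial()
  merge_channels <- function(tr) {
    out <- array(0, dim = c(dim(tr[[1]])[1], dim(tr[[1]])[2], length(tr)))
    for (l in seq_along(tr)) out[, , l] <- tr[[l]][, , 1]
    list(all = out)
  }
  for (v in model_variants()) {
    m <- tiny_model(v)
    tr <- if (m$flags$clustered) trial else merge_channels(trial)
    r <- full_model_forward(m, tr)
    expect_equal(sum(r$prob), 1, tolerance = 1e-6)
    expect_true(r$pred %in% 0:2)
    if (m$flags$bca) expect_false(is.null(r$alphas)) else expect_null(r$alphas)
  }
  # single-window trial (T = 1) still passes end to end
  m <- tiny_model()
  r1 <- full_model_forward(m, tiny_trial(T_ = 1L))
  expect_equal(sum(r1$prob), 1, tolerance = 1e-6)
})

test_that("shuffling cluster order together with per-cluster parameters leaves y unchanged", {
  set.seed(52)
  m <- tiny_model("C2G-DF-TCN")    # no BCA: wiring symmetry is exact up to the
                                   # flatten order, which we permute consistently
  trial <- tiny_trial()
  r <- full_model_forward(m, trial)
  perm <- sample(9)
  m2 <- m
  m2$params$deformers <- m$params$deformers[perm]
  # permute the flattened window-feature blocks feeding the TCN: features are
  # laid out cluster-fastest, i.e. index l + 9*(f-1)
  d <- m$cfg$deformer$out_dim
  idx <- as.vector(outer(perm, 9L * (seq_len(d) - 1L), "+"))
  for (b in seq_along(m2$params$tcn)) {
    if (!is.null(m2$params$tcn[[b]]$proj)) {
      m2$params$tcn[[b]]$proj$W <- m2$params$tcn[[b]]$proj$W[idx, ]
    }
    m2$params$tcn[[b]]$conv1$W <- m2$params$tcn[[b]]$conv1$W[, idx, , drop = FALSE]
    break
  }
  r2 <- full_model_forward(m2, trial[perm])
  expect_equal(r2$prob, r$prob, tolerance = 1e-8)
})
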