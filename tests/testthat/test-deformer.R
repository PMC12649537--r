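ns <- asNamespace("c2geeg")

test_that("temporal kernel rule rounds 0.1*fs to the next odd integer", {
  expect_identical(temporal_kernel_size(128), 13L)
  expect_identical(temporal_kernel_size(200), 21L)
  expect_identical(temporal_kernel_size(256), 27L)
  expect_identical(temporal_kernel_size(512), 51L)
  expect_error(temporal_kernel_size(20), ">= 30")
})

test_that("actual token counts match the closed form for random configurations", {
  set.seed(99)
  for (i in 1:50) {
    cfg <- deformer_config(fs = 64, n_filters = sample(2:6, 1),
                           n_hct_layers = sample(1:3, 1), n_heads = 1L,
                           d_k = 2L, mlp_hidden = 3L, dropout = 0,
                           temporal_kernel = sample(c(3L, 5L, 7L), 1),
                           sfe_pool = sample(2:5, 1),
                           sfe_stride = sample(1:3, 1),
                           out_dim = 4L)
    S <- sample(40:120, 1)
    tc <- token_counts(cfg, S)
    p <- deformer_init(cfg, 1L)
    x <- array(rnorm(2 * S), dim = c(2, S, 1))
    tok <- ns$sfe_fwd(x, p, cfg, train = FALSE)$out
    expect_identical(dim(tok)[2], tc$sfe,
                     label = sprintf("sfe count (S=%d k=%d s=%d p=%d)", S,
                                     cfg$temporal_kernel, cfg$sfe_stride, cfg$sfe_pool))
    if (tc$sfe >= 2) {
      cur <- tok
      for (l in seq_len(cfg$n_hct_layers)) {
        blk <- ns$hct_fwd(cur, p$hct[[l]], cfg, train = FALSE)
        expect_identical(dim(blk$out)[2], as.integer(tc$hct[l]))
        cur <- blk$out
      }
    }
  }
})

test_that("HCT concatenation restores the block's input token count (even counts)", {
  cfg <- tiny_deformer_config()
  set.seed(12)
  p <- ns$init_hct_layer(cfg)
  tok <- array(rnorm(2 * 16 * 4), dim = c(2, 16, 4))
  blk <- hct_block_forward(tok, p, cfg)
  expect_identical(dim(blk$out)[2], 16L)             # 8 coarse + 8 fine
  expect_identical(dim(hct_coarse_path(tok, p, cfg))[2], 8L)
  expect_identical(dim(hct_fine_path(tok, p, cfg))[2], 8L)
  # fine tap is bit-identical to the fine slice of the concatenation
  expect_identical(blk$fine, blk$out[, 9:16, , drop = FALSE])
  expect_error(hct_block_forward(array(1, dim = c(1, 1, 4)), p, cfg), "2 tokens")
})

test_that("coarse path residual wiring: zeroed attention leaves FFN(LayerNorm(MaxPool))", {
  cfg <- tiny_deformer_config(fs = 64)
  set.seed(13)
  p <- ns$init_hct_layer(cfg)
  # zero the value/output projections -> the MSA branch contributes exactly 0,
  # so the residual path must carry MaxPool(F) into the LayerNorm
  p$msa$Wv[] <- 0; p$msa$bv[] <- 0; p$msa$Wo[] <- 0; p$msa$bo[] <- 0
  tok <- array(rnorm(2 * 8 * 4), dim = c(2, 8, 4))
  mp <- ns$maxpool_time_fwd(tok, 2L)$out
  ln <- ns$layernorm_fwd(ns$as_mat(mp), p$ln)$out
  ffn <- ns$linear_fwd(ns$elu_fwd(ns$linear_fwd(ln, p$ffn1)$out)$out, p$ffn2)$out
  ref <- ffn; dim(ref) <- dim(mp)
  out <- hct_coarse_path(tok, p, cfg)
  expect_lt(max(abs(out - ref)), 1e-10)
})

test_that("SFE on zero input with zeroed biases yields exactly the positional encoding", {
  cfg <- tiny_deformer_config()
  set.seed(14)
  p <- deformer_init(cfg, 2L)
  p$conv1$b[] <- 0; p$conv2$b[] <- 0
  p$bn$beta[] <- 0
  x <- array(0, dim = c(3, 48, 2))
  tok <- ns$sfe_fwd(x, p, cfg, train = FALSE)$out
  pe <- ns$positional_encoding(dim(tok)[2], cfg$n_filters)
  for (b in 1:3) expect_lt(max(abs(tok[b, , ] - pe)), 1e-12)
})

test_that("the information-purification unit is a floored log mean-square power", {
  # constant 2 across tokens -> log(4 + eps)
  tok <- array(2, dim = c(1, 5, 3))
  expect_equal(as.vector(ip_unit(tok)), rep(log(4 + 1e-8), 3), tolerance = 1e-12)
  # zeros -> log(eps)
  expect_equal(as.vector(ip_unit(array(0, dim = c(1, 4, 2)))),
               rep(log(1e-8), 2))
  # scaling by c shifts the output by 2 log|c| and the map is monotone in power
  set.seed(15)
  x <- array(rnorm(2 * 6 * 4), dim = c(2, 6, 4))
  p1 <- ip_unit(x)
  p3 <- ip_unit(3 * x)
  expect_equal(p3 - p1, matrix(2 * log(3), 2, 4), tolerance = 1e-6)
  expect_true(all(ip_unit(2 * x) > p1))
})

test_that("dense purification concatenates blocks in order", {
  set.seed(16)
  P <- lapply(1:3, function(i) matrix(rnorm(2 * 4), 2, 4))
  d <- dip_aggregate(P)
  expect_identical(dim(d), c(2L, 12L))
  expect_identical(d[, 5:8], P[[2]])
  perm <- dip_aggregate(P[c(2, 1, 3)])
  expect_identical(perm[, 1:4], P[[2]])
  expect_identical(dip_aggregate(P[1]), P[[1]])
  expect_error(dip_aggregate(list(matrix(0, 1, 3), matrix(0, 1, 4))), "differ")
})

test_that("the fused Deformer output is finite, deterministic, and uses the DIP branch", {
  cfg <- tiny_deformer_config()
  set.seed(17)
  p <- deformer_init(cfg, 4L)
  w <- matrix(rnorm(4 * 64), 4, 64)   # channels x samples
  v1 <- deformer_forward(w, p, cfg)
  v2 <- deformer_forward(w, p, cfg)
  expect_identical(v1, v2)
  expect_identical(dim(v1), c(1L, 3L))
  expect_true(all(is.finite(v1)))
  # zeroing the DIP segment of the head changes the output
  p_no <- p
  p_no$head$W[(cfg$n_filters + 1):nrow(p_no$head$W), ] <- 0
  expect_gt(max(abs(deformer_forward(w, p_no, cfg) - v1)), 1e-8)
  # channel mismatch is a shape error
  expect_error(deformer_forward(matrix(0, 2, 64), p, cfg), "built for 4")
})

test_that("the full Deformer backpropagates exact gradients", {
  cfg <- tiny_deformer_config()
  set.seed(18)
  p <- deformer_init(cfg, 2L)
  x <- array(rnorm(3 * 64 * 2), dim = c(3, 64, 2))
  gt <- matrix(rnorm(3 * 3), 3, 3)
  fw <- ns$deformer_fwd(x, p, cfg, train = TRUE)
  an <- ns$deformer_bwd(gt, fw$cache)$grads
  ng <- numeric_gradient(function(pp) {
    pp$use_hct <- TRUE; pp$use_dip <- TRUE
    sum(ns$deformer_fwd(x, pp, cfg, train = TRUE)$out * gt)
  }, p[setdiff(names(p), c("use_hct", "use_dip"))])
  expect_lt(max_tree_diff(an, ng), 1e-6)
})
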