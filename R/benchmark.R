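#' The desk-scale synthetic benchmark
#'
#' A fixed, fully reproducible study used by the test suite, the acceptance
#' script and the vignette: 6 subjects x 16 trials of 20-s, 9-channel
#' (one channel per cluster) synthetic EEG at 128 Hz with strong four-quadrant
#' class contrast, evaluated leave-one-subject-out with a reduced-width model
#' (d = 16, 2 HCT layers, 4 attention heads, 1 BCA layer, 2 TCN blocks,
#' 15 training epochs).
#'
#' `benchmark_spec()` returns the generator specification;
#' `benchmark_configs()` the reduced model and training configurations;
#' `run_benchmark()` generates the data, trains one variant under LOSO and
#' returns the experiment report.
#'
#' @param seed master seed for generation and training.
#' @return `benchmark_spec()`: a [synthetic_spec()]; `benchmark_configs()`:
#'   named list of sub-configurations.
#' @export
benchmark_spec <- function(seed = 42L) {
  synthetic_spec(n_subjects = 6L, trials_per_subject = 16L, fs = 128,
                 trial_seconds = 20, montage_name = "toy-9ch",
                 class_scheme = "quadrant", seed = as.integer(seed))
}

#' @rdname benchmark_spec
#' @export
benchmark_configs <- function() {
  list(
    deformer = deformer_config(fs = 128, n_filters = 12L, n_hct_layers = 2L,
                               n_heads = 4L, d_k = 3L, mlp_hidden = 12L,
                               dropout = 0, sfe_pool = 8L, sfe_stride = 4L,
                               fine_kernel = 3L, out_dim = 16L),
    bca = bca_config(n_layers = 1L, heads = 4L, d_k = 4L, conv_kernel = 3L,
                     dilations = 1L, ffn_hidden = 32L, dropout = 0),
    tcn = tcn_config(n_blocks = 2L, kernel_sizes = c(3L, 3L),
                     dilations = c(1L, 2L), filters = 32L, dropout = 0),
    train = train_config(learning_rate = 0.02, weight_decay = 1e-3,
                         batch_size = 16L, epochs = 15L,
                         lr_schedule = "cosine"),
    mlp_hidden = 32L, rnn_hidden = 16L, dropout = 0.2)
}

#' @param variant architecture variant, see [model_variants()].
#' @param dataset optionally a pre-generated [generate_dataset()] result for
#'   the same seed (avoids regenerating when several variants share data).
#' @rdname benchmark_spec
#' @export
run_benchmark <- function(variant = "C2G-DF-BCA-TCN", seed = 42L,
                          dataset = NULL) {
  if (is.null(dataset)) dataset <- generate_dataset(benchmark_spec(seed))
  cfg <- benchmark_configs()
  run_experiment(dataset, protocol = "loso", variant = variant,
                 map = default_cluster_map("toy-9ch"), scheme = "quadrant",
                 deformer = cfg$deformer, bca = cfg$bca, tcn = cfg$tcn,
                 train = cfg$train, mlp_hidden = cfg$mlp_hidden,
                 rnn_hidden = cfg$rnn_hidden, dropout = cfg$dropout,
                 seed = as.integer(seed))
}
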