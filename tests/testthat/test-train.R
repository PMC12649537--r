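test_that("LOSO folds cover each subject exactly once with disjoint train sets", {
  ids <- paste0("s", 1:5)
  folds <- loso_folds(rep(ids, each = 3))
  expect_length(folds, 5L)
  expect_setequal(vapply(folds, `[[`, "", "test"), ids)
  for (f in folds) {
    expect_length(f$train, 4L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  expect_error(loso_folds("s1"), "2 distinct")
})

test_that("within-subject folds are stratified, trial-grouped and seed-stable", {
  labels <- rep(0:3, each = 10)          # 40 trials, 4 classes
  f1 <- within_subject_folds(labels, k = 5, seed = 3)
  f2 <- within_subject_folds(labels, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_length(f1, 5L)
  expect_setequal(unlist(f1), seq_along(labels))
  for (f in f1) {
    expect_length(f, 8L)
    expect_equal(unname(table(labels[f])), rep(2L, 4), ignore_attr = TRUE)
  }
  f3 <- within_subject_folds(labels, k = 5, seed = 4)
  expect_false(identical(f1, f3))
  expect_error(within_subject_folds(0:1, k = 5), "folds")
})

test_that("training reduces the loss on a separable toy problem and is seed-deterministic", {
  set.seed(60)
  # two classes with clearly different oscillation frequency structure
  make_trial <- function(cls) {
    lapply(1:9, function(l) {
      tt <- seq_len(64) / 64
      f0 <- if (cls == 0) 6 else 20
      x <- vapply(1:2, function(t.)
        sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi)) + 0.3 * rnorm(64), numeric(64))
      array(t(x), dim = c(2, 64, 1))
    })
  }
  trials <- c(lapply(1:10, function(i) make_trial(0)),
              lapply(1:10, function(i) make_trial(1)))
  labels <- rep(0:1, each = 10)
  m <- tiny_model(n_classes = 2L)
  cfg <- train_config(learning_rate = 0.01, epochs = 8, batch_size = 8, seed = 5)
  fit1 <- train_model(m, trials, labels, cfg)
  expect_lt(fit1$loss_curve[8], fit1$loss_curve[1])
  # identical seeds give identical loss curves and parameters
  m2 <- tiny_model(n_classes = 2L)   # note: same init requires same RNG state
  set.seed(61)
  ma <- tiny_model(n_classes = 2L)
  set.seed(61)
  mb <- tiny_model(n_classes = 2L)
  fa <- train_model(ma, trials, labels, cfg)
  fb <- train_model(mb, trials, labels, cfg)
  expect_identical(fa$loss_curve, fb$loss_curve)
  expect_identical(fa$model$params$mlp, fb$model$params$mlp)
  # protocol errors
  expect_error(train_model(m, list(), integer(0), cfg), "empty")
  expect_error(train_model(m, trials[1:5], rep(0L, 5), cfg), "2 classes")
})

test_that("run_experiment reports per-fold results that reproduce the summary", {
  spec <- synthetic_spec(n_subjects = 3, trials_per_subject = 4, trial_seconds = 8,
                         class_scheme = "valence2",
                         signatures = default_signatures("valence2"), seed = 71)
  ds <- generate_dataset(spec)
  cfg <- benchmark_configs()
  small_train <- train_config(learning_rate = 0.02, epochs = 2, batch_size = 8)
  rep1 <- run_experiment(ds, "loso", "DF-woHCTDIP", default_cluster_map("toy-9ch"),
                         scheme = "valence2", deformer = cfg$deformer,
                         bca = cfg$bca, tcn = cfg$tcn, train = small_train,
                         mlp_hidden = 8L, seed = 5)
  expect_s3_class(rep1, "c2g_report")
  expect_length(rep1$folds, 3L)
  expect_equal(rep1$mean_accuracy, mean(rep1$fold_accuracies))
  expect_equal(rep1$sd_accuracy, sd(rep1$fold_accuracies))
  expect_equal(sum(rep1$confusion), length(ds$recordings))
  # same seed -> identical report; different protocol also runs
  rep2 <- run_experiment(ds, "loso", "DF-woHCTDIP", default_cluster_map("toy-9ch"),
                         scheme = "valence2", deformer = cfg$deformer,
                         bca = cfg$bca, tcn = cfg$tcn, train = small_train,
                         mlp_hidden = 8L, seed = 5)
  expect_identical(rep1$fold_accuracies, rep2$fold_accuracies)
  # serialization writes json + csv
  stem <- file.path(tempdir(), "rep")
  write_report(rep1, stem)
  expect_true(file.exists(paste0(stem, ".json")))
  fold_df <- read.csv(paste0(stem, "_folds.csv"))
  expect_equal(fold_df$accuracy, rep1$fold_accuracies)
})

test_that("within-subject protocol never leaks a trial across the split", {
  spec <- synthetic_spec(n_subjects = 2, trials_per_subject = 8, trial_seconds = 8,
                         class_scheme = "valence2",
                         signatures = default_signatures("valence2"), seed = 81)
  ds <- generate_dataset(spec)
  cfg <- benchmark_configs()
  rep_ <- run_experiment(ds, "within", "DF-woHCTDIP", default_cluster_map("toy-9ch"),
                         scheme = "valence2", deformer = cfg$deformer,
                         bca = cfg$bca, tcn = cfg$tcn,
                         train = train_config(learning_rate = 0.02, epochs = 1,
                                              batch_size = 8),
                         mlp_hidden = 8L, seed = 5, k = 2L)
  expect_length(rep_$folds, 4L)          # 2 subjects x 2 folds
  expect_equal(sum(vapply(rep_$folds, `[[`, 1L, "n_test")), 16L)
})

test_that("shared Deformer weights train with pooled gradients", {
  set.seed(65)
  m <- c2g_model(rep(1L, 9), 2L, tiny_deformer_config(), tiny_bca_config(),
                 tiny_tcn_config(), mlp_hidden = 4L, dropout = 0,
                 share_deformers = TRUE)
  expect_length(m$params$deformers, 1L)
  trials <- lapply(1:6, function(i) tiny_trial())
  labels <- rep(0:1, 3)
  fit <- train_model(m, trials, labels, train_config(epochs = 2, batch_size = 3))
  expect_true(all(is.finite(fit$loss_curve)))
  r <- full_model_forward(fit$model, trials[[1]])
  expect_equal(sum(r$prob), 1, tolerance = 1e-6)
  expect_error(c2g_model(c(2L, rep(1L, 8)), 2L, tiny_deformer_config(),
                         tiny_bca_config(), tiny_tcn_config(),
                         share_deformers = TRUE),
               "equal cluster sizes")
})

test_that("build_variant returns constructors and rejects unknown names", {
  ctor <- build_variant("EEG-DF")
  m <- ctor(rep(1L, 9), 3L, tiny_deformer_config(), tiny_bca_config(),
            tiny_tcn_config())
  expect_identical(m$variant, "EEG-DF")
  expect_length(m$params$deformers, 1L)
  expect_error(build_variant("DF-nonsense"), "unknown variant")
  # DF-woDIP head excludes the dense segment
  m2 <- tiny_model("DF-woDIP")
  expect_identical(nrow(m2$params$deformers[[1]]$head$W),
                   tiny_deformer_config()$n_filters)
  # C2G-DF-TCN exports no attention matrices
  r <- full_model_forward(tiny_model("C2G-DF-TCN"), tiny_trial())
  expect_null(r$alphas)
})
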