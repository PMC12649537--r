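#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay decoupled weight decay.
#' @param batch_size trials per optimization step.
#' @param epochs training epochs (no early stopping unless `val_fraction > 0`
#'   is combined with `patience`).
#' @param seed optional RNG seed; when non-NULL, [train_model()] seeds the
#'   generator itself (standalone runs). [run_experiment()] manages per-fold
#'   seeds and ignores this field.
#' @param max_grad_norm global L2 gradient-norm clip (Inf disables); guards
#'   the small-batch Adam updates against occasional divergence.
#' @param lr_schedule `"constant"` or `"cosine"` (half-cosine decay of the
#'   learning rate to zero over the training run).
#' @param class_weights optional per-class loss weights.
#' @param val_fraction optional fraction of training trials held out for
#'   monitoring (0 disables).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 1e-5,
                         batch_size = 32L, epochs = 100L, seed = NULL,
                         max_grad_norm = 10, lr_schedule = c("constant", "cosine"),
                         class_weights = NULL, val_fraction = 0) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1) {
    stop("learning_rate, batch_size and epochs must be positive")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 max_grad_norm = max_grad_norm,
                 lr_schedule = match.arg(lr_schedule),
                 class_weights = class_weights,
                 val_fraction = val_fraction),
            class = "train_config")
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's trials form the test set and all
#' other subjects' trials the training set, so evaluation always happens on
#' an unseen individual.
#'
#' @param subject_ids vector of subject identifiers (one entry per trial or
#'   the unique ids; duplicates are collapsed).
#' @return List of folds, each `list(train = ids, test = id)`.
#' @export
loso_folds <- function(subject_ids) {
  ids <- unique(as.character(subject_ids))
  if (length(ids) < 2) stop("LOSO needs at least 2 distinct subjects")
  lapply(ids, function(s) list(train = setdiff(ids, s), test = s))
}

#' Stratified within-subject k-fold split over trials
#'
#' Folds are drawn at the trial level, so the windows of one trial can never
#' straddle a train/test boundary. Within each class the trials are shuffled
#' (seeded) and dealt round-robin to the k folds.
#'
#' @param labels integer class labels of one subject's trials.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return List of k integer vectors (test-trial indices per fold).
#' @export
within_subject_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop(sprintf("only %d trials for %d folds", n, k))
  folds <- vector("list", k)
  withr_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      for (i in seq_along(idx)) {
        f <- ((i - 1L) %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[i])
      }
    }
  })
  lapply(folds, sort)
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

## ---- turning recordings into trial tensors -------------------------------

#' Preprocess recordings into per-cluster trial tensors
#'
#' Runs the signal-conditioning chain on every recording, splits each window
#' into the nine cluster channel groups and maps the ratings to a class
#' label.
#'
#' @param recordings list of [raw_recording()] objects.
#' @param map a `cluster_map` covering the recordings' channels.
#' @param scheme labelling scheme, see [ratings_to_class()].
#' @param clustered set `FALSE` for the single-Deformer variant (all
#'   channels in one group).
#' @param window_seconds analysis window length.
#' @param ... further arguments passed to [preprocess_recording()].
#' @return List with `trials` (list of per-cluster window arrays
#'   `n_windows x samples x channels`), `labels` (0-based integers) and
#'   `subjects` (character).
#' @export
prepare_trials <- function(recordings, map, scheme = "quadrant",
                           clustered = TRUE, window_seconds = 4.0, ...) {
  trials <- vector("list", length(recordings))
  labels <- integer(length(recordings))
  subjects <- character(length(recordings))
  groups <- if (clustered) map$clusters else
    list(all = unlist(map$clusters, use.names = FALSE))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    ws <- preprocess_recording(rec, window_seconds = window_seconds, ...)
    w <- ws$windows                        # (n_win, C, S)
    chan <- ws$channel_labels
    trials[[i]] <- lapply(groups, function(g) {
      sel <- match(g, chan)
      aperm(w[, sel, , drop = FALSE], c(1L, 3L, 2L))   # (n_win, S, C)
    })
    labels[i] <- ratings_to_class(rec$ratings, scheme)
    subjects[i] <- rec$subject_id
  }
  list(trials = trials, labels = labels, subjects = subjects)
}

## ---- training --------------------------------------------------------------

# Pre-build fixed mini-batches (the partition is shuffled once, seeded by the
# caller's RNG state) so the first-layer im2col matrices can be cached and
# reused across epochs.
make_batches <- function(trials, labels, batch_size, cfg_def) {
  ord <- sample(length(trials))
  Ts <- vapply(trials, function(tr) dim(tr[[1]])[1], 1L)
  # group by window count so every batch stacks cleanly
  batches <- list()
  for (T_ in unique(Ts[ord])) {
    idx <- ord[Ts[ord] == T_]
    starts <- seq(1L, length(idx), by = batch_size)
    for (s in starts) {
      take <- idx[s:min(s + batch_size - 1L, length(idx))]
      b <- trials_to_batch(trials[take], y = labels[take])
      e <- new.env(parent = emptyenv())
      e$batch <- b
      e$ic1 <- NULL
      batches[[length(batches) + 1L]] <- e
    }
  }
  batches
}

batch_with_ic1 <- function(env, cfg_def) {
  if (is.null(env$ic1)) {
    env$ic1 <- lapply(env$batch$x, function(x) {
      d <- dim(x)
      xc <- aperm(x, c(1L, 3L, 2L))
      dim(xc) <- c(d[1] * d[3], d[2], 1L)
      conv_im2col(xc, cfg_def$temporal_kernel, cfg_def$sfe_stride, 1L, "same")
    })
  }
  b <- env$batch
  b$ic1 <- env$ic1
  b
}

clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  ss <- 0
  tree_map(function(g) { ss <<- ss + sum(g^2); g }, grads)
  nrm <- sqrt(ss)
  if (nrm <= max_norm) return(grads)
  tree_map(function(g) g * (max_norm / nrm), grads)
}

#' Train a model with Adam and cross-entropy loss
#'
#' @param model a [c2g_model()].
#' @param trials list of per-cluster trial tensors (see [prepare_trials()]).
#' @param labels 0-based integer class labels, one per trial.
#' @param config a [train_config()].
#' @param verbose print the per-epoch loss.
#' @return List with the trained `model` and the per-epoch `loss_curve`.
#' @export
train_model <- function(model, trials, labels, config = train_config(),
                        verbose = FALSE) {
  if (length(trials) == 0) stop("empty training set")
  if (length(unique(labels)) < 2) stop("training set must contain >= 2 classes")
  if (!is.null(config$seed)) set.seed(config$seed)
  cw <- config$class_weights
  batches <- make_batches(trials, labels, config$batch_size, model$cfg$deformer)
  opt <- adam_state(model$params)
  loss_curve <- numeric(config$epochs)
  n_steps <- config$epochs * length(batches)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0
    for (be in batches) {
      step <- step + 1L
      lr_now <- if (identical(config$lr_schedule, "cosine")) {
        config$learning_rate * 0.5 * (1 + cos(pi * (step - 1L) / n_steps))
      } else config$learning_rate
      b <- batch_with_ic1(be, model$cfg$deformer)
      fwd <- model_fwd(model, b, train = TRUE)
      ce <- cross_entropy_fwd(fwd$logits, b$y)
      dlogits <- ce$dlogits
      loss <- ce$loss
      if (!is.null(cw)) {
        wts <- cw[b$y + 1L]
        scale <- wts / mean(wts)
        dlogits <- dlogits * scale
        loss <- mean(-log(pmax(ce$prob[cbind(seq_along(b$y), b$y + 1L)], 1e-12)) * wts)
      }
      grads <- model_bwd(model, dlogits, fwd$cache)
      grads <- clip_global_norm(grads, config$max_grad_norm)
      model$params <- adam_step(model$params, grads, opt,
                                lr = lr_now,
                                weight_decay = config$weight_decay)
      ep_loss <- ep_loss + loss * b$n_trials
    }
    loss_curve[ep] <- ep_loss / length(trials)
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, loss_curve[ep]))
  }
  list(model = model, loss_curve = loss_curve)
}

#' Evaluate a model on held-out trials
#'
#' Inference mode; the trial label is the argmax of the trial-level class
#' probabilities.
#'
#' @inheritParams train_model
#' @return List with `accuracy`, `confusion` and per-trial `pred` / `prob`.
#' @export
evaluate_model <- function(model, trials, labels) {
  Ts <- vapply(trials, function(tr) dim(tr[[1]])[1], 1L)
  pred <- integer(length(trials))
  prob <- matrix(NA_real_, length(trials), model$n_classes)
  for (T_ in unique(Ts)) {
    idx <- which(Ts == T_)
    b <- trials_to_batch(trials[idx])
    r <- model_fwd(model, b, train = FALSE)
    pred[idx] <- max.col(r$prob) - 1L
    prob[idx, ] <- r$prob
  }
  cm <- confusion_matrix(labels, pred, model$n_classes)
  list(accuracy = accuracy_from_confusion(cm), confusion = cm,
       pred = pred, prob = prob)
}

## ---- experiment driver -----------------------------------------------------

#' Run a full cross-validated experiment
#'
#' Preprocesses a dataset, builds one model per fold under the chosen
#' protocol, trains and evaluates it, and aggregates fold accuracies and
#' confusion counts. Deterministic given `seed`.
#'
#' @param dataset list with `recordings` (list of [raw_recording()]) and a
#'   `manifest` data frame (as produced by [generate_dataset()]).
#' @param protocol `"loso"` or `"within"` (stratified 5-fold per subject).
#' @param variant architecture variant, see [model_variants()].
#' @param map cluster map used to group channels.
#' @param scheme labelling scheme.
#' @param deformer,bca,tcn model sub-configurations.
#' @param train training configuration ([train_config()]).
#' @param mlp_hidden,rnn_hidden,dropout classifier head settings.
#' @param seed master seed; fold f trains under `seed + f`.
#' @param k within-subject fold count.
#' @param ... preprocessing arguments forwarded to [prepare_trials()].
#' @return A `c2g_report`: mean/sd accuracy, per-fold results, pooled
#'   confusion matrix, and the configuration echo.
#' @export
run_experiment <- function(dataset, protocol = c("loso", "within"),
                           variant = "C2G-DF-BCA-TCN", map,
                           scheme = "quadrant",
                           deformer = deformer_config(128), bca = bca_config(),
                           tcn = tcn_config(), train = train_config(),
                           mlp_hidden = 128L, rnn_hidden = 64L, dropout = 0.2,
                           seed = 1L, k = 5L, ...) {
  protocol <- match.arg(protocol)
  fl <- variant_flags(variant)
  prep <- prepare_trials(dataset$recordings, map, scheme,
                         clustered = fl$clustered, ...)
  cl_sizes <- vapply(map$clusters, length, 1L)
  n_classes <- scheme_n_classes(scheme)
  build <- function() c2g_model(cl_sizes, n_classes, deformer, bca, tcn,
                                mlp_hidden, rnn_hidden, dropout,
                                variant = variant)
  train$seed <- NULL   # per-fold streams are seeded below
  run_fold <- function(fold_id, tr_idx, te_idx, fold_seed) {
    stopifnot(length(intersect(tr_idx, te_idx)) == 0)
    withr_seed(fold_seed, {
      model <- build()
      fit <- train_model(model, prep$trials[tr_idx], prep$labels[tr_idx], train)
      ev <- evaluate_model(fit$model, prep$trials[te_idx], prep$labels[te_idx])
      list(fold = fold_id, accuracy = ev$accuracy, confusion = ev$confusion,
           n_test = length(te_idx), final_loss = utils::tail(fit$loss_curve, 1))
    })
  }
  folds_out <- list()
  if (protocol == "loso") {
    folds <- loso_folds(prep$subjects)
    for (f in seq_along(folds)) {
      te_idx <- which(prep$subjects == folds[[f]]$test)
      tr_idx <- which(prep$subjects %in% folds[[f]]$train)
      stopifnot(!any(prep$subjects[tr_idx] %in% prep$subjects[te_idx]))
      folds_out[[f]] <- run_fold(folds[[f]]$test, tr_idx, te_idx, seed + f)
    }
  } else {
    fi <- 0L
    for (s in unique(prep$subjects)) {
      sidx <- which(prep$subjects == s)
      wfolds <- within_subject_folds(prep$labels[sidx], k, seed + fi)
      for (j in seq_along(wfolds)) {
        fi <- fi + 1L
        te_idx <- sidx[wfolds[[j]]]
        tr_idx <- setdiff(sidx, te_idx)
        folds_out[[fi]] <- run_fold(paste0(s, "/f", j), tr_idx, te_idx, seed + fi)
      }
    }
  }
  acc <- vapply(folds_out, `[[`, 1.0, "accuracy")
  pooled <- Reduce(`+`, lapply(folds_out, `[[`, "confusion"))
  structure(list(variant = variant, protocol = protocol, scheme = scheme,
                 seed = seed, mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 fold_accuracies = acc, folds = folds_out, confusion = pooled),
            class = "c2g_report")
}

#' @export
print.c2g_report <- function(x, ...) {
  cat(sprintf("<c2g_report> %s, %s protocol, %s labels (seed %d)\n",
              x$variant, x$protocol, x$scheme, x$seed))
  cat(sprintf("  accuracy %.3f (sd %.3f) over %d folds\n",
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracies)))
  invisible(x)
}

#' Serialize an experiment report
#'
#' Writes `<stem>.json` (full report) and `<stem>_folds.csv` (per-fold
#' accuracies).
#'
#' @param report a `c2g_report`.
#' @param stem output path stem (no extension).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, stem) {
  fold_df <- data.frame(fold = vapply(report$folds, function(f) as.character(f$fold), ""),
                        accuracy = report$fold_accuracies,
                        n_test = vapply(report$folds, `[[`, 1L, "n_test"))
  utils::write.csv(fold_df, paste0(stem, "_folds.csv"), row.names = FALSE)
  out <- list(variant = report$variant, protocol = report$protocol,
              scheme = report$scheme, seed = report$seed,
              mean_accuracy = report$mean_accuracy,
              sd_accuracy = report$sd_accuracy,
              fold_accuracies = report$fold_accuracies,
              confusion = report$confusion)
  jsonlite::write_json(out, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(paste0(stem, ".json"))
}
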