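#' Two-level rating map
#'
#' Self-assessment ratings on the 1-9 scale are split at the scale midpoint:
#' 1-5 maps to `"Low"`, 6-9 to `"High"`, for valence, arousal and dominance
#' alike.
#'
#' @param rv rating value(s), integers in 1..9 (vectorized).
#' @return Character vector of `"Low"` / `"High"`.
#' @export
binarize_rating <- function(rv) {
  check_rating_scale(rv)
  ifelse(rv <= 5, "Low", "High")
}

#' Three-level rating map
#'
#' 1-3, 4-6 and 7-9 map to dimension-specific class names. Note the arousal
#' naming runs 1-3 `"Activated"` / 7-9 `"Deactivated"`, i.e. inverted with
#' respect to the usual SAM arousal direction; the naming is kept exactly as
#' defined by the scheme this package implements.
#'
#' @param rv rating value(s), integers in 1..9 (vectorized).
#' @param dimension one of `"valence"`, `"arousal"`, `"dominance"`.
#' @return Character vector of three-level class names.
#' @export
trinarize_rating <- function(rv, dimension = c("valence", "arousal", "dominance")) {
  dimension <- match.arg(dimension)
  check_rating_scale(rv)
  lev <- findInterval(rv, c(1, 4, 7))  # 1, 2, 3
  names3 <- switch(dimension,
    valence   = c("Negative", "Neutral", "Positive"),
    arousal   = c("Activated", "Moderate", "Deactivated"),
    dominance = c("Controlled", "Moderate", "Overpowered"))
  names3[lev]
}

#' Four-quadrant valence-arousal label
#'
#' Valence and arousal are each binarized ([binarize_rating()]) and combined
#' into the four quadrant classes HVHA, LVHA, LVLA, HVLA.
#'
#' @param valence_rv,arousal_rv ratings on the 1-9 scale (vectorized).
#' @return Character vector of quadrant labels.
#' @export
quadrant_label <- function(valence_rv, arousal_rv) {
  v <- binarize_rating(valence_rv)
  a <- binarize_rating(arousal_rv)
  paste0(ifelse(v == "High", "HV", "LV"), ifelse(a == "High", "HA", "LA"))
}

#' Canonical order of the four quadrant classes
#' @return `c("HVHA", "LVHA", "LVLA", "HVLA")`
#' @export
quadrant_classes <- function() c("HVHA", "LVHA", "LVLA", "HVLA")

check_rating_scale <- function(rv) {
  if (any(!is.finite(rv)) || any(rv < 1) || any(rv > 9)) {
    stop("rating values must lie in 1..9")
  }
  invisible(rv)
}

#' Confusion matrix of integer class labels
#'
#' @param y_true,y_pred integer class labels in `0:(n_classes-1)` (or factors
#'   with identical level sets).
#' @param n_classes number of classes.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 0 | y_true >= n_classes) || any(y_pred < 0 | y_pred >= n_classes)) {
    stop("labels out of range 0..n_classes-1")
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1), pred = 0:(n_classes - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

#' Classification accuracy from a confusion matrix
#'
#' The proportion of correctly classified samples: the trace divided by the
#' total count (the multi-class generalization of
#' `(TP + TN) / (TP + TN + FP + FN)`).
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Paired t-test on per-fold accuracies
#'
#' Classical paired t-test on the fold-wise accuracy differences between two
#' methods evaluated on the same folds. When the differences have zero
#' variance the t statistic is undefined; the all-equal case is reported as
#' `t = 0, p = 1` and a constant non-zero difference is flagged as
#' degenerate.
#'
#' @param acc_a,acc_b numeric vectors of per-fold accuracies, equal length >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff` and `degenerate` flag.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("fold accuracy vectors differ in length")
  if (length(acc_a) < 2) stop("need at least 2 folds")
  d <- acc_a - acc_b
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    if (abs(mean(d)) < .Machine$double.eps^0.5) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0, degenerate = FALSE))
    }
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = unname(ht$estimate), degenerate = FALSE)
}

#' Map a ratings list to an integer class index for a labelling scheme
#'
#' @param ratings named list with `valence`, `arousal`, `dominance` (1-9) or a
#'   SEED-style `valence` in `-1/0/1`.
#' @param scheme `"quadrant"` (4-class), `"valence2"`/`"arousal2"`/`"dominance2"`
#'   (2-class Low=0 High=1), `"valence3"`/`"arousal3"`/`"dominance3"` (3-class
#'   in rating order), or `"seed3"` (classes -1/0/1 mapped to 0/1/2).
#' @return Integer class index starting at 0.
#' @export
ratings_to_class <- function(ratings, scheme = "quadrant") {
  r <- ratings
  switch(scheme,
    quadrant = match(quadrant_label(r$valence, r$arousal), quadrant_classes()) - 1L,
    valence2 = as.integer(binarize_rating(r$valence) == "High"),
    arousal2 = as.integer(binarize_rating(r$arousal) == "High"),
    dominance2 = as.integer(binarize_rating(r$dominance) == "High"),
    valence3 = findInterval(check_rating_scale(r$valence), c(1, 4, 7)) - 1L,
    arousal3 = findInterval(check_rating_scale(r$arousal), c(1, 4, 7)) - 1L,
    dominance3 = findInterval(check_rating_scale(r$dominance), c(1, 4, 7)) - 1L,
    seed3 = {
      if (!r$valence %in% c(-1, 0, 1)) stop("seed3 scheme expects valence in -1/0/1")
      as.integer(r$valence) + 1L
    },
    stop("unknown labelling scheme: ", scheme))
}

#' Number of classes of a labelling scheme
#' @param scheme see [ratings_to_class()].
#' @return Integer class count.
#' @export
scheme_n_classes <- function(scheme) {
  switch(scheme,
    quadrant = 4L,
    valence2 = , arousal2 = , dominance2 = 2L,
    valence3 = , arousal3 = , dominance3 = , seed3 = 3L,
    stop("unknown labelling scheme: ", scheme))
}
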