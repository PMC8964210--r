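# Evaluation protocol: confusion matrices, per-class and macro
# precision/recall/F1, the normal-vs-cancerous binary collapse with
# accuracy/sensitivity/specificity, Cohen's kappa, a Brier-style membership
# mean-squared error, stratified 70/30 splits and stratified k-fold
# cross-validation.

#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param y_true,y_pred equal-length label vectors; every label must appear
#'   in `class_names`.
#' @param class_names class order of the matrix.
#' @return K x K integer matrix of class `confusion_matrix` with dimnames
#'   `actual` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(bad))
    stop("labels not in class_names: ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = class_names),
              factor(y_pred, levels = class_names))
  cm <- unclass(cm)
  dimnames(cm) <- list(actual = class_names, predicted = class_names)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class and macro precision, recall and F1
#'
#' One-vs-rest precision (true positives over predicted positives), recall
#' (true positives over actual positives) and their harmonic mean F1; the
#' macro averages are unweighted over classes. A class with zero predicted
#' positives gets precision 0 (and hence F1 0) with a warning; a class
#' absent from the truth gets recall 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `per_class` (data.frame class/precision/recall/f1) and
#'   `macro` (named vector precision/recall/f1).
#' @export
prf <- function(cm) {
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  act_pos <- rowSums(cm)
  if (any(pred_pos == 0))
    warning("class(es) never predicted: ",
            paste(rownames(cm)[pred_pos == 0], collapse = ", "),
            "; precision/F1 set to 0")
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(act_pos > 0, tp / act_pos, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(per_class = data.frame(class = rownames(cm), precision = precision,
                              recall = recall, f1 = f1, row.names = NULL,
                              stringsAsFactors = FALSE),
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)))
}

#' Binary metrics from a 2x2 confusion matrix
#'
#' Rows/columns ordered positive, negative (rows = actual). Metrics with a
#' zero denominator are reported as `NA` (undefined).
#'
#' @param cm2 2x2 matrix, or the four cells as `c(TP, FN, FP, TN)` reading
#'   the matrix row-wise.
#' @return named vector: accuracy, error_rate, sensitivity, specificity,
#'   precision.
#' @export
binary_metrics <- function(cm2) {
  if (is.matrix(cm2)) {
    stopifnot(all(dim(cm2) == c(2, 2)))
    tp <- cm2[1, 1]; fn <- cm2[1, 2]; fp <- cm2[2, 1]; tn <- cm2[2, 2]
  } else {
    stopifnot(length(cm2) == 4)
    tp <- cm2[1]; fn <- cm2[2]; fp <- cm2[3]; tn <- cm2[4]
  }
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  c(accuracy = (tp + tn) / total,
    error_rate = (fn + fp) / total,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    precision = div(tp, tp + fp))
}

#' Collapse a 7-class confusion matrix to normal vs cancerous
#'
#' Positive = the four cancerous classes, negative = the three normal ones
#' (see [class_groups()]). A cancerous-class sample predicted as any other
#' cancerous class counts as a true positive; totals are preserved.
#'
#' @param cm a [confusion_matrix()] over the seven canonical classes.
#' @return 2x2 `confusion_matrix` with classes `cancerous`, `normal`.
#' @export
collapse_to_binary <- function(cm) {
  g <- class_groups()
  bad <- setdiff(rownames(cm), c(g$normal, g$cancerous))
  if (length(bad))
    stop("unknown class(es): ", paste(bad, collapse = ", "))
  pos <- intersect(rownames(cm), g$cancerous)
  neg <- intersect(rownames(cm), g$normal)
  out <- rbind(
    cancerous = c(sum(cm[pos, pos]), sum(cm[pos, neg])),
    normal = c(sum(cm[neg, pos]), sum(cm[neg, neg])))
  colnames(out) <- c("cancerous", "normal")
  names(dimnames(out)) <- c("actual", "predicted")
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` = diagonal/total and expected agreement
#' `p_e = sum_k row_k * col_k / total^2`. If `p_e = 1` (all mass in one
#' cell of a single class), kappa is defined as 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return scalar kappa.
#' @export
kappa_statistic <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Membership mean-squared error (Brier-style)
#'
#' Mean over samples of `||u_i - onehot(y_i)||^2 / K` where `u_i` is the
#' row-stochastic class-membership row and `K` the number of classes.
#'
#' @param memberships n x K row-stochastic matrix with class column names
#'   (or columns in `class_names` order).
#' @param y_true length-n labels.
#' @param class_names class order; defaults to the membership column names.
#' @return scalar in `[0, 1]` (0 iff exactly one-hot correct).
#' @export
mse_metric <- function(memberships, y_true, class_names = colnames(memberships)) {
  memberships <- as.matrix(memberships)
  stopifnot(nrow(memberships) == length(y_true), !is.null(class_names))
  k <- ncol(memberships)
  col <- match(as.character(y_true), class_names)
  if (anyNA(col)) stop("labels not covered by class_names")
  onehot <- matrix(0, nrow(memberships), k)
  onehot[cbind(seq_along(col), col)] <- 1
  mean(rowSums((memberships - onehot)^2) / k)
}

#' Stratified train/test split
#'
#' Per class, `round(n_class * test_fraction)` samples go to the test set
#' (proportions preserved to within one sample); the split is seeded and the
#' two index sets are disjoint and exhaustive.
#'
#' @param y labels; every class must have at least 2 samples.
#' @param test_fraction fraction held out (default 0.3).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction = 0.3, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  with_seed(derive_seed(seed, "split"), {
    test <- integer(0)
    for (cl in names(counts)) {
      idx <- which(y == cl)
      n_test <- max(1, min(length(idx) - 1, round(length(idx) * test_fraction)))
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(y), test), test = test)
  })
}

#' Stratified fold assignment
#'
#' Deals shuffled within-class indices round-robin across folds with a
#' running counter, so total fold sizes differ by at most one and each class
#' is spread as evenly as possible.
#'
#' @param y labels.
#' @param k number of folds; reduced (with a warning) to the smallest class
#'   count if some class has fewer than `k` samples.
#' @param seed integer seed.
#' @return list with `folds` (integer fold id per sample) and `k`.
#' @export
stratified_folds <- function(y, k = 12, seed = 1) {
  y <- as.character(y)
  n <- length(y)
  if (n < k) stop("n = ", n, " < k = ", k)
  min_class <- min(table(y))
  if (min_class < k) {
    warning("smallest class has ", min_class, " samples; reducing k from ",
            k, " to ", min_class)
    k <- min_class
  }
  if (k < 2) stop("cannot build fewer than 2 folds")
  folds <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    counter <- 0L
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      folds[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- counter + length(idx)
    }
  })
  list(folds = folds, k = k)
}

#' Full evaluation report from truth, predictions and memberships
#'
#' Computes the multi-class confusion matrix, per-class and macro
#' precision/recall/F1, accuracy and Cohen's kappa; if memberships are
#' given, the membership MSE; if the classes are the canonical seven, the
#' normal-vs-cancerous collapse with binary accuracy, sensitivity and
#' specificity.
#'
#' @param y_true,y_pred label vectors.
#' @param class_names class order.
#' @param memberships optional n x K class-membership matrix (see
#'   [predict.fcm()] type `"class_membership"`).
#' @param seed seed echoed into the report.
#' @return object of class `eval_report`.
#' @export
eval_report <- function(y_true, y_pred, class_names,
                        memberships = NULL, seed = NULL) {
  cm <- confusion_matrix(y_true, y_pred, class_names)
  metrics <- suppressWarnings(prf(cm))
  rep <- list(confusion = cm,
              per_class = metrics$per_class,
              macro = metrics$macro,
              accuracy = if (sum(cm) > 0) sum(diag(cm)) / sum(cm) else NA_real_,
              kappa = if (sum(cm) > 0) kappa_statistic(cm) else NA_real_,
              n = sum(cm), seed = seed)
  if (!is.null(memberships)) {
    full <- matrix(0, length(y_true), length(class_names),
                   dimnames = list(NULL, class_names))
    full[, colnames(memberships)] <- as.matrix(memberships)
    rep$mse <- mse_metric(full, y_true, class_names)
  }
  if (all(rownames(cm) %in% unlist(class_groups())) &&
      length(class_names) == 7) {
    cm2 <- collapse_to_binary(cm)
    rep$binary_confusion <- cm2
    rep$binary <- binary_metrics(cm2)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples: accuracy %.3f, macro-F1 %.3f, kappa %.3f\n",
              x$n, x$accuracy, x$macro["f1"], x$kappa))
  if (!is.null(x$mse)) cat(sprintf("  membership MSE %.4f\n", x$mse))
  if (!is.null(x$binary))
    cat(sprintf("  normal vs cancerous: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
                x$binary["accuracy"], x$binary["sensitivity"],
                x$binary["specificity"]))
  invisible(x)
}

#' Stratified k-fold cross-validation of the FCM classifier
#'
#' For each fold, fits [fcm_fit()] on the remaining folds (optionally
#' restricted to a feature-group subset) and evaluates the held-out fold.
#'
#' @param x n x p feature matrix.
#' @param y labels.
#' @param k folds (default 12).
#' @param seed master seed.
#' @param fcm an [fcm_config()].
#' @param subset optional group mask or preset passed to [reduce_features()].
#' @return object of class `cv_result`: `reports` (per fold), `summary`
#'   (mean/sd of accuracy and macro-F1), `folds`, `k`.
#' @export
kfold_cv <- function(x, y, k = 12, seed = 1, fcm = fcm_config(),
                     subset = NULL) {
  x <- as.matrix(x)
  if (!is.null(subset)) x <- as.matrix(reduce_features(x, subset))
  fa <- stratified_folds(y, k, seed)
  class_names <- sort(unique(as.character(y)))
  reports <- lapply(seq_len(fa$k), function(f) {
    tr <- fa$folds != f
    cfg <- fcm
    cfg$seed <- derive_seed(fcm$seed, "cv_fold", f)
    model <- fcm_fit(x[tr, , drop = FALSE], y[tr], cfg)
    pred <- predict(model, x[!tr, , drop = FALSE])
    suppressWarnings(
      eval_report(y[!tr], pred, class_names,
                  memberships = predict(model, x[!tr, , drop = FALSE],
                                        type = "class_membership")))
  })
  acc <- vapply(reports, `[[`, 0, "accuracy")
  f1 <- vapply(reports, function(r) unname(r$macro["f1"]), 0)
  structure(list(reports = reports,
                 summary = data.frame(
                   metric = c("accuracy", "macro_f1"),
                   mean = c(mean(acc), mean(f1)),
                   sd = c(stats::sd(acc), stats::sd(f1))),
                 folds = fa$folds, k = fa$k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation\n", x$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# 1-nearest-neighbor baseline (Euclidean, standardized with train stats)
nn1_predict <- function(x_train, y_train, x_test) {
  center <- colMeans(x_train)
  scale <- apply(x_train, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  a <- sweep(sweep(as.matrix(x_train), 2, center), 2, scale, "/")
  b <- sweep(sweep(as.matrix(x_test), 2, center), 2, scale, "/")
  d2 <- outer(rowSums(b^2), rep(1, nrow(a))) +
    outer(rep(1, nrow(b)), rowSums(a^2)) - 2 * b %*% t(a)
  y_train[apply(d2, 1, which.min)]
}
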