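# Model front-end and the five-stage experimental protocol:
# (1) data, (2) stratified 70/30 partition, (3) FCM classifier on all
# features, (4) QGH wrapper selection on the training set and FCM on the
# selected subset, (5) both models evaluated on the held-out test set.

#' Fit the swarm-selected fuzzy C-means classifier
#'
#' The central fitting function: optionally runs the QGH wrapper selection
#' ([qgh_run()]) on the training data, then fits the FCM classifier
#' ([fcm_fit()]) on the selected feature groups. With `select = FALSE` (or
#' `subset` given) the swarm stage is skipped.
#'
#' @param x n x p numeric training feature matrix (canonical column names,
#'   e.g. from [feature_table()]).
#' @param y length-n training class labels (>= 2 classes).
#' @param select run the swarm selection stage (default TRUE).
#' @param subset optional fixed group mask or preset (e.g. `"pruned7"`);
#'   implies `select = FALSE`.
#' @param swarm a [swarm_config()].
#' @param fcm an [fcm_config()] for the final model; the fitness function
#'   uses `fitness_fcm` (defaults to a lighter-budget copy).
#' @param fitness_fcm [fcm_config()] used inside [subset_fitness()].
#' @param seed master seed; overrides the seeds inside `swarm` and `fcm`.
#' @return object of class `qgh_fcm`: `model` (the fitted [fcm_fit()]
#'   classifier), `selection` (a `qgh_selection` or NULL), `mask` (named
#'   group mask actually used), `columns`, `seed`.
#' @export
qgh_fcm <- function(x, y, select = TRUE, subset = NULL,
                    swarm = swarm_config(), fcm = fcm_config(),
                    fitness_fcm = NULL, seed = 1) {
  x <- as.matrix(x)
  groups <- feature_groups(colnames(x))
  swarm$seed <- derive_seed(seed, "swarm")
  fcm$seed <- derive_seed(seed, "fcm_final")
  if (is.null(fitness_fcm)) {
    fitness_fcm <- fcm
    fitness_fcm$n_init <- min(fcm$n_init, 2L)
    fitness_fcm$max_iter <- min(fcm$max_iter, 60L)
    fitness_fcm$tol <- max(fcm$tol, 1e-4)
  }
  fitness_fcm$seed <- derive_seed(seed, "fcm_fitness")

  selection <- NULL
  if (!is.null(subset)) {
    keep <- subset_to_keep(subset, groups)
    mask <- stats::setNames(as.integer(names(groups) %in% keep), names(groups))
  } else if (select) {
    selection <- qgh_run(x, y, swarm = swarm, fcm = fitness_fcm,
                         groups = groups)
    mask <- selection$best_mask
  } else {
    mask <- stats::setNames(rep(1L, length(groups)), names(groups))
  }
  cols <- unlist(groups[mask == 1], use.names = FALSE)
  model <- fcm_fit(x[, cols, drop = FALSE], y, fcm)
  structure(list(model = model, selection = selection, mask = mask,
                 columns = cols, groups = groups, seed = seed,
                 classes = sort(unique(as.character(y)))),
            class = "qgh_fcm")
}

#' @export
predict.qgh_fcm <- function(object, newdata, type = "class", ...) {
  newdata <- as.matrix(newdata)
  predict(object$model, newdata[, object$columns, drop = FALSE], type = type, ...)
}

#' @export
print.qgh_fcm <- function(x, ...) {
  cat("Swarm-selected fuzzy C-means classifier\n")
  cat(sprintf("  feature groups used: %d/%d (%s)\n", sum(x$mask),
              length(x$mask),
              if (is.null(x$selection)) "fixed subset" else "QGH-selected"))
  cat(" ", paste(names(x$mask)[x$mask == 1], collapse = ", "), "\n")
  print(x$model)
  invisible(x)
}

#' @export
summary.qgh_fcm <- function(object, ...) {
  cat("Swarm-selected fuzzy C-means classifier\n")
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = ", ")))
  cat(sprintf("  selected groups (%d/%d): %s\n", sum(object$mask),
              length(object$mask),
              paste(names(object$mask)[object$mask == 1], collapse = ", ")))
  if (!is.null(object$selection))
    cat(sprintf("  selection fitness %.4f after %d memoized evaluations\n",
                object$selection$best_fitness, object$selection$evaluations))
  cat(sprintf("  FCM: %d clusters, m = %g, final J = %.5g\n",
              nrow(object$model$centroids), object$model$m,
              object$model$objective))
  invisible(object)
}

#' @export
plot.qgh_fcm <- function(x, ...) {
  if (!is.null(x$selection)) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    plot(x$selection, main = "swarm global best")
  }
  graphics::plot(x$model$objective_trace, type = "b",
                 xlab = "iteration", ylab = "FCM objective J",
                 main = "FCM convergence", ...)
  invisible(x)
}

#' Run the with/without-selection comparison experiment
#'
#' Stage 2: stratified 70/30 split; stage 3: FCM on all features; stage 4
#' (unless `select = FALSE`): QGH selection on the training part and FCM on
#' the selected groups; stage 5: both models evaluated on the held-out test
#' set (optionally also a 1-nearest-neighbor baseline).
#'
#' @param x n x p feature matrix.
#' @param y labels (>= 2 classes).
#' @param select run the selection stage (default TRUE).
#' @param test_fraction held-out fraction (default 0.3).
#' @param swarm,fcm,fitness_fcm configurations, see [qgh_fcm()].
#' @param baseline_1nn also evaluate a 1-NN baseline on both feature sets.
#' @param seed master seed; all stage sub-seeds derive from it.
#' @return object of class `cell_experiment`: `report_all`,
#'   `report_selected` (NULL if selection disabled), `selection`, `mask`,
#'   `split`, baseline reports if requested, `seed`.
#' @export
run_experiment <- function(x, y, select = TRUE, test_fraction = 0.3,
                           swarm = swarm_config(), fcm = fcm_config(),
                           fitness_fcm = NULL, baseline_1nn = FALSE,
                           seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("need at least 2 classes")
  class_names <- sort(unique(y))
  sp <- stratified_split(y, test_fraction, seed = derive_seed(seed, "holdout"))
  xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  xte <- x[sp$test, , drop = FALSE]; yte <- y[sp$test]

  fit_all <- qgh_fcm(xtr, ytr, select = FALSE, swarm = swarm, fcm = fcm,
                     seed = derive_seed(seed, "stage3"))
  report_all <- suppressWarnings(eval_report(
    yte, predict(fit_all, xte), class_names,
    memberships = predict(fit_all, xte, type = "class_membership"),
    seed = seed))

  report_selected <- NULL; selection <- NULL; mask <- NULL
  fit_sel <- NULL
  if (select) {
    fit_sel <- qgh_fcm(xtr, ytr, select = TRUE, swarm = swarm, fcm = fcm,
                       fitness_fcm = fitness_fcm,
                       seed = derive_seed(seed, "stage4"))
    selection <- fit_sel$selection
    mask <- fit_sel$mask
    report_selected <- suppressWarnings(eval_report(
      yte, predict(fit_sel, xte), class_names,
      memberships = predict(fit_sel, xte, type = "class_membership"),
      seed = seed))
  }

  out <- list(report_all = report_all, report_selected = report_selected,
              selection = selection, mask = mask, split = sp,
              fit_all = fit_all, fit_selected = fit_sel,
              class_names = class_names, seed = seed,
              selection_enabled = select)
  if (baseline_1nn) {
    out$report_1nn_all <- suppressWarnings(eval_report(
      yte, nn1_predict(xtr, ytr, xte), class_names, seed = seed))
    if (select) {
      cols <- fit_sel$columns
      out$report_1nn_selected <- suppressWarnings(eval_report(
        yte, nn1_predict(xtr[, cols, drop = FALSE], ytr,
                         xte[, cols, drop = FALSE]), class_names, seed = seed))
    }
  }
  structure(out, class = "cell_experiment")
}

#' @export
print.cell_experiment <- function(x, ...) {
  cat("With/without-selection comparison (held-out test set)\n")
  cat(sprintf("  all features     : accuracy %.3f, macro-F1 %.3f\n",
              x$report_all$accuracy, x$report_all$macro["f1"]))
  if (!is.null(x$report_selected)) {
    cat(sprintf("  selected features: accuracy %.3f, macro-F1 %.3f (%d/%d groups)\n",
                x$report_selected$accuracy, x$report_selected$macro["f1"],
                sum(x$mask), length(x$mask)))
  } else cat("  selection stage skipped\n")
  invisible(x)
}

#' Simulated feature matrix with planted informative groups
#'
#' Simulates the wrapper-selection testbed. Informative column `j` carries a
#' mean shift `sep` for class `((j - 1) mod n_classes) + 1` only, so each
#' informative feature is the sole separator of "its" class: with
#' `informative = n_classes`, dropping two informative columns makes two
#' classes indistinguishable, which keeps the whole informative set jointly
#' necessary. `noise` columns are pure standard normal. Each column is its
#' own feature group.
#'
#' @param n_per_class samples per class.
#' @param n_classes number of classes (default 7).
#' @param informative,noise numbers of informative / noise columns.
#' @param sep class-mean shift of an informative column (in noise sds).
#' @param seed integer seed.
#' @return list with `x` (matrix, columns `inf_*` then `noise_*`), `y`,
#'   `informative` (column indices).
#' @export
planted_features <- function(n_per_class = 20, n_classes = 7,
                             informative = 7, noise = 7, sep = 3,
                             seed = 1) {
  with_seed(derive_seed(seed, "planted"), {
    n <- n_per_class * n_classes
    y <- rep(paste0("class", seq_len(n_classes)), each = n_per_class)
    mu <- matrix(0, n_classes, informative)
    for (j in seq_len(informative))
      mu[(j - 1) %% n_classes + 1, j] <- sep
    xi <- mu[rep(seq_len(n_classes), each = n_per_class), , drop = FALSE] +
      matrix(stats::rnorm(n * informative), n, informative)
    xn <- matrix(stats::rnorm(n * noise), n, noise)
    x <- cbind(xi, xn)
    colnames(x) <- c(sprintf("inf_%02d", seq_len(informative)),
                     sprintf("noise_%02d", seq_len(noise)))
    list(x = x, y = y, informative = seq_len(informative))
  })
}

#' Serialize an evaluation report as JSON
#'
#' @param report an `eval_report` or `cell_experiment`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  to_list <- function(r) {
    if (is.null(r)) return(NULL)
    list(confusion = list(classes = rownames(r$confusion),
                          counts = unclass(r$confusion)),
         per_class = r$per_class, macro = as.list(r$macro),
         accuracy = r$accuracy, kappa = r$kappa, mse = r$mse,
         binary = if (!is.null(r$binary)) as.list(r$binary),
         n = r$n)
  }
  obj <- if (inherits(report, "cell_experiment")) {
    list(report_all = to_list(report$report_all),
         report_selected = to_list(report$report_selected),
         mask = if (!is.null(report$mask))
           as.list(stats::setNames(as.integer(report$mask), names(report$mask))),
         selection_enabled = report$selection_enabled,
         seed = report$seed)
  } else to_list(report)
  drop_null <- function(x) {
    if (is.data.frame(x) || !is.list(x)) return(x)
    Filter(Negate(is.null), lapply(x, drop_null))
  }
  obj <- drop_null(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
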