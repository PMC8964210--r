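# Fuzzy C-means (FCM) classifier.
#
# Standard alternating-optimization FCM: membership update
#   u_ij = [ sum_k (d_ij / d_ik)^(2/(m-1)) ]^(-1)
# (Euclidean d; a point coincident with a centroid gets membership 1 there)
# and centroid update c_j = sum_i u_ij^m x_i / sum_i u_ij^m, minimizing
#   J = sum_ij u_ij^m ||x_i - c_j||^2.
# FCM is unsupervised; it is used as a classifier by mapping each cluster to
# the majority class of its hard-assigned training points. Features are
# z-scored with training statistics before clustering because the raw units
# (pixel counts, gray levels, ratios) are incommensurable.

#' Fuzzy C-means configuration
#'
#' @param n_clusters number of clusters C (>= 2); default 7, one per class.
#' @param m fuzziness exponent (> 1).
#' @param tol convergence tolerance on the change of the objective J.
#' @param max_iter maximum alternating iterations per restart.
#' @param seed integer seed; restarts use sub-seeds derived from it.
#' @param n_init number of seeded restarts; the best final J is kept.
#' @return object of class `fcm_config`.
#' @export
fcm_config <- function(n_clusters = 7, m = 2, tol = 1e-5, max_iter = 300,
                       seed = 1, n_init = 5) {
  stopifnot(n_clusters >= 2, m > 1, tol > 0, max_iter >= 1, n_init >= 1)
  structure(list(n_clusters = as.integer(n_clusters), m = m, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 n_init = as.integer(n_init)),
            class = "fcm_config")
}

#' Fuzzy membership matrix for fixed centroids
#'
#' @param x n x d numeric matrix.
#' @param centroids C x d numeric matrix of distinct rows.
#' @param m fuzziness exponent (> 1).
#' @return n x C row-stochastic membership matrix.
#' @export
fcm_memberships <- function(x, centroids, m) {
  stopifnot(m > 1, ncol(x) == ncol(centroids))
  n <- nrow(x); C <- nrow(centroids)
  if (n == 0) return(matrix(numeric(0), 0, C))
  # squared Euclidean distances, n x C
  d2 <- outer(rowSums(x^2), rep(1, C)) + outer(rep(1, n), rowSums(centroids^2)) -
    2 * x %*% t(centroids)
  d2[d2 < 0] <- 0
  w <- d2^(-1 / (m - 1)) # (d^2)^(-1/(m-1)) = d^(-2/(m-1))
  zero <- d2 == 0
  has_zero <- rowSums(zero) > 0
  u <- w / rowSums(w)
  if (any(has_zero)) {
    u[has_zero, ] <- 0
    first_zero <- apply(zero[has_zero, , drop = FALSE], 1, which.max)
    u[cbind(which(has_zero), first_zero)] <- 1
  }
  u
}

fcm_objective <- function(x, centroids, u, m) {
  n <- nrow(x); C <- nrow(centroids)
  d2 <- outer(rowSums(x^2), rep(1, C)) + outer(rep(1, n), rowSums(centroids^2)) -
    2 * x %*% t(centroids)
  d2[d2 < 0] <- 0
  sum(u^m * d2)
}

# one seeded FCM run on standardized data
fcm_run_once <- function(x, C, m, tol, max_iter, seed) {
  n <- nrow(x)
  centroids <- with_seed(seed, {
    init <- x[sample.int(n, C), , drop = FALSE]
    # spread duplicate initial centroids apart
    init + matrix(stats::rnorm(C * ncol(x), 0, 1e-6), C)
  })
  trace <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    u <- fcm_memberships(x, centroids, m)
    j <- fcm_objective(x, centroids, u, m)
    trace <- c(trace, j)
    if (it > 1 && abs(trace[it - 1] - j) < tol) break
    um <- u^m
    denom <- colSums(um)
    denom[denom == 0] <- 1
    centroids <- t(um) %*% x / denom
  }
  list(centroids = centroids, u = u, objective_trace = trace,
       objective = trace[length(trace)])
}

#' Fit a fuzzy C-means model (optionally as a classifier)
#'
#' Standardizes `x` (per-feature training mean/sd; constant features get
#' sd 1), runs `n_init` seeded restarts of alternating optimization and
#' keeps the best final objective. If training labels `y` are supplied, each
#' cluster is mapped to a class with [assign_cluster_labels()], making the
#' model a classifier usable with [predict.fcm()].
#'
#' @param x n x d numeric feature matrix (raw scale).
#' @param y optional length-n class labels.
#' @param config an [fcm_config()].
#' @return object of class `fcm`: centroids (standardized space), `scaling`
#'   (`center`, `scale`), `m`, `u` (training memberships),
#'   `objective_trace` (best restart), `objective`, `cluster_to_class`
#'   (or NULL), `config`.
#' @export
fcm_fit <- function(x, y = NULL, config = fcm_config()) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains NA/NaN values")
  C <- config$n_clusters
  if (nrow(x) < C)
    stop("need at least as many samples (", nrow(x), ") as clusters (", C, ")")
  if (!is.null(y)) stopifnot(length(y) == nrow(x))

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  best <- NULL
  for (i in seq_len(config$n_init)) {
    run <- fcm_run_once(xs, C, config$m, config$tol, config$max_iter,
                        derive_seed(config$seed, "fcm_init", i))
    if (is.null(best) || run$objective < best$objective) best <- run
  }

  map <- NULL
  if (!is.null(y)) map <- assign_cluster_labels(best$u, y)
  structure(list(centroids = best$centroids,
                 scaling = list(center = center, scale = scale),
                 m = config$m, u = best$u,
                 objective_trace = best$objective_trace,
                 objective = best$objective,
                 cluster_to_class = map,
                 feature_names = colnames(x),
                 config = config),
            class = "fcm")
}

#' Map clusters to classes by training majority
#'
#' Each cluster is mapped to the majority class of its hard-assigned
#' (argmax membership) training points; ties break to the lowest class
#' index (alphabetical for character labels, level order for factors). A
#' cluster with no hard-assigned point is mapped to the globally most
#' frequent class with a warning.
#'
#' @param u n x C membership matrix.
#' @param y length-n training labels.
#' @return character vector of length C: class label per cluster.
#' @export
assign_cluster_labels <- function(u, y) {
  stopifnot(nrow(u) == length(y))
  lev <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  y <- as.character(y)
  hard <- max.col(u, ties.method = "first")
  global <- lev[which.max(table(factor(y, levels = lev)))]
  vapply(seq_len(ncol(u)), function(j) {
    yy <- y[hard == j]
    if (!length(yy)) {
      warning("cluster ", j, " has no hard-assigned training point; ",
              "mapped to global majority class '", global, "'")
      return(global)
    }
    tab <- table(factor(yy, levels = lev))
    lev[which.max(tab)] # which.max breaks ties to the lowest index
  }, "")
}

#' Predict from a fitted FCM model
#'
#' New data are standardized with the stored training statistics; each point
#' is assigned to the cluster of maximum membership (ties to the lowest
#' cluster index) and, if the model carries a cluster-to-class map, to that
#' cluster's class.
#'
#' @param object an `fcm` model.
#' @param newdata matrix with the model's feature columns.
#' @param type `"class"` (default), `"cluster"`, `"membership"` (per-cluster
#'   rows) or `"class_membership"` (cluster memberships summed per class).
#' @param ... unused.
#' @return per `type`: character labels, integer cluster indices, or a
#'   membership matrix.
#' @export
predict.fcm <- function(object, newdata,
                        type = c("class", "cluster", "membership",
                                 "class_membership"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centroids))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         ncol(object$centroids))
  xs <- sweep(sweep(newdata, 2, object$scaling$center), 2,
              object$scaling$scale, "/")
  u <- fcm_memberships(xs, object$centroids, object$m)
  if (type == "membership") return(u)
  if (type == "class_membership") {
    if (is.null(object$cluster_to_class))
      stop("model was fitted without labels; no cluster_to_class map")
    cls <- sort(unique(object$cluster_to_class))
    cu <- vapply(cls, function(cl)
      rowSums(u[, object$cluster_to_class == cl, drop = FALSE]), numeric(nrow(u)))
    cu <- matrix(cu, nrow = nrow(u), dimnames = list(NULL, cls))
    return(cu)
  }
  hard <- max.col(u, ties.method = "first")
  if (type == "cluster") return(hard)
  if (is.null(object$cluster_to_class))
    stop("model was fitted without labels; use type = 'cluster'")
  if (nrow(newdata) == 0) return(character(0))
  object$cluster_to_class[hard]
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy C-means model: %d clusters, %d features, m = %g\n",
              nrow(x$centroids), ncol(x$centroids), x$m))
  cat(sprintf("  final objective J = %.6g after %d iterations (best of %d restarts)\n",
              x$objective, length(x$objective_trace), x$config$n_init))
  if (!is.null(x$cluster_to_class))
    cat("  cluster -> class:", paste(x$cluster_to_class, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore an FCM model as JSON
#'
#' @param model an `fcm` model.
#' @param path JSON file path.
#' @return `path` invisibly (write); an `fcm` model (read).
#' @export
write_fcm_model <- function(model, path) {
  obj <- list(centroids = model$centroids,
              scaling = model$scaling, m = model$m,
              cluster_to_class = model$cluster_to_class,
              feature_names = model$feature_names,
              objective = model$objective,
              config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fcm_model
#' @export
read_fcm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centroids = as.matrix(obj$centroids),
                 scaling = list(center = obj$scaling$center,
                                scale = obj$scaling$scale),
                 m = obj$m, u = NULL,
                 objective_trace = NULL, objective = obj$objective,
                 cluster_to_class = obj$cluster_to_class,
                 feature_names = obj$feature_names,
                 config = do.call(fcm_config, as.list(obj$config))),
            class = "fcm")
}
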