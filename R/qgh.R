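# Quantum-behaved binary swarm feature-subset search ("QGH").
#
# A quantum-behaved swarm update (contraction-expansion coefficient beta on
# a linear schedule, mean-best attractor) drives real-valued particle
# positions; a logistic transfer with a Bernoulli draw binarizes each
# position into a feature-group mask. Fitness of a mask is the macro-F1 of
# the FCM classifier on a fixed internal stratified 70/30 split of the
# training data, minus a small parsimony penalty per selected group. The
# swarm is velocity-free: per particle and dimension,
#   p  = phi * pbest + (1 - phi) * gbest,          phi ~ U(0,1)
#   x' = p +/- beta * |mbest - x| * ln(1/u),       u ~ U(0,1), sign w.p. 1/2
#   bit = 1  iff  v < 1 / (1 + exp(-x')),          v ~ U(0,1)
# where mbest is the componentwise mean of all personal-best positions.
# An all-zero mask is repaired by setting one uniformly chosen bit.

#' Swarm configuration
#'
#' @param n_particles swarm size.
#' @param n_iterations number of update sweeps after initialization.
#' @param beta_start,beta_end contraction-expansion coefficient, linearly
#'   interpolated from start (first step) to end (last step).
#' @param lambda parsimony penalty: fitness = macro-F1 - lambda * (selected
#'   groups / total groups).
#' @param seed integer seed for the whole run.
#' @param seed_all_ones if TRUE, particle 1 starts with the all-ones mask,
#'   so the selected subset can never score below the all-features baseline
#'   on the internal split.
#' @return object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 20, n_iterations = 50,
                         beta_start = 1.0, beta_end = 0.5,
                         lambda = 0.01, seed = 1, seed_all_ones = TRUE) {
  stopifnot(n_particles >= 1, n_iterations >= 1,
            beta_start >= beta_end, beta_end > 0, lambda >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 beta_start = beta_start, beta_end = beta_end,
                 lambda = lambda, seed = as.integer(seed),
                 seed_all_ones = isTRUE(seed_all_ones)),
            class = "swarm_config")
}

#' Contraction-expansion coefficient at a 0-based iteration
#' @param config a [swarm_config()].
#' @param iteration 0-based iteration index in `0..n_iterations-1`.
#' @return beta for that sweep.
#' @export
beta_schedule <- function(config, iteration) {
  n <- config$n_iterations
  if (n == 1) return(config$beta_start)
  config$beta_start + (config$beta_end - config$beta_start) * iteration / (n - 1)
}

logistic <- function(x) 1 / (1 + exp(-x))

repair_mask <- function(mask) {
  if (!any(mask == 1)) mask[sample.int(length(mask), 1)] <- 1L
  mask
}

#' Fitness of a feature-group mask
#'
#' Splits the training data once (stratified 70/30, fixed by `split_seed`),
#' fits the FCM classifier on the 70% restricted to the selected groups,
#' predicts the held-back 30%, and returns macro-F1 minus
#' `lambda * (set bits / d)`. Deterministic given its inputs, so swarm
#' global-best monotonicity is meaningful.
#'
#' @param mask binary vector over feature groups, at least one bit set.
#' @param x n x p numeric feature matrix.
#' @param y length-n class labels.
#' @param fcm_config an [fcm_config()].
#' @param split_seed seed fixing the internal split for the whole run.
#' @param lambda parsimony penalty weight.
#' @param groups named list mapping each group to its columns of `x`
#'   (default [feature_groups()] of the column names).
#' @return scalar fitness.
#' @export
subset_fitness <- function(mask, x, y, fcm_config = fcm_config(),
                           split_seed = 1, lambda = 0.01,
                           groups = feature_groups(colnames(x))) {
  mask <- as.integer(mask != 0)
  if (length(mask) != length(groups))
    stop("mask length ", length(mask), " != number of groups ", length(groups))
  if (!any(mask == 1)) stop("mask must select at least one feature group")
  cols <- unlist(groups[mask == 1], use.names = FALSE)
  sp <- stratified_split(y, test_fraction = 0.3, seed = split_seed)
  xt <- x[sp$train, cols, drop = FALSE]
  # empty-cluster fallbacks are routine for poor masks during the search;
  # the final model fit outside the wrapper still warns
  model <- suppressWarnings(fcm_fit(xt, y[sp$train], fcm_config))
  pred <- predict(model, x[sp$test, cols, drop = FALSE])
  cm <- confusion_matrix(y[sp$test], pred, class_names = sort(unique(y)))
  f1 <- suppressWarnings(prf(cm)$macro["f1"])
  unname(f1) - lambda * sum(mask) / length(mask)
}

#' Initialize the swarm
#'
#' Positions are standard-normal per component; masks are binarized with the
#' same logistic transfer used in [qgh_step()]; all particles are evaluated
#' and personal/global bests set. Uses the RNG stream as seeded by the
#' caller ([qgh_optimize()] seeds it from `config$seed`).
#'
#' @param fitness_fn function(mask) -> scalar fitness.
#' @param d number of binary dimensions (feature groups).
#' @param config a [swarm_config()].
#' @return a swarm state list (positions, masks, bests, history, counters).
#' @export
qgh_init <- function(fitness_fn, d, config = swarm_config()) {
  stopifnot(d >= 1)
  np <- config$n_particles
  positions <- matrix(stats::rnorm(np * d), np, d)
  masks <- matrix(0L, np, d)
  for (i in seq_len(np)) {
    bits <- as.integer(stats::runif(d) < logistic(positions[i, ]))
    masks[i, ] <- repair_mask(bits)
  }
  if (config$seed_all_ones) masks[1, ] <- 1L
  fit <- vapply(seq_len(np), function(i) fitness_fn(masks[i, ]), 0)
  g <- which.max(fit)
  list(positions = positions, masks = masks,
       pbest_positions = positions, pbest_masks = masks, pbest_fitness = fit,
       gbest_position = positions[g, ], gbest_mask = masks[g, ],
       gbest_fitness = fit[g], history = fit[g],
       evaluations = np, iter = 0L, d = d, config = config)
}

#' One swarm update sweep
#'
#' @param state swarm state from [qgh_init()] / a previous step.
#' @param fitness_fn function(mask) -> scalar fitness.
#' @param iteration 0-based iteration index (defaults to the state counter);
#'   sets beta via [beta_schedule()].
#' @return updated state; `gbest_fitness` never decreases.
#' @export
qgh_step <- function(state, fitness_fn, iteration = state$iter) {
  cfg <- state$config
  beta <- beta_schedule(cfg, iteration)
  np <- cfg$n_particles
  d <- state$d
  mbest <- colMeans(state$pbest_positions)
  for (i in seq_len(np)) {
    phi <- stats::runif(d)
    p <- phi * state$pbest_positions[i, ] + (1 - phi) * state$gbest_position
    u <- stats::runif(d)
    sgn <- ifelse(stats::runif(d) < 0.5, 1, -1)
    xp <- p + sgn * beta * abs(mbest - state$positions[i, ]) * log(1 / u)
    bits <- as.integer(stats::runif(d) < logistic(xp))
    bits <- repair_mask(bits)
    state$positions[i, ] <- xp
    state$masks[i, ] <- bits
    f <- fitness_fn(bits)
    state$evaluations <- state$evaluations + 1L
    if (f > state$pbest_fitness[i]) {
      state$pbest_fitness[i] <- f
      state$pbest_positions[i, ] <- xp
      state$pbest_masks[i, ] <- bits
    }
    if (f > state$gbest_fitness) {
      state$gbest_fitness <- f
      state$gbest_position <- xp
      state$gbest_mask <- bits
    }
  }
  state$iter <- state$iter + 1L
  state$history <- c(state$history, state$gbest_fitness)
  state
}

#' Run the swarm on an arbitrary binary fitness function
#'
#' Generic engine: seeds the RNG from `config$seed`, initializes and runs
#' `n_iterations` sweeps. Fitness evaluations are memoized per mask, so the
#' fitness function must be deterministic.
#'
#' @param fitness_fn function(mask) -> scalar.
#' @param d number of binary dimensions.
#' @param config a [swarm_config()].
#' @return object of class `qgh_selection`: `best_mask`, `best_fitness`,
#'   `history` (length `n_iterations + 1`, including initialization),
#'   `evaluations` (memoized fitness calls), `config`.
#' @export
qgh_optimize <- function(fitness_fn, d, config = swarm_config()) {
  cache <- new.env(parent = emptyenv())
  calls <- 0L
  memo <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    calls <<- calls + 1L
    v <- fitness_fn(mask)
    cache[[key]] <- v
    v
  }
  state <- with_seed(derive_seed(config$seed, "qgh"), {
    st <- qgh_init(memo, d, config)
    for (it in seq_len(config$n_iterations) - 1L)
      st <- qgh_step(st, memo, iteration = it)
    st
  })
  structure(list(best_mask = state$gbest_mask,
                 best_fitness = state$gbest_fitness,
                 history = state$history,
                 evaluations = calls,
                 config = config),
            class = "qgh_selection")
}

#' Wrapper feature selection on a feature matrix
#'
#' Runs the swarm over the feature groups of `x` with [subset_fitness()] as
#' the objective (FCM macro-F1 on a fixed internal stratified 70/30 split of
#' the supplied training data, minus the parsimony penalty).
#'
#' @param x n x p numeric training feature matrix (canonical column names).
#' @param y length-n training labels (>= 2 classes).
#' @param swarm a [swarm_config()].
#' @param fcm an [fcm_config()] used inside the fitness function.
#' @param groups feature-group mapping (default [feature_groups()]).
#' @return a `qgh_selection` whose `best_mask` is named by group.
#' @export
qgh_run <- function(x, y, swarm = swarm_config(), fcm = fcm_config(),
                    groups = feature_groups(colnames(x))) {
  if (length(unique(y)) < 2)
    stop("feature selection needs at least 2 classes")
  split_seed <- derive_seed(swarm$seed, "fitness_split")
  fit_fn <- function(mask)
    subset_fitness(mask, x, y, fcm_config = fcm, split_seed = split_seed,
                   lambda = swarm$lambda, groups = groups)
  res <- qgh_optimize(fit_fn, length(groups), swarm)
  names(res$best_mask) <- names(groups)
  res$groups <- names(groups)
  res
}

#' @export
print.qgh_selection <- function(x, ...) {
  cat(sprintf("QGH selection: %d/%d groups, best fitness %.4f (%d evaluations)\n",
              sum(x$best_mask), length(x$best_mask), x$best_fitness,
              x$evaluations))
  if (!is.null(names(x$best_mask)))
    cat("  selected:", paste(names(x$best_mask)[x$best_mask == 1],
                             collapse = ", "), "\n")
  invisible(x)
}

#' Fitness-history plot of a selection run
#' @param x a `qgh_selection`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qgh_selection <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1, x$history, type = "s",
                 xlab = "iteration", ylab = "global-best fitness", ...)
  invisible(x)
}

#' Exhaustive search over all nonempty masks (verification oracle)
#'
#' Evaluates all `2^d - 1` nonempty masks. Ties break to fewer set bits,
#' then to lexicographically smallest mask string. Dimension is capped at 16.
#'
#' @param fitness_fn function(mask) -> scalar.
#' @param d number of binary dimensions (<= 16).
#' @return list with `best_mask`, `best_fitness`, `fitness` (all values in
#'   enumeration order of the integer code 1..2^d-1, bit 1 = dimension 1).
#' @export
exhaustive_subset_search <- function(fitness_fn, d) {
  if (d > 16) stop("exhaustive search limited to d <= 16")
  stopifnot(d >= 1)
  codes <- seq_len(2^d - 1)
  masks <- lapply(codes, function(cd) as.integer(intToBits(cd))[1:d])
  fitness <- vapply(masks, fitness_fn, 0)
  bits <- vapply(masks, sum, 0L)
  keys <- vapply(masks, paste, "", collapse = "")
  ord <- order(-fitness, bits, keys)
  best <- ord[1]
  list(best_mask = masks[[best]], best_fitness = fitness[best],
       fitness = fitness)
}

#' Serialize a selection result as JSON
#'
#' @param sel a `qgh_selection`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  obj <- list(best_mask = as.integer(sel$best_mask),
              groups = sel$groups %||% names(sel$best_mask),
              best_fitness = sel$best_fitness,
              history = sel$history,
              evaluations = sel$evaluations,
              config = unclass(sel$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
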