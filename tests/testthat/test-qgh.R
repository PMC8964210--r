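bitcount_fitness <- function(mask) sum(mask)

test_that("beta schedule hits its endpoints", {
  cfg <- swarm_config(n_iterations = 50, beta_start = 1, beta_end = 0.5)
  expect_equal(beta_schedule(cfg, 0), 1)
  expect_equal(beta_schedule(cfg, 49), 0.5)
  expect_equal(beta_schedule(swarm_config(n_iterations = 1), 0), 1)
})

test_that("initialization seeds the all-ones particle and sets gbest", {
  cfg <- swarm_config(n_particles = 10, seed = 3)
  fit <- function(mask) sum(mask * seq_along(mask)) / 100
  st1 <- with_seed_test(42, qgh_init(fit, 6, cfg))
  st2 <- with_seed_test(42, qgh_init(fit, 6, cfg))
  expect_identical(st1, st2)
  expect_true(all(st1$masks[1, ] == 1))
  expect_true(all(rowSums(st1$masks) >= 1))
  expect_equal(st1$gbest_fitness, max(st1$pbest_fitness))
})

test_that("global best never decreases and history includes initialization", {
  set.seed(1)
  target <- c(1, 0, 1, 1, 0, 0, 1, 0)
  fit <- function(mask) mean(mask == target)
  res <- qgh_optimize(fit, 8, swarm_config(n_particles = 15,
                                           n_iterations = 30, seed = 5))
  expect_length(res$history, 31)
  expect_true(all(diff(res$history) >= 0))
  expect_equal(res$best_fitness, fit(res$best_mask))
})

test_that("the swarm finds a hidden target mask in most seeds", {
  succ <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    target <- sample(0:1, 8, replace = TRUE)
    if (!any(target)) target[1] <- 1
    fit <- function(mask) mean(mask == target)
    r <- qgh_optimize(fit, 8, swarm_config(n_particles = 20,
                                           n_iterations = 50, seed = s))
    succ <- succ + (r$best_fitness == 1)
  }
  expect_gte(succ, 9)
})

test_that("exhaustive search enumerates all masks with deterministic ties", {
  r <- exhaustive_subset_search(bitcount_fitness, 3)
  expect_identical(r$best_mask, c(1L, 1L, 1L))
  expect_length(r$fitness, 7)
  # constant fitness: ties break to fewest bits, then lexicographic order;
  # mask (1,0,0) encodes integer 1 but string "100" sorts after "001"
  r2 <- exhaustive_subset_search(function(mask) 1, 3)
  expect_equal(sum(r2$best_mask), 1)
  expect_identical(r2$best_mask, c(0L, 0L, 1L))
  expect_error(exhaustive_subset_search(bitcount_fitness, 17), "d <= 16")
})

test_that("exhaustive search matches a direct table scan", {
  set.seed(99)
  tab <- runif(2^10 - 1)
  fit <- function(mask) tab[sum(mask * 2^(seq_along(mask) - 1))]
  r <- exhaustive_subset_search(fit, 10)
  expect_equal(r$best_fitness, max(tab))
  expect_equal(sum(r$best_mask * 2^(0:9)), which.max(tab))
  expect_equal(r$fitness, tab)
})

test_that("subset fitness is deterministic, penalized and errors on empty masks", {
  pf <- planted_features(n_per_class = 10, n_classes = 3, informative = 2,
                         noise = 2, seed = 4)
  cfg <- fcm_config(n_clusters = 3, n_init = 1, max_iter = 40, tol = 1e-4,
                    seed = 2)
  f1 <- subset_fitness(c(1, 1, 0, 0), pf$x, pf$y, cfg, split_seed = 8,
                       lambda = 0)
  f2 <- subset_fitness(c(1, 1, 0, 0), pf$x, pf$y, cfg, split_seed = 8,
                       lambda = 0)
  expect_identical(f1, f2)
  # the penalty is pure arithmetic on top of the macro-F1
  f3 <- subset_fitness(c(1, 1, 0, 0), pf$x, pf$y, cfg, split_seed = 8,
                       lambda = 0.01)
  expect_equal(f3, f1 - 0.01 * 2 / 4)
  expect_error(subset_fitness(c(0, 0, 0, 0), pf$x, pf$y, cfg, 8),
               "at least one")
})

test_that("a perfectly separating feature yields fitness 1 at lambda 0", {
  y <- rep(c("a", "b", "c"), each = 10)
  x <- cbind(sep = rep(c(0, 10, 20), each = 10) + rnorm(30, 0, 0.01),
             junk = rnorm(30))
  f <- subset_fitness(c(1, 0), x, y,
                      fcm_config(n_clusters = 3, n_init = 2, seed = 1),
                      split_seed = 3, lambda = 0)
  expect_equal(f, 1.0)
})

test_that("selection beats noise-only subsets on planted data", {
  pf <- planted_features(n_per_class = 15, n_classes = 4, informative = 3,
                         noise = 3, seed = 6)
  cfg <- fcm_config(n_clusters = 4, n_init = 2, max_iter = 50, tol = 1e-4,
                    seed = 3)
  inf_mask <- c(1, 1, 1, 0, 0, 0)
  noise_mask <- c(0, 0, 0, 1, 1, 1)
  wins <- 0
  for (s in 1:10)
    wins <- wins + (subset_fitness(inf_mask, pf$x, pf$y, cfg, split_seed = s,
                                   lambda = 0) >
                    subset_fitness(noise_mask, pf$x, pf$y, cfg, split_seed = s,
                                   lambda = 0))
  expect_gte(wins, 9)
})

test_that("wrapper selection returns named masks and beats the all-ones baseline", {
  pf <- planted_features(n_per_class = 12, n_classes = 4, informative = 4,
                         noise = 4, seed = 2)
  swarm <- swarm_config(n_particles = 10, n_iterations = 10, seed = 2)
  fcm <- fcm_config(n_clusters = 4, n_init = 1, max_iter = 40, tol = 1e-4,
                    seed = 2)
  sel <- qgh_run(pf$x, pf$y, swarm = swarm, fcm = fcm)
  expect_s3_class(sel, "qgh_selection")
  expect_identical(names(sel$best_mask), colnames(pf$x))
  expect_length(sel$history, 11)
  split_seed <- cytoswarm:::derive_seed(swarm$seed, "fitness_split")
  f_all <- subset_fitness(rep(1, 8), pf$x, pf$y, fcm, split_seed,
                          lambda = swarm$lambda)
  expect_gte(sel$best_fitness, f_all)
  expect_error(qgh_run(pf$x, rep("a", nrow(pf$x))), "2 classes")
})
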