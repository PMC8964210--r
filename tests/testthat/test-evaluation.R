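test_that("confusion matrices count actual x predicted pairs", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(actual = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = "class")
  perfect <- confusion_matrix(c("A", "B", "B"), c("A", "B", "B"), c("A", "B"))
  expect_true(all(perfect == diag(c(1, 2))))
  empty <- confusion_matrix(character(0), character(0), c("A", "B"))
  expect_true(all(empty == 0))
  expect_error(confusion_matrix("A", "C", c("A", "B")), "class_names")
})

test_that("precision/recall/F1 match hand arithmetic", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  m <- prf(cm)
  expect_equal(m$per_class$precision, c(1, 0.5))
  expect_equal(m$per_class$recall, c(0.5, 1))
  expect_equal(m$per_class$f1, c(2 / 3, 2 / 3))
  expect_equal(unname(m$macro["f1"]), 2 / 3)
  perfect <- confusion_matrix(c("A", "B"), c("A", "B"), c("A", "B"))
  expect_true(all(unlist(prf(perfect)$macro) == 1))
  # class never predicted: precision/F1 0 with a warning, no exception
  cm2 <- confusion_matrix(c("A", "B"), c("A", "A"), c("A", "B"))
  expect_warning(m2 <- prf(cm2), "never predicted")
  expect_equal(m2$per_class$precision[2], 0)
  expect_equal(m2$per_class$f1[2], 0)
})

test_that("binary metrics reproduce the printed confusion-matrix arithmetic", {
  b <- binary_metrics(c(482, 30, 6, 382))
  expect_equal(unname(b["accuracy"]), 0.96)
  expect_equal(unname(b["error_rate"]), 0.04)
  expect_equal(unname(b["sensitivity"]), 482 / 512)
  expect_equal(unname(b["specificity"]), 382 / 388)
  # degenerate: everything positive and correct
  b2 <- binary_metrics(c(10, 0, 0, 0))
  expect_equal(unname(b2["accuracy"]), 1)
  expect_equal(unname(b2["sensitivity"]), 1)
  expect_true(is.na(b2["specificity"]))
})

test_that("the normal/cancerous collapse preserves totals and grouping", {
  cls <- cell_classes()
  set.seed(2)
  y <- sample(cls, 200, replace = TRUE)
  p <- sample(cls, 200, replace = TRUE)
  cm <- confusion_matrix(y, p, cls)
  cm2 <- collapse_to_binary(cm)
  expect_equal(sum(cm2), sum(cm))
  # all-correct 7-class matrix collapses to a diagonal 2x2
  cmd <- confusion_matrix(y, y, cls)
  d2 <- collapse_to_binary(cmd)
  expect_equal(unname(d2["cancerous", "normal"]), 0)
  expect_equal(unname(d2["normal", "cancerous"]), 0)
  # a cancerous sample predicted as a different cancerous class is a TP
  cm3 <- confusion_matrix("in_situ", "last_stage_dysplastic", cls)
  expect_equal(unname(collapse_to_binary(cm3)["cancerous", "cancerous"]), 1)
  bad <- cm
  rownames(bad)[1] <- colnames(bad)[1] <- "mystery"
  expect_error(collapse_to_binary(bad), "unknown class")
})

test_that("kappa matches hand arithmetic and its conventions", {
  cls <- c("A", "B")
  perfect <- confusion_matrix(c("A", "B", "B"), c("A", "B", "B"), cls)
  expect_equal(kappa_statistic(perfect), 1)
  # constant prediction on balanced binary truth: chance level, kappa 0
  const <- confusion_matrix(c("A", "A", "B", "B"), rep("A", 4), cls)
  expect_equal(kappa_statistic(const), 0)
  # printed 2x2 cells: kappa ~ 0.919
  t6 <- matrix(c(482, 30, 6, 382), 2, byrow = TRUE)
  expect_equal(kappa_statistic(t6), 0.9190583, tolerance = 1e-6)
  # single occupied class: expected agreement 1, kappa defined as 0
  one <- confusion_matrix(c("A", "A"), c("A", "A"), cls)
  expect_warning(k <- kappa_statistic(one), "expected agreement")
  expect_equal(k, 0)
})

test_that("membership MSE follows the Brier-style definition", {
  u <- rbind(c(1, 0), c(0, 1))
  expect_equal(mse_metric(u, c("A", "B"), c("A", "B")), 0)
  expect_equal(mse_metric(u, c("B", "A"), c("A", "B")), 1)
  uu <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(mse_metric(uu, c("A", "B"), c("A", "B")), 0.25)
})

test_that("stratified splits preserve proportions, disjointness and seeds", {
  y <- rep(c("a", "b"), each = 50)
  sp <- stratified_split(y, 0.3, seed = 4)
  expect_length(sp$test, 30)
  expect_length(sp$train, 70)
  expect_equal(as.vector(table(y[sp$test])), c(15, 15))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(stratified_split(y, 0.3, seed = 4), sp)
  expect_false(identical(stratified_split(y, 0.3, seed = 5)$test, sp$test))
  expect_error(stratified_split(c("a", "a", "b"), 0.3, 1), "fewer than 2")
})

test_that("stratified folds are balanced, exhaustive and class-aware", {
  y <- rep(letters[1:4], each = 30)
  fa <- stratified_folds(y, k = 12, seed = 2)
  expect_equal(as.vector(table(fa$folds)), rep(10, 12))
  for (cl in letters[1:4])
    expect_true(all(table(fa$folds[y == cl]) <= ceiling(30 / 12)))
  # random label vectors: partition is exhaustive and sizes differ <= 1
  for (s in 1:10) {
    set.seed(s)
    yy <- sample(letters[1:3], 40 + s, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    if (min(table(yy)) < 2) next
    k <- min(5, min(table(yy)))
    fs <- suppressWarnings(stratified_folds(yy, k = 5, seed = s))
    expect_equal(sort(unique(fs$folds)), seq_len(fs$k))
    expect_lte(diff(range(table(fs$folds))), 1)
  }
  expect_warning(stratified_folds(rep(c("a", "b"), c(30, 3)), k = 12, seed = 1),
                 "reducing k")
  expect_error(stratified_folds(rep("a", 5), k = 12), "n = 5")
})

test_that("cross-validation evaluates each sample exactly once", {
  pf <- planted_features(n_per_class = 12, n_classes = 3, informative = 3,
                         noise = 1, seed = 9)
  cv <- suppressWarnings(
    kfold_cv(pf$x, pf$y, k = 4, seed = 1,
             fcm = fcm_config(n_clusters = 3, n_init = 1, max_iter = 40,
                              tol = 1e-4)))
  expect_equal(cv$k, 4)
  expect_equal(sum(vapply(cv$reports, `[[`, 0, "n")), length(pf$y))
  f1 <- vapply(cv$reports, function(r) unname(r$macro["f1"]), 0)
  expect_equal(cv$summary$mean[cv$summary$metric == "macro_f1"], mean(f1))
})

test_that("eval_report assembles all metric families", {
  cls <- cell_classes()
  set.seed(3)
  y <- rep(cls, each = 5)
  p <- y; p[seq(1, 35, by = 7)] <- sample(cls, 5, replace = TRUE)
  u <- matrix(1 / 7, length(y), 7, dimnames = list(NULL, cls))
  r <- suppressWarnings(eval_report(y, p, cls, memberships = u, seed = 42))
  expect_s3_class(r, "eval_report")
  expect_equal(r$n, 35)
  expect_equal(r$accuracy, sum(diag(r$confusion)) / 35)
  expect_true(!is.null(r$binary))
  expect_equal(sum(r$binary_confusion), 35)
  expect_equal(r$mse, mse_metric(u, y, cls))
  expect_true(r$macro["f1"] >= 0 && r$macro["f1"] <= 1)
  expect_equal(r$seed, 42)
})
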