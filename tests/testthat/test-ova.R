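test_that("stratified split sizes follow the rounding contract", {
  labels <- rep(1:3, c(255, 124, 39))
  ids <- sprintf("S%03d", seq_along(labels))
  sp <- split_train_test(ids, labels, 0.1, seed = 1)
  expect_identical(length(sp$test), 42L)  # 26 + 12 + 4 per class
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  # per-class allocation
  tl <- labels[sp$test_idx]
  expect_identical(as.integer(table(tl)), c(26L, 12L, 4L))
  # two balanced classes of five: one test subject per class
  sp2 <- split_train_test(letters[1:10], rep(1:2, each = 5), 0.1, seed = 2)
  expect_identical(unname(tabulate(rep(1:2, each = 5)[sp2$test_idx])), c(1L, 1L))
  # determinism
  expect_identical(split_train_test(ids, labels, seed = 9),
                   split_train_test(ids, labels, seed = 9))
  expect_error(split_train_test(1:3, c(1, 1, 2)), "at least 2")
})

test_that("informedness matches its definition and balanced accuracy", {
  expect_equal(informedness(10, 0, 0, 20), 1)          # perfect
  expect_equal(informedness(10, 0, 20, 0), 0)          # constant positive
  expect_equal(informedness(8, 2, 6, 25), 0.8 + 25 / 31 - 1)
  expect_equal(informedness(rbind(c(8, 2), c(6, 25))), 0.8 + 25 / 31 - 1)
  expect_error(informedness(0, 0, 3, 4), "positive ground truth")
  expect_error(informedness(3, 4, 0, 0), "negative ground truth")
  # J = 2 * balanced accuracy - 1, exactly
  set.seed(70)
  for (rep in 1:10) {
    cc <- sample(1:30, 4, replace = TRUE)
    bal <- (cc[1] / (cc[1] + cc[2]) + cc[4] / (cc[4] + cc[3])) / 2
    expect_identical(informedness(cc[1], cc[2], cc[3], cc[4]), 2 * bal - 1)
  }
})

test_that("rank-based AUROC equals the pairwise probability oracle", {
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_lt(auroc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0.5)
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    scores <- sample(1:8, n, replace = TRUE)   # heavy ties
    pos <- runif(n) < 0.4
    if (sum(pos) == 0 || sum(!pos) == 0) next
    expect_equal(auroc(scores, pos), auroc_oracle(scores, pos),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auroc(1:3, c(TRUE, TRUE, TRUE))))
})

test_that("hyper-parameter search honours budget, seed and separability", {
  toy <- separable_toy(20, seed = 5)
  # budget 1: exactly one evaluated configuration returned
  t1 <- tune_hyperparameters(toy$x, toy$y, budget = 1, folds = 5, seed = 3)
  expect_identical(nrow(t1$trace), 1L)
  expect_identical(t1$best$kernel, t1$trace$kernel[1])
  # linearly separable data reaches perfect CV informedness within 25
  t2 <- tune_hyperparameters(toy$x, toy$y, budget = 25, folds = 5, seed = 4)
  expect_equal(t2$best$cv_informedness, 1)
  # identical seeds give identical trajectories
  t3 <- tune_hyperparameters(toy$x, toy$y, budget = 10, folds = 5, seed = 8)
  t4 <- tune_hyperparameters(toy$x, toy$y, budget = 10, folds = 5, seed = 8)
  expect_identical(t3$trace, t4$trace)
  expect_error(tune_hyperparameters(toy$x, toy$y, budget = 0), "budget")
})

test_that("one-against-all training produces one model per class", {
  set.seed(80)
  n <- 60
  x <- matrix(rnorm(n * 12), n, 12)
  labels <- rep(1:3, each = 20)
  for (cl in 1:3) x[labels == cl, cl] <- x[labels == cl, cl] + 6
  rankings <- lapply(1:3, function(cl)
    class_aware_ranking(x, labels, cl, m = 4, n_neighbors = 3))
  models <- suppressWarnings(
    train_ova(x, labels, rankings, budget = 8, folds = 4, seed = 2))
  expect_length(models, 3)
  for (i in 1:3) {
    expect_identical(models[[i]]$class_id, i)
    expect_identical(models[[i]]$feature_set, rankings[[i]]$selected)
  }
  # overlapping feature sets across models are allowed
  same <- lapply(1:3, function(cl)
    structure(list(class_id = cl, scores = numeric(12), order = 1:12,
                   selected = 1:4, m = 4L, n_class = 20L),
              class = "class_ranking"))
  m2 <- suppressWarnings(train_ova(x, labels, same, budget = 2, folds = 3, seed = 1))
  expect_length(m2, 3)
  expect_error(train_ova(x, labels, rankings[1:2], budget = 2), "cover")
})

test_that("holdout evaluation reports calibrated per-class metrics", {
  set.seed(81)
  n <- 80
  x <- matrix(rnorm(n * 10), n, 10)
  labels <- rep(1:2, each = 40)
  x[labels == 1, 1] <- x[labels == 1, 1] + 8
  # fixed feature sets containing the informative column: this block
  # tests the evaluation contract, not the selection stage
  rankings <- lapply(1:2, function(cl)
    structure(list(class_id = cl, scores = numeric(10), order = 1:10,
                   selected = 1:3, m = 3L, n_class = 40L),
              class = "class_ranking"))
  tr <- c(1:30, 41:70); te <- setdiff(1:n, tr)
  models <- suppressWarnings(
    train_ova(x[tr, ], labels[tr], rankings, budget = 6, folds = 4, seed = 5))
  ev <- evaluate_holdout(models, x[te, ], labels[te])
  expect_s3_class(ev, "eval_report")
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$error_rate, (ev$fp + ev$fn) / length(te))
  expect_true(all(ev$c_statistic > 0.9))    # separable construction
  expect_true(all(ev$informedness > 0.5))
  # a class absent from the test set is flagged, not an error
  ev2 <- evaluate_holdout(models, x[te, ][labels[te] == 1, ],
                          labels[te][labels[te] == 1])
  expect_true(all(ev2$flagged))
  expect_true(all(is.na(ev2$informedness)))
})

test_that("k-NN baseline honours the shared evaluation contract", {
  toy <- separable_toy(15, seed = 9)
  y <- ifelse(toy$y == "pos", 1L, 2L)
  # k = 1 evaluated on the training points: zero error
  ev <- baseline_knn(toy$x, y, feature_set = 1:2, k_neighbors = 1,
                     x_test = toy$x, labels_test = y, class_id = 1L)
  expect_equal(ev$error_rate, 0)
  expect_equal(ev$c_statistic, 1)
  expect_error(baseline_knn(toy$x, y, integer(0), 1, toy$x, y), "empty")
  expect_error(baseline_knn(toy$x, y, 1:2, 30, toy$x, y), "below the training size")
})
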