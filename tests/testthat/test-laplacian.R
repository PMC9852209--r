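test_that("similarity graph reproduces stated geometries", {
  # identical subjects: complete graph of unit weights
  X <- matrix(1, 3, 4)
  g <- build_similarity_graph(X, n_neighbors = 2)
  expect_equal(g$weights, matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(g$n_components, 1L)
  # two separated pairs on a line with k = 1: disconnected, flagged
  X2 <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_warning(g2 <- build_similarity_graph(X2, n_neighbors = 1),
                 "disconnected")
  expect_equal(g2$n_components, 2L)
  expect_equal(g2$weights[1, 3], 0)
  expect_gt(g2$weights[1, 2], 0)
  expect_error(build_similarity_graph(X2, n_neighbors = 4), "class size")
  expect_error(build_similarity_graph(X[1:2, , drop = FALSE], 1), "at least 3")
})

test_that("graph weights equal the brute-force pairwise computation", {
  set.seed(20)
  X <- matrix(rnorm(24), 6, 4)
  g <- build_similarity_graph(X, n_neighbors = 2)
  expect_equal(g$weights, knn_graph_oracle(X, 2), tolerance = 1e-12)
  expect_equal(g$degree, rowSums(g$weights))
  expect_equal(g$laplacian, diag(g$degree) - g$weights)
  # exact symmetry and zero diagonal
  expect_identical(g$weights, t(g$weights))
  expect_true(all(diag(g$weights) == 0))
})

test_that("laplacian score sentinels and exact cases", {
  set.seed(21)
  X <- matrix(rnorm(20), 5, 4)
  g <- build_similarity_graph(X, n_neighbors = 2)
  # constant feature: zero denominator -> Inf sentinel, flagged, no error
  s <- laplacian_score(rep(3, 5), g)
  expect_identical(as.numeric(s), Inf)
  expect_true(attr(s, "flagged"))
  # piecewise-constant feature on a two-component graph: perfect locality
  X2 <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  suppressWarnings(g2 <- build_similarity_graph(X2, n_neighbors = 1))
  s2 <- laplacian_score(c(2, 2, 7, 7), g2)
  expect_equal(as.numeric(s2), 0)
})

test_that("scores match the dense pairwise-identity oracle", {
  for (rep in 1:5) {
    set.seed(30 + rep)
    X <- matrix(rnorm(8 * 20), 8, 20)
    g <- build_similarity_graph(X, n_neighbors = 3)
    got <- vapply(seq_len(ncol(X)),
                  function(c) as.numeric(laplacian_score(X[, c], g)),
                  numeric(1))
    want <- apply(X, 2, laplacian_score_oracle, W = g$weights)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("smooth features on a path outrank shuffled copies", {
  X <- matrix(seq(0, 4), ncol = 1)  # 5 nodes along a line -> path graph
  g <- build_similarity_graph(X, n_neighbors = 1)
  monotone <- as.numeric(laplacian_score(0:4, g))
  shuffled <- as.numeric(laplacian_score(c(2, 4, 0, 3, 1), g))
  expect_lt(monotone, shuffled)
})

test_that("scores are invariant to affine feature rescaling", {
  set.seed(40)
  X <- matrix(rnorm(36), 6, 6)
  g <- build_similarity_graph(X, n_neighbors = 2)
  for (c in 1:6) {
    s0 <- as.numeric(laplacian_score(X[, c], g))
    s1 <- as.numeric(laplacian_score(-2.5 * X[, c] + 7, g))
    expect_equal(s0, s1, tolerance = 1e-9)
  }
})

test_that("class-aware ranking is order-stable and class-specific", {
  set.seed(50)
  X <- matrix(rnorm(10 * 30), 10, 30)
  labels <- rep(1:2, each = 5)
  r1 <- class_aware_ranking(X, labels, 1, m = 5, n_neighbors = 2)
  # permuting subjects leaves the ranking unchanged
  perm <- sample(10)
  r1p <- class_aware_ranking(X[perm, ], labels[perm], 1, m = 5, n_neighbors = 2)
  expect_identical(r1$selected, r1p$selected)
  expect_equal(r1$scores, r1p$scores)
  # m equal to the feature count selects everything
  rall <- class_aware_ranking(X, labels, 1, m = 30, n_neighbors = 2)
  expect_setequal(rall$selected, 1:30)
  expect_identical(rall$selected, rall$order[1:30])
  # identical subject rows in both classes: identical rankings
  X2 <- rbind(X[1:5, ], X[1:5, ])
  r_a <- class_aware_ranking(X2, labels, 1, m = 8, n_neighbors = 2)
  r_b <- class_aware_ranking(X2, labels, 2, m = 8, n_neighbors = 2)
  expect_identical(r_a$selected, r_b$selected)
  # zero-variance features carry the sentinel and rank last
  X3 <- cbind(X[1:5, ], 0)
  r3 <- class_aware_ranking(X3, rep(1, 5), 1, m = 31, n_neighbors = 2)
  expect_identical(r3$order[31], 31L)
  expect_identical(r3$scores[31], Inf)
  expect_error(class_aware_ranking(X, labels, 1, m = 31), "exceeds")
  expect_error(class_aware_ranking(X, c(rep(1, 2), rep(2, 8)), 1, m = 2), ">= 3")
})

test_that("score profile shares are monotone and complete", {
  set.seed(60)
  X <- matrix(rnorm(8 * 15), 8, 15)
  r <- class_aware_ranking(X, rep(1, 8), 1, m = 15, n_neighbors = 3)
  prof <- score_profile(r, c(3, 10, 15))
  expect_equal(prof$share[3], 1)
  expect_true(all(diff(prof$share) >= 0))
  expect_identical(nrow(score_profile(r, integer(0))), 0L)
  expect_error(score_profile(r, c(10, 3)), "sorted")
})
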