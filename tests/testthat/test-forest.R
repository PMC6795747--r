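test_that("train/test split is disjoint, exhaustive and ratio-sized", {
  labels <- rep(c(-1, 1), each = 5)
  sp <- split_train_test(labels, ratio = c(6, 4), stratified = FALSE, seed = 2)
  expect_length(sp$train, 6)
  expect_length(sp$test, 4)
  expect_setequal(c(sp$train, sp$test), 1:10)

  # stratified: per-class rounding gives 3 + 3 in train
  sp2 <- split_train_test(labels, stratified = TRUE, seed = 2)
  expect_equal(sum(labels[sp2$train] == -1), 3)
  expect_equal(sum(labels[sp2$train] == 1), 3)

  expect_identical(split_train_test(labels, seed = 7),
                   split_train_test(labels, seed = 7))
  expect_error(split_train_test(c(-1, -1, 1), stratified = TRUE), "class")
})

test_that("the default per-tree feature count is the rounded square root", {
  expect_equal(default_feature_count(3240), 57L)
  expect_equal(default_feature_count(1), 1L)
  expect_equal(default_feature_count(100), 10L)
})

test_that("tree input draws are bootstrap + distinct uniform features", {
  set.seed(5)
  inp <- draw_tree_inputs(20, 50, 7)
  expect_length(inp$sample_draw, 20)
  expect_true(all(inp$sample_draw %in% 1:20))
  expect_length(inp$feature_subset, 7)
  expect_false(anyDuplicated(inp$feature_subset) > 0)
  expect_error(draw_tree_inputs(10, 5, 6), "exceeds")
  # m = M: the full feature set
  expect_setequal(draw_tree_inputs(5, 8, 8)$feature_subset, 1:8)
  # inclusion frequency matches the binomial rate m/M over many trees
  set.seed(11)
  M <- 40; m <- 6; B <- 4000
  counts <- integer(M)
  for (b in seq_len(B)) {
    fs <- draw_tree_inputs(10, M, m)$feature_subset
    counts[fs] <- counts[fs] + 1L
  }
  p <- m / M
  se <- sqrt(p * (1 - p) / B)
  expect_true(all(abs(counts / B - p) < 3.5 * se))
})

test_that("CART handles pure and separable inputs", {
  # single-class input: one leaf
  tr <- fit_cart(matrix(rnorm(8), 4, 2), rep(-1, 4))
  expect_true(all(is.na(tr$feature)))
  expect_equal(predict(tr, matrix(rnorm(4), 2, 2)), c(-1, -1))
  # 1-D linearly separable: depth-1 tree, perfect training accuracy
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  tr <- fit_cart(x, y)
  expect_equal(sum(!is.na(tr$feature)), 1)  # one internal node
  expect_equal(predict(tr, x), y)
  expect_equal(tr$threshold[1], 6.5)
  expect_error(fit_cart(matrix(numeric(0), 0, 1), numeric(0)), "empty")
})

test_that("CART training accuracy matches the exhaustive stump oracle at depth 1", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    x <- matrix(sample(1:4, n * 2, TRUE) + rnorm(n * 2, 0, 0.01), n, 2)
    y <- sample(c(-1, 1), n, TRUE)
    if (length(unique(y)) == 1) next
    tr <- fit_cart(x, y, max_depth = 1)
    expect_equal(mean(predict(tr, x) == y), stump_oracle_accuracy(x, y),
                 label = sprintf("stump rep %d", rep))
  }
})

test_that("CART agrees with rpart on a separable two-feature problem", {
  skip_if_not_installed("rpart")
  set.seed(31)
  n <- 60
  x <- matrix(rnorm(2 * n), n, 2)
  y <- ifelse(x[, 1] + 0.2 * rnorm(n) > 0, 1, -1)
  tr <- fit_cart(x, y, min_leaf = 5, max_depth = 3)
  rp <- rpart::rpart(factor(y) ~ ., data.frame(x),
                     control = rpart::rpart.control(minsplit = 2,
                                                    minbucket = 5, cp = 0,
                                                    maxdepth = 3, xval = 0))
  rp_pred <- as.numeric(as.character(predict(rp, data.frame(x), type = "class")))
  agree <- mean(predict(tr, x) == rp_pred)
  expect_gt(agree, 0.95)
})

test_that("a one-tree forest predicts exactly as its tree", {
  set.seed(41)
  x <- matrix(rnorm(20 * 6), 20, 6)
  y <- ifelse(x[, 2] > 0, 1, -1)
  fit <- mrf(x, y, n_trees = 1, m = 6, seed = 3)
  tree_pred <- predict(fit$trees[[1]],
                       x[, fit$feature_subsets[[1]], drop = FALSE])
  expect_equal(as.numeric(suppressMessages(predict(fit, x))), tree_pred)
})

test_that("majority voting takes the sign of the vote sum, ties to -1", {
  votes <- rbind(c(-1, 1, 1), c(-1, 1, -1), c(1, 1, -1))
  s <- colSums(votes)
  expect_equal(ifelse(s > 0, 1, -1), c(-1, 1, -1))
  # tie on an even forest resolves to -1 with a logged event
  set.seed(2)
  x <- matrix(rnorm(8 * 4), 8, 4)
  y <- rep(c(-1, 1), 4)
  fit <- mrf(x, y, n_trees = 2, m = 2, seed = 10)
  fit$trees[[1]] <- structure(list(feature = NA_integer_,
                                   threshold = NA_real_, left = NA_integer_,
                                   right = NA_integer_, label = -1),
                              class = "cart_tree")
  fit$trees[[2]] <- structure(list(feature = NA_integer_,
                                   threshold = NA_real_, left = NA_integer_,
                                   right = NA_integer_, label = 1),
                              class = "cart_tree")
  expect_message(pred <- predict(fit, x), "tie")
  expect_equal(as.numeric(pred), rep(-1, 8))
  expect_equal(attr(pred, "ties"), 8)
})

test_that("tree order never changes a majority-vote prediction", {
  set.seed(53)
  x <- matrix(rnorm(30 * 10), 30, 10)
  y <- ifelse(x[, 1] - x[, 3] > 0, 1, -1)
  fit <- mrf(x, y, n_trees = 11, m = 4, seed = 5)
  xnew <- matrix(rnorm(12 * 10), 12, 10)
  p1 <- suppressMessages(predict(fit, xnew))
  perm <- sample(11)
  fit2 <- fit
  fit2$trees <- fit$trees[perm]
  fit2$feature_subsets <- fit$feature_subsets[perm]
  p2 <- suppressMessages(predict(fit2, xnew))
  expect_equal(as.numeric(p1), as.numeric(p2))
})

test_that("accuracy is the fraction of correct predictions", {
  expect_equal(accuracy(c(1, 1, -1), c(1, 1, -1)), 1.0)
  expect_equal(accuracy(c(1, 1), c(-1, -1)), 0.0)
  expect_equal(accuracy(c(rep(1, 25), rep(-1, 5)), rep(1, 30)), 25 / 30)
  expect_error(accuracy(1, c(1, -1)), "length")
})

test_that("the default scan grid has 60 points and scans are deterministic", {
  expect_length(tree_count_grid(), 60)
  expect_equal(tree_count_grid()[c(1, 60)], c(10L, 600L))
  expect_length(tree_count_grid(10, 10, 10), 1)
  expect_error(tree_count_grid(5, 100, 10))

  set.seed(61)
  x <- matrix(rnorm(20 * 8), 20, 8)
  y <- ifelse(x[, 1] > 0, 1, -1)
  sp <- split_train_test(y, seed = 1)
  c1 <- scan_tree_counts(x[sp$train, ], y[sp$train], x[sp$test, ], y[sp$test],
                         grid = c(5L, 10L, 15L), m = 3, seed = 9)
  c2 <- scan_tree_counts(x[sp$train, ], y[sp$train], x[sp$test, ], y[sp$test],
                         grid = c(5L, 10L, 15L), m = 3, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$accuracy >= 0 & c1$accuracy <= 1))
})

test_that("stability selection finds the start of the plateau", {
  mk <- function(acc) structure(data.frame(n_trees = seq(10, by = 10,
                                                         length.out = length(acc)),
                                           accuracy = acc),
                                class = c("accuracy_curve", "data.frame"))
  # constant curve: immediately stable
  expect_equal(as.integer(select_stable_count(mk(rep(0.8, 12)))), 10L)
  # step curve: returns the step point
  step <- mk(c(rep(0.5, 6), rep(0.8, 8)))
  expect_equal(as.integer(select_stable_count(step)), 70L)
  # no stable region: grid maximum with a warning
  wild <- mk(c(0.2, 0.9, 0.1, 0.95, 0.15, 0.9, 0.2, 0.9, 0.1, 0.85))
  expect_warning(res <- select_stable_count(wild), "no stable region")
  expect_equal(as.integer(res), 100L)

  # noisy monotone curves with a plateau: the pick lands on the plateau
  set.seed(71)
  on_plateau <- vapply(1:100, function(i) {
    k <- sample(5:12, 1)
    acc <- c(seq(0.5, 0.85, length.out = k), rep(0.85, 20 - k)) +
      rnorm(20, 0, 0.004)
    a <- select_stable_count(mk(acc))
    idx <- match(as.integer(a), mk(acc)$n_trees)
    abs(mean(acc[idx:20]) - 0.85) < 0.02
  }, logical(1))
  expect_gte(mean(on_plateau), 0.95)
})
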