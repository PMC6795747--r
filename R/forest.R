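#' Stratified train/test split
#'
#' Partitions subjects into disjoint, exhaustive train and test sets at the
#' given ratio (default 6:4). Under stratification the train size is rounded
#' per class; otherwise over all subjects.
#'
#' @param labels numeric vector of labels in `{-1, +1}`.
#' @param ratio length-2 positive vector, train:test (default `c(6, 4)`).
#' @param stratified split within each class?
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, ratio = c(6, 4), stratified = TRUE,
                             seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio > 0), all(labels %in% c(-1, 1)))
  frac <- ratio[1] / sum(ratio)
  set.seed(seed)
  n <- length(labels)
  if (stratified) {
    train <- integer(0)
    for (cl in c(-1, 1)) {
      idx <- which(labels == cl)
      if (length(idx) < 2) stop("need >= 2 subjects per class to split")
      k <- round(frac * length(idx))
      if (k == 0 || k == length(idx)) {
        stop("class ", cl, " would be absent from one side of the split")
      }
      train <- c(train, sort(sample(idx, k)))
    }
    train <- sort(train)
  } else {
    k <- round(frac * n)
    if (k == 0 || k == n) stop("degenerate split: one side would be empty")
    train <- sort(sample.int(n, k))
  }
  test <- setdiff(seq_len(n), train)
  if (stratified &&
      (!all(c(-1, 1) %in% labels[train]) || !all(c(-1, 1) %in% labels[test]))) {
    stop("a class is absent from one side of the stratified split")
  }
  list(train = train, test = test)
}

#' Default per-tree feature-subset size
#'
#' The nearest integer to the square root of the total feature count M (so
#' M = 3240 fusion features gives 57 features per tree).
#'
#' @param M total feature count (>= 1).
#' @return Integer subset size, at least 1.
#' @export
default_feature_count <- function(M) {
  stopifnot(M >= 1)
  max(1L, as.integer(round(sqrt(M))))
}

#' Draw the random inputs of one tree
#'
#' A bootstrap sample (with replacement, full training size) of the training
#' subjects, and `m` distinct features drawn uniformly without replacement.
#' Draws consume the current RNG stream so that successive trees get
#' independent inputs under one forest seed.
#'
#' @param n_train training-set size.
#' @param M total feature count.
#' @param m per-tree feature-subset size (`m <= M`).
#' @param sample_mode `"bootstrap"` (default) or `"subsample"` (without
#'   replacement, 63.2% of the training size, the expected bootstrap support).
#' @return List with `sample_draw` (indices into the training set) and
#'   `feature_subset` (sorted feature column indices).
#' @export
draw_tree_inputs <- function(n_train, M, m,
                             sample_mode = c("bootstrap", "subsample")) {
  sample_mode <- match.arg(sample_mode)
  if (m > M) stop("m (", m, ") exceeds the number of features (", M, ")")
  draw <- if (sample_mode == "bootstrap") {
    sample.int(n_train, n_train, replace = TRUE)
  } else {
    sort(sample.int(n_train, max(1L, round(0.632 * n_train))))
  }
  list(sample_draw = draw, feature_subset = sort(sample.int(M, m)))
}

#' Fit a multimodal random forest
#'
#' A random-subspace ensemble of CART trees over fusion features: each tree
#' draws its own bootstrap sample of training subjects and its own random
#' subset of `m` features (once per tree, not per node), and is grown to
#' purity. Prediction is by majority vote with ties going to -1.
#'
#' @param x numeric matrix (training subjects x features).
#' @param y labels in `{-1, +1}`.
#' @param n_trees number of trees `a`.
#' @param m per-tree feature-subset size; default `round(sqrt(M))`.
#' @param seed forest RNG seed.
#' @param sample_mode passed to [draw_tree_inputs()].
#' @param min_leaf,max_depth CART stopping controls (defaults grow to purity).
#' @return Object of class `mrf`: trees, their feature subsets and sample
#'   draws, `m`, and the seed.
#' @export
mrf <- function(x, y, n_trees, m = default_feature_count(ncol(x)), seed = 1L,
                sample_mode = c("bootstrap", "subsample"),
                min_leaf = 1L, max_depth = Inf) {
  x <- as.matrix(x)
  sample_mode <- match.arg(sample_mode)
  stopifnot(n_trees >= 1, nrow(x) == length(y), all(y %in% c(-1, 1)))
  set.seed(seed)
  trees <- vector("list", n_trees)
  subsets <- vector("list", n_trees)
  draws <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    inp <- draw_tree_inputs(nrow(x), ncol(x), m, sample_mode)
    trees[[t]] <- fit_cart(x[inp$sample_draw, inp$feature_subset, drop = FALSE],
                           y[inp$sample_draw], min_leaf, max_depth)
    subsets[[t]] <- inp$feature_subset
    draws[[t]] <- inp$sample_draw
  }
  structure(list(trees = trees, feature_subsets = subsets,
                 sample_draws = draws, m = as.integer(m),
                 n_features = ncol(x), seed = as.integer(seed)),
            class = "mrf")
}

#' @export
print.mrf <- function(x, ...) {
  cat(sprintf("<mrf> %d trees, m = %d of %d features\n",
              length(x$trees), x$m, x$n_features))
  invisible(x)
}

#' Per-tree votes on new samples
#'
#' @param model an [mrf()] forest.
#' @param newdata numeric matrix with the full feature columns.
#' @return Matrix (trees x samples) of votes in `{-1, +1}`.
#' @export
mrf_votes <- function(model, newdata) {
  stopifnot(inherits(model, "mrf"))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != model$n_features) {
    stop("newdata has ", ncol(newdata), " features; forest expects ",
         model$n_features)
  }
  t(vapply(seq_along(model$trees), function(t) {
    predict(model$trees[[t]], newdata[, model$feature_subsets[[t]], drop = FALSE])
  }, numeric(nrow(newdata))))
}

#' Majority-vote prediction
#'
#' The sign of the vote sum over all trees; an exact tie predicts -1 (the
#' patient class) and is counted in the `ties` attribute.
#'
#' @param object an [mrf()] forest.
#' @param newdata numeric matrix (samples x full feature set).
#' @param ... unused.
#' @return Numeric label vector; attribute `ties` gives the tie count.
#' @export
predict.mrf <- function(object, newdata, ...) {
  votes <- mrf_votes(object, newdata)
  s <- colSums(votes)
  pred <- ifelse(s > 0, 1, -1)
  n_ties <- sum(s == 0)
  if (n_ties > 0) message(n_ties, " majority-vote tie(s) resolved to -1")
  structure(pred, ties = n_ties)
}

#' Classification accuracy
#'
#' Fraction of correct predictions: the sum of per-subject indicators over
#' the test-set size.
#'
#' @param predictions,truth equal-length label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth differ in length")
  }
  stopifnot(length(truth) >= 1)
  sum(as.numeric(predictions) == as.numeric(truth)) / length(truth)
}

#' Tree-count search grid
#'
#' @param from,to,step arithmetic sequence of forest sizes; the default
#'   10, 20, ..., 600 searches the interval up to 600 trees in steps of 10
#'   (an empty forest is undefined, so the grid starts at `step`).
#' @return Strictly increasing integer vector.
#' @export
tree_count_grid <- function(from = 10L, to = 600L, step = 10L) {
  stopifnot(step >= 1, from >= step, to >= from)
  as.integer(seq(from, to, by = step))
}

#' Accuracy over a grid of forest sizes
#'
#' Trains one forest per grid point (with a deterministic per-point seed
#' derived from `seed`) and records its majority-vote accuracy on the test
#' set.
#'
#' @param x_train,y_train,x_test,y_test split fusion-feature data.
#' @param grid increasing forest sizes, see [tree_count_grid()].
#' @param m per-tree feature count.
#' @param seed master seed for the scan.
#' @param ... passed to [mrf()].
#' @return Object of class `accuracy_curve`: data.frame (`n_trees`,
#'   `accuracy`).
#' @export
scan_tree_counts <- function(x_train, y_train, x_test, y_test,
                             grid = tree_count_grid(),
                             m = default_feature_count(ncol(x_train)),
                             seed = 1L, ...) {
  stopifnot(length(grid) >= 1, all(diff(grid) > 0))
  set.seed(seed)
  point_seeds <- sample.int(.Machine$integer.max, length(grid))
  acc <- vapply(seq_along(grid), function(i) {
    fit <- mrf(x_train, y_train, n_trees = grid[i], m = m,
               seed = point_seeds[i], ...)
    accuracy(suppressMessages(predict(fit, x_test)), y_test)
  }, numeric(1))
  structure(data.frame(n_trees = as.integer(grid), accuracy = acc),
            class = c("accuracy_curve", "data.frame"))
}

#' Select the stable forest size from an accuracy curve
#'
#' The forest-size/accuracy curve fluctuates before settling on a plateau;
#' isolated spikes above the plateau are random fluctuations, not usable
#' optima. The stable size is the smallest grid point from which every
#' subsequent rolling-window mean stays within `epsilon` of the plateau mean
#' (the mean of the final window).
#'
#' @param curve an `accuracy_curve`.
#' @param window rolling-window width in grid points.
#' @param epsilon allowed deviation from the plateau mean.
#' @return The chosen tree count (integer); attribute `stable` is FALSE when
#'   no point qualifies, in which case the grid maximum is returned with a
#'   warning.
#' @export
select_stable_count <- function(curve, window = 5L, epsilon = 0.02) {
  stopifnot(inherits(curve, "accuracy_curve"), nrow(curve) >= window)
  acc <- curve$accuracy
  n <- length(acc)
  roll <- vapply(seq_len(n - window + 1),
                 function(j) mean(acc[j:(j + window - 1)]), numeric(1))
  plateau <- roll[length(roll)]
  # the tail must itself be flat for a plateau to exist at all; individual
  # grid points may wiggle at the test-set granularity, hence the wider band
  if (max(abs(acc[(n - window + 1):n] - plateau)) >= 5 * epsilon) {
    warning("no stable region found; returning the grid maximum")
    return(structure(curve$n_trees[n], stable = FALSE))
  }
  ok <- abs(roll - plateau) < epsilon
  # smallest start index from which every later window stays near the plateau
  good_from <- rev(cumprod(rev(ok))) == 1
  structure(curve$n_trees[which(good_from)[1]], stable = TRUE,
            plateau_mean = plateau)
}
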