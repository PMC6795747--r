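#' Rank trees by individual classification performance
#'
#' Scores every tree of the forest on the evaluation set and keeps the
#' `top_k` best; ties at the cutoff are broken by tree index (lower first).
#'
#' @param model an [mrf()] forest.
#' @param x_eval,y_eval evaluation data (full feature columns) and labels.
#' @param top_k number of trees to retain (default 100).
#' @return Integer vector of retained tree indices; attribute `accuracy`
#'   holds every tree's accuracy.
#' @export
rank_trees <- function(model, x_eval, y_eval, top_k = 100L) {
  stopifnot(inherits(model, "mrf"))
  if (top_k > length(model$trees)) {
    stop("top_k (", top_k, ") exceeds the forest size (", length(model$trees), ")")
  }
  votes <- mrf_votes(model, x_eval)
  acc <- rowMeans(votes == matrix(y_eval, nrow(votes), ncol(votes), byrow = TRUE))
  ord <- order(-acc, seq_along(acc))
  structure(ord[seq_len(top_k)], accuracy = acc)
}

#' Fusion-feature frequencies among retained trees
#'
#' Counts, for every feature, the number of retained trees whose random
#' feature subset contains it; sorts descending with ties broken by canonical
#' feature order (column index); keeps the first `top_b`.
#'
#' @param model an [mrf()] forest.
#' @param retained retained tree indices from [rank_trees()].
#' @param top_b number of high-frequency features to keep (default 400).
#' @return data.frame of class `feature_frequency_table` with columns
#'   `feature` (column index), `count`, `rank`.
#' @export
feature_frequencies <- function(model, retained = seq_along(model$trees),
                                top_b = 400L) {
  stopifnot(inherits(model, "mrf"), length(retained) >= 1)
  counts <- tabulate(unlist(model$feature_subsets[retained]),
                     nbins = model$n_features)
  feat <- which(counts > 0)
  ord <- feat[order(-counts[feat], feat)]
  if (top_b > length(ord)) {
    warning("only ", length(ord), " distinct features occur in the retained ",
            "trees; keeping all of them")
    top_b <- length(ord)
  }
  kept <- ord[seq_len(top_b)]
  structure(data.frame(feature = kept, count = counts[kept],
                       rank = seq_along(kept)),
            class = c("feature_frequency_table", "data.frame"))
}

#' Nested feature-subset sizes
#'
#' Prefix subsets of the frequency ranking, sizes `size_min`,
#' `size_min + step`, ..., `size_max` (defaults 70, 75, ..., 400 give 67
#' subsets); each subset contains all smaller ones by construction.
#'
#' @param size_min,size_max,step arithmetic size sequence.
#' @param n_available number of ranked features available (`>= size_max`).
#' @return Strictly increasing integer vector of subset sizes.
#' @export
nested_subset_sizes <- function(size_min = 70L, size_max = 400L, step = 5L,
                                n_available = size_max) {
  stopifnot(step >= 1, size_min >= 1)
  if (size_min > size_max) stop("size_min exceeds size_max")
  if (size_max > n_available) {
    stop("size_max (", size_max, ") exceeds the ", n_available,
         " available ranked features")
  }
  as.integer(seq(size_min, size_max, by = step))
}

#' Evaluate nested feature subsets with freshly trained forests
#'
#' For each subset size s, restricts the fusion matrix to the first s
#' features of the frequency ranking, retrains a forest (per-tree feature
#' count recomputed as `round(sqrt(s))`, capped at s) with a deterministic
#' per-subset seed, and records the majority-vote accuracy on the held-out
#' test split.
#'
#' @param freq_table a `feature_frequency_table`.
#' @param x_train,y_train,x_test,y_test split fusion-feature data (full
#'   feature columns).
#' @param sizes subset sizes from [nested_subset_sizes()].
#' @param n_trees forest size per subset.
#' @param seed master seed for the scan.
#' @param ... passed to [mrf()].
#' @return Object of class `subset_scan`: data.frame (`size`, `accuracy`),
#'   with the ranked feature indices in attribute `ranking`.
#' @export
evaluate_subsets <- function(freq_table, x_train, y_train, x_test, y_test,
                             sizes, n_trees = 100L, seed = 1L, ...) {
  stopifnot(inherits(freq_table, "feature_frequency_table"),
            length(sizes) >= 1, all(diff(sizes) > 0) || length(sizes) == 1)
  if (max(sizes) > nrow(freq_table)) {
    stop("a subset is larger than the ranked feature count")
  }
  set.seed(seed)
  subset_seeds <- sample.int(.Machine$integer.max, length(sizes))
  acc <- vapply(seq_along(sizes), function(i) {
    cols <- freq_table$feature[seq_len(sizes[i])]
    m <- min(default_feature_count(sizes[i]), sizes[i])
    fit <- mrf(x_train[, cols, drop = FALSE], y_train, n_trees = n_trees,
               m = m, seed = subset_seeds[i], ...)
    accuracy(suppressMessages(predict(fit, x_test[, cols, drop = FALSE])),
             y_test)
  }, numeric(1))
  structure(data.frame(size = as.integer(sizes), accuracy = acc),
            class = c("subset_scan", "data.frame"),
            ranking = freq_table$feature)
}

#' Select the optimal fusion-feature subset
#'
#' The smallest subset size attaining the maximum accuracy of the scan
#' (parsimony tie-break); the optimal subset is that prefix of the frequency
#' ranking.
#'
#' @param scan a `subset_scan` from [evaluate_subsets()].
#' @return List with `size`, `accuracy` and `features` (ranked column
#'   indices of the optimal subset).
#' @export
select_optimal <- function(scan) {
  stopifnot(inherits(scan, "subset_scan"), nrow(scan) >= 1)
  i <- which.max(scan$accuracy)   # first max = smallest size
  ranking <- attr(scan, "ranking")
  list(size = scan$size[i], accuracy = scan$accuracy[i],
       features = ranking[seq_len(scan$size[i])])
}
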