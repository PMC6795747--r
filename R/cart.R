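# Classification trees (CART): greedy binary splits minimizing weighted Gini
# impurity, candidate thresholds at midpoints between consecutive distinct
# sorted feature values, grown to purity unless capped. Binary labels -1/+1;
# all ties resolve to -1.

gini_impurity <- function(n_neg, n_tot) {
  p <- n_neg / n_tot
  1 - p^2 - (1 - p)^2
}

# Best split over all features of x: minimal weighted child impurity.
# Ties: smaller feature index, then smaller threshold. NULL if no split
# reduces impurity.
best_split <- function(x, y, min_leaf = 1L) {
  n <- length(y)
  parent <- gini_impurity(sum(y == -1), n)
  best <- NULL
  best_imp <- parent - 1e-12
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    ord <- order(xj)
    xs <- xj[ord]
    cum_neg <- cumsum(y[ord] == -1)
    i <- seq_len(n - 1)
    valid <- xs[i] < xs[i + 1] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(valid)) next
    i <- i[valid]
    nl <- i
    nr <- n - i
    neg_l <- cum_neg[i]
    neg_r <- cum_neg[n] - neg_l
    imp <- (nl * gini_impurity(neg_l, nl) + nr * gini_impurity(neg_r, nr)) / n
    k <- which.min(imp)           # first minimum = smallest threshold
    if (imp[k] < best_imp) {
      best_imp <- imp[k]
      best <- list(feature = j, threshold = (xs[i[k]] + xs[i[k] + 1]) / 2)
    }
  }
  best
}

leaf_label <- function(y) if (sum(y == -1) >= sum(y == 1)) -1 else 1

#' Fit a classification tree
#'
#' Greedy CART on a numeric feature matrix with labels in `{-1, +1}`.
#' Splits minimize weighted Gini impurity over midpoint thresholds and stop
#' at pure nodes or when no split reduces impurity; leaf labels are the
#' majority class with ties going to -1.
#'
#' @param x numeric matrix (samples x features).
#' @param y labels in `{-1, +1}`.
#' @param min_leaf minimum samples per child node.
#' @param max_depth depth cap (root = depth 0); `Inf` grows to purity.
#' @return Object of class `cart_tree`: a node table with columns `feature`,
#'   `threshold`, `left`, `right`, `label` (non-NA only at leaves; `left` is
#'   taken when `x[, feature] <= threshold`).
#' @export
fit_cart <- function(x, y, min_leaf = 1L, max_depth = Inf) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty sample set")
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  nodes <- new.env()
  nodes$feature <- integer(0)
  nodes$threshold <- numeric(0)
  nodes$left <- integer(0)
  nodes$right <- integer(0)
  nodes$label <- numeric(0)

  add_node <- function() {
    i <- length(nodes$feature) + 1L
    nodes$feature[i] <- NA_integer_
    nodes$threshold[i] <- NA_real_
    nodes$left[i] <- NA_integer_
    nodes$right[i] <- NA_integer_
    nodes$label[i] <- NA_real_
    i
  }

  grow <- function(idx, depth) {
    me <- add_node()
    ys <- y[idx]
    sp <- if (length(unique(ys)) > 1 && depth < max_depth) {
      best_split(x[idx, , drop = FALSE], ys, min_leaf)
    } else NULL
    if (is.null(sp)) {
      nodes$label[me] <- leaf_label(ys)
      return(me)
    }
    go_left <- x[idx, sp$feature] <= sp$threshold
    l <- grow(idx[go_left], depth + 1)
    r <- grow(idx[!go_left], depth + 1)
    nodes$feature[me] <- sp$feature
    nodes$threshold[me] <- sp$threshold
    nodes$left[me] <- l
    nodes$right[me] <- r
    me
  }
  grow(seq_along(y), 0)
  structure(list(feature = nodes$feature, threshold = nodes$threshold,
                 left = nodes$left, right = nodes$right, label = nodes$label),
            class = "cart_tree")
}

#' Predict with a classification tree
#'
#' @param object a `cart_tree`.
#' @param newdata numeric matrix with the same feature columns the tree was
#'   fitted on.
#' @param ... unused.
#' @return Numeric vector of labels in `{-1, +1}`.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- numeric(nrow(newdata))
  for (s in seq_len(nrow(newdata))) {
    i <- 1L
    while (is.na(object$label[i])) {
      i <- if (newdata[s, object$feature[i]] <= object$threshold[i]) {
        object$left[i]
      } else {
        object$right[i]
      }
    }
    out[s] <- object$label[i]
  }
  out
}
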