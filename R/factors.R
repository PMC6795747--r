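#' Split optimal fusion features into region and gene rankings
#'
#' Every fusion feature names one brain region and one gene; counting how
#' often each region (and each gene) appears in the optimal subset ranks the
#' factors by their association with the disease. Both rankings are sorted
#' by descending count with ties broken by name, and each conserves the
#' subset size as its column sum.
#'
#' @param features data.frame with columns `region` and `gene` (e.g. rows of
#'   a fusion matrix's `features` frame, or [parse_feature_id()] output).
#' @return Object of class `factor_ranking`: list of two data.frames
#'   `regions` (`region`, `count`) and `genes` (`gene`, `count`).
#' @export
extract_factors <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) >= 1,
            all(c("region", "gene") %in% names(features)))
  rank_one <- function(v, nm) {
    tab <- table(v)
    df <- data.frame(name = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$name), , drop = FALSE]
    rownames(df) <- NULL
    names(df)[1] <- nm
    df
  }
  structure(list(regions = rank_one(features$region, "region"),
                 genes = rank_one(features$gene, "gene")),
            class = "factor_ranking")
}

#' @export
print.factor_ranking <- function(x, ...) {
  cat("<factor_ranking> top regions:\n")
  print(utils::head(x$regions, 5))
  cat("top genes:\n")
  print(utils::head(x$genes, 5))
  invisible(x)
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability that two fixed-size sets drawn from a common
#' universe of N features share at least `x` elements:
#' P(X >= x) with X ~ Hypergeometric(N, K, n).
#'
#' @param N universe size.
#' @param K,n sizes of the two sets.
#' @param x observed overlap.
#' @return p-value in (0, 1].
#' @export
hypergeometric_overlap <- function(N, K, n, x) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(x) == 1)
  if (!(x >= 0 && K <= N && n <= N && x <= min(K, n))) {
    stop("inconsistent counts: need 0 <= x <= min(K, n) <= N")
  }
  if (x == 0) return(1)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Welch t-test feature filter (unimodal baseline)
#'
#' Per-feature Welch two-sample t statistics between the two label groups,
#' used as the classical feature-screening baseline against which the
#' forest-frequency selection is compared. Selection is by the `top_k`
#' largest |t| or by p < `alpha` (optionally Bonferroni-adjusted); ties break
#' by feature index. If both within-class variances vanish, the statistic is
#' 0 for equal means and infinite (ranked first) for differing means.
#'
#' @param x numeric matrix (subjects x features).
#' @param labels labels in `{-1, +1}`, at least two subjects per class.
#' @param top_k keep this many features by |t| (exclusive with `alpha`).
#' @param alpha significance level for p-value selection.
#' @param adjust `"none"` or `"bonferroni"` (applies to `alpha` selection).
#' @return data.frame (`feature`, `t`, `p`, `selected`) in feature order.
#' @export
ttest_feature_filter <- function(x, labels, top_k = NULL, alpha = NULL,
                                 adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  x <- as.matrix(x)
  stopifnot(all(labels %in% c(-1, 1)),
            sum(labels == -1) >= 2, sum(labels == 1) >= 2)
  if (is.null(top_k) == is.null(alpha)) {
    stop("give exactly one of top_k or alpha")
  }
  g1 <- labels == -1
  n1 <- sum(g1)
  n2 <- sum(!g1)
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(x[!g1, , drop = FALSE], 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                  ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df), 0)
  out <- data.frame(feature = seq_len(ncol(x)), t = tstat, p = p)
  if (!is.null(top_k)) {
    stopifnot(top_k >= 1, top_k <= ncol(x))
    ord <- order(-abs(out$t), out$feature)
    out$selected <- out$feature %in% ord[seq_len(top_k)]
  } else {
    cut <- if (adjust == "bonferroni") alpha / ncol(x) else alpha
    out$selected <- out$p < cut
  }
  out
}
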