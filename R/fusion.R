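#' The 90 cerebral regions of the AAL parcellation
#'
#' Region names of the Automated Anatomical Labeling atlas restricted to its
#' 90 cerebral regions (odd indices left hemisphere, even right), the default
#' parcellation for the ROI time-series modality.
#'
#' @return Character vector of length 90.
#' @export
aal90_regions <- function() {
  base <- c("Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
            "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
            "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area",
            "Olfactory", "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus",
            "Insula", "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post",
            "Hippocampus", "ParaHippocampal", "Amygdala", "Calcarine",
            "Cuneus", "Lingual", "Occipital_Sup", "Occipital_Mid",
            "Occipital_Inf", "Fusiform", "Postcentral", "Parietal_Sup",
            "Parietal_Inf", "SupraMarginal", "Angular", "Precuneus",
            "Paracentral_Lobule", "Caudate", "Putamen", "Pallidum",
            "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
            "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  paste(rep(base, each = 2), c("L", "R"), sep = "_")
}

#' ROI time-series set
#'
#' @param subject_ids character vector.
#' @param region_names unique region names (length R).
#' @param series numeric array subjects x R x T.
#' @return Object of class `roi_series`.
#' @export
roi_series <- function(subject_ids, region_names, series) {
  subject_ids <- as.character(subject_ids)
  stopifnot(length(region_names) >= 1, !anyDuplicated(region_names),
            is.array(series), length(dim(series)) == 3,
            dim(series)[1] == length(subject_ids),
            dim(series)[2] == length(region_names))
  dimnames(series) <- list(subject_ids, region_names, NULL)
  structure(list(subject_ids = subject_ids,
                 region_names = as.character(region_names),
                 series = series),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf("<roi_series> %d subjects x %d regions x %d timepoints\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Truncate every region time series to the gene segment length
#'
#' Keeps the first `L` timepoints of every region series so that the imaging
#' modality matches the encoded gene sequences in length.
#'
#' @param series_set a [roi_series()].
#' @param L target length.
#' @return A [roi_series()] with T = L.
#' @export
truncate_series <- function(series_set, L) {
  stopifnot(inherits(series_set, "roi_series"))
  T_len <- dim(series_set$series)[3]
  if (T_len < L) {
    stop(sprintf("series of subject '%s' has %d timepoints, fewer than L = %d",
                 series_set$subject_ids[1], T_len, L))
  }
  roi_series(series_set$subject_ids, series_set$region_names,
             series_set$series[, , seq_len(L), drop = FALSE])
}

#' Pearson correlation with a degenerate-input guard
#'
#' Sample Pearson coefficient of two equal-length vectors. If either vector
#' has zero variance the coefficient is undefined; it is reported as 0 with a
#' warning so that downstream feature matrices keep a fixed shape.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A number in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; degenerate correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Canonical fusion-feature identifiers
#'
#' Region-major order: all genes of region 1, then region 2, and so on. The
#' string form is `"<region>|<gene>"` and parses back to the pair.
#'
#' @param region_names,gene_ids character vectors.
#' @return data.frame with columns `region`, `gene`, `id`.
#' @export
feature_ids <- function(region_names, gene_ids) {
  df <- data.frame(region = rep(region_names, each = length(gene_ids)),
                   gene = rep(gene_ids, times = length(region_names)),
                   stringsAsFactors = FALSE)
  df$id <- paste(df$region, df$gene, sep = "|")
  df
}

#' @rdname feature_ids
#' @param id character vector of `"<region>|<gene>"` strings.
#' @export
parse_feature_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed feature id: ", id[bad][1])
  data.frame(region = vapply(parts, `[`, character(1), 1),
             gene = vapply(parts, `[`, character(1), 2),
             id = id, stringsAsFactors = FALSE)
}

#' Build the fusion-feature matrix
#'
#' One column per (region, gene) pair in region-major order; the entry for
#' subject s is the Pearson correlation between the first L points of s's
#' region time series and s's encoded gene sequence. Degenerate correlations
#' (zero-variance series or constant code) are set to 0 and counted.
#'
#' @param series_set a [roi_series()] with T >= L (the first L points are used).
#' @param encoded an `encoded_genes` object from [encode_genes()].
#' @param labels numeric vector of class labels in `{-1, +1}`, one per
#'   subject, in the subject order shared by both modalities.
#' @return Object of class `fusion_matrix`: `values` (subjects x R*G),
#'   `features` (the [feature_ids()] frame), `labels`, `subject_ids`, and the
#'   dimensions `R`, `G`, `L`. Attribute `n_degenerate` counts zero-filled
#'   entries.
#' @export
build_fusion_matrix <- function(series_set, encoded, labels) {
  stopifnot(inherits(series_set, "roi_series"), inherits(encoded, "encoded_genes"))
  if (!identical(as.character(series_set$subject_ids),
                 as.character(encoded$subject_ids))) {
    only_roi <- setdiff(series_set$subject_ids, encoded$subject_ids)
    only_gen <- setdiff(encoded$subject_ids, series_set$subject_ids)
    stop("subject sets differ between modalities; only in ROI set: {",
         paste(only_roi, collapse = ", "), "}; only in genotype set: {",
         paste(only_gen, collapse = ", "),
         "}; or the ordering differs")
  }
  stopifnot(length(labels) == length(series_set$subject_ids),
            all(labels %in% c(-1, 1)))
  L <- encoded$L
  trunc <- truncate_series(series_set, L)
  genes <- names(encoded$codes)
  R <- length(trunc$region_names)
  G <- length(genes)
  n <- length(trunc$subject_ids)
  vals <- matrix(NA_real_, n, R * G)
  for (s in seq_len(n)) {
    A <- t(matrix(trunc$series[s, , ], nrow = R))          # L x R
    B <- vapply(encoded$codes, function(cm) as.numeric(cm[s, ]), numeric(L))
    cc <- suppressWarnings(stats::cor(A, B))               # R x G
    vals[s, ] <- as.vector(t(cc))                          # region-major
  }
  n_degenerate <- sum(is.na(vals))
  if (n_degenerate > 0) {
    warning(n_degenerate, " degenerate correlation(s) set to 0")
    vals[is.na(vals)] <- 0
  }
  feats <- feature_ids(trunc$region_names, genes)
  colnames(vals) <- feats$id
  rownames(vals) <- trunc$subject_ids
  structure(list(values = vals, features = feats,
                 labels = as.numeric(labels),
                 subject_ids = trunc$subject_ids,
                 R = R, G = G, L = L),
            class = "fusion_matrix", n_degenerate = n_degenerate)
}

#' @export
print.fusion_matrix <- function(x, ...) {
  cat(sprintf("<fusion_matrix> %d subjects x %d features (%d regions x %d genes, L = %d)\n",
              nrow(x$values), ncol(x$values), x$R, x$G, x$L))
  invisible(x)
}
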