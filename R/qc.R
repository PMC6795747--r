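#' Genotype table
#'
#' Container for diploid nucleotide genotype calls: subjects in rows, SNPs in
#' columns, each call an unordered pair of alleles from `{A, C, G, T}` or
#' missing (`NA`).
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `gene_id`,
#'   `allele_a`, `allele_b`. `gene_id` may be `NA` for unmapped SNPs.
#' @param a1,a2 character matrices (subjects x SNPs) holding the two alleles
#'   of each call; both `NA` where the call is missing.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(subject_ids, snps, a1, a2) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  needed <- c("snp_id", "chrom", "pos", "gene_id", "allele_a", "allele_b")
  if (!all(needed %in% names(snps))) {
    stop("snps must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp ids")
  if (!is.matrix(a1) || !is.matrix(a2) ||
      !identical(dim(a1), dim(a2)) ||
      nrow(a1) != length(subject_ids) || ncol(a1) != nrow(snps)) {
    stop("call matrices must be |subjects| x |snps|")
  }
  ok <- is.na(a1) | a1 %in% c("A", "C", "G", "T")
  ok2 <- is.na(a2) | a2 %in% c("A", "C", "G", "T")
  if (!all(ok) || !all(ok2)) stop("non-nucleotide allele in calls")
  if (!identical(is.na(a1), is.na(a2))) {
    stop("half-missing calls are not representable; a1 and a2 must be NA together")
  }
  dimnames(a1) <- dimnames(a2) <- list(subject_ids, snps$snp_id)
  structure(list(subject_ids = subject_ids, snps = snps, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d subjects x %d SNPs (%d genes mapped)\n",
              length(x$subject_ids), nrow(x$snps),
              length(unique(stats::na.omit(x$snps$gene_id)))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$subject_ids), nrow(x$snps))

#' Quality-control thresholds
#'
#' Defaults are the standard chip-QC settings used throughout this pipeline:
#' subjects must have a call rate of at least 95%, SNPs a genotyping rate of
#' at least 99.9% and a minor allele frequency of at least 4%, and SNPs
#' failing the Hardy-Weinberg exact test at p < 1e-4 are removed.
#'
#' @param sample_call_rate_min,snp_call_rate_min,maf_min fractions in (0, 1].
#' @param hwe_p_min Hardy-Weinberg exact-test p-value cutoff in (0, 1].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95,
                          snp_call_rate_min = 0.999,
                          maf_min = 0.04,
                          hwe_p_min = 1e-4) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             snp_call_rate_min = snp_call_rate_min,
             maf_min = maf_min, hwe_p_min = hwe_p_min)
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a single number in [0, 1]")
    }
  }
  structure(th, class = "qc_thresholds")
}

#' Per-subject call rate
#'
#' Fraction of non-missing genotype calls for each subject.
#'
#' @param table a [genotype_table()].
#' @return Named numeric vector in `[0, 1]`, one entry per subject.
#' @export
sample_call_rate <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  if (ncol(table$a1) == 0) stop("table has zero SNPs")
  rowMeans(!is.na(table$a1))
}

#' Per-SNP call rate (genotyping rate)
#'
#' @param table a [genotype_table()].
#' @return Named numeric vector in `[0, 1]`, one entry per SNP.
#' @export
snp_call_rate <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  if (nrow(table$a1) == 0) stop("table has zero subjects")
  colMeans(!is.na(table$a1))
}

#' Minor allele frequency per SNP
#'
#' Count of the rarer allele over twice the number of non-missing calls;
#' missing calls are excluded from the denominator.
#'
#' @param table a [genotype_table()].
#' @return Named numeric vector in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  nb <- (table$a1 == table$snps$allele_b[col(table$a1)]) +
        (table$a2 == table$snps$allele_b[col(table$a2)])
  n_called <- colSums(!is.na(table$a1))
  if (any(n_called == 0)) {
    stop("all-missing SNP column(s): ",
         paste(table$snps$snp_id[n_called == 0], collapse = ", "))
  }
  fb <- colSums(nb, na.rm = TRUE) / (2 * n_called)
  stats::setNames(pmin(fb, 1 - fb), table$snps$snp_id)
}

#' Genotype counts per SNP
#'
#' Tallies homozygous-a, heterozygous and homozygous-b calls for each SNP
#' relative to the table's recorded allele pair.
#'
#' @param table a [genotype_table()].
#' @return Integer matrix with columns `n_hom_a`, `n_het`, `n_hom_b`.
#' @export
genotype_counts <- function(table) {
  aa <- table$snps$allele_a[col(table$a1)]
  hom_a <- colSums(table$a1 == aa & table$a2 == aa, na.rm = TRUE)
  bb <- table$snps$allele_b[col(table$a1)]
  hom_b <- colSums(table$a1 == bb & table$a2 == bb, na.rm = TRUE)
  het <- colSums(!is.na(table$a1)) - hom_a - hom_b
  cbind(n_hom_a = hom_a, n_het = het, n_hom_b = hom_b)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions. Given the observed
#' allele counts, the p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count (the standard two-sided exact formulation used in genotype QC).
#'
#' @param n_hom_a,n_het,n_hom_b non-negative genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b) {
  stopifnot(length(n_hom_a) == 1, length(n_het) == 1, length(n_hom_b) == 1,
            n_hom_a >= 0, n_het >= 0, n_hom_b >= 0)
  n <- n_hom_a + n_het + n_hom_b
  if (n == 0) stop("all genotype counts are zero")
  na <- 2 * n_hom_a + n_het             # copies of allele a
  nb <- 2 * n_hom_b + n_het
  if (na == 0 || nb == 0) return(1)     # monomorphic: single configuration
  # attainable heterozygote counts share the parity of the minor allele count
  nm <- min(na, nb)
  hets <- seq.int(nm %% 2, nm, by = 2)
  # log P(N_het = h | n, na) = log[ n! / (haa! h! hbb!) * 2^h * na! nb! / (2n)! ]
  haa <- (na - hets) / 2
  hbb <- (nb - hets) / 2
  logp <- lgamma(n + 1) - lgamma(haa + 1) - lgamma(hets + 1) - lgamma(hbb + 1) +
    hets * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Apply the four genotype quality-control filters
#'
#' Filters are applied in a fixed order: subject call rate, then SNP call
#' rate, then minor allele frequency, then the Hardy-Weinberg exact test.
#' Entities at or above a call-rate/MAF threshold are kept; SNPs with HWE
#' p-values below `hwe_p_min` are removed.
#'
#' @param table a [genotype_table()].
#' @param thresholds a [qc_thresholds()].
#' @return List with elements `table` (the filtered [genotype_table()]) and
#'   `report` (a `qc_report`: per-step removal counts and the thresholds used).
#' @export
apply_qc <- function(table, thresholds = qc_thresholds()) {
  stopifnot(inherits(table, "genotype_table"), inherits(thresholds, "qc_thresholds"))
  report <- list(thresholds = unclass(thresholds),
                 n_subjects_in = length(table$subject_ids),
                 n_snps_in = nrow(table$snps))

  subset_table <- function(tab, keep_subj, keep_snp) {
    genotype_table(tab$subject_ids[keep_subj],
                   tab$snps[keep_snp, , drop = FALSE],
                   tab$a1[keep_subj, keep_snp, drop = FALSE],
                   tab$a2[keep_subj, keep_snp, drop = FALSE])
  }

  scr <- sample_call_rate(table)
  keep <- scr >= thresholds$sample_call_rate_min
  report$removed_subjects_call_rate <- sum(!keep)
  if (!any(keep)) stop("QC removed every subject at the sample call-rate step")
  table <- subset_table(table, keep, rep(TRUE, nrow(table$snps)))

  gcr <- snp_call_rate(table)
  keep <- gcr >= thresholds$snp_call_rate_min
  report$removed_snps_call_rate <- sum(!keep)
  if (!any(keep)) stop("QC removed every SNP at the genotyping-rate step")
  table <- subset_table(table, rep(TRUE, length(table$subject_ids)), keep)

  maf <- minor_allele_frequency(table)
  keep <- maf >= thresholds$maf_min
  report$removed_snps_maf <- sum(!keep)
  if (!any(keep)) stop("QC removed every SNP at the MAF step")
  table <- subset_table(table, rep(TRUE, length(table$subject_ids)), keep)

  gc <- genotype_counts(table)
  hwe_p <- vapply(seq_len(nrow(gc)), function(i) {
    hwe_exact_test(gc[i, 1], gc[i, 2], gc[i, 3])
  }, numeric(1))
  keep <- hwe_p >= thresholds$hwe_p_min
  report$removed_snps_hwe <- sum(!keep)
  if (!any(keep)) stop("QC removed every SNP at the Hardy-Weinberg step")
  table <- subset_table(table, rep(TRUE, length(table$subject_ids)), keep)

  report$n_subjects_out <- length(table$subject_ids)
  report$n_snps_out <- nrow(table$snps)
  list(table = table, report = structure(report, class = "qc_report"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<qc_report> %d -> %d subjects, %d -> %d SNPs\n",
    "  removed: %d subjects (call rate), %d SNPs (genotyping), ",
    "%d (MAF), %d (HWE)\n"),
    x$n_subjects_in, x$n_subjects_out, x$n_snps_in, x$n_snps_out,
    x$removed_subjects_call_rate, x$removed_snps_call_rate,
    x$removed_snps_maf, x$removed_snps_hwe))
  invisible(x)
}

#' Group surviving SNPs into genes
#'
#' Keeps genes with strictly more than `min_snps` surviving SNPs; within a
#' gene, SNPs are ordered by genomic position. Unmapped SNPs (gene `NA`) are
#' dropped and counted.
#'
#' @param table a QC-filtered [genotype_table()].
#' @param gene_map optional data.frame (`snp_id`, `gene_id`) overriding the
#'   table's gene assignments.
#' @param min_snps retention threshold; a gene needs more than this many SNPs.
#' @return List of `gene_group`s (`gene_id`, `snp_ids`, `group_size`), ordered
#'   by gene id, with attributes `n_unmapped` and `n_genes_dropped`.
#' @export
group_by_gene <- function(table, gene_map = NULL, min_snps = 30) {
  stopifnot(inherits(table, "genotype_table"))
  snps <- table$snps
  if (!is.null(gene_map)) {
    stopifnot(all(c("snp_id", "gene_id") %in% names(gene_map)))
    if (nrow(gene_map) == 0) stop("empty gene map")
    if (anyDuplicated(gene_map$snp_id)) stop("a SNP maps to more than one gene")
    snps$gene_id <- gene_map$gene_id[match(snps$snp_id, gene_map$snp_id)]
  }
  if (all(is.na(snps$gene_id))) stop("empty gene map: no SNP has a gene assignment")
  n_unmapped <- sum(is.na(snps$gene_id))
  snps <- snps[!is.na(snps$gene_id), , drop = FALSE]
  snps <- snps[order(snps$gene_id, snps$chrom, snps$pos, snps$snp_id), , drop = FALSE]
  by_gene <- split(snps$snp_id, snps$gene_id)
  sizes <- lengths(by_gene)
  kept <- sizes > min_snps
  groups <- lapply(names(by_gene)[kept], function(g) {
    structure(list(gene_id = g, snp_ids = by_gene[[g]],
                   group_size = length(by_gene[[g]])),
              class = "gene_group")
  })
  attr(groups, "n_unmapped") <- n_unmapped
  attr(groups, "n_genes_dropped") <- sum(!kept)
  groups
}

#' Segment gene groups to a common length and resolve one nucleotide per SNP
#'
#' All retained genes are cut to the length of the smallest group: each gene
#' contributes its first `L` SNPs in genomic order. Each subject's sequence
#' takes one nucleotide per SNP according to the allele policy:
#' `"major_allele"` (homozygotes keep their allele; heterozygotes carry the
#' cohort-major allele), `"first_allele"` (the first recorded allele of the
#' call) or `"seeded_random"` (one of the two alleles chosen at random under
#' `seed`). Missing calls that survived QC are imputed to the cohort-major
#' allele; the imputation count is recorded.
#'
#' @param groups output of [group_by_gene()].
#' @param table the QC-filtered [genotype_table()] the groups came from.
#' @param policy heterozygote-resolution policy.
#' @param seed integer, used only by `"seeded_random"`.
#' @return List with `sequences` (named list, per gene a subjects x L
#'   character matrix), `L`, `subject_ids` and `n_imputed`.
#' @export
segment_to_length <- function(groups, table,
                              policy = c("major_allele", "first_allele",
                                         "seeded_random"),
                              seed = 1L) {
  policy <- match.arg(policy)
  if (length(groups) == 0) stop("no retained gene groups")
  L <- min(vapply(groups, `[[`, integer(1), "group_size"))
  if (L == 0) stop("segment length is zero")

  # cohort-major allele per SNP, ties broken alphabetically
  nb <- (table$a1 == table$snps$allele_b[col(table$a1)]) +
        (table$a2 == table$snps$allele_b[col(table$a2)])
  fb <- colSums(nb, na.rm = TRUE) / (2 * colSums(!is.na(table$a1)))
  major <- ifelse(fb > 0.5, table$snps$allele_b,
           ifelse(fb < 0.5, table$snps$allele_a,
                  pmin(table$snps$allele_a, table$snps$allele_b)))
  names(major) <- table$snps$snp_id

  if (policy == "seeded_random") set.seed(seed)
  n_imputed <- 0L
  sequences <- lapply(groups, function(gr) {
    ids <- gr$snp_ids[seq_len(L)]
    j <- match(ids, table$snps$snp_id)
    a1 <- table$a1[, j, drop = FALSE]
    a2 <- table$a2[, j, drop = FALSE]
    maj <- matrix(major[ids], nrow = nrow(a1), ncol = L, byrow = TRUE)
    seqm <- switch(policy,
      major_allele = ifelse(a1 == a2, a1, maj),
      first_allele = a1,
      seeded_random = ifelse(matrix(stats::runif(length(a1)) < 0.5,
                                    nrow(a1), ncol(a1)), a1, a2))
    miss <- is.na(seqm)
    n_imputed <<- n_imputed + sum(miss)
    seqm[miss] <- maj[miss]
    dimnames(seqm) <- list(table$subject_ids, ids)
    seqm
  })
  names(sequences) <- vapply(groups, `[[`, character(1), "gene_id")
  list(sequences = sequences, L = L, subject_ids = table$subject_ids,
       n_imputed = n_imputed)
}

#' Digital encoding of a nucleotide sequence
#'
#' Positionwise map A -> 1, T -> 2, C -> 3, G -> 4.
#'
#' @param x a character vector of single nucleotides, or one string.
#' @return Integer vector of the same length.
#' @export
encode_sequence <- function(x) {
  if (length(x) == 1 && !is.na(x) && nchar(x) != 1) {
    x <- strsplit(x, "", fixed = TRUE)[[1]]
  }
  if (length(x) == 0) return(integer(0))
  code <- match(x, c("A", "T", "C", "G"))
  if (anyNA(code)) {
    bad <- unique(x[is.na(code)])
    stop("cannot encode symbol(s): ", paste(bad, collapse = ", "))
  }
  code
}

#' @rdname encode_sequence
#' @param code integer vector of codes in `{1, 2, 3, 4}`.
#' @export
decode_sequence <- function(code) {
  if (length(code) == 0) return(character(0))
  stopifnot(all(code %in% 1:4))
  c("A", "T", "C", "G")[code]
}

#' Encode all segmented gene sequences
#'
#' @param segmented output of [segment_to_length()].
#' @return List of class `encoded_genes`: `codes` (named list, per gene a
#'   subjects x L integer matrix), `L`, `subject_ids`.
#' @export
encode_genes <- function(segmented) {
  codes <- lapply(segmented$sequences, function(m) {
    em <- matrix(encode_sequence(as.vector(m)), nrow(m), ncol(m),
                 dimnames = dimnames(m))
    em
  })
  structure(list(codes = codes, L = segmented$L,
                 subject_ids = segmented$subject_ids),
            class = "encoded_genes")
}
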