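test_that("call rates count non-missing calls per subject and per SNP", {
  tab <- make_table(matrix(c("AA", "AG", "GG",
                             "AA", "--", "AG",
                             "AA", "AG", "--",
                             "AA", "AG", "GG"), 4, 3, byrow = TRUE),
                    "A", "G")
  expect_equal(unname(sample_call_rate(tab)), c(1, 2 / 3, 2 / 3, 1))
  expect_equal(unname(snp_call_rate(tab)), c(1, 3 / 4, 3 / 4))

  complete <- make_table(matrix("AG", 5, 2), "A", "G")
  expect_equal(unname(sample_call_rate(complete)), rep(1, 5))
  expect_equal(unname(snp_call_rate(complete)), rep(1, 2))
})

test_that("minor allele frequency counts the rarer allele over called alleles", {
  # 4 het + 6 hom-major: 4 minor alleles of 20
  tab <- counts_table(6, 4, 0)
  expect_equal(unname(minor_allele_frequency(tab)), 4 / 20)
  # monomorphic
  expect_equal(unname(minor_allele_frequency(counts_table(7, 0, 0))), 0)
  # 50/50 alleles
  expect_equal(unname(minor_allele_frequency(counts_table(5, 0, 5))), 0.5)
  # missing calls leave the denominator
  tab <- make_table(matrix(c("AG", "AG", "--", "AA"), 4, 1), "A", "G")
  expect_equal(unname(minor_allele_frequency(tab)), 2 / 6)
  expect_error(minor_allele_frequency(make_table(matrix("--", 2, 1), "A", "G")),
               "all-missing")
})

test_that("HWE exact test matches full enumeration of the conditional law", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0, tolerance = 1e-9)
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)   # monomorphic
  expect_lt(hwe_exact_test(20, 0, 20), 1e-4)    # extreme het deficit
  # exhaustive small-table agreement with the enumeration oracle
  for (naa in 0:8) for (nab in 0:8) for (nbb in 0:8) {
    if (naa + nab + nbb == 0 || naa + nab + nbb > 12) next
    expect_equal(hwe_exact_test(naa, nab, nbb),
                 hwe_enum_oracle(naa, nab, nbb),
                 tolerance = 1e-9,
                 label = sprintf("hwe(%d,%d,%d)", naa, nab, nbb))
  }
  # a handful of larger tables up to 30 subjects
  for (cnt in list(c(12, 6, 12), c(25, 3, 2), c(0, 15, 15), c(10, 10, 10))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-9)
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("apply_qc filters in order and reports removals", {
  hwe_ok <- c(rep("AA", 3), rep("AG", 5), rep("GG", 3))  # near-HW proportions
  calls <- matrix(hwe_ok, 11, 24)
  calls <- rbind("--", calls)            # subject 1: call rate 0
  calls[2:12, 22] <- c("--", hwe_ok[-1]) # SNP 22: one missing call
  calls[, 23] <- "AA"                    # SNP 23: monomorphic, MAF 0
  calls[2:12, 24] <- c(rep("AA", 6), rep("GG", 5))  # SNP 24: het deficit
  tab <- make_table(calls, "A", "G")
  res <- apply_qc(tab, qc_thresholds(0.95, 0.999, 0.04, 0.20))
  expect_equal(res$report$removed_subjects_call_rate, 1)
  expect_equal(res$report$removed_snps_call_rate, 1)
  expect_equal(res$report$removed_snps_maf, 1)
  expect_equal(res$report$removed_snps_hwe, 1)
  expect_equal(res$table$snps$snp_id, sprintf("s%03d", 1:21))
  expect_equal(length(res$table$subject_ids), 11)

  # vacuous thresholds are the identity
  res0 <- apply_qc(tab, qc_thresholds(0, 0, 0, 0))
  expect_equal(dim(res0$table), dim(tab))
  expect_equal(res0$report$removed_snps_maf, 0)
})

test_that("QC is monotone: tightening one threshold never adds survivors", {
  sim <- generate_genotypes(sim_config(n_ad = 15, n_nc = 15, n_genes = 4,
                                       snps_per_gene = c(10, 20),
                                       maf_range = c(0.02, 0.5),
                                       missing_rate = 0.05, seed = 11))
  base <- qc_thresholds(0.9, 0.95, 0.03, 1e-4)
  loose <- apply_qc(sim$table, base)
  # tightening any SNP-level threshold keeps the subject set fixed, so the
  # surviving SNPs must nest; tightening the subject threshold nests the
  # subject set (SNP statistics are then computed on a different cohort, so
  # SNP nesting is not implied)
  snp_tighter <- list(qc_thresholds(0.9, 0.99, 0.03, 1e-4),
                      qc_thresholds(0.9, 0.95, 0.10, 1e-4),
                      qc_thresholds(0.9, 0.95, 0.03, 0.05))
  for (th in snp_tighter) {
    strict <- apply_qc(sim$table, th)
    expect_identical(strict$table$subject_ids, loose$table$subject_ids)
    expect_true(all(strict$table$snps$snp_id %in% loose$table$snps$snp_id))
  }
  strict_subj <- apply_qc(sim$table, qc_thresholds(0.95, 0.95, 0.03, 1e-4))
  expect_true(all(strict_subj$table$subject_ids %in% loose$table$subject_ids))
})

test_that("a planted HWE violator is removed by the HWE step alone", {
  set.seed(7)
  n <- 500
  p <- 0.3
  # HWE-consistent SNP and an excess-homozygosity violator at the same MAF
  draw <- function(p_aa, p_ab) {
    u <- runif(n)
    g <- ifelse(u < p_aa, "GG", ifelse(u < p_aa + p_ab, "AG", "AA"))
    g
  }
  ok_snp <- draw(p^2, 2 * p * (1 - p))
  bad_snp <- draw(p^2 + 0.5 * p * (1 - p), 2 * p * (1 - p) * 0.5)
  tab <- make_table(cbind(ok_snp, bad_snp), "A", "G")
  res <- apply_qc(tab, qc_thresholds())
  expect_equal(res$report$removed_snps_hwe, 1)
  expect_equal(res$table$snps$snp_id, "s001")
})

test_that("gene grouping keeps genes with strictly more than min_snps SNPs", {
  calls <- matrix("AG", 4, 63)
  genes <- c(rep("geneA", 30), rep("geneB", 31), rep(NA, 2))
  tab <- make_table(calls, "A", "G", gene_id = genes)
  groups <- group_by_gene(tab, min_snps = 30)
  expect_length(groups, 1)
  expect_equal(groups[[1]]$gene_id, "geneB")
  expect_equal(groups[[1]]$group_size, 31)
  expect_equal(attr(groups, "n_unmapped"), 2)
  # SNPs ordered by genomic position within the gene
  expect_equal(groups[[1]]$snp_ids,
               tab$snps$snp_id[31:61][order(tab$snps$pos[31:61])])
  expect_error(group_by_gene(make_table(calls, "A", "G")), "empty gene map")
})

test_that("segmentation takes the first L SNPs and resolves heterozygotes", {
  calls <- rbind(c("AA", "GG", "AG", "AA", "CC"),
                 c("AG", "GG", "AA", "AA", "CC"),
                 c("GG", "AG", "AG", "AA", "CC"))
  genes <- c("g1", "g1", "g1", "g2", "g2")
  tab <- make_table(calls, c("A", "G", "A", "A", "C"),
                    c("G", "A", "G", "G", "A"), gene_id = genes)
  groups <- group_by_gene(tab, min_snps = 1)
  seg <- segment_to_length(groups, tab, policy = "major_allele")
  expect_equal(seg$L, 2)  # min(3, 2)
  expect_equal(dim(seg$sequences$g1), c(3, 2))
  # SNP1 alleles tie 3-3; the tie resolves alphabetically, so het subject 2
  # carries A
  expect_equal(unname(seg$sequences$g1[, 1]), c("A", "A", "G"))
  # homozygotes keep their allele under every policy
  seg_first <- segment_to_length(groups, tab, policy = "first_allele")
  expect_equal(seg$sequences$g2, seg_first$sequences$g2)

  # single gene: L is its own size
  solo <- group_by_gene(tab, gene_map = data.frame(
    snp_id = tab$snps$snp_id[1:3], gene_id = "g1"), min_snps = 2)
  expect_equal(segment_to_length(solo, tab)$L, 3)
})

test_that("missing calls surviving QC are imputed to the major allele and counted", {
  calls <- rbind(c("AA", "AG"), c("--", "AA"), c("AA", "AA"), c("AG", "AA"))
  tab <- make_table(calls, "A", "G", gene_id = "g1")
  groups <- group_by_gene(tab, min_snps = 1)
  seg <- segment_to_length(groups, tab)
  expect_equal(seg$n_imputed, 1)
  expect_equal(unname(seg$sequences$g1[2, 1]), "A")
})

test_that("digital encoding is the stated bijection on A, T, C, G", {
  expect_equal(encode_sequence("ATCG"), c(1L, 2L, 3L, 4L))
  expect_equal(encode_sequence(character(0)), integer(0))
  expect_equal(encode_sequence("GGGG"), c(4L, 4L, 4L, 4L))
  expect_error(encode_sequence(c("A", "N")), "cannot encode")
  # bijective and order-preserving over positions
  set.seed(3)
  s <- sample(c("A", "T", "C", "G"), 50, replace = TRUE)
  expect_equal(decode_sequence(encode_sequence(s)), s)
  expect_equal(encode_sequence(s[10:20]), encode_sequence(s)[10:20])
})

test_that("all retained genes share one encoded length L", {
  sim <- generate_genotypes(sim_config(n_ad = 8, n_nc = 8, n_genes = 5,
                                       snps_per_gene = c(32, 40), seed = 5))
  qc <- apply_qc(sim$table)
  groups <- group_by_gene(qc$table)
  enc <- encode_genes(segment_to_length(groups, qc$table))
  lens <- vapply(enc$codes, ncol, integer(1))
  expect_true(all(lens == enc$L))
  expect_true(all(unlist(enc$codes) %in% 1:4))
  expect_equal(sum(lengths(lapply(enc$codes, as.vector))),
               16 * length(enc$codes) * enc$L)
})
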