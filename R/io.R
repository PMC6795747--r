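# On-disk formats: PLINK-style .ped/.map text (missing allele "0"),
# TSV tables (UTF-8, Unix newlines, 9-significant-digit floats), JSON
# reports. Every writer has a reader that round-trips to equal values.

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], fmt_num)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a genotype table as PLINK-style text
#'
#' `.ped`: family id, individual id, paternal/maternal ids (0), sex (0),
#' phenotype, then two alleles per SNP; missing allele `"0"`; tab-separated.
#' `.map`: chromosome, SNP id, genetic distance (0), position.
#'
#' @param table a [genotype_table()].
#' @param ped_path,map_path output paths.
#' @param phenotypes optional numeric vector written to the phenotype column
#'   (default -9, unknown).
#' @export
write_ped_map <- function(table, ped_path, map_path, phenotypes = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  n <- length(table$subject_ids)
  if (is.null(phenotypes)) phenotypes <- rep(-9, n)
  a1 <- table$a1
  a2 <- table$a2
  a1[is.na(a1)] <- "0"
  a2[is.na(a2)] <- "0"
  inter <- matrix("", n, 2 * ncol(a1))
  inter[, seq(1, by = 2, length.out = ncol(a1))] <- a1
  inter[, seq(2, by = 2, length.out = ncol(a1))] <- a2
  lines <- paste(table$subject_ids, table$subject_ids, 0, 0, 0, phenotypes,
                 apply(inter, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(ped_path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  map <- data.frame(chrom = table$snps$chrom, snp_id = table$snps$snp_id,
                    cm = 0L, pos = table$snps$pos)
  con <- file(map_path, open = "wb")
  writeLines(do.call(paste, c(unname(map), sep = "\t")), con, sep = "\n",
             useBytes = TRUE)
  close(con)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK-style .ped/.map text into a genotype table
#'
#' Missing alleles (`"0"`) become missing calls; any allele outside
#' `{A, C, G, T, 0}` is a parse error naming the line and column. Allele-pair
#' metadata (`allele_a` = major) is derived from observed frequencies, and
#' gene assignments can be supplied via `gene_map`.
#'
#' @param ped_path,map_path input paths.
#' @param gene_map optional data.frame (`snp_id`, `gene_id`).
#' @return A [genotype_table()]; attribute `phenotypes` carries the .ped
#'   phenotype column.
#' @export
read_ped_map <- function(ped_path, map_path, gene_map = NULL) {
  map_lines <- readLines(map_path)
  if (length(map_lines) == 0) stop("empty .map file: ", map_path)
  map_fields <- strsplit(map_lines, "\t", fixed = TRUE)
  if (any(lengths(map_fields) != 4)) {
    stop(".map line ", which(lengths(map_fields) != 4)[1],
         " does not have 4 columns")
  }
  n_snp <- length(map_lines)
  snp_id <- vapply(map_fields, `[`, character(1), 2)
  ped_lines <- readLines(ped_path)
  if (length(ped_lines) == 0) stop("empty .ped file: ", ped_path)
  ped_fields <- strsplit(ped_lines, "\t", fixed = TRUE)
  expected <- 6 + 2 * n_snp
  bad <- which(lengths(ped_fields) != expected)
  if (length(bad) > 0) {
    stop(".ped line ", bad[1], " has ", lengths(ped_fields)[bad[1]],
         " columns; expected ", expected)
  }
  subject_ids <- vapply(ped_fields, `[`, character(1), 2)
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject id in .ped: ",
         subject_ids[duplicated(subject_ids)][1])
  }
  phenotypes <- as.numeric(vapply(ped_fields, `[`, character(1), 6))
  geno <- t(vapply(ped_fields, function(f) f[-(1:6)], character(2 * n_snp)))
  ok <- matrix(geno %in% c("A", "C", "G", "T", "0"), nrow(geno))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(".ped line ", bad[1], ", allele column ", bad[2],
         ": invalid allele '", geno[bad[1], bad[2]], "'")
  }
  a1 <- geno[, seq(1, by = 2, length.out = n_snp), drop = FALSE]
  a2 <- geno[, seq(2, by = 2, length.out = n_snp), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) stop("half-missing call at .ped line ", which(half, arr.ind = TRUE)[1, 1])
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  # derive the allele pair per SNP from the observed calls (major first)
  allele_a <- character(n_snp)
  allele_b <- character(n_snp)
  for (j in seq_len(n_snp)) {
    tab <- sort(table(c(a1[, j], a2[, j])), decreasing = TRUE)
    als <- names(tab)
    if (length(als) > 2) {
      stop("SNP ", snp_id[j], " has more than two alleles: ",
           paste(als, collapse = ", "))
    }
    allele_a[j] <- if (length(als) >= 1) als[1] else "A"
    allele_b[j] <- if (length(als) == 2) als[2] else setdiff(c("A", "C", "G", "T"), allele_a[j])[1]
  }
  snps <- data.frame(
    snp_id = snp_id,
    chrom = as.integer(vapply(map_fields, `[`, character(1), 1)),
    pos = as.integer(vapply(map_fields, `[`, character(1), 4)),
    gene_id = NA_character_, allele_a = allele_a, allele_b = allele_b,
    stringsAsFactors = FALSE)
  if (!is.null(gene_map)) {
    snps$gene_id <- gene_map$gene_id[match(snps$snp_id, gene_map$snp_id)]
  }
  out <- genotype_table(subject_ids, snps, a1, a2)
  attr(out, "phenotypes") <- phenotypes
  out
}

#' Write / read the SNP-to-gene map
#'
#' @param table a [genotype_table()] (mapped SNPs only are written).
#' @param path TSV path with columns `snp_id`, `gene_id`.
#' @export
write_gene_map <- function(table, path) {
  keep <- !is.na(table$snps$gene_id)
  write_tsv(data.frame(snp_id = table$snps$snp_id[keep],
                       gene_id = table$snps$gene_id[keep]), path)
  invisible(path)
}

#' @rdname write_gene_map
#' @export
read_gene_map <- function(path) {
  gm <- read_tsv(path)
  if (!all(c("snp_id", "gene_id") %in% names(gm)) || nrow(gm) == 0) {
    stop("gene map must be a non-empty TSV with columns snp_id, gene_id")
  }
  gm
}

#' Write / read ROI time series (one TSV per subject)
#'
#' Each file `<subject>_roi.tsv` has a `region` column followed by one
#' column per timepoint (header = timepoint index); rows are regions.
#'
#' @param series_set a [roi_series()].
#' @param dir output directory (created if needed).
#' @export
write_roi_dir <- function(series_set, dir) {
  stopifnot(inherits(series_set, "roi_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  T_len <- dim(series_set$series)[3]
  for (s in seq_along(series_set$subject_ids)) {
    mat <- matrix(series_set$series[s, , ], nrow = length(series_set$region_names))
    df <- data.frame(region = series_set$region_names,
                     as.data.frame(mat), check.names = FALSE)
    names(df)[-1] <- as.character(seq_len(T_len))
    write_tsv(df, file.path(dir, paste0(series_set$subject_ids[s], "_roi.tsv")))
  }
  invisible(dir)
}

#' @rdname write_roi_dir
#' @param subject_ids subjects to read, in order (`<id>_roi.tsv` each).
#' @export
read_roi_dir <- function(dir, subject_ids) {
  mats <- lapply(subject_ids, function(id) {
    path <- file.path(dir, paste0(id, "_roi.tsv"))
    if (!file.exists(path)) stop("missing ROI file for subject ", id, ": ", path)
    df <- read_tsv(path)
    as.matrix(df[, -1, drop = FALSE])
  })
  region_names <- read_tsv(file.path(dir, paste0(subject_ids[1], "_roi.tsv")))$region
  dims <- unique(t(vapply(mats, dim, integer(2))))
  if (nrow(dims) != 1) stop("ROI files disagree in shape")
  series <- array(NA_real_, c(length(subject_ids), dims[1, 1], dims[1, 2]))
  for (s in seq_along(mats)) series[s, , ] <- mats[[s]]
  roi_series(subject_ids, region_names, series)
}

#' Write / read subject labels
#'
#' @param labels named numeric vector (-1 patient, +1 control).
#' @param path TSV with columns `subject_id`, `label`.
#' @export
write_labels <- function(labels, path) {
  write_tsv(data.frame(subject_id = names(labels),
                       label = as.integer(labels)), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read_tsv(path)
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("labels file must have columns subject_id, label")
  }
  if (!all(df$label %in% c(-1, 1))) stop("labels must be -1 or +1")
  stats::setNames(as.numeric(df$label), df$subject_id)
}

#' Write a simulated dataset as a pipeline-readable fixture
#'
#' Emits PLINK-style `.ped`/`.map`, the SNP-to-gene map TSV, one ROI TSV per
#' subject, the labels TSV and a ground-truth JSON; all files round-trip
#' through the package readers losslessly.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param out_dir output directory.
#' @return Named character vector of paths, invisibly.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(out_dir, "genotypes.ped"),
             map = file.path(out_dir, "genotypes.map"),
             gene_map = file.path(out_dir, "gene_map.tsv"),
             roi_dir = file.path(out_dir, "roi"),
             labels = file.path(out_dir, "labels.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_ped_map(dataset$genotypes, paths["ped"], paths["map"],
                phenotypes = as.integer(dataset$truth$labels))
  write_gene_map(dataset$genotypes, paths["gene_map"])
  write_roi_dir(dataset$roi, paths["roi_dir"])
  write_labels(dataset$truth$labels, paths["labels"])
  truth <- dataset$truth
  truth_json <- list(
    config = unclass(truth$config),
    true_maf = as.list(truth$true_maf),
    planted_couplings = truth$planted_couplings,
    labels = as.list(truth$labels),
    seed_roi = truth$seed_roi)
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a fixture directory back into pipeline inputs
#'
#' @param dir a directory written by [write_fixture()].
#' @return List with `genotypes` (gene map applied), `roi`, `labels`.
#' @export
read_fixture <- function(dir) {
  gene_map <- read_gene_map(file.path(dir, "gene_map.tsv"))
  table <- read_ped_map(file.path(dir, "genotypes.ped"),
                        file.path(dir, "genotypes.map"), gene_map = gene_map)
  labels <- read_labels(file.path(dir, "labels.tsv"))
  roi <- read_roi_dir(file.path(dir, "roi"), table$subject_ids)
  list(genotypes = table, roi = roi, labels = labels)
}
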