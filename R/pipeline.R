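#' Full pipeline configuration
#'
#' All stage parameters with the study defaults: QC thresholds 0.95 / 0.999 /
#' 0.04 / 1e-4, gene retention above 30 SNPs, major-allele heterozygote
#' policy, 6:4 stratified split, tree grid 10-600 by 10 with plateau
#' detection (window 5, epsilon 0.02), top 100 trees, top 400 features, and
#' the 70-400-by-5 nested subset scan. Simulation fields configure the
#' synthetic data source used by [run_all()] when `simulate = TRUE`.
#'
#' @param seed master seed; every random stage derives its own seed from it.
#' @param qc a [qc_thresholds()].
#' @param min_snps gene retention threshold (strictly more than this many).
#' @param allele_policy heterozygote policy for [segment_to_length()].
#' @param split_ratio train:test ratio.
#' @param tree_grid forest-size grid for [scan_tree_counts()].
#' @param stability_window,stability_epsilon plateau detection controls.
#' @param top_trees,top_features retained trees b and features for selection.
#' @param subset_min,subset_max,subset_step nested subset sizes.
#' @param subset_trees forest size used when evaluating each subset.
#' @param sim a [sim_config()] for simulated runs (its seed is overridden by
#'   the derived simulation-stage seed).
#' @param ... must be empty; unknown parameters are rejected.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            qc = qc_thresholds(),
                            min_snps = 30L,
                            allele_policy = "major_allele",
                            split_ratio = c(6, 4),
                            tree_grid = tree_count_grid(),
                            stability_window = 5L,
                            stability_epsilon = 0.02,
                            top_trees = 100L,
                            top_features = 400L,
                            subset_min = 70L,
                            subset_max = 400L,
                            subset_step = 5L,
                            subset_trees = 100L,
                            sim = sim_config(),
                            ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  }
  stopifnot(inherits(qc, "qc_thresholds"), inherits(sim, "sim_config"),
            min_snps >= 0, top_trees >= 1, top_features >= 1,
            subset_min >= 1, subset_min <= subset_max, subset_step >= 1,
            subset_trees >= 1, stability_window >= 1,
            stability_epsilon > 0)
  structure(list(seed = as.integer(seed), qc = qc,
                 min_snps = as.integer(min_snps),
                 allele_policy = allele_policy,
                 split_ratio = as.numeric(split_ratio),
                 tree_grid = as.integer(tree_grid),
                 stability_window = as.integer(stability_window),
                 stability_epsilon = stability_epsilon,
                 top_trees = as.integer(top_trees),
                 top_features = as.integer(top_features),
                 subset_min = as.integer(subset_min),
                 subset_max = as.integer(subset_max),
                 subset_step = as.integer(subset_step),
                 subset_trees = as.integer(subset_trees),
                 sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `qc` and `sim` are
#' nested maps with the arguments of [qc_thresholds()] and [sim_config()].
#' Unknown keys at any level are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_nested <- function(vals, fn, label) {
    known <- names(formals(fn))
    bad <- setdiff(names(vals), known)
    if (length(bad) > 0) {
      stop("unknown ", label, " key(s): ", paste(bad, collapse = ", "))
    }
    do.call(fn, vals)
  }
  if (!is.null(raw$qc)) raw$qc <- build_nested(raw$qc, qc_thresholds, "qc")
  if (!is.null(raw$sim)) raw$sim <- build_nested(raw$sim, sim_config, "sim")
  build_nested(raw, pipeline_config, "configuration")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(strip_classes(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the complete fusion analysis
#'
#' Orchestrates the full flow: (optionally) simulate paired data, genotype
#' QC, gene grouping / segmentation / encoding, fusion-feature construction,
#' stratified split, forest-size scan with plateau selection, final forest,
#' tree ranking and feature-frequency selection, nested-subset scan, and
#' region/gene factor extraction. Every random stage uses a named seed
#' derived from the master seed, so a run is reproduced exactly by its
#' configuration. All stage outputs are written under `out_dir` together
#' with a JSON manifest (config hash, seeds, input digests, stage summaries,
#' warnings); the manifest carries no timestamps, so identical runs produce
#' byte-identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param simulate generate inputs with the `sim` configuration (`TRUE`) or
#'   read them from `input_dir` (`FALSE`).
#' @param input_dir fixture directory (see [write_fixture()]) when
#'   `simulate = FALSE`.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config, out_dir, simulate = TRUE, input_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  set.seed(config$seed)
  stage_seeds <- stats::setNames(
    sample.int(.Machine$integer.max, 5),
    c("simulate", "split", "scan", "train", "subsets"))

  manifest <- list(config = strip_classes(config),
                   config_hash = config_hash(config),
                   master_seed = config$seed,
                   stage_seeds = as.list(stage_seeds))

  stage <- "input"
  result <- tryCatch({
    if (simulate) {
      stage <- "simulate"
      sim_cfg <- config$sim
      sim_cfg$seed <- stage_seeds[["simulate"]]
      dataset <- simulate_dataset(sim_cfg)
      input_dir <- file.path(out_dir, "input")
      write_fixture(dataset, input_dir)
      genotypes <- dataset$genotypes
      roi <- dataset$roi
      labels <- dataset$truth$labels
    } else {
      stage <- "input"
      if (is.null(input_dir)) stop("input_dir is required when simulate = FALSE")
      fx <- read_fixture(input_dir)
      genotypes <- fx$genotypes
      roi <- fx$roi
      labels <- fx$labels
    }
    input_files <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
    manifest$input_digests <- as.list(stats::setNames(
      unname(tools::md5sum(sort(input_files))),
      sub(paste0("^", input_dir, "/?"), "", sort(input_files))))

    stage <- "qc"
    qcres <- apply_qc(genotypes, config$qc)
    manifest$qc <- unclass(qcres$report)
    labels <- labels[qcres$table$subject_ids]

    stage <- "encode"
    groups <- group_by_gene(qcres$table, min_snps = config$min_snps)
    if (length(groups) == 0) stop("no gene retained after grouping")
    seg <- segment_to_length(groups, qcres$table, policy = config$allele_policy)
    if (seg$n_imputed > 0) note(seg$n_imputed, " missing call(s) imputed to the major allele")
    encoded <- encode_genes(seg)
    manifest$encode <- list(n_genes = length(encoded$codes), L = encoded$L,
                            n_imputed = seg$n_imputed)
    enc_df <- do.call(rbind, lapply(names(encoded$codes), function(g) {
      data.frame(gene = g, subject = rownames(encoded$codes[[g]]),
                 code = apply(encoded$codes[[g]], 1, paste, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(enc_df, file.path(out_dir, "encoded_genes.tsv"))

    stage <- "fuse"
    roi_kept <- roi_series(
      qcres$table$subject_ids, roi$region_names,
      roi$series[match(qcres$table$subject_ids, roi$subject_ids), , ,
                 drop = FALSE])
    fm <- withCallingHandlers(
      build_fusion_matrix(roi_kept, encoded, labels),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    manifest$fusion <- list(n_subjects = nrow(fm$values), R = fm$R, G = fm$G,
                            L = fm$L, n_features = ncol(fm$values),
                            n_degenerate = attr(fm, "n_degenerate"))
    fus_df <- data.frame(subject_id = fm$subject_ids, label = fm$labels,
                         as.data.frame(fm$values), check.names = FALSE)
    write_tsv(fus_df, file.path(out_dir, "fusion_matrix.tsv"))
    jsonlite::write_json(
      list(R = fm$R, G = fm$G, L = fm$L, subjects = fm$subject_ids,
           labels = as.list(stats::setNames(fm$labels, fm$subject_ids))),
      file.path(out_dir, "fusion_matrix.json"), auto_unbox = TRUE, digits = NA)

    stage <- "split"
    sp <- split_train_test(fm$labels, ratio = config$split_ratio,
                           stratified = TRUE, seed = stage_seeds[["split"]])
    manifest$split <- list(n_train = length(sp$train), n_test = length(sp$test))
    xtr <- fm$values[sp$train, , drop = FALSE]
    ytr <- fm$labels[sp$train]
    xte <- fm$values[sp$test, , drop = FALSE]
    yte <- fm$labels[sp$test]

    stage <- "scan"
    m <- default_feature_count(ncol(fm$values))
    curve <- scan_tree_counts(xtr, ytr, xte, yte, grid = config$tree_grid,
                              m = m, seed = stage_seeds[["scan"]])
    write_tsv(as.data.frame(curve), file.path(out_dir, "tree_scan.tsv"))
    a_star <- withCallingHandlers(
      select_stable_count(curve, config$stability_window,
                          config$stability_epsilon),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    manifest$scan <- list(m = m, n_points = nrow(curve),
                          stable_count = as.integer(a_star),
                          stable = isTRUE(attr(a_star, "stable")))

    stage <- "train"
    model <- mrf(xtr, ytr, n_trees = as.integer(a_star), m = m,
                 seed = stage_seeds[["train"]])
    pred <- withCallingHandlers(
      predict(model, xte),
      message = function(m2) { note(conditionMessage(m2)); invokeRestart("muffleMessage") })
    manifest$train <- list(n_trees = length(model$trees), m = model$m,
                           test_accuracy = accuracy(pred, yte),
                           vote_ties = attr(pred, "ties"))

    stage <- "select"
    top_k <- min(config$top_trees, length(model$trees))
    if (top_k < config$top_trees) note("forest smaller than top_trees; retaining all ", top_k, " trees")
    retained <- rank_trees(model, xte, yte, top_k = top_k)
    freq <- withCallingHandlers(
      feature_frequencies(model, retained, top_b = config$top_features),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    freq_out <- data.frame(feature_id = fm$features$id[freq$feature],
                           count = freq$count, rank = freq$rank)
    write_tsv(freq_out, file.path(out_dir, "feature_frequencies.tsv"))
    sizes <- nested_subset_sizes(min(config$subset_min, nrow(freq)),
                                 min(config$subset_max, nrow(freq)),
                                 config$subset_step, n_available = nrow(freq))
    scan <- evaluate_subsets(freq, xtr, ytr, xte, yte, sizes = sizes,
                             n_trees = config$subset_trees,
                             seed = stage_seeds[["subsets"]])
    write_tsv(as.data.frame(scan), file.path(out_dir, "subset_scan.tsv"))
    opt <- select_optimal(scan)
    write_tsv(data.frame(rank = seq_len(opt$size),
                         feature_id = fm$features$id[opt$features]),
              file.path(out_dir, "optimal_subset.tsv"))
    manifest$selection <- list(top_trees = top_k, top_features = nrow(freq),
                               n_subsets = length(sizes),
                               optimal_size = opt$size,
                               optimal_accuracy = opt$accuracy)

    stage <- "factors"
    fr <- extract_factors(fm$features[opt$features, , drop = FALSE])
    write_tsv(fr$regions, file.path(out_dir, "region_ranking.tsv"))
    write_tsv(fr$genes, file.path(out_dir, "gene_ranking.tsv"))
    manifest$factors <- list(
      n_regions = nrow(fr$regions), n_genes = nrow(fr$genes),
      top_region = fr$regions$region[1], top_gene = fr$genes$gene[1])
    TRUE
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    manifest$warnings <<- as.list(warnings_log)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest$warnings <- as.list(warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
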