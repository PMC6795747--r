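#!/usr/bin/env Rscript

# Step 5: frequency-based optimal fusion-feature selection.
#
# Retains the 100 individually best trees of the trained forest, counts how
# often each fusion feature occurs in their random subsets, keeps the 400
# most frequent, evaluates nested prefix subsets (70..400 by 5, 67 subsets)
# with freshly trained forests, and picks the smallest subset attaining the
# maximum held-out accuracy.

suppressPackageStartupMessages(library(mrfusion))

state <- readRDS("results/forest.rds")
fus <- read.delim("results/fusion_matrix.tsv", check.names = FALSE)
x <- as.matrix(fus[, -(1:2)])
y <- fus$label
feature_names <- colnames(x)
sp <- state$split

set.seed(state$seed + 1L)
subset_seed <- sample.int(.Machine$integer.max, 1)

retained <- rank_trees(state$model, x[sp$test, ], y[sp$test], top_k = 100)
freq <- feature_frequencies(state$model, retained, top_b = 400)
write.table(data.frame(feature_id = feature_names[freq$feature],
                       count = freq$count, rank = freq$rank),
            "results/feature_frequencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sizes <- nested_subset_sizes(70, min(400, nrow(freq)), 5,
                             n_available = nrow(freq))
scan <- evaluate_subsets(freq, x[sp$train, ], y[sp$train], x[sp$test, ],
                         y[sp$test], sizes = sizes, n_trees = 100,
                         seed = subset_seed)
write.table(scan, "results/subset_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

opt <- select_optimal(scan)
cat(sprintf("%d nested subsets evaluated; optimal subset: %d features at accuracy %.4f\n",
            length(sizes), opt$size, opt$accuracy))
write.table(data.frame(rank = seq_len(opt$size),
                       feature_id = feature_names[opt$features]),
            "results/optimal_subset.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
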