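#!/usr/bin/env Rscript

# Step 4: forest-size search and multimodal random-forest training.
#
# Splits subjects 6:4 (stratified), scans forest sizes 10..600 in steps of
# 10 (one independently seeded forest per point, 57 features per tree),
# detects the accuracy plateau, and trains the reference 350-tree forest
# whose majority vote is evaluated on the held-out 40%.

suppressPackageStartupMessages(library(mrfusion))

seed <- 20260930L
set.seed(seed)
seeds <- sample.int(.Machine$integer.max, 3)

fus <- read.delim("results/fusion_matrix.tsv", check.names = FALSE)
x <- as.matrix(fus[, -(1:2)])
y <- fus$label

sp <- split_train_test(y, ratio = c(6, 4), stratified = TRUE, seed = seeds[1])
m <- default_feature_count(ncol(x))
cat("Train", length(sp$train), "/ test", length(sp$test),
    "subjects; m =", m, "features per tree\n")

curve <- scan_tree_counts(x[sp$train, ], y[sp$train], x[sp$test, ],
                          y[sp$test], grid = tree_count_grid(),
                          m = m, seed = seeds[2])
write.table(curve, "results/tree_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
stable <- select_stable_count(curve)
cat("Accuracy plateaus from", as.integer(stable), "trees (plateau mean",
    sprintf("%.3f", attr(stable, "plateau_mean")), ")\n")

model <- mrf(x[sp$train, ], y[sp$train], n_trees = 350, m = m,
             seed = seeds[3])
pred <- predict(model, x[sp$test, ])
cat(sprintf("Majority-vote test accuracy of the 350-tree forest: %.4f\n",
            accuracy(pred, y[sp$test])))

saveRDS(list(model = model, split = sp, seed = seed),
        "results/forest.rds")  # scratch artifact for steps 5-6
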