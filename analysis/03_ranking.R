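#!/usr/bin/env Rscript
# Rank the groups: per-EU two-round z-scores for each metric, the weighted
# composite S, the cumulative sum-of-positive-S ranking, best-model counts
# on GDT_TS, and a Ward-clustered heatmap ordering of the GDT_TS matrix.

suppressMessages(library(modelcritic))

scores <- read.delim("results/02_metrics.tsv", stringsAsFactors = FALSE)
truth <- read.delim("results/01_truth.tsv", stringsAsFactors = FALSE)

comp <- eu_composites(scores)
rk <- rank_groups(comp)
m <- merge(rk, truth, by = "group")
rho <- cor(-m$rank, m$skill, method = "spearman")

cat("Final ranking (sum of positive composite S over EUs):\n")
print(rk, row.names = FALSE)
cat("Spearman correlation of rank with planted skill:", round(rho, 3), "\n")

gts <- scores[scores$metric == "gdt_ts", c("eu_id", "group", "value")]
bmc <- best_model_counts(gts)
cat("\nBest-model counts (GDT_TS, ties split):\n")
print(round(sort(bmc, decreasing = TRUE), 2))

gmat <- with(gts, tapply(value, list(group, eu_id), mean))
wo <- ward_order(gmat)
heat <- data.frame(group = rownames(gmat)[wo$row_order],
                   order = seq_along(wo$row_order))

dir.create("results", showWarnings = FALSE)
write.table(rk, "results/03_ranking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(group = names(bmc), best_models = as.numeric(bmc)),
            "results/03_best_model_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(heat, "results/03_heatmap_row_order.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/03_ranking.tsv, 03_best_model_counts.tsv,",
    "03_heatmap_row_order.tsv\n")
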