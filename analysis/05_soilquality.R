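#!/usr/bin/env Rscript
# Stage 5: composite soil quality index and its microbial drivers.
#
# The index averages z-scores of 13 soil chemical, enzymatic and
# respiration variables; control and residue-retention groups are compared
# by Welch t test.  A random forest (1000 trees) then ranks microbial
# features -- richness per community, module abundance z-scores, and
# treatment-subnetwork metrics (P/N, robustness, connectedness, broadcast
# to member samples) -- by permutation importance (%IncMSE), with
# significance from 50 target-permuted refits.

library(soilwebs)

seed <- 1L
data_dir <- "results/data"
net_dir <- "results/network"
out <- "results/soilquality"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

meta <- read_sample_table(file.path(data_dir, "metadata.tsv"))
soil <- read_sample_table(file.path(data_dir, "soil.tsv"))

qi <- quality_index(soil)
write_sample_table(qi, file.path(out, "quality_index.tsv"))
cmp <- group_compare(qi$sqi, meta$residue)
cat(sprintf("soil quality: CK %.2f, RR %.2f (t = %.2f, p = %.2g)\n",
            cmp$mean_a, cmp$mean_b, cmp$statistic, cmp$p_value))

rich <- list(); modz <- list(); tm_rows <- list()
for (nm in c("prokaryote", "fungus")) {
  tab <- read_asv_table(file.path(data_dir, paste0("asv_", nm, ".tsv")))
  rich[[nm]] <- richness(tab)
  z <- read_sample_table(file.path(net_dir, paste0("module_z_", nm, ".tsv")))
  zm <- as.matrix(z[, -1]); rownames(zm) <- z$sample_id
  modz[[nm]] <- zm
  sub <- read.delim(file.path(net_dir, paste0("subnetworks_", nm, ".tsv")))
  row <- sub[, c("group", "robustness", "connectedness", "pn_ratio")]
  colnames(row)[-1] <- paste0(nm, "_", colnames(row)[-1])
  tm_rows[[nm]] <- row
}
tm <- Reduce(function(a, b) merge(a, b, by = "group"), tm_rows)
tm <- tm[, c(TRUE, !vapply(tm[-1], anyNA, logical(1))), drop = FALSE]

feats <- feature_matrix(meta, richness = rich, module_z = modz,
                        treatment_metrics = tm)
write_sample_table(feats, file.path(out, "features.tsv"))

imp <- importance(feats, qi$sqi, n_trees = 1000L, seed = seed, n_null = 50L)
write.table(imp$importance, file.path(out, "importance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("random forest: %.1f%% variance explained\n",
            100 * imp$variance_explained))
cat("top predictors of soil quality:\n")
print(head(imp$importance, 8))
cat("wrote", out, "\n")
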