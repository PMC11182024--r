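#!/usr/bin/env Rscript
# Stage 2: alpha diversity, ordination, and permutation tests.
#
# Richness per sample, Bray-Curtis PCoA, sequential three-factor PERMANOVA
# (residue, FT intensity, cycle; 999 permutations), and a Mantel test of
# community dissimilarity against the soil-property distance matrix.

library(soilwebs)

seed <- 1L
data_dir <- "results/data"
out <- "results/diversity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

meta <- read_sample_table(file.path(data_dir, "metadata.tsv"))
soil <- read_sample_table(file.path(data_dir, "soil.tsv"))
soil_num <- as.matrix(soil[, setdiff(colnames(soil), "sample_id")])
rownames(soil_num) <- soil$sample_id

for (nm in c("prokaryote", "fungus")) {
  tab <- read_asv_table(file.path(data_dir, paste0("asv_", nm, ".tsv")))
  rich <- richness(tab)
  write_sample_table(data.frame(sample_id = names(rich), richness = rich),
                     file.path(out, paste0("richness_", nm, ".tsv")))
  is_rr <- meta$residue == "RR"
  cat(sprintf("%s richness: CK %.1f, RR %.1f (t-test p = %.2g)\n", nm,
              mean(rich[!is_rr]), mean(rich[is_rr]),
              group_compare(rich, meta$residue)$p_value))

  d <- bray_curtis(tab)
  write_distance_matrix(d, file.path(out, paste0("braycurtis_", nm, ".tsv")))
  ord <- pcoa(d, n_axes = 2)
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates)
  write_sample_table(coords, file.path(out, paste0("pcoa_", nm, ".tsv")))
  cat(sprintf("%s PCoA: axes explain %.1f%% + %.1f%%\n", nm,
              100 * ord$proportion_explained[1],
              100 * ord$proportion_explained[2]))

  terms <- data.frame(residue = meta$residue, ft_intensity = meta$ft_intensity,
                      cycle = factor(meta$cycle))
  pm <- permanova(d, terms, n_perm = 999, seed = seed)
  write.table(pm, file.path(out, paste0("permanova_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s PERMANOVA: %s\n", nm,
              paste(sprintf("%s F=%.2f p=%.3f", pm$term, pm$statistic,
                            pm$p_value), collapse = "; ")))

  mt <- mantel_test(d, dist(scale(soil_num)), n_perm = 999, seed = seed)
  cat(sprintf("%s Mantel vs soil properties: r = %.3f, p = %.3f\n",
              nm, mt$statistic, mt$p_value))
}
cat("wrote", out, "\n")
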