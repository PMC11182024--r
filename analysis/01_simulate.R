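#!/usr/bin/env Rscript
# Stage 1: generate the synthetic microcosm datasets.
#
# Emulates the 96-pot factorial incubation (control vs maize residue
# retention x three freeze-thaw intensities x 1/3/6/12 cycles x 4
# replicates): a prokaryote-like ASV table rarefied to 32,582 reads, a
# fungus-like table rarefied to 11,975 reads, and the 15 monitored soil
# variables with planted residue-retention effects.  Ground truth (planted
# modules, responder taxa, soil effects) is saved for the recovery stages.

library(soilwebs)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

meta <- generate_design(design_spec())
write_sample_table(meta, file.path(out, "metadata.tsv"))
cat(sprintf("design: %d samples (%s)\n", nrow(meta),
            paste(dim(table(meta$residue, meta$ft_intensity)), collapse = " x ")))

communities <- list(
  prokaryote = community_params(),
  fungus = community_params(n_taxa = 300L, depth = 11975L,
                            module_sizes = c(30L, 25L, 20L, 15L))
)
truths <- list()
for (nm in names(communities)) {
  gen <- generate_community(meta, communities[[nm]], seed = seed + match(nm, names(communities)))
  write_asv_table(gen$table, file.path(out, paste0("asv_", nm, ".tsv")))
  truths[[nm]] <- gen$truth
  cat(sprintf("%s table: %d taxa, depth %d, richness %.0f-%.0f\n", nm,
              ncol(gen$table), sum(gen$table[1, ]),
              min(richness(gen$table)), max(richness(gen$table))))
}
jsonlite::write_json(lapply(truths, function(t) {
  mot <- t$module_of_taxon
  t$module_of_taxon <- as.list(mot[!is.na(mot)])   # background taxa omitted
  t
}), file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

soil <- generate_soil_properties(meta, seed = seed + 10L)
write_sample_table(soil, file.path(out, "soil.tsv"))
is_rr <- meta$residue == "RR"
for (v in names(soil_default_effects())) {
  cat(sprintf("  %s: RR/CK ratio %.3f (planted %.3f)\n", v,
              mean(soil[[v]][is_rr]) / mean(soil[[v]][!is_rr]),
              soil_default_effects()[[v]]))
}
cat("wrote", out, "\n")
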