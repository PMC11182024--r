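#!/usr/bin/env Rscript
# Stage 4: co-occurrence networks, modules, node roles and stability.
#
# Networks are built from Spearman correlations among taxa occurring in
# more than half the samples (|rho| >= 0.6, BH-adjusted p <= 0.01).
# Modules come from greedy modularity optimization (module 1 = largest);
# node roles use the Zi-Pi scheme (keystones: Zi > 2.5 or Pi > 0.625).
# Stability is summarized as robustness to random removal of half the
# nodes, same-component connectedness, and the positive/negative edge
# ratio; residue-level subnetworks allow treatment contrasts.  Planted
# module recovery is scored against ground truth when available.

library(soilwebs)

seed <- 1L
data_dir <- "results/data"
out <- "results/network"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

meta <- read_sample_table(file.path(data_dir, "metadata.tsv"))
truth_path <- file.path(data_dir, "ground_truth.json")
truths <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL

for (nm in c("prokaryote", "fungus")) {
  tab <- read_asv_table(file.path(data_dir, paste0("asv_", nm, ".tsv")))
  net <- cooccurrence_network(tab)
  part <- detect_modules(net, seed = seed)
  zp <- zipi(net, part)
  write_network(net, file.path(out, paste0("network_", nm)))
  write.table(zp, file.path(out, paste0("zipi_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pn <- pn_ratio(net)
  cat(sprintf("%s: %d nodes, %d edges (%d+/%d-), modularity %.2f, %d keystones\n",
              nm, igraph::vcount(net), igraph::ecount(net), pn$positive,
              pn$negative, part$modularity, sum(zp$keystone)))
  cat(sprintf("%s: robustness %.3f, connectedness %.3f, P/N %s\n", nm,
              robustness(net, seed = seed), connectedness(net),
              ifelse(pn$degenerate, "undefined (no negative edges)",
                     sprintf("%.2f", pn$ratio))))

  if (!is.null(truths) && requireNamespace("mclust", quietly = TRUE)) {
    truth <- unlist(truths[[nm]]$module_of_taxon)   # planted taxa only
    common <- intersect(names(truth), names(part$membership))
    cat(sprintf("%s planted-module recovery ARI: %.3f\n", nm,
                mclust::adjustedRandIndex(truth[common],
                                          part$membership[common])))
  }

  # module abundance (z-scores) for the four largest modules
  sizes <- sort(base::table(part$membership), decreasing = TRUE)
  keep <- as.integer(names(sizes))[seq_len(min(4, length(sizes)))]
  mem <- part$membership[part$membership %in% keep]
  z <- module_abundance(tab, mem)
  write_sample_table(data.frame(sample_id = rownames(z), z),
                     file.path(out, paste0("module_z_", nm, ".tsv")))
  is_rr <- meta$residue == "RR"
  for (m in colnames(z))
    cat(sprintf("  %s %s: mean z CK %.2f, RR %.2f\n", nm, m,
                mean(z[!is_rr, m]), mean(z[is_rr, m])))

  # residue-level subnetworks
  metrics <- do.call(rbind, lapply(unique(meta$residue), function(lv) {
    sn <- subnetwork(net, tab, meta$sample_id[meta$residue == lv])
    pn_s <- pn_ratio(sn)
    data.frame(group = lv, nodes = igraph::vcount(sn),
               edges = igraph::ecount(sn),
               robustness = robustness(sn, seed = seed),
               connectedness = connectedness(sn),
               pn_ratio = pn_s$ratio)
  }))
  write.table(metrics, file.path(out, paste0("subnetworks_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(metrics)
}
cat("wrote", out, "\n")
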