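#' Pairwise Spearman correlation with t-approximation p-values
#'
#' Correlates taxa across samples using Spearman's rho (average ranks for
#' ties) and two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.  Constant taxa have undefined
#' correlations; these are recorded as rho 0 with p 1 and flagged.
#'
#' @param table samples x taxa matrix (>= 4 samples), normally
#'   prevalence-filtered first.
#' @param method correlation method; only `"spearman"` is offered.
#' @return List with symmetric `rho` and `p` matrices (unit diagonal,
#'   zero-diagonal p) and `flagged`, the taxa with zero variance.
#' @export
correlation_matrix <- function(table, method = "spearman") {
  method <- match.arg(method, "spearman")
  if (nrow(table) < 4) stopf("need at least 4 samples for correlation")
  n <- nrow(table)
  constant <- apply(table, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(cor(table, method = "spearman"))
  rho[constant, ] <- 0
  rho[, constant] <- 0
  diag(rho) <- 1
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  p[constant, ] <- 1
  p[, constant] <- 1
  diag(p) <- 0
  list(rho = rho, p = p, flagged = colnames(table)[constant])
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `adj_(k) = min_(j>=k) (p_(j) * m / j)`, capped at 1.
#' Thin wrapper over [stats::p.adjust()] that also accepts a symmetric
#' p-value matrix, adjusting the upper triangle and mirroring it back.
#'
#' @param p numeric vector in \\[0, 1\\], or a symmetric matrix.
#' @return Adjusted values, same shape as the input.
#' @export
bh_adjust <- function(p) {
  if (is.matrix(p)) {
    up <- upper.tri(p)
    adj <- p
    adj[up] <- p.adjust(p[up], method = "BH")
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    return(adj)
  }
  p.adjust(p, method = "BH")
}

#' Build a signed co-occurrence network from thresholded correlations
#'
#' Keeps an edge between two taxa iff `|rho| >= r_min` and
#' `p_adj <= p_max`; the threshold is on the correlation magnitude so that
#' negative associations survive (they carry sign `"-"`).  Isolated nodes
#' are retained.
#'
#' @param rho symmetric Spearman matrix.
#' @param p_adj symmetric FDR-adjusted p-value matrix.
#' @param r_min correlation magnitude threshold in (0, 1].
#' @param p_max adjusted p-value threshold.
#' @return An undirected [igraph::igraph] graph with edge attributes `rho`,
#'   `p_adj`, `sign` and `weight` (= |rho|), plus graph attributes recording
#'   the thresholds.
#' @export
build_network <- function(rho, p_adj, r_min = 0.6, p_max = 0.01) {
  if (r_min <= 0 || r_min > 1) stopf("`r_min` must be in (0, 1]")
  if (!identical(dim(rho), dim(p_adj))) stopf("rho and p_adj differ in size")
  taxa <- colnames(rho)
  keep <- abs(rho) >= r_min & p_adj <= p_max
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = ncol(rho), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = taxa)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$rho <- rho[idx]
    igraph::E(g)$p_adj <- p_adj[idx]
    igraph::E(g)$sign <- ifelse(rho[idx] >= 0, "+", "-")
    igraph::E(g)$weight <- abs(rho[idx])
  }
  g <- igraph::set_graph_attr(g, "r_min", r_min)
  igraph::set_graph_attr(g, "p_max", p_max)
}

#' Construct a co-occurrence network from a count table
#'
#' Convenience wrapper chaining [prevalence_filter()],
#' [correlation_matrix()], [bh_adjust()] and [build_network()].
#'
#' @inheritParams build_network
#' @param table samples x taxa count matrix.
#' @param min_prevalence occurrence-prevalence threshold (strict).
#' @export
cooccurrence_network <- function(table, min_prevalence = 0.5,
                                 r_min = 0.6, p_max = 0.01) {
  filtered <- prevalence_filter(table, min_prevalence)
  if (ncol(filtered) < 2) stopf("fewer than 2 taxa pass the prevalence filter")
  cm <- correlation_matrix(filtered)
  build_network(cm$rho, bh_adjust(cm$p), r_min = r_min, p_max = p_max)
}

#' Detect network modules by greedy modularity optimization
#'
#' Fast-greedy modularity optimization on the unsigned graph.  Module ids
#' are assigned in order of decreasing node count, so module 1 is always the
#' largest.  An edgeless network yields singleton modules.
#'
#' @param network igraph graph.
#' @param seed integer seed (the greedy algorithm is deterministic; the seed
#'   is consumed for interface uniformity and forward compatibility).
#' @return List with `membership` (named integer vector, one id per node)
#'   and `modularity`.
#' @export
detect_modules <- function(network, seed = 1L) {
  if (igraph::vcount(network) == 0) stopf("empty network")
  if (igraph::ecount(network) == 0) {
    mem <- seq_len(igraph::vcount(network))
    names(mem) <- igraph::V(network)$name
    return(list(membership = mem, modularity = 0))
  }
  cl <- with_seed(seed, igraph::cluster_fast_greedy(
    network, weights = abs(igraph::E(network)$weight)))
  # cut the merge tree at the fewest communities attaining max modularity
  # (ties resolved toward merging, so a clique is one module)
  Q <- cl$modularity
  i_best <- max(which(Q >= max(Q) - 1e-12))
  mem <- igraph::cut_at(cl, no = igraph::vcount(network) - i_best + 1L)
  names(mem) <- igraph::V(network)$name
  sizes <- table(mem)
  # relabel by descending size; ties broken by first appearance
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  mem2 <- relabel[as.character(mem)]
  names(mem2) <- igraph::V(network)$name
  list(membership = mem2,
       modularity = igraph::modularity(network, mem,
                                       weights = abs(igraph::E(network)$weight)))
}

#' Zi-Pi node topology and keystone classification
#'
#' Within-module degree z-score `Zi = (k_within - mean_module) / sd_module`
#' (0 where the module sd is 0) and among-module connectivity (participation
#' coefficient) `Pi = 1 - sum_s (k_is / k_i)^2`; isolated nodes get Pi = 0.
#' Nodes are classed as peripheral, module hub (`Zi > zi_threshold`),
#' connector (`Pi > pi_threshold`) or network hub (both); hubs and
#' connectors are keystones.
#'
#' @param network igraph graph.
#' @param partition result of [detect_modules()] (or a named membership
#'   vector covering every node).
#' @param zi_threshold,pi_threshold role thresholds (defaults 2.5 / 0.625).
#' @return data.frame with `node`, `module`, `degree`, `zi`, `pi`, `role`,
#'   `keystone`.
#' @export
zipi <- function(network, partition, zi_threshold = 2.5, pi_threshold = 0.625) {
  mem <- if (is.list(partition)) partition$membership else partition
  nodes <- igraph::V(network)$name
  if (!all(nodes %in% names(mem))) stopf("partition does not cover all nodes")
  mem <- mem[nodes]
  A <- as.matrix(igraph::as_adjacency_matrix(network, sparse = TRUE)) > 0
  k <- rowSums(A)
  mods <- sort(unique(mem))
  # k_is: links of node i into module s
  k_is <- sapply(mods, function(s) rowSums(A[, mem == s, drop = FALSE]))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, nrow = length(nodes))
  k_within <- k_is[cbind(seq_along(nodes), match(mem, mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    in_s <- mem == s
    mu <- mean(k_within[in_s])
    sdev <- sd(k_within[in_s])
    zi[in_s] <- if (is.na(sdev) || sdev == 0) 0 else (k_within[in_s] - mu) / sdev
  }
  pi <- ifelse(k == 0, 0, 1 - rowSums((k_is / pmax(k, 1))^2))
  hub <- zi > zi_threshold
  conn <- pi > pi_threshold
  role <- ifelse(hub & conn, "network-hub",
          ifelse(hub, "module-hub",
          ifelse(conn, "connector", "peripheral")))
  data.frame(node = nodes, module = unname(mem), degree = unname(k),
             zi = unname(zi), pi = unname(pi), role = role,
             keystone = hub | conn, row.names = NULL)
}

#' Network robustness to random node removal
#'
#' Removes `floor(removal_fraction * N)` nodes uniformly at random and
#' scores the fraction of the original nodes that survive with at least one
#' remaining link; reported as the mean over trials.  `exact = TRUE`
#' enumerates every removal set instead (feasible for small graphs) and
#' returns the exact expectation.
#'
#' @param network igraph graph (>= 2 nodes).
#' @param removal_fraction fraction of nodes to remove, in (0, 1).
#' @param trials Monte-Carlo trials.
#' @param seed integer seed.
#' @param exact enumerate all removal sets.
#' @return Robustness in \\[0, 1\\].
#' @export
robustness <- function(network, removal_fraction = 0.5, trials = 100L,
                       seed = 1L, exact = FALSE) {
  N <- igraph::vcount(network)
  if (N < 2) stopf("need at least 2 nodes")
  if (removal_fraction <= 0 || removal_fraction >= 1)
    stopf("`removal_fraction` must be in (0, 1)")
  k <- floor(removal_fraction * N)
  if (k == 0) return(mean(igraph::degree(network) > 0))
  A <- as.matrix(igraph::as_adjacency_matrix(network)) > 0
  survivors <- function(removed) {
    keep <- setdiff(seq_len(N), removed)
    sum(rowSums(A[keep, keep, drop = FALSE]) > 0)
  }
  if (exact) {
    if (choose(N, k) > 2e5) stopf("exact enumeration infeasible for this graph")
    sets <- combn(N, k)
    return(mean(apply(sets, 2, survivors)) / N)
  }
  with_seed(seed, {
    mean(vapply(seq_len(trials),
                function(t) survivors(sample.int(N, k)), numeric(1))) / N
  })
}

#' Connectedness of a network
#'
#' Fraction of unordered node pairs lying in the same connected component,
#' `sum_c n_c (n_c - 1) / (N (N - 1))`; alternatively the fraction of nodes
#' in the largest component.
#'
#' @param network igraph graph (>= 2 nodes).
#' @param method `"pairs"` (default) or `"largest"`.
#' @return Value in \\[0, 1\\]; 1 for a connected graph, 0 for an edgeless one
#'   under `"pairs"`.
#' @export
connectedness <- function(network, method = c("pairs", "largest")) {
  method <- match.arg(method)
  N <- igraph::vcount(network)
  if (N < 2) stopf("need at least 2 nodes")
  sizes <- igraph::components(network)$csize
  if (method == "pairs") sum(sizes * (sizes - 1)) / (N * (N - 1))
  else max(sizes) / N
}

#' Ratio of positive to negative edges
#'
#' @param network igraph graph with a `sign` edge attribute.
#' @return List with `ratio` (NA when there are no negative edges),
#'   `positive`, `negative` and `degenerate`.
#' @export
pn_ratio <- function(network) {
  signs <- if (igraph::ecount(network) > 0) igraph::E(network)$sign else character(0)
  pos <- sum(signs == "+")
  neg <- sum(signs == "-")
  list(ratio = if (neg == 0) NA_real_ else pos / neg,
       positive = pos, negative = neg, degenerate = neg == 0)
}

#' Treatment subnetwork
#'
#' Induced subgraph on the taxa present (count > 0) in at least one sample
#' of the subset; edges are inherited from the full network.
#'
#' @param network full igraph network.
#' @param table samples x taxa count matrix the network was built from.
#' @param sample_subset sample ids defining the treatment.
#' @return igraph graph.
#' @export
subnetwork <- function(network, table, sample_subset) {
  if (length(sample_subset) == 0) stopf("`sample_subset` is empty")
  missing <- setdiff(sample_subset, rownames(table))
  if (length(missing))
    stopf("unknown sample(s): %s", paste(missing, collapse = ", "))
  sub <- table[sample_subset, , drop = FALSE]
  present <- colnames(sub)[colSums(sub) > 0]
  keep <- intersect(igraph::V(network)$name, present)
  igraph::induced_subgraph(network, keep)
}

#' Per-sample module abundance z-scores
#'
#' For each module, sums the relative abundances of its member taxa in every
#' sample and z-scores the sums across samples (sample sd, n - 1).  Modules
#' with zero variance get NA z-scores and are flagged.
#'
#' @param table samples x taxa count matrix (must contain every partitioned
#'   taxon).
#' @param partition result of [detect_modules()] or a named membership
#'   vector.
#' @param min_size only report modules with at least this many member taxa.
#' @return samples x modules matrix of z-scores (columns `M1`, `M2`, ...),
#'   with attributes `raw` (unstandardized relative abundances) and
#'   `degenerate` (modules with zero variance).
#' @export
module_abundance <- function(table, partition, min_size = 1L) {
  mem <- if (is.list(partition)) partition$membership else partition
  missing <- setdiff(names(mem), colnames(table))
  if (length(missing))
    stopf("module taxa absent from table: %s",
          paste(head(missing, 5), collapse = ", "))
  rel <- relative_abundance(table)
  sizes <- base::table(mem)
  mods <- as.integer(names(sizes)[sizes >= min_size])
  mods <- sort(mods)
  raw <- sapply(mods, function(m) {
    members <- names(mem)[mem == m]
    rowSums(rel[, members, drop = FALSE])
  })
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = nrow(table))
  colnames(raw) <- paste0("M", mods)
  rownames(raw) <- rownames(table)
  sds <- apply(raw, 2, sd)
  z <- scale(raw)
  z[, sds == 0] <- NA_real_
  degenerate <- colnames(raw)[sds == 0]
  if (length(degenerate))
    warnf("module(s) with zero abundance variance: %s",
          paste(degenerate, collapse = ", "))
  out <- z[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "raw") <- raw
  attr(out, "degenerate") <- degenerate
  out
}

#' Serialize a network
#'
#' Writes a tab-separated edge list (`node_a`, `node_b`, `rho`, `p_adj`,
#' `sign`) and, optionally, GraphML.
#'
#' @param network igraph graph.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml` when `graphml = TRUE`.
#' @param graphml also write GraphML.
#' @export
write_network <- function(network, prefix, graphml = FALSE) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   rho = if (nrow(el)) igraph::E(network)$rho else numeric(0),
                   p_adj = if (nrow(el)) igraph::E(network)$p_adj else numeric(0),
                   sign = if (nrow(el)) igraph::E(network)$sign else character(0))
  write.table(df, paste0(prefix, "_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (graphml)
    igraph::write_graph(network, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
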