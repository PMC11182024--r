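# Shared fixtures, all built in code.

# A small deterministic count table with named dimensions.
toy_table <- function(counts, samples = NULL, taxa = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- taxa %||% paste0("T", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_tempfile <- function(ext = ".tsv") {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(path), envir = parent.frame())
  path
}

# A compact factorial design: 2 residues x 1 FT level x 2 cycles x `reps`.
small_design <- function(reps = 3L) {
  generate_design(design_spec(ft_levels = "FT1", cycles = c(1L, 3L),
                              replicates = reps))
}

# Desk-scale community parameters used where full depth is unnecessary.
small_params <- function(...) {
  defaults <- list(n_taxa = 80L, depth = 1500L, n_modules = 2L,
                   module_sizes = c(15L, 12L), copiotroph_fraction = 0.15)
  do.call(community_params, utils::modifyList(defaults, list(...)))
}

# Graph from an explicit edge list over named nodes, with sign attributes.
graph_from_edges <- function(nodes, edges, rho = NULL) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(edges)) {
    ends <- unlist(edges)
    g <- igraph::add_edges(g, match(ends, nodes))
    rho <- rho %||% rep(0.8, length(ends) / 2)
    igraph::E(g)$rho <- rho
    igraph::E(g)$weight <- abs(rho)
    igraph::E(g)$sign <- ifelse(rho >= 0, "+", "-")
    igraph::E(g)$p_adj <- 0.001
  }
  g
}

# Brute-force Spearman from the classic sum-of-squared-rank-differences
# formula (valid without ties); independent of stats::cor.
spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
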