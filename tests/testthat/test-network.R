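test_that("Spearman matches the exhaustive rank formula on 5-point vectors", {
  set.seed(31)
  tab <- toy_table(matrix(sample(1:100, 25), nrow = 5))  # no ties
  cm <- correlation_matrix(tab)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(cm$rho[i, j], spearman_d2(tab[, i], tab[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(cm$rho)), rep(1, 5))
  rev5 <- toy_table(cbind(1:5, 5:1, c(2L, 1L, 4L, 3L, 5L)))
  cmr <- correlation_matrix(rev5)
  expect_equal(cmr$rho[1, 2], -1)
  expect_equal(cmr$p[1, 2], 0)
})

test_that("constant taxa are flagged with rho 0 and p 1", {
  tab <- toy_table(cbind(c(1L, 2L, 3L, 4L), rep(7L, 4), c(2L, 1L, 4L, 3L)))
  cm <- correlation_matrix(tab)
  expect_equal(cm$flagged, "T2")
  expect_equal(cm$rho[1, 2], 0)
  expect_equal(cm$p[1, 2], 1)
  expect_error(correlation_matrix(tab[1:3, ]), "at least 4")
})

test_that("BH adjustment applies the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # matrix form adjusts the off-diagonal entries symmetrically
  p <- matrix(c(0, 0.01, 0.02, 0.01, 0, 0.03, 0.02, 0.03, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  adj <- bh_adjust(p)
  expect_equal(adj[1, 2], 0.03)
  expect_equal(adj, t(adj))
})

test_that("network construction enforces both thresholds and stores signs", {
  taxa <- c("A", "B", "C")
  rho <- matrix(c(1, 0.7, -0.8, 0.7, 1, 0.59, -0.8, 0.59, 1), 3,
                dimnames = list(taxa, taxa))
  p <- matrix(c(0, 0.001, 0.005, 0.001, 0, 1e-4, 0.005, 1e-4, 0), 3,
              dimnames = list(taxa, taxa))
  net <- build_network(rho, p, r_min = 0.6, p_max = 0.01)
  edges <- igraph::as_edgelist(net)
  expect_equal(nrow(edges), 2)                     # |0.59| fails r_min
  key <- paste(edges[, 1], edges[, 2])
  expect_setequal(key, c("A B", "A C"))
  signs <- stats::setNames(igraph::E(net)$sign, key)
  expect_equal(unname(signs["A B"]), "+")
  expect_equal(unname(signs["A C"]), "-")
  expect_equal(igraph::vcount(net), 3)             # isolated node retained
  expect_error(build_network(rho, p, r_min = 0), "r_min")

  # raising r_min never adds edges
  e1 <- igraph::ecount(build_network(rho, p, r_min = 0.5))
  e2 <- igraph::ecount(build_network(rho, p, r_min = 0.75))
  expect_lte(e2, e1)
})

test_that("module detection separates disconnected cliques and orders by size", {
  nodes <- paste0("n", 1:11)
  clique <- function(members) t(combn(members, 2))
  edges <- rbind(clique(nodes[1:5]), clique(nodes[6:11]))
  g <- graph_from_edges(nodes, as.list(t(edges)))
  part <- detect_modules(g)
  expect_equal(length(unique(part$membership)), 2)
  # clique of 6 is module 1 (largest first)
  expect_true(all(part$membership[nodes[6:11]] == 1))
  expect_true(all(part$membership[nodes[1:5]] == 2))
  expect_gt(part$modularity, 0.4)

  tri <- graph_from_edges(c("a", "b", "c"), list(c("a","b"), c("b","c"), c("a","c")))
  expect_equal(length(unique(detect_modules(tri)$membership)), 1)

  lone <- graph_from_edges(paste0("x", 1:5), list())
  expect_equal(sort(unname(detect_modules(lone)$membership)), 1:5)
})

test_that("Zi-Pi matches hand-computed values on a two-module toy graph", {
  # two triangles bridged by node b1 with 4 links split evenly
  nodes <- c("a1", "a2", "a3", "b1", "c1", "c2", "c3")
  edges <- list(c("a1","a2"), c("a1","a3"), c("a2","a3"),
                c("c1","c2"), c("c1","c3"), c("c2","c3"),
                c("b1","a1"), c("b1","a2"), c("b1","c1"), c("b1","c2"))
  g <- graph_from_edges(nodes, edges)
  mem <- c(a1 = 1, a2 = 1, a3 = 1, b1 = 1, c1 = 2, c2 = 2, c3 = 2)
  zp <- zipi(g, mem)
  rownames(zp) <- zp$node
  # b1: degree 4, 2 links in each module -> pi = 1 - (0.5^2 + 0.5^2) = 0.5
  expect_equal(zp["b1", "pi"], 0.5, tolerance = 1e-12)
  # a3: all links inside its module -> pi = 0
  expect_equal(zp["a3", "pi"], 0, tolerance = 1e-12)
  # hand Zi in module 1: within-degrees a1=3, a2=3, a3=2, b1=2 (mean 2.5, sd 0.5774)
  expect_equal(zp["a1", "zi"], (3 - 2.5) / sd(c(3, 3, 2, 2)), tolerance = 1e-12)
  expect_equal(zp["a3", "zi"], (2 - 2.5) / sd(c(3, 3, 2, 2)), tolerance = 1e-12)
  # keystone rule: pi > 0.625 or zi > 2.5
  expect_false(zp["b1", "keystone"])
  hub <- zipi(g, mem, pi_threshold = 0.45)
  rownames(hub) <- hub$node
  expect_true(hub["b1", "keystone"])
  expect_equal(hub["b1", "role"], "connector")
})

test_that("robustness: complete graph, edgeless graph, exact star enumeration", {
  k10 <- graph_from_edges(paste0("k", 1:10),
                          as.list(as.data.frame(combn(paste0("k", 1:10), 2))))
  expect_equal(robustness(k10, 0.5, trials = 25, seed = 1), 0.5)

  lone <- graph_from_edges(paste0("x", 1:4), list())
  expect_equal(robustness(lone, 0.5, trials = 10, seed = 1), 0)

  star <- graph_from_edges(c("hub", paste0("leaf", 1:4)),
                           lapply(paste0("leaf", 1:4), function(l) c("hub", l)))
  # enumeration oracle over all C(5,2) removals of 2 nodes
  A <- as.matrix(igraph::as_adjacency_matrix(star)) > 0
  combos <- combn(5, 2)
  oracle <- mean(apply(combos, 2, function(rm) {
    keep <- setdiff(1:5, rm)
    sum(rowSums(A[keep, keep, drop = FALSE]) > 0)
  })) / 5
  expect_equal(oracle, 0.36)
  expect_equal(robustness(star, 0.4, exact = TRUE), oracle, tolerance = 1e-12)
  expect_equal(robustness(star, 0.4, trials = 4000, seed = 2), oracle,
               tolerance = 0.03)
  expect_error(robustness(star, 1.2), "removal_fraction")

  # robustness is non-increasing in the removal fraction
  vals <- sapply(seq(0.1, 0.9, by = 0.2),
                 function(f) robustness(k10, f, exact = TRUE))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("connectedness counts same-component pairs", {
  nodes <- paste0("n", 1:5)
  g <- graph_from_edges(nodes, list(c("n1","n2"), c("n2","n3"), c("n4","n5")))
  expect_equal(connectedness(g), (6 + 2) / 20)
  expect_equal(connectedness(g, method = "largest"), 3 / 5)
  full <- graph_from_edges(nodes, as.list(as.data.frame(combn(nodes, 2))))
  expect_equal(connectedness(full), 1)
  lone <- graph_from_edges(nodes, list())
  expect_equal(connectedness(lone), 0)
})

test_that("P/N ratio counts signed edges and flags the degenerate case", {
  nodes <- paste0("n", 1:8)
  pairs <- t(combn(nodes, 2))[1:8, ]
  g <- graph_from_edges(nodes, as.list(as.data.frame(t(pairs))),
                        rho = c(rep(0.8, 6), rep(-0.8, 2)))
  pn <- pn_ratio(g)
  expect_equal(pn$ratio, 3)
  expect_equal(pn$positive, 6)
  g2 <- graph_from_edges(nodes, as.list(as.data.frame(t(pairs))),
                         rho = rep(0.8, 8))
  pn2 <- pn_ratio(g2)
  expect_true(pn2$degenerate)
  expect_true(is.na(pn2$ratio))
  # random signs with p = 0.5: ratio near 1
  set.seed(17)
  nodes <- paste0("m", 1:50)
  pairs <- t(combn(nodes, 2))
  pick <- pairs[sample(nrow(pairs), 1000), ]
  g3 <- graph_from_edges(nodes, as.list(as.data.frame(t(pick))),
                         rho = sample(c(0.8, -0.8), 1000, replace = TRUE))
  expect_equal(pn_ratio(g3)$ratio, 1, tolerance = 0.15)
})

test_that("subnetworks drop taxa absent from the sample subset", {
  tab <- toy_table(rbind(c(5L, 0L, 2L), c(3L, 1L, 0L), c(0L, 4L, 1L)),
                   taxa = c("A", "B", "C"))
  net <- graph_from_edges(c("A", "B", "C"),
                          list(c("A", "B"), c("B", "C"), c("A", "C")))
  all_s <- subnetwork(net, tab, rownames(tab))
  expect_equal(igraph::vcount(all_s), 3)
  expect_equal(igraph::ecount(all_s), 3)
  s1 <- subnetwork(net, tab, "S1")       # B absent in S1
  expect_setequal(igraph::V(s1)$name, c("A", "C"))
  expect_equal(igraph::ecount(s1), 1)
  expect_error(subnetwork(net, tab, "nope"), "unknown sample")
  expect_error(subnetwork(net, tab, character(0)), "empty")
})

test_that("module abundance z-scores are centered and flag degenerate modules", {
  meta <- small_design()
  gen <- generate_community(meta, small_params(), seed = 12)
  truth_mem <- gen$truth$module_of_taxon
  mem <- truth_mem[!is.na(truth_mem)]
  z <- module_abundance(gen$table, mem)
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-10)

  # module covering all taxa: abundance 1 everywhere, sd 0 -> flagged NA
  tab <- toy_table(matrix(rpois(12, 8) + 1L, nrow = 3))
  full <- stats::setNames(rep(1L, 4), colnames(tab))
  expect_warning(zf <- module_abundance(tab, full), "zero abundance variance")
  expect_true(all(is.na(zf[, "M1"])))
  expect_error(module_abundance(tab[, 1:2], full), "absent from table")
})

test_that("networks serialize to edge lists", {
  nodes <- c("A", "B", "C")
  g <- graph_from_edges(nodes, list(c("A", "B"), c("B", "C")),
                        rho = c(0.9, -0.7))
  prefix <- tempfile()
  write_network(g, prefix)
  el <- read.delim(paste0(prefix, "_edges.tsv"))
  expect_equal(nrow(el), 2)
  expect_setequal(el$sign, c("+", "-"))
  unlink(paste0(prefix, "_edges.tsv"))
})
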