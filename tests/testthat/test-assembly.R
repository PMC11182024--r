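test_that("null draws preserve per-sample richness and totals", {
  meta <- small_design()
  tab <- generate_community(meta, small_params(), seed = 4)$table
  spec <- nst_spec(n_draws = 10, seed = 2)
  for (k in 1:5) {
    nul <- null_draw(tab, spec, draw_index = k)
    expect_equal(richness(nul), richness(tab))
    expect_equal(rowSums(nul), rowSums(tab))
  }
  # single-taxon table leaves no freedom
  one <- toy_table(matrix(c(5L, 3L, 7L), ncol = 1))
  expect_identical(null_draw(one, spec), one)
})

test_that("null occupancy tracks taxon selection probability", {
  # one focal sample with richness 1 drawn against fixed frequencies:
  # inclusion probability equals the normalized occurrence frequency
  tab <- toy_table(rbind(c(9L, 0L, 0L),
                         c(5L, 5L, 0L),
                         c(5L, 5L, 5L),
                         c(10L, 0L, 0L)))
  freq <- colMeans(tab > 0)            # 1, 0.5, 0.25
  prob <- freq / sum(freq)
  spec <- nst_spec(seed = 6)
  hits <- rowSums(sapply(1:2000, function(k) {
    null_draw(tab, spec, draw_index = k)["S1", ] > 0
  }))
  expect_equal(unname(hits / 2000), unname(prob), tolerance = 0.05)
})

test_that("NST boundary semantics: identity, coincidence, monotonicity", {
  v <- nst_pair_values(G = 0, E = 0.6)
  expect_equal(v$NST, 0)                         # identical communities
  expect_equal(nst_pair_values(0.4, 0.4)$NST, 1) # G = E
  d <- nst_pair_values(0.9, 1e-15)
  expect_equal(d$NST, 0)
  expect_true(d$degenerate)
  # holding E fixed, NST falls as |G - E| grows
  E <- 0.5
  above <- sapply(seq(0.5, 0.95, by = 0.05), function(G) nst_pair_values(G, E)$NST)
  below <- sapply(seq(0.5, 0.05, by = -0.05), function(G) nst_pair_values(G, E)$NST)
  expect_true(all(diff(above) < 1e-12))
  expect_true(all(diff(below) < 1e-12))
})

test_that("identical communities give group NST of zero", {
  row <- c(5L, 3L, 2L, 0L, 1L)
  tab <- toy_table(matrix(rep(row, 4), nrow = 4, byrow = TRUE))
  res <- pairwise_nst(tab, rep("g", 4), nst_spec(n_draws = 50, seed = 1))
  expect_equal(res$g$group_nst, 0)
})

test_that("data generated by the null model score as stochastic", {
  # template at the realistic table scale (deep rarefied community)
  meta <- generate_design(design_spec(ft_levels = "FT1", cycles = 1L,
                                      replicates = 12L))
  template <- generate_community(meta[meta$residue == "CK", ],
                                 community_params(n_modules = 0L,
                                                  copiotroph_fraction = 0),
                                 seed = 5)$table
  nulldata <- null_draw(template, nst_spec(seed = 9), draw_index = 999)
  res <- pairwise_nst(nulldata, rep("g", nrow(nulldata)),
                      nst_spec(n_draws = 200, seed = 10))
  expect_gt(res$g$group_nst, 90)
  expect_lte(res$g$group_nst, 100)
})

test_that("nst_compare behaves on self-comparison and guards inputs", {
  meta <- small_design()
  tab <- generate_community(meta, small_params(), seed = 6)$table
  res <- pairwise_nst(tab, rep("g", nrow(tab)), nst_spec(n_draws = 30, seed = 2))
  self <- nst_compare(res$g, res$g)
  expect_gt(self$p_value, 0.99)

  two <- pairwise_nst(tab[1:4, ], c("a", "a", "b", "b"),
                      nst_spec(n_draws = 20, seed = 3))
  expect_error(nst_compare(two$a, two$b), "at least 3")
})

test_that("nst_compare detects a planted deterministic shift", {
  # group A: independent draws from the null model (stochastic assembly);
  # group B: repeated subsamples of one fixed community (strong selection)
  meta <- generate_design(design_spec(ft_levels = "FT1", cycles = 1L,
                                      replicates = 8L))
  template <- generate_community(meta[meta$residue == "CK", ],
                                 community_params(n_taxa = 150L,
                                                  depth = 4000L,
                                                  n_modules = 0L,
                                                  copiotroph_fraction = 0),
                                 seed = 30)$table
  hits <- sapply(1:20, function(s) {
    a <- null_draw(template, nst_spec(seed = s), draw_index = 1)
    fixed <- template[1, , drop = FALSE]
    b <- do.call(rbind, lapply(1:8, function(i) {
      rarefy(fixed, 2000, seed = s * 100 + i)
    }))
    rownames(b) <- paste0("B", 1:8)
    tab <- rbind(a, b)
    res <- pairwise_nst(tab, rep(c("A", "B"), each = 8),
                        nst_spec(n_draws = 60, seed = s + 500))
    cmp <- nst_compare(res$A, res$B, seed = s)
    cmp$p_value < 0.05 && res$A$group_nst > res$B$group_nst
  })
  expect_gte(mean(hits), 0.9)
})

test_that("NST results serialize with their null spec", {
  tab <- toy_table(matrix(rpois(40, 6) + 1L, nrow = 4))
  res <- pairwise_nst(tab, rep("g", 4), nst_spec(n_draws = 20, seed = 5))
  prefix <- tempfile()
  write_nst(res$g, prefix)
  pairs <- read.delim(paste0(prefix, "_pairs.tsv"))
  expect_equal(nrow(pairs), 6)
  js <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(js$spec$n_draws, 20)
  expect_equal(js$group_nst_percent, res$g$group_nst, tolerance = 1e-10)
  unlink(paste0(prefix, c("_pairs.tsv", "_summary.json")))
})
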