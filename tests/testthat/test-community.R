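test_that("richness counts occupied taxa", {
  tab <- toy_table(rbind(c(0L, 0L, 5L), c(0L, 0L, 0L), c(1L, 2L, 3L)))
  expect_equal(unname(richness(tab)), c(1L, 0L, 3L))
})

test_that("Bray-Curtis matches hand values and stays in [0, 1]", {
  tab <- toy_table(rbind(c(1L, 2L), c(2L, 1L), c(1L, 2L), c(4L, 0L)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["S1", "S2"], 2 / 6)
  expect_equal(d["S1", "S3"], 0)
  expect_lt(abs(d["S4", "S1"] - (abs(4 - 1) + abs(0 - 2)) / 7), 1e-12)
  disjoint <- toy_table(rbind(c(4L, 0L), c(0L, 4L)))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)
  meta <- small_design()
  big <- generate_community(meta, small_params(), seed = 3)$table
  expect_true(all(as.vector(bray_curtis(big)) >= 0 &
                  as.vector(bray_curtis(big)) <= 1))
})

test_that("PCoA reproduces Euclidean geometry", {
  set.seed(5)
  pts <- matrix(rnorm(7 * 3), nrow = 7,
                dimnames = list(paste0("S", 1:7), NULL))
  res <- pcoa(dist(pts), n_axes = 3)
  expect_equal(as.matrix(dist(res$coordinates)), as.matrix(dist(pts)),
               tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-8))   # non-increasing
  expect_equal(sum(res$proportion_explained), 1)

  # 3 collinear points: a single positive eigenvalue carries all distance
  line <- matrix(c(0, 1, 3), dimnames = list(paste0("S", 1:3), NULL))
  expect_warning(res1 <- pcoa(dist(line), n_axes = 2), "truncating")
  expect_equal(length(res1$eigenvalues), 1L)
  expect_equal(as.vector(dist(res1$coordinates)), as.vector(dist(line)),
               tolerance = 1e-10)

  # all-equal distances among 3 samples: two equal positive eigenvalues
  eq <- matrix(1, 3, 3, dimnames = list(1:3, 1:3)) - diag(3)
  res2 <- pcoa(stats::as.dist(eq), n_axes = 2)
  expect_equal(length(res2$eigenvalues), 2L)
  expect_equal(res2$eigenvalues[1], res2$eigenvalues[2], tolerance = 1e-10)

  # single sample: zero-dimensional result
  res3 <- pcoa(matrix(0, 1, 1, dimnames = list("S1", "S1")))
  expect_equal(ncol(res3$coordinates), 0L)
})

test_that("distance matrices round-trip through disk", {
  tab <- toy_table(matrix(rpois(20, 5) + 1L, nrow = 4))
  d <- bray_curtis(tab)
  path <- withr_tempfile()
  write_distance_matrix(d, path)
  expect_equal(as.matrix(read_distance_matrix(path)), as.matrix(d),
               tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F agrees with vegan and flags bad groups", {
  set.seed(11)
  tab <- toy_table(matrix(rpois(12 * 8, 10) + 1L, nrow = 12))
  g <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(tab)
  mine <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$df, ref$Df[1])
  expect_error(permanova(d, c(rep("a", 11), "b"), n_perm = 9), "at least 2")
})

test_that("sequential factorial PERMANOVA matches vegan by-terms analysis", {
  meta <- small_design(reps = 3L)
  tab <- generate_community(meta, small_params(), seed = 8)$table
  d <- bray_curtis(tab)
  terms <- data.frame(residue = meta$residue, cycle = factor(meta$cycle))
  mine <- permanova(d, terms, n_perm = 49, seed = 2)
  ref <- vegan::adonis2(d ~ residue + cycle, data = terms, by = "terms",
                        permutations = 49)
  expect_equal(mine$statistic, ref$F[1:2], tolerance = 1e-10)
  expect_equal(mine$ss, ref$SumOfSqs[1:2], tolerance = 1e-10)
})

test_that("exhaustive PERMANOVA equals brute-force enumeration", {
  d <- stats::as.dist(matrix(c(0, 1, 4, 5,
                               1, 0, 4.2, 5.1,
                               4, 4.2, 0, 1.1,
                               5, 5.1, 1.1, 0), 4,
                             dimnames = list(paste0("S", 1:4), paste0("S", 1:4))))
  g <- c("a", "a", "b", "b")
  res <- permanova(d, g, exhaustive = TRUE)

  # independent brute force: pseudo-F over all 24 label orders
  m <- as.matrix(d)^2
  n <- 4
  f_of <- function(lab) {
    ss_tot <- sum(m[upper.tri(m)]) / n
    ss_w <- sum(sapply(unique(lab), function(l) {
      idx <- which(lab == l)
      sum(m[idx, idx][upper.tri(m[idx, idx])]) / length(idx)
    }))
    ((ss_tot - ss_w) / 1) / (ss_w / (n - 2))
  }
  perms <- rbind(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
                 c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
                 c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
                 c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                 c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  f_obs <- f_of(g)
  f_all <- apply(perms, 1, function(p) f_of(g[p]))
  expect_equal(res$statistic, f_obs, tolerance = 1e-10)
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)

  # Monte-Carlo p converges to the brute-force value
  mc <- permanova(d, g, n_perm = 9999, seed = 3)
  expect_lt(abs(mc$p_value - res$p_value), 0.03)
})

test_that("two far-separated clusters give the minimal p-value", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(16, 0, 0.01), 8), matrix(rnorm(16, 50, 0.01), 8))
  rownames(pts) <- paste0("S", 1:16)
  res <- permanova(dist(pts), rep(c("a", "b"), each = 8), n_perm = 99, seed = 1)
  expect_equal(res$p_value, 1 / 100)
})

test_that("Mantel test handles identity, degeneracy and brute force", {
  set.seed(21)
  pts <- matrix(rnorm(8), 4, dimnames = list(paste0("S", 1:4), NULL))
  d <- dist(pts)
  expect_equal(mantel_test(d, d, n_perm = 99)$statistic, 1)

  const <- stats::as.dist(matrix(1, 4, 4,
                                 dimnames = list(paste0("S", 1:4),
                                                 paste0("S", 1:4))) - diag(4))
  degen <- mantel_test(d, const)
  expect_true(degen$degenerate)
  expect_equal(degen$statistic, 0)

  d2 <- dist(pts + rnorm(8, sd = 0.3))
  ex <- mantel_test(d, d2, exhaustive = TRUE)
  r_ref <- vegan::mantel(d, d2, permutations = 0)$statistic
  expect_equal(ex$statistic, unname(r_ref), tolerance = 1e-10)
  expect_equal(ex$n_permutations, 24L)
  mc <- mantel_test(d, d2, n_perm = 9999, seed = 4)
  expect_lt(abs(mc$p_value - ex$p_value), 0.03)
  expect_error(mantel_test(d, dist(pts[1:3, ])), "size")
})
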