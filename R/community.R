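#' Per-sample richness
#'
#' Number of taxa observed (count > 0) in each sample.
#'
#' @param table samples x taxa matrix.
#' @return Named integer vector.
#' @export
richness <- function(table) {
  assert_asv_table(table)
  as.integer(rowSums(table > 0)) -> r
  stats::setNames(r, rownames(table))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d[i, j] = sum |x_i - x_j| / sum (x_i + x_j)` over taxa; bounded in
#' \\[0, 1\\] for non-negative data.
#'
#' @param table samples x taxa matrix with positive sample totals.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  assert_asv_table(table)
  if (any(rowSums(table) == 0)) stopf("zero-total sample(s) have no defined dissimilarity")
  vegan::vegdist(table, method = "bray")
}

#' Write or read a distance matrix as a square tab-separated table
#' @param d `dist` object or square matrix.
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stopf("distance matrix in %s is not symmetric", path)
  stats::as.dist(m)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of `-d^2 / 2` followed by
#' eigendecomposition.  Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; axes with non-positive eigenvalues
#' are dropped and the negative eigenvalues reported (no Cailliez
#' correction).
#'
#' @param d `dist` object or symmetric matrix.
#' @param n_axes number of axes requested; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return List with `coordinates` (samples x axes), `eigenvalues`
#'   (non-increasing, positive ones), `proportion_explained`, and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2) {
  m <- as.matrix(d)
  n <- nrow(m)
  ids <- rownames(m)
  if (n < 2) {
    return(list(coordinates = matrix(numeric(0), nrow = n, ncol = 0,
                                     dimnames = list(ids, NULL)),
                eigenvalues = numeric(0), proportion_explained = numeric(0),
                negative_eigenvalues = numeric(0)))
  }
  A <- -0.5 * m^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  neg <- e$values[e$values < -tol]
  if (n_axes > length(pos)) {
    warnf("only %d positive eigenvalue(s); truncating n_axes from %d",
          length(pos), n_axes)
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = length(keep))
  dimnames(coords) <- list(ids, if (length(keep)) paste0("PCo", seq_along(keep)))
  list(coordinates = coords,
       eigenvalues = e$values[pos],
       proportion_explained = e$values[pos] / sum(e$values[pos]),
       negative_eigenvalues = neg)
}

# All permutations of 1..n (n small); used by the exhaustive test modes.
all_perms <- function(n) {
  if (n > 8) stopf("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based ANOVA with a pseudo-F statistic and a raw-label permutation
#' test.  `groups` may be a single factor (one-way) or a data.frame whose
#' columns enter as sequential terms (Type-I sums of squares on the
#' Gower-centered inner-product matrix); interaction columns can be supplied
#' explicitly.  p-values use the `(1 + b) / (1 + m)` estimator, or exact
#' enumeration of all label orders when `exhaustive = TRUE` (then
#' `p = #\{F_perm >= F_obs\} / n!`, identity included).
#'
#' @param d `dist` or symmetric distance matrix.
#' @param groups factor/vector, or data.frame of factors (sequential terms).
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all permutations (n <= 8 samples).
#' @return data.frame with one row per term: `term`, `df`, `ss`, `statistic`
#'   (pseudo-F), `p_value`, plus attributes `n_permutations` and `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, exhaustive = FALSE) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (is.data.frame(groups)) {
    terms <- lapply(groups, function(x) factor(x))
    term_names <- colnames(groups)
  } else {
    terms <- list(factor(groups))
    term_names <- "groups"
  }
  if (length(terms[[1]]) != n) stopf("groups length must match distance matrix")
  g1 <- terms[[1]]
  if (length(terms) == 1) {
    sizes <- table(g1)
    if (length(sizes) < 2) stopf("need at least 2 groups")
    if (any(sizes < 2)) stopf("every group needs at least 2 samples")
  }

  A <- -0.5 * m^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C

  # sequential hat-matrix differences for each term
  X <- matrix(1, n, 1)
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  Hdiff <- list()
  df <- integer(0)
  for (j in seq_along(terms)) {
    X <- cbind(X, stats::model.matrix(~t, data.frame(t = terms[[j]]))[, -1, drop = FALSE])
    q <- qr(X)
    H <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    Hdiff[[j]] <- H - H_prev
    df[j] <- q$rank - rank_prev
    if (df[j] < 1) stopf("term '%s' adds no degrees of freedom", term_names[j])
    H_prev <- H
    rank_prev <- q$rank
  }
  H_res <- diag(n) - H_prev
  df_res <- n - rank_prev
  if (df_res < 1) stopf("no residual degrees of freedom")

  f_stats <- function(Gp) {
    ss_res <- sum(H_res * Gp)
    vapply(seq_along(Hdiff), function(j) {
      (sum(Hdiff[[j]] * Gp) / df[j]) / (ss_res / df_res)
    }, numeric(1))
  }
  obs <- f_stats(G)
  ss_obs <- vapply(Hdiff, function(H) sum(H * G), numeric(1))

  if (exhaustive) {
    P <- all_perms(n)
    hits <- numeric(length(obs))
    for (r in seq_len(nrow(P))) {
      Fp <- f_stats(G[P[r, ], P[r, ]])
      hits <- hits + (Fp >= obs - 1e-12)
    }
    p <- hits / nrow(P)
    n_used <- nrow(P)
  } else {
    p <- with_seed(seed, {
      hits <- numeric(length(obs))
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        Fp <- f_stats(G[idx, idx])
        hits <- hits + (Fp >= obs - 1e-12)
      }
      (1 + hits) / (1 + n_perm)
    })
    n_used <- n_perm
  }
  out <- data.frame(term = term_names, df = df, ss = ss_obs,
                    statistic = obs, p_value = p)
  attr(out, "n_permutations") <- n_used
  attr(out, "seed") <- seed
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal (lower-triangle) entries, with
#' significance from permuting one matrix's sample order.  The p-value is
#' one-sided (greater), the convention for distance-matrix association.
#' If either matrix is constant the correlation is undefined and reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param d_a,d_b `dist` objects or symmetric matrices over the same samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exhaustive enumerate all sample orders (n <= 8).
#' @return List with `statistic` (r), `p_value`, `n_permutations`, `seed`,
#'   `degenerate`.
#' @export
mantel_test <- function(d_a, d_b, n_perm = 999, seed = 1, exhaustive = FALSE) {
  a <- as.matrix(d_a); b <- as.matrix(d_b)
  if (!identical(dim(a), dim(b))) stopf("distance matrices differ in size")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stopf("distance matrices cover different samples")
  n <- nrow(a)
  low <- lower.tri(a)
  va <- a[low]
  if (sd(va) == 0 || sd(b[low]) == 0) {
    return(list(statistic = 0, p_value = NA_real_, n_permutations = 0L,
                seed = seed, degenerate = TRUE))
  }
  r_for <- function(idx) {
    vb <- b[idx, idx][low]
    if (sd(vb) == 0) return(NA_real_)
    cor(va, vb)
  }
  obs <- r_for(seq_len(n))
  if (exhaustive) {
    P <- all_perms(n)
    rs <- apply(P, 1, r_for)
    p <- mean(rs >= obs - 1e-12, na.rm = TRUE)
    n_used <- nrow(P)
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      for (k in seq_len(n_perm)) {
        rp <- r_for(sample.int(n))
        if (!is.na(rp) && rp >= obs - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
    n_used <- n_perm
  }
  list(statistic = obs, p_value = p, n_permutations = n_used, seed = seed,
       degenerate = FALSE)
}
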