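#' Null-model specification for stochasticity analysis
#'
#' The null model preserves each sample's richness (number of occupied taxa)
#' and total reads.  Occupying taxa are drawn without replacement with
#' probability proportional to their occurrence frequency across the pool of
#' samples; the sample's reads are then redistributed among the drawn taxa
#' proportional to the pool's mean relative abundances (each drawn taxon
#' keeps at least one read so realized richness is exact).
#'
#' @param n_draws number of null draws (>= 100 for reported results).
#' @param metric dissimilarity used: `"ruzicka"` (abundance-based Jaccard,
#'   the default) or `"jaccard"` (presence/absence).
#' @param seed integer seed governing all draws.
#' @return An object of class `nst_spec`.
#' @export
nst_spec <- function(n_draws = 1000L, metric = c("ruzicka", "jaccard"),
                     seed = 1L) {
  metric <- match.arg(metric)
  if (n_draws < 1) stopf("`n_draws` must be positive")
  structure(list(algorithm = "richness-and-frequency-proportional",
                 n_draws = as.integer(n_draws), metric = metric,
                 seed = as.integer(seed)),
            class = "nst_spec")
}

nst_dissimilarity <- function(table, metric) {
  if (metric == "ruzicka")
    vegan::vegdist(table, method = "jaccard")        # quantitative Jaccard
  else
    vegan::vegdist(table, method = "jaccard", binary = TRUE)
}

#' One draw from the richness/frequency-constrained null model
#'
#' @param table samples x taxa count matrix (the pool defining occurrence
#'   frequencies and regional abundances).
#' @param spec an [nst_spec()].
#' @param draw_index index of the draw; together with `spec$seed` it fixes
#'   the RNG stream, so draw k is reproducible in isolation.
#' @return A count matrix of the same shape; per-sample richness and totals
#'   match the observed table.
#' @export
null_draw <- function(table, spec = nst_spec(), draw_index = 1L) {
  assert_asv_table(table)
  freq <- colMeans(table > 0)
  regional <- colMeans(relative_abundance(table))
  with_seed(child_seed(spec$seed, draw_index), {
    null_draw_impl(table, freq, regional)
  })
}

# RNG-state-managed by the caller.
null_draw_impl <- function(table, freq, regional) {
  p <- ncol(table)
  out <- matrix(0L, nrow = nrow(table), ncol = p, dimnames = dimnames(table))
  candidates <- which(freq > 0)
  for (i in seq_len(nrow(table))) {
    r <- sum(table[i, ] > 0)
    if (r == 0) next
    total <- sum(table[i, ])
    occ <- if (length(candidates) == r) candidates
           else candidates[sample.int(length(candidates), r,
                                      prob = freq[candidates])]
    w <- regional[occ]
    if (sum(w) == 0) w <- rep(1, r)
    counts <- rep(1L, r)                       # guarantee occupancy
    extra <- total - r
    if (extra > 0)
      counts <- counts + as.integer(rmultinom(1, extra, prob = w))
    out[i, occ] <- counts
  }
  out
}

#' Pairwise normalized stochasticity ratio (NST) per group
#'
#' For every within-group sample pair: `G` is the observed dissimilarity,
#' `E` the mean dissimilarity of the corresponding pair across null draws,
#' `ST = min(G, E) / max(G, E)`, and
#' `NST = (1 - G) / (1 - E)` when `G >= E`, `G / E` otherwise, clamped to
#' \\[0, 1\\].  NST is 1 when observed and null coincide (fully stochastic)
#' and 0 at maximal divergence or identity (fully deterministic).  The group
#' value is the mean pairwise NST, reported in percent.  Null frequencies
#' and regional abundances are computed within each group.
#'
#' @param table samples x taxa count matrix.
#' @param groups factor/vector of group labels aligned with the rows.
#' @param spec an [nst_spec()].
#' @return Named list of `nst_result` objects (one per group), each with
#'   `group`, `pairwise` (data.frame: sample_a, sample_b, G, E, ST, NST,
#'   degenerate), `group_nst` (percent) and `spec`.
#' @export
pairwise_nst <- function(table, groups, spec = nst_spec()) {
  assert_asv_table(table)
  groups <- as.character(groups)
  if (length(groups) != nrow(table)) stopf("`groups` must match table rows")
  out <- lapply(unique(groups), function(g) {
    sub <- table[groups == g, , drop = FALSE]
    if (nrow(sub) < 2) stopf("group '%s' has fewer than 2 samples", g)
    nst_group(sub, g, spec)
  })
  stats::setNames(out, unique(groups))
}

nst_group <- function(sub, label, spec) {
  n <- nrow(sub)
  idx <- pair_index(n)
  Gv <- as.matrix(nst_dissimilarity(sub, spec$metric))[idx]
  freq <- colMeans(sub > 0)
  regional <- colMeans(relative_abundance(sub))
  Esum <- numeric(nrow(idx))
  with_seed(child_seed(spec$seed, 0L), {
    for (k in seq_len(spec$n_draws)) {
      nul <- null_draw_impl(sub, freq, regional)
      Esum <- Esum + as.matrix(nst_dissimilarity(nul, spec$metric))[idx]
    }
  })
  Ev <- Esum / spec$n_draws
  res <- nst_pair_values(Gv, Ev)
  pairwise <- data.frame(sample_a = rownames(sub)[idx[, 1]],
                         sample_b = rownames(sub)[idx[, 2]],
                         G = Gv, E = Ev, ST = res$ST, NST = res$NST,
                         degenerate = res$degenerate)
  structure(list(group = label, pairwise = pairwise,
                 group_nst = 100 * mean(res$NST), spec = spec),
            class = "nst_result")
}

# Vectorized ST/NST with boundary handling (E = 0 or 1).
nst_pair_values <- function(G, E, eps = 1e-12) {
  mx <- pmax(G, E)
  ST <- ifelse(mx < eps, 1, pmin(G, E) / mx)
  NST <- ifelse(abs(G - E) < eps, 1,
         ifelse(E < eps, 0,                       # null expects identity, G diverges
         ifelse(G >= E,
                ifelse(1 - E < eps, 0, (1 - G) / (1 - E)),
                G / E)))
  degenerate <- (E < eps & G > eps) | (abs(1 - E) < eps & G < 1 - eps)
  list(ST = pmin(pmax(ST, 0), 1), NST = pmin(pmax(NST, 0), 1),
       degenerate = degenerate)
}

#' Compare group-level stochasticity between two NST results
#'
#' Two-sided Welch t test on the pairwise NST values; if the t test is
#' degenerate (zero variance in both groups) the p-value falls back to a
#' pair-resampling bootstrap of the mean difference.
#'
#' @param result_a,result_b `nst_result` objects sharing a null spec.
#' @param n_boot bootstrap resamples for the fallback.
#' @param seed integer seed for the bootstrap.
#' @return List with `statistic`, `p_value`, `method`, `mean_a`, `mean_b`.
#' @export
nst_compare <- function(result_a, result_b, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(result_a, "nst_result"), inherits(result_b, "nst_result"))
  if (!identical(result_a$spec[c("algorithm", "metric")],
                 result_b$spec[c("algorithm", "metric")]))
    stopf("NST results were computed under different null specs")
  a <- result_a$pairwise$NST
  b <- result_b$pairwise$NST
  if (length(a) < 3 || length(b) < 3)
    stopf("need at least 3 sample pairs per group")
  tt <- tryCatch(t.test(a, b), error = function(e) NULL)
  if (!is.null(tt) && is.finite(tt$p.value)) {
    return(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                method = "welch-t", mean_a = mean(a), mean_b = mean(b)))
  }
  obs <- mean(a) - mean(b)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(k) {
      mean(sample(a, replace = TRUE)) - mean(sample(b, replace = TRUE))
    }, numeric(1))
  })
  centered <- boot - obs
  p <- (1 + sum(abs(centered) >= abs(obs))) / (1 + n_boot)
  list(statistic = obs, p_value = min(1, p), method = "bootstrap",
       mean_a = mean(a), mean_b = mean(b))
}

#' Serialize an NST result
#'
#' Writes the pairwise table as tab-separated text and a JSON summary that
#' embeds the null spec for reproducibility.
#'
#' @param result an `nst_result`.
#' @param prefix output path prefix; writes `<prefix>_pairs.tsv` and
#'   `<prefix>_summary.json`.
#' @export
write_nst <- function(result, prefix) {
  stopifnot(inherits(result, "nst_result"))
  write.table(result$pairwise, paste0(prefix, "_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(group = result$group,
                            group_nst_percent = result$group_nst,
                            n_pairs = nrow(result$pairwise),
                            spec = unclass(result$spec)),
                       paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
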