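#' The 13 variables entering the default soil quality index
#'
#' Four hydrolytic enzymes (acid phosphatase APE, beta-glucosidase BG,
#' beta-xylosidase XYL, leucine aminopeptidase LAP), polyphenol oxidase PPO
#' and urease UE, available potassium and phosphorus, ammonium and nitrate
#' nitrogen, soil respiration, and total nitrogen and carbon.
#'
#' @return Character vector of variable names.
#' @export
sqi_variables <- function() {
  c("APE", "BG", "XYL", "LAP", "PPO", "UE", "AK", "AP",
    "NH4", "NO3", "Respiration", "TN", "TC")
}

#' Composite soil quality index
#'
#' Each variable is z-scored across all samples (sample sd, n - 1) and the
#' per-sample index is the mean of the z-scores, so the index is
#' dimensionless, has mean ~0 across samples, and is invariant to affine
#' rescaling of any input variable.  Variables that are constant across
#' samples carry no information and are dropped with a warning.
#'
#' @param soil data.frame with `sample_id` and one column per soil variable.
#' @param variables variables to include; defaults to the standard 13 of
#'   [sqi_variables()].
#' @return data.frame with `sample_id` and `sqi`; the variables actually
#'   used are attached as attribute `"variables"`.
#' @export
quality_index <- function(soil, variables = sqi_variables()) {
  missing <- setdiff(variables, colnames(soil))
  if (length(missing))
    stopf("soil table is missing variable(s): %s", paste(missing, collapse = ", "))
  m <- as.matrix(soil[, variables, drop = FALSE])
  if (!is.numeric(m)) stopf("soil variables must be numeric")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warnf("dropping constant variable(s): %s",
          paste(variables[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    variables <- variables[sds > 0]
  }
  if (ncol(m) == 0) stopf("no non-constant variables left")
  z <- scale(m)
  out <- data.frame(sample_id = soil$sample_id, sqi = rowMeans(z))
  attr(out, "variables") <- variables
  out
}

#' Two-group comparison of per-sample values
#'
#' Two-sided Welch t test by default, with a label-permutation test either
#' on request or as automatic fallback when the t test is undefined
#' (e.g. zero variance in both groups).
#'
#' @param values numeric vector, one value per sample.
#' @param grouping vector of two group labels aligned with `values`.
#' @param method `"t"` or `"permutation"`.
#' @param n_perm permutations for the permutation test.
#' @param seed integer seed.
#' @return List with `statistic`, `p_value`, `method`, group means, and
#'   `n_permutations`/`seed` when permutation-based.
#' @export
group_compare <- function(values, grouping, method = c("t", "permutation"),
                          n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  grouping <- as.character(grouping)
  levels <- unique(grouping)
  if (length(levels) != 2) stopf("`grouping` must have exactly 2 levels")
  a <- values[grouping == levels[1]]
  b <- values[grouping == levels[2]]
  if (length(a) < 3 || length(b) < 3) stopf("need at least 3 samples per group")
  if (method == "t") {
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    if (!is.null(tt) && is.finite(tt$p.value))
      return(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                  method = "welch-t", mean_a = mean(a), mean_b = mean(b),
                  levels = levels))
    method <- "permutation"      # degenerate t: fall through
  }
  obs <- mean(a) - mean(b)
  p <- with_seed(seed, {
    hits <- 0L
    n_a <- length(a)
    pool <- c(a, b)
    for (k in seq_len(n_perm)) {
      idx <- sample.int(length(pool), n_a)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs) - 1e-12)
        hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  list(statistic = obs, p_value = p, method = "permutation",
       mean_a = mean(a), mean_b = mean(b), levels = levels,
       n_permutations = n_perm, seed = seed)
}

#' Assemble the per-sample feature matrix for importance analysis
#'
#' Binds per-sample richness vectors and module abundance z-scores with
#' treatment-level network metrics (P/N ratio, robustness, connectedness of
#' the sample's treatment subnetwork), the latter broadcast to every member
#' sample.  Column order is deterministic: richness features in list order,
#' then module columns in list order, then network metric columns in the
#' order of `treatment_metrics`.
#'
#' @param metadata sample metadata with `sample_id` and the grouping column.
#' @param richness named list of per-sample richness vectors (names become
#'   `<name>_richness`); vectors must be named by sample id.
#' @param module_z named list of samples x modules z-score matrices (names
#'   prefix the module columns).
#' @param treatment_metrics data.frame with a `group` column matching
#'   `metadata[[group_by]]` plus numeric metric columns to broadcast.
#' @param group_by metadata column defining the treatment of each sample.
#' @return data.frame keyed by `sample_id`, complete (errors on any missing
#'   sample).
#' @export
feature_matrix <- function(metadata, richness = list(), module_z = list(),
                           treatment_metrics = NULL, group_by = "residue") {
  ids <- metadata$sample_id
  out <- data.frame(sample_id = ids)
  for (nm in names(richness)) {
    v <- richness[[nm]]
    if (!all(ids %in% names(v)))
      stopf("richness '%s' is missing sample(s)", nm)
    out[[paste0(nm, "_richness")]] <- as.numeric(v[ids])
  }
  for (nm in names(module_z)) {
    z <- module_z[[nm]]
    if (!all(ids %in% rownames(z)))
      stopf("module z-scores '%s' are missing sample(s)", nm)
    z <- z[ids, , drop = FALSE]
    colnames(z) <- paste0(nm, "_", colnames(z))
    out <- cbind(out, as.data.frame(z, row.names = NULL))
  }
  if (!is.null(treatment_metrics)) {
    if (!group_by %in% colnames(metadata)) stopf("metadata lacks '%s'", group_by)
    grp <- metadata[[group_by]]
    if (!all(grp %in% treatment_metrics$group))
      stopf("treatment_metrics missing group(s): %s",
            paste(setdiff(grp, treatment_metrics$group), collapse = ", "))
    rows <- match(grp, treatment_metrics$group)
    for (col in setdiff(colnames(treatment_metrics), "group"))
      out[[col]] <- treatment_metrics[[col]][rows]
  }
  if (anyNA(out)) stopf("feature matrix has missing cells")
  rownames(out) <- NULL
  out
}

#' Random-forest importance of microbial features for soil quality
#'
#' Random-forest regression of the target on the features; importance is
#' reported as percent increase in mean squared error (%IncMSE, OOB
#' permutation importance).  Significance comes from refitting on
#' target-permuted data: for each feature, `p = (1 + #\{null >= observed\}) /
#' (1 + n_null)` against its own null importance distribution.  The model's
#' OOB variance explained is reported.
#'
#' @param features feature data.frame from [feature_matrix()] (the
#'   `sample_id` column is dropped automatically).
#' @param target numeric response, e.g. the `sqi` column of
#'   [quality_index()], aligned with the feature rows.
#' @param n_trees trees per forest.
#' @param seed integer seed (fixes forests and permutations; identical
#'   inputs give identical importances).
#' @param n_null target-permutation refits for significance; 0 skips the
#'   significance test.
#' @param alpha significance level.
#' @return List with `importance` (data.frame: feature, inc_mse, p_value,
#'   significant, ordered by decreasing importance), `variance_explained`,
#'   `n_trees`, `seed`.
#' @export
importance <- function(features, target, n_trees = 1000L, seed = 1L,
                       n_null = 50L, alpha = 0.05) {
  x <- features[, setdiff(colnames(features), "sample_id"), drop = FALSE]
  if (nrow(x) < 20) stopf("need at least 20 samples")
  if (anyNA(x) || anyNA(target)) stopf("missing values are not allowed")
  if (sd(target) == 0) stopf("constant target")
  if (length(target) != nrow(x)) stopf("target length must match features")
  with_seed(seed, {
    fit <- randomForest::randomForest(x, target, ntree = n_trees,
                                      importance = TRUE)
    obs <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
    pv <- rep(NA_real_, length(obs))
    if (n_null > 0) {
      nulls <- matrix(NA_real_, nrow = n_null, ncol = length(obs))
      for (b in seq_len(n_null)) {
        y_perm <- sample(target)
        fit_b <- randomForest::randomForest(x, y_perm, ntree = n_trees,
                                            importance = TRUE)
        nulls[b, ] <- randomForest::importance(fit_b, type = 1, scale = TRUE)[, 1]
      }
      pv <- vapply(seq_along(obs), function(j) {
        (1 + sum(nulls[, j] >= obs[j])) / (1 + n_null)
      }, numeric(1))
    }
    imp <- data.frame(feature = names(obs), inc_mse = unname(obs),
                      p_value = pv,
                      significant = !is.na(pv) & pv <= alpha)
    imp <- imp[order(-imp$inc_mse), ]
    rownames(imp) <- NULL
    list(importance = imp,
         variance_explained = max(0, utils::tail(fit$rsq, 1)),
         n_trees = n_trees, seed = seed)
  })
}
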