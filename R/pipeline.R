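#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' threshold at the standard analysis value: prevalence 0.5 (strict),
#' correlation magnitude 0.6, adjusted p 0.01, Zi 2.5, Pi 0.625, 999
#' permutations, robustness at 50% removal with 100 trials.  By default the
#' run is synthetic: a 96-sample factorial design with a prokaryote-like
#' (depth 32,582) and a fungus-like (depth 11,975) community.  Setting
#' `synthetic = FALSE` and filling `paths$asv_tables` (named list),
#' `paths$metadata` and `paths$soil` runs the same pipeline on real tables.
#'
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param outdir output directory (NULL: nothing is written).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = TRUE,
    paths = list(asv_tables = NULL, metadata = NULL, soil = NULL,
                 trait_map = NULL),
    design = list(),
    communities = list(
      prokaryote = list(depth = 32582L),
      fungus = list(n_taxa = 300L, depth = 11975L,
                    module_sizes = c(30L, 25L, 20L, 15L))
    ),
    soil = list(noise_sd = 0.15),
    thresholds = list(prevalence = 0.5, r_min = 0.6, p_max = 0.01,
                      zi = 2.5, pi = 0.625, n_perm = 999L),
    nst = list(n_draws = 1000L, metric = "ruzicka", per = "residue"),
    robustness = list(removal_fraction = 0.5, trials = 100L),
    modules = list(top = 4L, min_size = 5L),
    rf = list(n_trees = 1000L, n_null = 50L),
    group_by = "residue"
  )
}

# Recursive default-filling (named lists only).
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return Configuration list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_stop("config file not found: %s", path)
  merge_config(default_config(), yaml::read_yaml(path))
}

config_stop <- function(fmt, ...) {
  stop(structure(class = c("soilwebs_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (th$prevalence < 0 || th$prevalence >= 1)
    config_stop("prevalence threshold must be in [0, 1)")
  if (th$r_min <= 0 || th$r_min > 1) config_stop("r_min must be in (0, 1]")
  if (th$p_max <= 0 || th$p_max > 1) config_stop("p_max must be in (0, 1]")
  if (cfg$robustness$removal_fraction <= 0 || cfg$robustness$removal_fraction >= 1)
    config_stop("robustness removal_fraction must be in (0, 1)")
  if (is.null(cfg$seed)) config_stop("a seed is mandatory")
  if (!isTRUE(cfg$synthetic)) {
    for (what in c("metadata", "soil")) {
      p <- cfg$paths[[what]]
      if (is.null(p)) config_stop("paths$%s is required when synthetic = FALSE", what)
      if (!file.exists(p)) config_stop("paths$%s not found: %s", what, p)
    }
    if (is.null(cfg$paths$asv_tables) || length(cfg$paths$asv_tables) == 0)
      config_stop("paths$asv_tables is required when synthetic = FALSE")
    for (p in unlist(cfg$paths$asv_tables))
      if (!file.exists(p)) config_stop("ASV table not found: %s", p)
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation or loading, preprocessing,
#' diversity/ordination/permutation tests, NST community assembly,
#' co-occurrence networks (modules, Zi-Pi, stability, treatment
#' subnetworks), and the soil quality index with random-forest feature
#' importance.  Every stochastic stage is seeded from `config$seed`, so two
#' runs with an identical configuration produce identical numbers.  If
#' `outdir` is set, all tables are written there together with
#' `manifest.json` (configuration, seeds, outputs); on a stage failure a
#' `FAILED` marker naming the stage is left beside any partial outputs.
#'
#' @param config configuration list (see [default_config()]) or the path to
#'   a YAML file.
#' @return Invisible report list: `exit_status` (0), `summary` (key numbers
#'   per community group), `results` (full per-stage objects), `outputs`
#'   (written files).
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- if (is.character(config)) read_config(config)
         else merge_config(default_config(), config)
  validate_config(cfg)
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "inputs"
  outputs <- character(0)
  emit <- function(name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    writer(path)
    outputs <<- c(outputs, path)
  }
  on_fail <- function(e) {
    if (!is.null(outdir))
      writeLines(c(paste("stage:", stage), conditionMessage(e)),
                 file.path(outdir, "FAILED"))
    stop(e)
  }

  tryCatch({
    ## ---- inputs ----
    if (isTRUE(cfg$synthetic)) {
      meta <- generate_design(do.call(design_spec, cfg$design))
      truths <- list()
      tables <- list()
      for (i in seq_along(cfg$communities)) {
        nm <- names(cfg$communities)[i]
        params <- do.call(community_params, cfg$communities[[i]])
        gen <- generate_community(meta, params,
                                  seed = child_seed(cfg$seed, 10L + i))
        tables[[nm]] <- gen$table
        truths[[nm]] <- gen$truth
      }
      soil_args <- cfg$soil
      soil_args$design <- meta
      soil_args$seed <- child_seed(cfg$seed, 20L)
      soil <- do.call(generate_soil_properties, soil_args)
    } else {
      meta <- read_sample_table(cfg$paths$metadata)
      soil <- read_sample_table(cfg$paths$soil)
      tables <- lapply(cfg$paths$asv_tables, read_asv_table)
      truths <- NULL
      for (nm in names(tables)) {
        missing <- setdiff(meta$sample_id, rownames(tables[[nm]]))
        if (length(missing))
          stopf("table '%s' lacks sample(s): %s", nm,
                paste(head(missing, 5), collapse = ", "))
        tables[[nm]] <- tables[[nm]][meta$sample_id, , drop = FALSE]
      }
    }
    soil <- soil[match(meta$sample_id, soil$sample_id), ]
    emit("metadata.tsv", function(p) write_sample_table(meta, p))
    emit("soil.tsv", function(p) write_sample_table(soil, p))
    for (nm in names(tables))
      emit(paste0("asv_", nm, ".tsv"),
           local({ t0 <- tables[[nm]]; function(p) write_asv_table(t0, p) }))

    th <- cfg$thresholds
    residue_levels <- unique(meta$residue)
    soil_vars <- intersect(colnames(soil), names(soil_baselines()))
    soil_num <- as.matrix(soil[, soil_vars, drop = FALSE])
    rownames(soil_num) <- soil$sample_id
    results <- list(metadata = meta, soil = soil, tables = tables,
                    truth = truths)

    groups_out <- list()
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      g <- list()

      ## ---- diversity ----
      stage <- paste0("diversity:", nm)
      g$richness <- richness(tab)
      d <- bray_curtis(tab)
      g$pcoa <- pcoa(d, n_axes = 2)
      perm_terms <- data.frame(residue = meta$residue,
                               ft_intensity = meta$ft_intensity,
                               cycle = factor(meta$cycle))
      g$permanova <- permanova(d, perm_terms, n_perm = th$n_perm,
                               seed = child_seed(cfg$seed, 30L))
      g$mantel <- mantel_test(d, stats::dist(scale(soil_num)),
                              n_perm = th$n_perm,
                              seed = child_seed(cfg$seed, 31L))

      ## ---- assembly ----
      stage <- paste0("assembly:", nm)
      spec <- nst_spec(n_draws = cfg$nst$n_draws, metric = cfg$nst$metric,
                       seed = child_seed(cfg$seed, 40L))
      g$nst <- pairwise_nst(tab, meta[[cfg$nst$per]], spec)
      if (length(residue_levels) >= 2 &&
          all(residue_levels[1:2] %in% names(g$nst)))
        g$nst_test <- nst_compare(g$nst[[residue_levels[1]]],
                                  g$nst[[residue_levels[2]]],
                                  seed = child_seed(cfg$seed, 41L))

      ## ---- network ----
      stage <- paste0("network:", nm)
      net <- cooccurrence_network(tab, min_prevalence = th$prevalence,
                                  r_min = th$r_min, p_max = th$p_max)
      part <- detect_modules(net, seed = child_seed(cfg$seed, 50L))
      g$network <- net
      g$modules <- part
      g$zipi <- zipi(net, part, zi_threshold = th$zi, pi_threshold = th$pi)
      g$robustness <- robustness(net, cfg$robustness$removal_fraction,
                                 trials = cfg$robustness$trials,
                                 seed = child_seed(cfg$seed, 51L))
      g$connectedness <- connectedness(net)
      g$pn <- pn_ratio(net)
      keep_mods <- names(sort(base::table(part$membership),
                              decreasing = TRUE))
      keep_mods <- as.integer(keep_mods)[seq_len(min(cfg$modules$top,
                                                     length(keep_mods)))]
      big <- part$membership[part$membership %in% keep_mods]
      sizes <- base::table(big)
      big <- big[big %in% as.integer(names(sizes)[sizes >= cfg$modules$min_size])]
      g$module_z <- if (length(big)) module_abundance(tab, big) else NULL

      g$subnetworks <- lapply(residue_levels, function(lv) {
        sn <- subnetwork(net, tab, meta$sample_id[meta$residue == lv])
        list(level = lv, network = sn,
             robustness = if (igraph::vcount(sn) >= 2)
               robustness(sn, cfg$robustness$removal_fraction,
                          trials = cfg$robustness$trials,
                          seed = child_seed(cfg$seed, 52L)) else NA_real_,
             connectedness = if (igraph::vcount(sn) >= 2)
               connectedness(sn) else NA_real_,
             pn = pn_ratio(sn))
      })
      names(g$subnetworks) <- residue_levels

      emit(paste0("network_", nm, "_edges.tsv"),
           local({ n0 <- net; function(p)
             write_network(n0, sub("_edges\\.tsv$", "", p)) }))
      emit(paste0("zipi_", nm, ".tsv"),
           local({ z0 <- g$zipi; function(p)
             write.table(z0, p, sep = "\t", quote = FALSE, row.names = FALSE) }))
      groups_out[[nm]] <- g
    }
    results$groups <- groups_out

    ## ---- soil quality ----
    stage <- "soilquality"
    qi <- quality_index(soil)
    sq_test <- group_compare(qi$sqi, meta$residue)
    rich_feats <- lapply(groups_out, `[[`, "richness")
    modz_feats <- Filter(Negate(is.null), lapply(groups_out, `[[`, "module_z"))
    tm <- do.call(rbind, lapply(residue_levels, function(lv) {
      row <- data.frame(group = lv)
      for (nm in names(groups_out)) {
        sn <- groups_out[[nm]]$subnetworks[[lv]]
        row[[paste0(nm, "_pn_ratio")]] <- sn$pn$ratio
        row[[paste0(nm, "_robustness")]] <- sn$robustness
        row[[paste0(nm, "_connectedness")]] <- sn$connectedness
      }
      row
    }))
    tm <- tm[, c(TRUE, !vapply(tm[-1], anyNA, logical(1))), drop = FALSE]
    feats <- feature_matrix(meta, richness = rich_feats,
                            module_z = modz_feats, treatment_metrics = tm,
                            group_by = cfg$group_by)
    imp <- importance(feats, qi$sqi, n_trees = cfg$rf$n_trees,
                      seed = child_seed(cfg$seed, 60L),
                      n_null = cfg$rf$n_null)
    results$quality <- list(index = qi, test = sq_test, features = feats,
                            importance = imp)
    emit("quality_index.tsv", function(p)
      write.table(qi, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("features.tsv", function(p)
      write.table(feats, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("importance.tsv", function(p)
      write.table(imp$importance, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))

    ## ---- report ----
    stage <- "report"
    summary <- lapply(names(groups_out), function(nm) {
      g <- groups_out[[nm]]
      list(n_nodes = igraph::vcount(g$network),
           n_edges = igraph::ecount(g$network),
           modularity = g$modules$modularity,
           n_keystones = sum(g$zipi$keystone),
           robustness = g$robustness,
           connectedness = g$connectedness,
           pn_ratio = g$pn$ratio,
           nst_percent = vapply(g$nst, `[[`, numeric(1), "group_nst"),
           permanova_p = stats::setNames(g$permanova$p_value,
                                         g$permanova$term),
           mantel_r = g$mantel$statistic)
    })
    names(summary) <- names(groups_out)
    summary$soil_quality <- list(p_value = sq_test$p_value,
                                 mean_by_group = c(sq_test$mean_a, sq_test$mean_b),
                                 rf_variance_explained = imp$variance_explained,
                                 top_feature = imp$importance$feature[1])
    report <- list(exit_status = 0L, seed = cfg$seed, summary = summary,
                   results = results, outputs = outputs)
    if (!is.null(outdir)) {
      manifest <- list(seed = cfg$seed, thresholds = cfg$thresholds,
                       nst = cfg$nst, robustness = cfg$robustness,
                       synthetic = isTRUE(cfg$synthetic),
                       outputs = basename(outputs),
                       r_version = as.character(getRversion()))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(report)
  }, error = function(e) {
    if (inherits(e, "soilwebs_config_error")) stop(e)
    on_fail(e)
  })
}
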