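#' Read and write ASV tables
#'
#' On disk an ASV table is a tab-separated matrix with taxa as rows and
#' samples as columns; the first column holds taxon ids and the header row
#' sample ids.  In memory the table is an integer matrix with samples in rows
#' (the orientation community-ecology tooling expects).  `read_asv_table()`
#' also accepts BIOM-format JSON (read-only, requires the biomformat
#' package) when the path ends in `.biom`.
#'
#' @param path file path.
#' @param table integer matrix, samples x taxa.
#' @return `read_asv_table()` returns the samples x taxa integer matrix;
#'   `write_asv_table()` returns `path` invisibly.  Round-trip is lossless:
#'   `read_asv_table(write_asv_table(t, p))` equals `t`.
#' @export
read_asv_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stopf("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))   # biom is taxa x samples
    storage.mode(m) <- "double"
    return(assert_asv_table(round(m)))
  }
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stopf("malformed ASV table: %s", path)
  taxa <- as.character(raw[[1]])
  samples <- colnames(raw)[-1]
  if (anyDuplicated(taxa)) stopf("duplicate taxon ids in %s", path)
  if (anyDuplicated(samples)) stopf("duplicate sample ids in %s", path)
  m <- t(as.matrix(raw[, -1, drop = FALSE]))
  dimnames(m) <- list(samples, taxa)
  if (!is.numeric(m)) stopf("non-numeric counts in %s", path)
  assert_asv_table(m)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_asv_table
#' @export
write_asv_table <- function(table, path) {
  assert_asv_table(table)
  df <- data.frame(taxon_id = colnames(table), t(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write sample metadata and soil property tables
#'
#' Tab-separated tables keyed by a `sample_id` column.
#' @param path file path.
#' @param df data.frame with a `sample_id` column.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stopf("missing sample_id column: %s", path)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in %s", path)
  df
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column taxon trait map
#'
#' @param path tab-separated file with columns `taxon_id` and `trait`.
#' @return Named character vector: taxon id -> trait label.
#' @export
read_trait_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("trait map needs two columns: %s", path)
  if (any(!nzchar(df[[2]]))) stopf("empty trait labels in %s", path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

# Core without-replacement subsampling to fixed depth (vegan::rrarefy);
# assumes the caller controls the RNG state.
rarefy_counts <- function(table, depth) {
  # vegan heuristically warns on dense toy tables; counts here are integral
  out <- suppressWarnings(vegan::rrarefy(table, depth))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(table)
  out
}

#' Rarefy an ASV table to fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`.
#' Samples whose total is below `depth` are dropped with a warning (standard
#' rarefaction semantics; nothing is padded).
#'
#' @param table samples x taxa integer matrix.
#' @param depth target reads per sample (> 0).
#' @param seed integer seed.
#' @return Rarefied matrix; every retained row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  assert_asv_table(table)
  if (depth <= 0) stopf("`depth` must be positive")
  totals <- rowSums(table)
  drop <- totals < depth
  if (any(drop)) {
    warnf("dropping %d sample(s) below rarefaction depth %d: %s",
          sum(drop), depth, paste(rownames(table)[drop], collapse = ", "))
    table <- table[!drop, , drop = FALSE]
    if (nrow(table) == 0) stopf("no samples at or above depth %d", depth)
  }
  with_seed(seed, rarefy_counts(table, depth))
}

#' Filter taxa by occurrence prevalence
#'
#' Retains taxa present (count > 0) in strictly more than `min_prevalence`
#' of the samples — the usual pre-filter before co-occurrence network
#' construction.  With the default 0.5 a taxon seen in 49 of 96 samples is
#' kept; one seen in exactly 48 of 96 is removed.
#'
#' @param table samples x taxa matrix.
#' @param min_prevalence proportion threshold in \\[0, 1); strict inequality.
#' @return The table restricted to retained taxa; samples unchanged.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.5) {
  assert_asv_table(table)
  if (min_prevalence < 0 || min_prevalence >= 1)
    stopf("`min_prevalence` must be in [0, 1)")
  prev <- colMeans(table > 0)
  table[, prev > min_prevalence, drop = FALSE]
}

#' Convert counts to relative abundances
#'
#' @param table samples x taxa matrix with positive sample totals.
#' @return Real matrix whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  assert_asv_table(table)
  totals <- rowSums(table)
  if (any(totals == 0))
    stopf("zero-total sample(s): %s",
          paste(rownames(table)[totals == 0], collapse = ", "))
  sweep(table, 1, totals, "/")
}

#' Aggregate relative abundance by taxon trait
#'
#' Sums each sample's relative abundances over taxa sharing a trait label
#' (e.g. fungal guilds or predicted functions).  Unassigned taxa are
#' excluded from the trait table; the fraction of table taxa carrying any
#' trait is reported.
#'
#' @param table samples x taxa count matrix.
#' @param traits named character vector (taxon id -> trait) as from
#'   [read_trait_map()].  Entries for taxa absent from the table are ignored
#'   with a warning.
#' @return List with `abundance` (samples x traits relative-abundance
#'   matrix) and `assigned_fraction` (proportion of table taxa mapped).
#' @export
annotate_traits <- function(table, traits) {
  assert_asv_table(table)
  unknown <- setdiff(names(traits), colnames(table))
  if (length(unknown))
    warnf("trait map names %d taxa absent from the table; ignored", length(unknown))
  traits <- traits[names(traits) %in% colnames(table)]
  rel <- relative_abundance(table)
  labels <- sort(unique(traits))
  ab <- sapply(labels, function(tr) {
    members <- names(traits)[traits == tr]
    rowSums(rel[, members, drop = FALSE])
  })
  if (length(labels) == 0)
    ab <- matrix(numeric(0), nrow = nrow(table), ncol = 0,
                 dimnames = list(rownames(table), NULL))
  else if (is.null(dim(ab)))
    ab <- matrix(ab, nrow = nrow(table),
                 dimnames = list(rownames(table), labels))
  list(abundance = ab,
       assigned_fraction = length(unique(names(traits))) / ncol(table))
}
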