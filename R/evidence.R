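#' Load a literature-mined interaction table
#'
#' Reads a text-mining evidence TSV with columns `gene1`, `gene2`, `pmid`,
#' `sentence`, `confidence` (one row per supporting sentence) and aggregates
#' rows into unordered gene pairs with sentence counts and maximum classifier
#' confidence. Self-pairs and rows with missing genes are skipped and
#' counted in a message.
#'
#' @param path File path.
#' @return An `evidence_set`: list with `pairs` (data frame `gene1`, `gene2`,
#'   `n_sentences`, `max_confidence`) and `sentences` (the retained rows with
#'   a canonical pair `key`).
#' @export
load_interaction_table <- function(path) {
  df <- read_tsv_base(path, colClasses = "character")
  need <- c("gene1", "gene2", "pmid", "sentence", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("interaction table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$confidence <- as.numeric(df$confidence)
  bad <- is.na(df$gene1) | is.na(df$gene2) | !nzchar(df$gene1) |
    !nzchar(df$gene2) | is.na(df$confidence)
  self <- !bad & df$gene1 == df$gene2
  if (any(bad | self))
    msgf("load_interaction_table: skipped %d malformed and %d self-pair row(s)",
         sum(bad), sum(self))
  df <- df[!(bad | self), , drop = FALSE]
  df$key <- pair_key(df$gene1, df$gene2)
  agg_n <- tapply(df$key, df$key, length)
  agg_c <- tapply(df$confidence, df$key, max)
  keys <- names(agg_n)
  gk <- strsplit(keys, "\r", fixed = TRUE)
  pairs <- data.frame(
    gene1 = vapply(gk, `[[`, character(1), 1L),
    gene2 = vapply(gk, `[[`, character(1), 2L),
    n_sentences = as.integer(agg_n),
    max_confidence = as.numeric(agg_c),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, sentences = df), class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("<evidence_set: %d pairs, %d sentences>\n",
              nrow(x$pairs), nrow(x$sentences)))
  invisible(x)
}

#' Most frequent interaction partners per seed gene
#'
#' For each seed gene, ranks its text-mined partners by sentence count
#' (descending), breaking ties by maximum confidence then lexical gene id so
#' the selection is deterministic, and keeps the top `n_top`. Returns the
#' union of kept partners, excluding seed genes themselves.
#'
#' @param evidence An `evidence_set` from [load_interaction_table()].
#' @param seed Seed network or character vector of seed gene ids.
#' @param n_top Partners kept per seed gene (default 50).
#' @return List with `genes` (sorted union of partners) and `table`
#'   (per-seed partner data frame `seed`, `partner`, `n_sentences`,
#'   `max_confidence`, `rank`).
#' @export
top_partners <- function(evidence, seed, n_top = 50) {
  if (!is_count(n_top)) stopf("n_top must be >= 1")
  sg <- seed_genes(seed)
  p <- evidence$pairs
  touches <- p$gene1 %in% sg | p$gene2 %in% sg
  p <- p[touches, , drop = FALSE]
  rows <- rbind(
    data.frame(seed = p$gene1, partner = p$gene2,
               n_sentences = p$n_sentences,
               max_confidence = p$max_confidence, stringsAsFactors = FALSE),
    data.frame(seed = p$gene2, partner = p$gene1,
               n_sentences = p$n_sentences,
               max_confidence = p$max_confidence, stringsAsFactors = FALSE))
  rows <- rows[rows$seed %in% sg, , drop = FALSE]
  rows <- rows[order(rows$seed, -rows$n_sentences, -rows$max_confidence,
                     rows$partner), , drop = FALSE]
  kept <- do.call(rbind, lapply(split(rows, rows$seed), function(d) {
    d$rank <- seq_len(nrow(d))
    d[seq_len(min(n_top, nrow(d))), , drop = FALSE]
  }))
  rownames(kept) <- NULL
  list(genes = sort(setdiff(unique(kept$partner), sg)), table = kept)
}

#' Cap supporting sentences per pair
#'
#' Retains at most `max_sentences` sentences per pair, keeping the
#' highest-confidence ones; the aggregate pair table (original sentence
#' counts) is preserved as metadata.
#'
#' @param evidence An `evidence_set`.
#' @param max_sentences Cap per pair (default 5).
#' @return The `evidence_set` with trimmed `sentences`; original totals stay
#'   in `pairs$n_sentences`.
#' @export
cap_sentences <- function(evidence, max_sentences = 5) {
  if (!is_count(max_sentences)) stopf("max_sentences must be >= 1")
  s <- evidence$sentences
  s <- s[order(s$key, -s$confidence), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(s)), s$key, FUN = seq_along)
  evidence$sentences <- s[idx <= max_sentences, , drop = FALSE]
  rownames(evidence$sentences) <- NULL
  evidence
}

#' Read a homology cluster table
#'
#' HomoloGene-style TSV with columns `cluster_id`, `taxon_id`, `gene_id`;
#' each gene may belong to at most one cluster.
#'
#' @param path File path.
#' @return A `homology_table` data frame.
#' @export
read_homology_table <- function(path) {
  df <- read_tsv_base(path, colClasses = "character")
  need <- c("cluster_id", "taxon_id", "gene_id")
  if (!all(need %in% names(df)))
    stopf("homology table needs columns %s", paste(need, collapse = ", "))
  multi <- tapply(df$cluster_id, df$gene_id,
                  function(x) length(unique(x))) > 1L
  if (any(multi))
    stopf("gene(s) in more than one homology cluster: %s",
          paste(names(multi)[multi], collapse = ", "))
  class(df) <- c("homology_table", class(df))
  df
}

#' Map genes across species via homology clusters
#'
#' Replaces each input gene by all members of its homology cluster in the
#' target taxon (one-to-many mappings keep every paralog; results are
#' deduplicated). Genes without a cluster, or whose cluster has no
#' target-taxon member, are reported unmapped.
#'
#' @param genes Character vector of gene ids.
#' @param table A [read_homology_table()] data frame (columns `cluster_id`,
#'   `taxon_id`, `gene_id`).
#' @param target_taxon Taxon id to map into.
#' @return List with `mapped` (sorted unique target-taxon gene ids) and
#'   `unmapped` (input genes that could not be mapped).
#' @export
map_homologs <- function(genes, table, target_taxon) {
  genes <- as.character(genes)
  target_taxon <- as.character(target_taxon)
  cluster_of <- stats::setNames(table$cluster_id, table$gene_id)
  tt <- table[table$taxon_id == target_taxon, , drop = FALSE]
  members <- split(tt$gene_id, tt$cluster_id)
  mapped <- character()
  unmapped <- character()
  for (g in unique(genes)) {
    cl <- unname(cluster_of[g])
    hits <- if (is.na(cl)) character() else members[[cl]] %||% character()
    if (length(hits)) mapped <- c(mapped, hits) else unmapped <- c(unmapped, g)
  }
  list(mapped = sort(unique(mapped)), unmapped = unmapped)
}
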