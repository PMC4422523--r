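#' Read the clock seed network
#'
#' Loads a two-layer seed network: a node table with columns `gene` and
#' `layer` (`CCN` for the core oscillator, `ECCN` for the curated extension)
#' and a directed edge table with columns `gene1`, `gene2`, `sign`
#' (`activation`/`inhibition`/`other`) and `pmids`. Defaults to the packaged
#' 43-gene fixture (14 core-clock genes plus 29 curated-interactor symbols;
#' the extension membership is synthetic).
#'
#' @param nodes_path,edges_path TSV paths; defaults use the packaged fixture.
#' @return A `seed_network` object (list with `nodes` and `edges`).
#' @export
read_seed_network <- function(
    nodes_path = circanet_extdata("eccn_seed_nodes_synthetic.tsv"),
    edges_path = circanet_extdata("eccn_seed_edges_synthetic.tsv")) {
  nodes <- read_tsv_base(nodes_path)
  edges <- read_tsv_base(edges_path)
  if (!all(c("gene", "layer") %in% names(nodes)))
    stopf("seed node table needs columns gene, layer")
  if (!all(c("gene1", "gene2", "sign") %in% names(edges)))
    stopf("seed edge table needs columns gene1, gene2, sign")
  if (!all(nodes$layer %in% c("CCN", "ECCN")))
    stopf("seed layers must be CCN or ECCN")
  if (anyDuplicated(nodes$gene)) stopf("duplicate seed genes")
  bad <- setdiff(unique(c(edges$gene1, edges$gene2)), nodes$gene)
  if (length(bad)) stopf("seed edges reference unknown genes: %s",
                         paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat(sprintf("<seed_network: %d genes (%d CCN), %d edges>\n",
              nrow(x$nodes), sum(x$nodes$layer == "CCN"), nrow(x$edges)))
  invisible(x)
}

seed_genes <- function(seed) {
  if (inherits(seed, "seed_network")) seed$nodes$gene else as.character(seed)
}

#' Selection report arithmetic
#'
#' Summarises a top-K pair selection: the selected fraction of the
#' seed-by-universe pair space (in percent) and the implied correlation
#' cutoff expressed in background standard deviations.
#'
#' @param K Number of selected pairs.
#' @param n_seed Number of seed genes.
#' @param n_universe Number of genes in the expression universe.
#' @param cutoff Implied absolute-correlation cutoff (smallest selected), or
#'   `NA` when not available.
#' @param sd_background Standard deviation of the background correlation
#'   distribution, or `NA`.
#' @return A `selection_report` list with `K`, `n_seed_genes`,
#'   `n_universe_genes`, `implied_cutoff`, `fraction` (percent) and
#'   `cutoff_in_sd`.
#' @export
selection_report <- function(K, n_seed, n_universe, cutoff = NA_real_,
                             sd_background = NA_real_) {
  structure(list(
    K = K, n_seed_genes = n_seed, n_universe_genes = n_universe,
    implied_cutoff = cutoff,
    fraction = 100 * K / (n_seed * n_universe),
    cutoff_in_sd = cutoff / sd_background
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(paste0("<selection_report: K=%d over %d seed x %d universe ",
                     "genes = %.2f%%; cutoff %.4f (%.1f sd)>\n"),
              x$K, x$n_seed_genes, x$n_universe_genes, x$fraction,
              x$implied_cutoff, x$cutoff_in_sd))
  invisible(x)
}

#' Select the top correlating seed-gene pairs
#'
#' Ranks all (seed gene, non-seed gene) pairs by correlation strength and
#' returns the top `K`. Ties at the selection boundary are all retained, so
#' slightly more than `K` pairs may be returned (reported in a message).
#' Ranking uses absolute correlation by default; `ranking = "signed"` ranks
#' by the raw correlation instead.
#'
#' @param corr Correlation matrix over the expression universe.
#' @param seed A `seed_network` or character vector of seed gene ids; seed
#'   genes absent from `corr` are an error.
#' @param K Number of pairs to select.
#' @param ranking `"absolute"` (default) or `"signed"`.
#' @return A data frame of class `coexpression_pairs` with columns `seed`,
#'   `gene`, `rho`; attribute `report` holds the [selection_report()].
#' @export
select_top_pairs <- function(corr, seed, K = 10000,
                             ranking = c("absolute", "signed")) {
  ranking <- match.arg(ranking)
  if (!is_count(K)) stopf("K must be a positive integer")
  sg <- seed_genes(seed)
  missing_seed <- setdiff(sg, rownames(corr))
  if (length(missing_seed))
    stopf("seed genes absent from correlation matrix: %s",
          paste(missing_seed, collapse = ", "))
  universe <- rownames(corr)
  others <- setdiff(universe, sg)
  sub <- corr[sg, others, drop = FALSE]
  pairs <- data.frame(
    seed = rep(sg, times = length(others)),
    gene = rep(others, each = length(sg)),
    rho = as.vector(sub),
    stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$rho), , drop = FALSE]
  score <- if (ranking == "absolute") abs(pairs$rho) else pairs$rho
  if (K >= nrow(pairs)) {
    warning(sprintf("K = %d >= %d available pairs; returning all", K,
                    nrow(pairs)), call. = FALSE)
    sel <- rep(TRUE, nrow(pairs))
    cutoff <- min(score)
  } else {
    cutoff <- sort(score, decreasing = TRUE)[K]
    sel <- score >= cutoff
    if (sum(sel) > K)
      msgf("select_top_pairs: %d boundary tie(s) retained beyond K",
           sum(sel) - K)
  }
  out <- pairs[sel, , drop = FALSE]
  ord <- order(-(if (ranking == "absolute") abs(out$rho) else out$rho),
               out$seed, out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- selection_report(
    K = K, n_seed = length(sg), n_universe = length(universe),
    cutoff = if (ranking == "absolute") min(abs(out$rho)) else min(out$rho),
    sd_background = stats::sd(pairs$rho))
  attr(out, "ranking") <- ranking
  class(out) <- c("coexpression_pairs", class(out))
  out
}

#' Tightness of predicted target genes
#'
#' Tightness of a candidate gene is the number of distinct seed-network
#' genes it is linked to by selected co-expression pairs. Pairs whose
#' non-seed side is itself a seed gene are excluded (with a message).
#'
#' @param pairs Data frame with columns `seed`, `gene` (and optionally
#'   `rho`), e.g. from [select_top_pairs()].
#' @param seed Optional seed network / gene vector used to detect and drop
#'   seed-seed pairs.
#' @return A data frame of class `candidate_genes` with one row per distinct
#'   candidate: `gene`, `tightness`, `partners` (comma-joined seed ids,
#'   ordered by descending `|rho|` when available).
#' @export
compute_tightness <- function(pairs, seed = NULL) {
  stopifnot(all(c("seed", "gene") %in% names(pairs)))
  if (!is.null(seed)) {
    sg <- seed_genes(seed)
    bad <- pairs$gene %in% sg
    if (any(bad)) {
      msgf("compute_tightness: %d pair(s) between two seed genes excluded",
           sum(bad))
      pairs <- pairs[!bad, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L) {
    out <- data.frame(gene = character(), tightness = integer(),
                      partners = character(), stringsAsFactors = FALSE)
    class(out) <- c("candidate_genes", class(out))
    return(out)
  }
  # distinct (seed, gene) pairs only: duplicates carry no extra tightness
  key <- paste(pairs$seed, pairs$gene, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  if ("rho" %in% names(pairs))
    pairs <- pairs[order(pairs$gene, -abs(pairs$rho)), , drop = FALSE]
  split_seed <- split(pairs$seed, pairs$gene)
  out <- data.frame(
    gene = names(split_seed),
    tightness = vapply(split_seed, length, integer(1)),
    partners = vapply(split_seed, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("candidate_genes", class(out))
  out
}

#' Filter candidates by minimum tightness
#'
#' Keeps candidate genes linked to at least `min_t` distinct seed genes.
#' When the originating pair list is supplied, the retained pairs are
#' attached as attribute `pairs`.
#'
#' @param candidates Output of [compute_tightness()].
#' @param min_t Minimum tightness (default 2, the threshold at which the
#'   candidate count drops most steeply on real compendia).
#' @param pairs Optional pair data frame to subset alongside.
#' @return Filtered `candidate_genes` data frame.
#' @export
filter_tightness <- function(candidates, min_t = 2, pairs = NULL) {
  if (!is_count(min_t)) stopf("min_t must be >= 1")
  out <- candidates[candidates$tightness >= min_t, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(pairs))
    attr(out, "pairs") <- pairs[pairs$gene %in% out$gene, , drop = FALSE]
  class(out) <- unique(c("candidate_genes", class(out)))
  out
}

#' Tightness sweep diagnostic
#'
#' For each minimum-tightness level, records the number of surviving
#' candidate genes and (optionally) the q-value and rank of tracked terms
#' returned by an enrichment callback, tracing how functional signal behaves
#' as the tightness filter hardens.
#'
#' @param candidates Output of [compute_tightness()].
#' @param enrich_fun Optional callback `function(genes)` returning a data
#'   frame with columns `term` and `q`.
#' @param t_range Integer vector of tightness thresholds (default `1:10`).
#' @param track_terms Terms whose q/rank trajectories to record; default all
#'   terms returned at the first threshold.
#' @return A list with `counts` (data frame `min_tightness`, `n_candidates`)
#'   and, when a callback is given, `trajectories` (long data frame
#'   `min_tightness`, `term`, `q`, `rank`).
#' @export
tightness_sweep <- function(candidates, enrich_fun = NULL, t_range = 1:10,
                            track_terms = NULL) {
  counts <- data.frame(min_tightness = t_range, n_candidates = NA_integer_)
  traj <- NULL
  for (i in seq_along(t_range)) {
    keep <- filter_tightness(candidates, min_t = t_range[i])
    counts$n_candidates[i] <- nrow(keep)
    if (!is.null(enrich_fun)) {
      res <- if (nrow(keep)) enrich_fun(keep$gene) else
        data.frame(term = character(), q = numeric())
      if (is.null(track_terms)) track_terms <- res$term
      res$rank <- seq_len(nrow(res))
      m <- match(track_terms, res$term)
      traj <- rbind(traj, data.frame(
        min_tightness = t_range[i], term = track_terms,
        q = res$q[m], rank = res$rank[m], stringsAsFactors = FALSE))
    }
  }
  list(counts = counts, trajectories = traj)
}
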