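#' Intersect the two evidence streams
#'
#' The consensus gene set is the intersection of the co-expression-predicted
#' and text-mining-predicted target sets (both in one gene-id namespace,
#' i.e. after any homolog mapping). Input and output sizes are logged.
#'
#' @param coexp_genes,textmine_genes Character vectors of predicted genes.
#' @return List with `consensus` (sorted), `n_coexpression`, `n_textmining`,
#'   `n_consensus`.
#' @export
intersect_evidence <- function(coexp_genes, textmine_genes) {
  consensus <- sort(intersect(unique(coexp_genes), unique(textmine_genes)))
  msgf("intersect_evidence: %d coexpression, %d textmining -> %d consensus",
       length(unique(coexp_genes)), length(unique(textmine_genes)),
       length(consensus))
  if (length(consensus) == 0L)
    warning("empty consensus: the extension layer will be empty",
            call. = FALSE)
  list(consensus = consensus,
       n_coexpression = length(unique(coexp_genes)),
       n_textmining = length(unique(textmine_genes)),
       n_consensus = length(consensus))
}

#' Classify evidence edges by provenance
#'
#' Partitions the distinct evidence edges that touch a consensus gene into
#' those predicted by both streams, co-expression only, or text-mining only.
#'
#' @param coexp_pairs,textmine_pairs Two-column data frames of gene pairs
#'   (columns are taken positionally; unordered comparison).
#' @param consensus Character vector of consensus genes.
#' @return Data frame of class `provenance_edges` with columns `gene1`,
#'   `gene2`, `provenance` (`both`/`coexpression`/`textmining`); attribute
#'   `counts` gives the three totals.
#' @export
classify_edges <- function(coexp_pairs, textmine_pairs, consensus) {
  norm <- function(p) {
    p <- as.data.frame(p)[, 1:2]
    names(p) <- c("gene1", "gene2")
    p$key <- pair_key(p$gene1, p$gene2)
    p[!duplicated(p$key), , drop = FALSE]
  }
  cx <- norm(coexp_pairs)
  tm <- norm(textmine_pairs)
  touch <- function(p) p[p$gene1 %in% consensus | p$gene2 %in% consensus, ,
                         drop = FALSE]
  cx <- touch(cx)
  tm <- touch(tm)
  both_keys <- intersect(cx$key, tm$key)
  all_edges <- rbind(cx, tm[!(tm$key %in% cx$key), , drop = FALSE])
  all_edges$provenance <- ifelse(all_edges$key %in% both_keys, "both",
                          ifelse(all_edges$key %in% cx$key, "coexpression",
                                 "textmining"))
  all_edges <- all_edges[order(all_edges$gene1, all_edges$gene2),
                         c("gene1", "gene2", "provenance")]
  rownames(all_edges) <- NULL
  counts <- c(both = sum(all_edges$provenance == "both"),
              coexpression = sum(all_edges$provenance == "coexpression"),
              textmining = sum(all_edges$provenance == "textmining"))
  msgf("classify_edges: %d both, %d coexpression-specific, %d textmining-specific",
       counts[["both"]], counts[["coexpression"]], counts[["textmining"]])
  attr(all_edges, "counts") <- counts
  class(all_edges) <- c("provenance_edges", class(all_edges))
  all_edges
}

#' Assemble the layered regulated-gene network
#'
#' Builds the three-layer network: the core-clock layer (`CCN`), the curated
#' extension (`ECCN`) and the consensus-predicted extension layer (`NCRG`).
#' Known seed edges keep their direction and sign with provenance `known`;
#' evidence edges (undirected) keep their stream provenance. Consensus genes
#' that are already seed genes are dropped from the consensus layer with a
#' message — the extension layer holds new genes only.
#'
#' @param seed A `seed_network`.
#' @param consensus Character vector of consensus genes.
#' @param edges Optional `provenance_edges` from [classify_edges()].
#' @return An `assembled_network`: list with `nodes` (`gene`, `layer`, flag
#'   columns added by [annotate_nodes()]) and `edges` (`gene1`, `gene2`,
#'   `provenance`, `sign`).
#' @export
assemble_ncrg <- function(seed, consensus, edges = NULL) {
  overlap <- intersect(consensus, seed$nodes$gene)
  if (length(overlap)) {
    msgf("assemble_ncrg: %d consensus gene(s) already in the seed dropped",
         length(overlap))
    consensus <- setdiff(consensus, overlap)
  }
  nodes <- rbind(
    seed$nodes[, c("gene", "layer")],
    if (length(consensus))
      data.frame(gene = sort(consensus), layer = "NCRG",
                 stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  known <- data.frame(gene1 = seed$edges$gene1, gene2 = seed$edges$gene2,
                      provenance = "known", sign = seed$edges$sign,
                      stringsAsFactors = FALSE)
  ev <- NULL
  if (!is.null(edges) && nrow(edges)) {
    ev <- data.frame(gene1 = edges$gene1, gene2 = edges$gene2,
                     provenance = edges$provenance, sign = "other",
                     stringsAsFactors = FALSE)
    dangling <- !(ev$gene1 %in% nodes$gene & ev$gene2 %in% nodes$gene)
    if (any(dangling)) {
      msgf("assemble_ncrg: %d evidence edge(s) with endpoints outside the network dropped",
           sum(dangling))
      ev <- ev[!dangling, , drop = FALSE]
    }
  }
  structure(list(nodes = nodes, edges = rbind(known, ev)),
            class = "assembled_network")
}

#' @export
print.assembled_network <- function(x, ...) {
  tab <- table(factor(x$nodes$layer, levels = c("CCN", "ECCN", "NCRG")))
  cat(sprintf("<assembled_network: %d nodes (CCN %d, ECCN %d, NCRG %d), %d edges>\n",
              nrow(x$nodes), tab[["CCN"]], tab[["ECCN"]], tab[["NCRG"]],
              nrow(x$edges)))
  invisible(x)
}

#' Annotate network nodes with validation evidence
#'
#' Joins per-TF ChIP-seq target sets, circadian rhythmicity flags, RNAi
#' phenotype classes, disease annotations and a similar-to-clock gene list
#' onto the network nodes, and produces the summary report: one row per
#' extension-layer (NCRG) gene carrying at least one flag. Annotation ids
#' that match no network node are counted and ignored.
#'
#' @param network An `assembled_network`.
#' @param tf_targets Named list of character gene sets (one per factor).
#' @param circadian Character vector of rhythmic genes.
#' @param rnai Data frame with columns `gene` and `phenotype` (one of
#'   `high-A`, `long-T`, `short-T`).
#' @param disease Data frame with columns `gene` and `annotation`.
#' @param ml_similar Character vector of genes classified as similar to
#'   known clock genes.
#' @return List with `network` (nodes gain one logical column per factor,
#'   `circadian`, `high_A`, `long_T`, `short_T`, `ml_similar` and a
#'   `disease` text column) and `report` (flagged NCRG genes only).
#' @export
annotate_nodes <- function(network, tf_targets = list(), circadian = character(),
                           rnai = NULL, disease = NULL,
                           ml_similar = character()) {
  nodes <- network$nodes
  known_genes <- nodes$gene
  unknown <- 0L
  take <- function(g) {
    g <- unique(as.character(g))
    unknown <<- unknown + sum(!(g %in% known_genes))
    g[g %in% known_genes]
  }
  for (tf in names(tf_targets))
    nodes[[paste0("target_", tf)]] <- nodes$gene %in% take(tf_targets[[tf]])
  nodes$circadian <- nodes$gene %in% take(circadian)
  for (cls in c("high-A", "long-T", "short-T")) {
    col <- gsub("-", "_", cls)
    hits <- if (is.null(rnai)) character() else
      take(rnai$gene[rnai$phenotype == cls])
    nodes[[col]] <- nodes$gene %in% hits
  }
  nodes$ml_similar <- nodes$gene %in% take(ml_similar)
  nodes$disease <- ""
  if (!is.null(disease)) {
    d <- disease[disease$gene %in% known_genes & nzchar(disease$annotation), ,
                 drop = FALSE]
    unknown <- unknown + sum(!(disease$gene %in% known_genes))
    nodes$disease[match(d$gene, nodes$gene)] <- d$annotation
  }
  if (unknown > 0L)
    msgf("annotate_nodes: %d annotation id(s) not in the network ignored",
         unknown)
  flag_cols <- setdiff(names(nodes), c("gene", "layer", "disease"))
  any_flag <- Reduce(`|`, nodes[flag_cols]) | nzchar(nodes$disease)
  report <- nodes[nodes$layer == "NCRG" & any_flag, , drop = FALSE]
  rownames(report) <- NULL
  network$nodes <- nodes
  list(network = network, report = report)
}

#' Export / import the assembled network
#'
#' GraphML export goes through igraph with the layer and provenance kept as
#' attributes; the SIF export writes `gene1 <provenance> gene2` lines. The
#' GraphML reader restores an `assembled_network` losslessly.
#'
#' @param network An `assembled_network`.
#' @param path Output (or input) file path.
#' @name network_io
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_io
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  names(nodes)[names(nodes) == "name"] <- "gene"
  edges <- igraph::as_data_frame(g, what = "edges")
  names(edges)[names(edges) == "from"] <- "gene1"
  names(edges)[names(edges) == "to"] <- "gene2"
  rownames(nodes) <- NULL
  logical_cols <- setdiff(names(nodes), c("gene", "layer", "disease"))
  for (cl in logical_cols)
    if (all(nodes[[cl]] %in% c(0, 1))) nodes[[cl]] <- as.logical(nodes[[cl]])
  structure(list(nodes = nodes[, c("gene", "layer",
                                   setdiff(names(nodes), c("gene", "layer"))),
                               drop = FALSE],
                 edges = edges),
            class = "assembled_network")
}

#' @rdname network_io
#' @export
write_network_sif <- function(network, path) {
  writeLines(sprintf("%s\t%s\t%s", network$edges$gene1,
                     network$edges$provenance, network$edges$gene2), path)
  invisible(path)
}

#' Read the consensus annotation fixture
#'
#' Loads the packaged annotation table of consensus-predicted genes (per-TF
#' ChIP-seq target marks, circadian expression, RNAi phenotype classes,
#' BMAL1 marks and disease annotations) and converts the `x` marks into the
#' inputs [annotate_nodes()] consumes.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return List with `table` (raw data frame), `tf_targets` (named list:
#'   REV-ERB and ROR column sets plus `BMAL1`), `circadian`, `rnai`,
#'   `disease` in the [annotate_nodes()] shapes.
#' @export
read_consensus_annotations <- function(
    path = circanet_extdata("consensus_annotations.tsv")) {
  df <- read_tsv_base(path, colClasses = "character")
  marked <- function(col) df$symbol[df[[col]] == "x"]
  tf_cols <- c(reverb_a = "REV-ERBa", reverb_b = "REV-ERBb",
               reverb_ab = "REV-ERBab", ror_a = "RORa", ror_g = "RORg",
               ror_ag = "RORag")
  tf_targets <- lapply(names(tf_cols), marked)
  names(tf_targets) <- unname(tf_cols)
  tf_targets$BMAL1 <- df$symbol[df$bmal1 == "x"]
  rnai <- rbind(
    data.frame(gene = marked("high_A"), phenotype = "high-A"),
    data.frame(gene = marked("long_T"), phenotype = "long-T"),
    data.frame(gene = marked("short_T"), phenotype = "short-T"))
  list(table = df,
       tf_targets = tf_targets,
       circadian = marked("circadian"),
       rnai = rnai,
       disease = data.frame(gene = df$symbol, annotation = df$omim,
                            stringsAsFactors = FALSE))
}
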