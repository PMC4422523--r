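#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return Named list of character gene vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stopf("malformed GMT line(s): %s",
                      paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in GMT")
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character gene vectors.
#' @param path Output file path.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("all gene sets must be named")
  if (any(vapply(sets, length, integer(1)) == 0L))
    stopf("empty gene set(s) cannot be written")
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Annotation catalog
#'
#' Bundles gene-set annotations by namespace (e.g. a GO-like ontology and a
#' pathway-like catalog), each with its own gene universe. The default
#' universe of a namespace is the union of its annotated genes.
#'
#' @param namespaces Named list; each element a named list of character gene
#'   vectors (as from [read_gmt()]).
#' @param universes Optional named list of character vectors overriding the
#'   per-namespace universe (e.g. the expression universe).
#' @return An `annotation_catalog` object.
#' @export
annotation_catalog <- function(namespaces, universes = NULL) {
  if (is.null(names(namespaces)) || any(!nzchar(names(namespaces))))
    stopf("namespaces must be named")
  for (ns in names(namespaces)) {
    sets <- namespaces[[ns]]
    if (length(sets) == 0L) stopf("namespace '%s' has no terms", ns)
    if (any(vapply(sets, length, integer(1)) == 0L))
      stopf("namespace '%s' contains an empty term", ns)
  }
  default_uni <- lapply(namespaces, function(s) unique(unlist(s)))
  if (!is.null(universes)) {
    for (ns in names(universes)) {
      extra <- setdiff(default_uni[[ns]], universes[[ns]])
      if (length(extra))
        stopf("namespace '%s': %d annotated gene(s) outside given universe",
              ns, length(extra))
      default_uni[[ns]] <- unique(as.character(universes[[ns]]))
    }
  }
  structure(list(namespaces = namespaces, universes = default_uni),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  for (ns in names(x$namespaces))
    cat(sprintf("<annotation_catalog namespace '%s': %d terms, universe %d>\n",
                ns, length(x$namespaces[[ns]]), length(x$universes[[ns]])))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_{j >= i}(p_(j) * m / j)`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Expected annotation count
#'
#' The expected number of annotated genes among a query drawn at random:
#' `Annotated * sampling_fraction`, where the sampling fraction is the
#' query's share of the namespace universe. Exposed separately because the
#' fraction can be recovered from any reported (Expected, Annotated) row of
#' an enrichment table.
#'
#' @param annotated Number of universe genes carrying the term.
#' @param sampling_fraction Query size divided by universe size.
#' @return Expected count.
#' @export
enrichment_expected <- function(annotated, sampling_fraction) {
  annotated * sampling_fraction
}

#' Term overrepresentation analysis
#'
#' One-sided hypergeometric test per term (classic count test, equivalently
#' Fisher's exact upper tail): drawing `|query ∩ universe|` genes from the
#' namespace universe, `p = P(X >= Significant)` where `Significant` is the
#' number of query genes annotated with the term. Rows are sorted by q then
#' p.
#'
#' @param query Character vector of query gene ids.
#' @param catalog An [annotation_catalog()].
#' @param namespace Namespace name within the catalog.
#' @return Data frame with the standard enrichment columns: `term`,
#'   `annotated`, `significant`, `expected`, `p`, `q`.
#' @export
overrepresentation <- function(query, catalog, namespace) {
  if (!namespace %in% names(catalog$namespaces))
    stopf("unknown namespace '%s'", namespace)
  sets <- catalog$namespaces[[namespace]]
  universe <- catalog$universes[[namespace]]
  if (length(universe) == 0L) stopf("empty universe")
  q_in <- unique(intersect(as.character(query), universe))
  if (length(q_in) == 0L)
    stopf("query does not intersect the '%s' universe", namespace)
  N <- length(universe)
  drawn <- length(q_in)
  annotated <- vapply(sets, function(s) length(intersect(s, universe)),
                      integer(1))
  significant <- vapply(sets, function(s) length(intersect(s, q_in)),
                        integer(1))
  p <- stats::phyper(significant - 1L, annotated, N - annotated, drawn,
                     lower.tail = FALSE)
  out <- data.frame(
    term = names(sets),
    annotated = annotated,
    significant = significant,
    expected = enrichment_expected(annotated, drawn / N),
    p = p,
    q = bh_fdr(p),
    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query") <- drawn
  attr(out, "n_universe") <- N
  out
}

#' Seed-gene by term cross-table
#'
#' For each seed gene, counts how many of its predicted target genes carry
#' each enriched term; the heat-map substrate relating individual seed genes
#' to the functions of their predicted targets. Row and column orders from
#' hierarchical clustering (complete linkage on Euclidean distance) are
#' attached for plotting.
#'
#' @param pairs Data frame with columns `seed`, `gene` (selected pairs).
#' @param terms Character vector of term names, all present in the namespace.
#' @param catalog An [annotation_catalog()].
#' @param namespace Namespace holding `terms`.
#' @return A list with `counts` (seed x term integer matrix), `row_order`
#'   and `col_order` (integer index permutations).
#' @export
cross_table <- function(pairs, terms, catalog, namespace) {
  if (!namespace %in% names(catalog$namespaces))
    stopf("unknown namespace '%s'", namespace)
  sets <- catalog$namespaces[[namespace]]
  missing <- setdiff(terms, names(sets))
  if (length(missing)) stopf("term(s) not in catalog: %s",
                             paste(missing, collapse = ", "))
  seeds <- sort(unique(pairs$seed))
  m <- matrix(0L, length(seeds), length(terms),
              dimnames = list(seeds, terms))
  targets_by_seed <- split(pairs$gene, pairs$seed)
  for (s in seeds) {
    tg <- unique(targets_by_seed[[s]])
    m[s, ] <- vapply(terms, function(tm) length(intersect(tg, sets[[tm]])),
                     integer(1))
  }
  order_of <- function(x) {
    if (nrow(x) < 3L) return(seq_len(nrow(x)))
    stats::hclust(stats::dist(x), method = "complete")$order
  }
  list(counts = m, row_order = order_of(m), col_order = order_of(t(m)))
}
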