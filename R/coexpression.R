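#' Expression compendium container
#'
#' A genes-by-samples numeric matrix with a dataset label, the substrate for
#' correlation and mutual-rank analysis. Emulates the aggregated microarray
#' collections ("Hsa"-style) distributed by co-expression databases.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers.
#' @param dataset Character label for the collection.
#' @return An object of class `expression_compendium`.
#' @export
expression_compendium <- function(values, dataset = "synthetic") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values))) stopf("values must have gene row names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids in compendium")
  if (ncol(values) < 3L) stopf("a compendium needs at least 3 samples")
  if (any(apply(values, 1L, function(r) all(is.na(r)))))
    stopf("compendium contains all-missing gene rows")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, dataset = dataset),
            class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("<expression_compendium '%s': %d genes x %d samples>\n",
              x$dataset, length(x$genes), length(x$samples)))
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Computes all pairwise Pearson correlations over the compendium using
#' pairwise-complete observations. Gene pairs with fewer than `min_obs`
#' complete paired observations, and genes with zero variance, yield missing
#' entries (counted in a message).
#'
#' @param compendium An [expression_compendium()] or a genes-by-samples
#'   numeric matrix with row names.
#' @param min_obs Minimum number of complete paired observations required for
#'   an entry; `NULL` (default) uses `min(20, n_samples)`.
#' @return A symmetric correlation matrix with unit diagonal (for genes with
#'   positive variance), class `c("correlation_matrix", "matrix")`.
#' @export
pearson_matrix <- function(compendium, min_obs = NULL) {
  values <- if (inherits(compendium, "expression_compendium"))
    compendium$values else compendium
  if (!is.matrix(values)) stopf("expected a matrix or expression_compendium")
  if (ncol(values) < 3L) stopf("need at least 3 samples")
  min_obs <- min_obs %||% min(20L, ncol(values))
  tv <- t(values)
  rho <- suppressWarnings(stats::cor(tv, use = "pairwise.complete.obs"))
  nobs <- crossprod(!is.na(tv))
  rho[nobs < min_obs] <- NA_real_
  zero_var <- apply(values, 1L, function(r) {
    s <- stats::sd(r, na.rm = TRUE)
    is.na(s) || s == 0
  })
  if (any(zero_var)) {
    msgf("pearson_matrix: %d zero-variance gene(s) set to missing", sum(zero_var))
    rho[zero_var, ] <- NA_real_
    rho[, zero_var] <- NA_real_
  }
  diag(rho)[!zero_var] <- 1
  class(rho) <- c("correlation_matrix", class(rho))
  rho
}

#' Mutual rank matrix
#'
#' For each gene, all partners are ranked by descending correlation
#' (self-correlations excluded, ties averaged); the mutual rank of a pair is
#' the geometric mean of the two reciprocal ranks,
#' `MR(a,b) = sqrt(rank_a(b) * rank_b(a))`. Low MR indicates a strong mutual
#' association; `MR = 1` iff the two genes are each other's top partner.
#'
#' @param corr Square symmetric correlation matrix (e.g. [pearson_matrix()]).
#' @return Symmetric matrix of mutual ranks, `NA` where correlations are
#'   missing, class `c("mutual_rank_matrix", "matrix")`.
#' @export
mutual_rank <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stopf("mutual_rank expects a square matrix")
  n <- nrow(corr)
  if (n < 2L) stopf("need at least 2 genes")
  ranks <- matrix(NA_real_, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n)) {
    v <- corr[i, ]
    v[i] <- NA
    ranks[i, ] <- rank(-v, na.last = "keep", ties.method = "average")
  }
  n_missing <- sum(is.na(corr[upper.tri(corr)]))
  if (n_missing > 0L)
    msgf("mutual_rank: %d missing correlation entrie(s) propagated", n_missing)
  mr <- sqrt(ranks * t(ranks))
  class(mr) <- c("mutual_rank_matrix", class(mr))
  mr
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(rho)`, approximately variance-stabilising and normalising the
#' sampling distribution of a Pearson correlation.
#'
#' @param rho Correlation value(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(rho) {
  if (any(!is.na(rho) & abs(rho) >= 1))
    stopf("fisher_z is defined for |rho| < 1")
  atanh(rho)
}

#' Compare foreground and background co-expression distributions
#'
#' Tests whether a foreground set of gene pairs (e.g. curated clock-network
#' interactions) is more strongly co-expressed than a background set: a
#' one-sided two-sample t-test on Fisher-z transformed correlations
#' (alternative: background smaller) and, when a mutual-rank matrix is given,
#' a one-sided Wilcoxon rank-sum test on MR values (alternative: foreground
#' smaller). Cumulative-distribution points are returned for plotting.
#'
#' @param fg_pairs,bg_pairs Two-column matrices or data frames of gene ids;
#'   the sets must be non-empty and disjoint.
#' @param corr Correlation matrix covering the pair genes.
#' @param mr Optional mutual-rank matrix on the same genes.
#' @return A list of class `distribution_comparison` with the test
#'   statistics, sample sizes, Fisher-z values and ecdf points.
#' @export
compare_foreground_background <- function(fg_pairs, bg_pairs, corr, mr = NULL) {
  fg_pairs <- as.matrix(fg_pairs)[, 1:2, drop = FALSE]
  bg_pairs <- as.matrix(bg_pairs)[, 1:2, drop = FALSE]
  if (nrow(fg_pairs) < 2L || nrow(bg_pairs) < 2L)
    stopf("need at least 2 pairs in each set")
  if (any(pair_key(fg_pairs[, 1], fg_pairs[, 2]) %in%
          pair_key(bg_pairs[, 1], bg_pairs[, 2])))
    stopf("foreground and background pair sets must be disjoint")
  get_vals <- function(pairs, m) m[cbind(match(pairs[, 1], rownames(m)),
                                         match(pairs[, 2], colnames(m)))]
  fg_rho <- get_vals(fg_pairs, corr)
  bg_rho <- get_vals(bg_pairs, corr)
  dropped <- sum(is.na(fg_rho)) + sum(is.na(bg_rho))
  if (dropped > 0L)
    msgf("compare_foreground_background: %d pair(s) without correlation dropped",
         dropped)
  fg_z <- fisher_z(fg_rho[!is.na(fg_rho)])
  bg_z <- fisher_z(bg_rho[!is.na(bg_rho)])
  tt <- stats::t.test(fg_z, bg_z, alternative = "greater")
  wil <- NULL
  if (!is.null(mr)) {
    fg_mr <- get_vals(fg_pairs, mr)
    bg_mr <- get_vals(bg_pairs, mr)
    wil <- suppressWarnings(
      stats::wilcox.test(fg_mr[!is.na(fg_mr)], bg_mr[!is.na(bg_mr)],
                         alternative = "less"))
  }
  ecdf_points <- function(x) {
    x <- sort(x)
    data.frame(rho = x, cum = seq_along(x) / length(x))
  }
  structure(list(
    n_fg = length(fg_z), n_bg = length(bg_z),
    t_statistic = unname(tt$statistic), p_t = tt$p.value,
    p_wilcoxon_mr = if (is.null(wil)) NA_real_ else wil$p.value,
    fg_z = fg_z, bg_z = bg_z,
    ecdf_fg = ecdf_points(fg_rho[!is.na(fg_rho)]),
    ecdf_bg = ecdf_points(bg_rho[!is.na(bg_rho)])
  ), class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf(paste0("<distribution_comparison: n_fg=%d n_bg=%d ",
                     "t=%.3f p_t=%.3g p_wilcoxon_mr=%.3g>\n"),
              x$n_fg, x$n_bg, x$t_statistic, x$p_t, x$p_wilcoxon_mr))
  invisible(x)
}

#' Read an expression TSV
#'
#' Reads the genes-by-samples dialect written by [write_expression_tsv()]:
#' header row of sample ids, first column `entrez` of gene ids.
#'
#' @param path File path.
#' @param dataset Dataset label for the resulting compendium.
#' @return An [expression_compendium()].
#' @export
read_expression_tsv <- function(path, dataset = basename(path)) {
  df <- read_tsv_base(path)
  if (names(df)[1] != "entrez") stopf("expected first column 'entrez'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$entrez)
  expression_compendium(m, dataset = dataset)
}

#' Write an expression compendium as TSV
#'
#' @param compendium An [expression_compendium()].
#' @param path Output file path.
#' @export
write_expression_tsv <- function(compendium, path) {
  df <- data.frame(entrez = compendium$genes,
                   compendium$values, check.names = FALSE)
  write_tsv_base(df, path)
  invisible(path)
}
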