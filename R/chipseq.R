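#' Read ChIP-seq peaks from BED / narrowPeak
#'
#' Accepts BED3+ and ENCODE narrowPeak (BED6+4). Coordinates are 0-based
#' half-open. The peak anchor position is the summit (`start + summit
#' offset`) when a narrowPeak summit column is present and non-negative,
#' otherwise the interval midpoint. Peak weight is the narrowPeak
#' `signalValue` (column 7) when present, else the BED score (column 5),
#' else 1.
#'
#' @param path File path.
#' @return A `peak_set` data frame with columns `chrom`, `start`, `end`,
#'   `weight`, `pos`.
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("need at least 3 BED columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  out$weight <- if (ncol(df) >= 7L) as.numeric(df[[7]])
    else if (ncol(df) >= 5L) as.numeric(df[[5]])
    else 1
  summit <- if (ncol(df) >= 10L) as.integer(df[[10]]) else rep(-1L, nrow(df))
  out$pos <- ifelse(summit >= 0L, out$start + summit,
                    (out$start + out$end) %/% 2L)
  peak_set(out)
}

#' Peak set constructor
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `weight`
#'   (positive) and optionally `pos` (anchor; defaults to the midpoint).
#' @return A validated `peak_set` data frame.
#' @export
peak_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "weight") %in% names(df)))
  if (any(df$start >= df$end)) stopf("peaks must satisfy start < end")
  if (any(df$weight <= 0)) stopf("peak weights must be positive")
  if (is.null(df$pos)) df$pos <- (df$start + df$end) %/% 2L
  class(df) <- unique(c("peak_set", class(df)))
  df
}

#' Read gene models with TSS
#'
#' From BED6 (`chrom`, `start`, `end`, `name`, `score`, `strand`; 0-based
#' half-open) the TSS is `start` on the + strand and `end - 1` on the -
#' strand. From a minimal GTF, rows with feature `gene` (falling back to
#' `transcript`) are used with the 1-based `start`/`end` converted the same
#' way; the gene id is taken from the `gene_id` attribute. Duplicated gene
#' ids keep the first record (with a message), so each gene has one TSS.
#'
#' @param path File path.
#' @param format `"bed"` (default) or `"gtf"`.
#' @return A `gene_models` data frame with columns `gene`, `chrom`, `tss`,
#'   `strand`.
#' @export
read_gene_models <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stopf("gene model BED needs 6 columns")
    out <- data.frame(gene = as.character(df[[4]]),
                      chrom = as.character(df[[1]]),
                      tss = ifelse(df[[6]] == "+", as.integer(df[[2]]),
                                   as.integer(df[[3]]) - 1L),
                      strand = as.character(df[[6]]),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                            stringsAsFactors = FALSE)
    feat <- if (any(df[[3]] == "gene")) "gene" else "transcript"
    df <- df[df[[3]] == feat, , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df[[9]])
    out <- data.frame(gene = gid, chrom = as.character(df[[1]]),
                      tss = ifelse(df[[7]] == "+", as.integer(df[[4]]) - 1L,
                                   as.integer(df[[5]]) - 1L),
                      strand = as.character(df[[7]]),
                      stringsAsFactors = FALSE)
  }
  gene_models(out)
}

#' Gene model constructor
#'
#' @param df Data frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @return A validated `gene_models` data frame (one TSS per gene).
#' @export
gene_models <- function(df) {
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(df)))
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be + or -")
  if (anyDuplicated(df$gene)) {
    msgf("gene_models: %d duplicated gene id(s), keeping first record",
         sum(duplicated(df$gene)))
    df <- df[!duplicated(df$gene), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- unique(c("gene_models", class(df)))
  df
}

#' Write peaks as narrowPeak / gene models as BED6
#'
#' @param peaks A `peak_set`.
#' @param genes A `gene_models` data frame.
#' @param path Output file path.
#' @name chip_writers
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   paste0("peak", seq_len(nrow(peaks))), 0L, ".",
                   peaks$weight, -1, -1, peaks$pos - peaks$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname chip_writers
#' @export
write_gene_models_bed <- function(genes, path) {
  start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 999L)
  df <- data.frame(genes$chrom, start, start + 1000L, genes$gene, 0L,
                   genes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Closest-gene association scores
#'
#' Assigns every peak to the gene whose TSS is nearest the peak anchor
#' position on the same chromosome (deterministic tie-break: the lexically
#' smaller gene id). A gene's association score is the sum of the weights of
#' its assigned peaks, so total signal is conserved:
#' `sum(S_g) = sum(assigned peak weights)`. Peaks on chromosomes absent from
#' the gene models stay unassigned (counted in a message).
#'
#' @param peaks A `peak_set`.
#' @param genes A `gene_models` data frame.
#' @param tf Label of the profiled transcription factor.
#' @return A `target_scores` data frame with columns `gene`, `score` (all
#'   genes, zero when peak-free); attributes `tf`, `n_gene` (genes with
#'   positive score) and `n_unassigned`.
#' @export
closest_gene_scores <- function(peaks, genes, tf = "TF") {
  score <- stats::setNames(numeric(nrow(genes)), genes$gene)
  unassigned <- 0L
  for (chr in unique(peaks$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) {
      unassigned <- unassigned + nrow(p)
      next
    }
    g <- g[order(g$tss, g$gene), , drop = FALSE]
    idx <- findInterval(p$pos, g$tss)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, nrow(g))
    dl <- abs(p$pos - g$tss[left])
    dr <- abs(p$pos - g$tss[right])
    pick <- ifelse(dl < dr, left,
            ifelse(dr < dl, right,
                   # equidistant: lexically smaller gene id
                   ifelse(g$gene[left] <= g$gene[right], left, right)))
    hits <- tapply(p$weight, g$gene[pick], sum)
    score[names(hits)] <- score[names(hits)] + hits
  }
  if (unassigned > 0L)
    msgf("closest_gene_scores: %d peak(s) on chromosomes without gene models",
         unassigned)
  out <- data.frame(gene = names(score), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "tf") <- tf
  attr(out, "n_gene") <- sum(out$score > 0)
  attr(out, "n_unassigned") <- unassigned
  class(out) <- c("target_scores", class(out))
  out
}

#' Call transcription-factor target genes
#'
#' Accepts genes whose association score satisfies
#' `log2(S_g) >= log2_threshold` (scores of zero are never called).
#'
#' @param scores A `target_scores` data frame.
#' @param log2_threshold Acceptance threshold on the log2 score scale
#'   (default 3).
#' @return Sorted character vector of called target genes.
#' @export
call_targets <- function(scores, log2_threshold = 3) {
  if (!is.finite(log2_threshold) && log2_threshold != -Inf)
    stopf("threshold must be finite or -Inf")
  sort(scores$gene[scores$score > 0 & log2(scores$score) >= log2_threshold])
}

#' Suggest a log2 score threshold
#'
#' Fits a two-component Gaussian mixture to the log2 association scores of
#' peak-bearing genes and suggests the density valley between the component
#' means — the natural cut between the background mode and the bound-gene
#' mode of a bimodal score distribution. When the components merge (means
#' closer than one pooled standard deviation, the "right shoulder" case) the
#' fallback `mean + 1 sd` is returned and flagged. Histogram data for a
#' diagnostic plot are included.
#'
#' @param scores A `target_scores` data frame.
#' @param min_n Minimum number of positive scores required (default 50).
#' @return List with `suggestion` (log2 threshold or `NA`), `fallback`
#'   (logical), component `means`/`sds`/`weights`, and `histogram`
#'   (`hist()` data of the log2 scores).
#' @export
threshold_suggest <- function(scores, min_n = 50) {
  x <- log2(scores$score[scores$score > 0])
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  if (length(x) < min_n) {
    msgf("threshold_suggest: only %d positive scores (< %d), no suggestion",
         length(x), min_n)
    return(list(suggestion = NA_real_, fallback = NA, means = NULL,
                sds = NULL, weights = NULL, histogram = h))
  }
  fit <- Mclust(x, G = 2, modelNames = c("V", "E"), verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  var <- fit$parameters$variance$sigmasq
  if (length(var) == 1L) var <- rep(var, 2L)
  var <- var[order(fit$parameters$mean)]
  w <- fit$parameters$pro[order(fit$parameters$mean)]
  mix_dens <- function(z) w[1] * stats::dnorm(z, mu[1], sqrt(var[1])) +
    w[2] * stats::dnorm(z, mu[2], sqrt(var[2]))
  grid <- seq(mu[1], mu[2], length.out = 512L)
  dens <- mix_dens(grid)
  valley <- which.min(dens)
  # a shoulder rather than a second mode: the between-means dip is shallow
  # (or absent) relative to the weaker mode -> fall back to mean + 1 sd
  merged <- valley %in% c(1L, 512L) ||
    dens[valley] >= 0.7 * min(mix_dens(mu))
  if (merged) {
    return(list(suggestion = mean(x) + stats::sd(x), fallback = TRUE,
                means = mu, sds = sqrt(var), weights = w, histogram = h))
  }
  list(suggestion = grid[valley], fallback = FALSE,
       means = mu, sds = sqrt(var), weights = w, histogram = h)
}

#' Read a provided target list
#'
#' Bypass for factors whose raw peak coordinates are not available but whose
#' author-provided predicted target lists are (one gene id per line, or a
#' TSV whose first column is the gene id; an optional header line named
#' `gene` is skipped).
#'
#' @param path File path.
#' @return Sorted character vector of target gene ids.
#' @export
read_target_list <- function(path) {
  x <- utils::read.table(path, sep = "\t", quote = "",
                         stringsAsFactors = FALSE)[[1]]
  x <- as.character(x)
  if (length(x) && x[1] == "gene") x <- x[-1]
  sort(unique(x))
}
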