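#' Generate a synthetic expression compendium with planted truth
#'
#' Emulates an aggregated, unsynchronised expression collection. Each sample
#' draws a latent circadian phase uniformly on `[0, 24)` hours; a clock gene
#' with amplitude `a` and peak phase `phi` takes the value
#' `a * cos(2*pi*(theta_s - phi)/24)` plus Gaussian observation noise. A
#' planted target gene is a noisy linear mix of its (observed) seed genes,
#' scaled so the configured fraction of its variance is seed-driven;
#' background genes are independent noise. Because sample phases are
#' independent, the expected correlation of two clock genes with common
#' amplitude `a` is `cos(2*pi*dphi/24) / (1 + 2*sigma^2/a^2)` — attenuated
#' relative to the noiseless `cos` by the noise, as in real compendia.
#'
#' The returned truth also fixes, deterministically under the config seed,
#' the rhythmic gene set, per-TF true target sets and planted term
#' memberships consumed by the other generators.
#'
#' @param config A [synthetic_config()].
#' @return List with `compendium` (an [expression_compendium()]) and `truth`
#'   (a `synthetic_truth` list: `genes`, `true_edges`, `true_rhythmic`,
#'   `true_tf_targets`, `true_term_memberships`).
#' @export
generate_compendium <- function(config) {
  validate_synthetic_config(config)
  cg <- config$clock_genes
  pe <- config$planted_edges
  targets <- unique(pe$target)
  background <- if (config$n_background_genes > 0)
    sprintf("BG%04d", seq_len(config$n_background_genes)) else character()
  all_genes <- c(cg$gene, targets, background)
  if (anyDuplicated(all_genes)) stopf("duplicate gene ids in generated universe")
  n <- config$n_samples

  out <- with_seed(config$rng_seed + 101L, {
    theta <- stats::runif(n, 0, 24)
    values <- matrix(NA_real_, length(all_genes), n,
                     dimnames = list(all_genes,
                                     sprintf("S%03d", seq_len(n))))
    for (i in seq_len(nrow(cg)))
      values[cg$gene[i], ] <- cg$amplitude[i] *
        cos(2 * pi * (theta - cg$phase[i]) / 24) +
        stats::rnorm(n, sd = config$noise_sd)
    for (tg in targets) {
      rows <- pe[pe$target == tg, , drop = FALSE]
      mix <- rowSums(scale(t(values[rows$seed, , drop = FALSE])))
      mix <- as.vector(scale(mix))
      e <- rows$effect[1]
      values[tg, ] <- sqrt(e) * mix + sqrt(1 - e) * stats::rnorm(n)
    }
    if (length(background))
      values[background, ] <- stats::rnorm(length(background) * n)

    n_rhyt <- round(config$rhythmic_fraction * length(targets))
    rhythmic_targets <- if (n_rhyt > 0) targets[seq_len(n_rhyt)] else character()
    true_rhythmic <- data.frame(gene = cg$gene, period = 24, phase = cg$phase,
                                stringsAsFactors = FALSE)
    if (length(rhythmic_targets)) {
      first_seed <- vapply(rhythmic_targets, function(tg)
        pe$seed[pe$target == tg][1], character(1))
      true_rhythmic <- rbind(true_rhythmic, data.frame(
        gene = rhythmic_targets, period = 24,
        phase = cg$phase[match(first_seed, cg$gene)],
        stringsAsFactors = FALSE))
    }
    tfs <- intersect(c("NR1D1", "NR1D2", "ARNTL"), cg$gene)
    candidate_pool <- c(targets, background)
    true_tf_targets <- lapply(tfs, function(tf)
      sort(sample(candidate_pool, min(config$n_tf_targets,
                                      length(candidate_pool)))))
    names(true_tf_targets) <- tfs
    memberships <- list(
      "BP:planted_target_program" = sort(c(
        sample(targets, ceiling(0.8 * length(targets))),
        sample(background, min(5L, length(background))))),
      "PW:planted_target_pathway" = sort(c(
        sample(targets, ceiling(0.6 * length(targets))),
        sample(background, min(8L, length(background))))))
    list(values = values, true_rhythmic = true_rhythmic,
         true_tf_targets = true_tf_targets, memberships = memberships)
  })

  truth <- structure(list(
    genes = all_genes,
    true_edges = data.frame(seed = pe$seed, target = pe$target,
                            stringsAsFactors = FALSE),
    true_rhythmic = out$true_rhythmic,
    true_tf_targets = out$true_tf_targets,
    true_term_memberships = out$memberships
  ), class = "synthetic_truth")
  list(compendium = expression_compendium(out$values, dataset = "synthetic"),
       truth = truth)
}

#' Generate deterministic gene models for the synthetic universe
#'
#' Places every gene's TSS on one of two chromosomes with 10 kb spacing and
#' alternating strand — wide enough apart that a peak planted within 2 kb of
#' a TSS is always closest to that TSS.
#'
#' @param truth A `synthetic_truth`.
#' @return A `gene_models` data frame.
#' @export
generate_gene_models <- function(truth) {
  genes <- truth$genes
  chrom <- rep(c("chr1", "chr2"), length.out = length(genes))
  idx <- stats::ave(seq_along(genes), chrom, FUN = seq_along)
  gene_models(data.frame(
    gene = genes, chrom = chrom, tss = 10000L * idx,
    strand = rep(c("+", "-"), length.out = length(genes)),
    stringsAsFactors = FALSE))
}

#' Generate ChIP-seq peak sets with planted targets
#'
#' For every transcription factor in the truth, each true target receives
#' one or two peaks within 2 kb of its TSS whose summed weight exceeds the
#' default log2 calling threshold of 3 by at least one unit; background
#' peaks are placed uniformly along the chromosomes with low weights, making
#' the per-gene log2 score distribution bimodal.
#'
#' @param truth A `synthetic_truth` with non-empty `true_tf_targets`.
#' @param gene_models A `gene_models` data frame covering all true targets.
#' @param config A [synthetic_config()].
#' @param n_background_peaks Background peaks per factor; default three per
#'   true target.
#' @return Named list of `peak_set` data frames, one per factor.
#' @export
generate_peaks <- function(truth, gene_models, config,
                           n_background_peaks = NULL) {
  tss_key <- paste(gene_models$chrom, gene_models$tss)
  if (anyDuplicated(tss_key))
    stopf("gene models contain overlapping identical TSS coordinates")
  missing <- setdiff(unique(unlist(truth$true_tf_targets)), gene_models$gene)
  if (length(missing))
    stopf("true TF targets without gene models: %s",
          paste(missing, collapse = ", "))
  chrom_span <- tapply(gene_models$tss, gene_models$chrom, max)
  with_seed(config$rng_seed + 303L, {
    lapply(truth$true_tf_targets, function(tf_targets) {
      n_bg <- n_background_peaks %||% (3L * length(tf_targets))
      rows <- do.call(rbind, lapply(tf_targets, function(g) {
        gm <- gene_models[gene_models$gene == g, ]
        npk <- sample(1:2, 1)
        total_w <- 2^stats::runif(1, 4, 6)
        centers <- round(gm$tss + stats::runif(npk, -2000, 2000))
        w <- as.vector(total_w * prop.table(stats::runif(npk, 0.5, 1)))
        data.frame(chrom = gm$chrom, start = centers - 150L,
                   end = centers + 150L, weight = w,
                   stringsAsFactors = FALSE)
      }))
      if (n_bg > 0) {
        chroms <- sample(names(chrom_span), n_bg, replace = TRUE)
        centers <- round(stats::runif(n_bg, 1000, chrom_span[chroms]))
        rows <- rbind(rows, data.frame(
          chrom = chroms, start = centers - 150L, end = centers + 150L,
          weight = 2^stats::runif(n_bg, -0.5, 1.5),
          stringsAsFactors = FALSE))
      }
      rows$start <- pmax(rows$start, 0L)
      peak_set(rows)
    })
  })
}

#' Generate a literature-mined interaction table
#'
#' Emits every true planted edge with a shifted-geometric number of
#' supporting sentences (a heavy-tailed count whose mean sits well above its
#' median, as text-mined support does) and per-sentence classifier
#' confidences; a configured fraction of the emitted pairs are random
#' non-edges standing in for text-mining false positives.
#'
#' @param truth A `synthetic_truth` with non-empty `true_edges`.
#' @param config A [synthetic_config()]; `literature_fp_rate` controls the
#'   non-edge fraction.
#' @param mean_sentences Mean sentences per pair (default 8).
#' @return Data frame with columns `gene1`, `gene2`, `pmid`, `sentence`,
#'   `confidence`, one row per sentence.
#' @export
generate_literature_table <- function(truth, config, mean_sentences = 8) {
  if (nrow(truth$true_edges) == 0L) stopf("truth has no true edges")
  fp <- config$literature_fp_rate
  true_pairs <- unique(truth$true_edges[, c("seed", "target")])
  names(true_pairs) <- c("gene1", "gene2")
  n_true <- nrow(true_pairs)
  n_fp <- round(fp / (1 - fp) * n_true)
  with_seed(config$rng_seed + 202L, {
    pairs <- true_pairs
    if (n_fp > 0) {
      seeds <- unique(config$clock_genes$gene)
      others <- setdiff(truth$genes, seeds)
      true_key <- pair_key(true_pairs$gene1, true_pairs$gene2)
      fp_rows <- NULL
      guard <- 0L
      while (is.null(fp_rows) || nrow(fp_rows) < n_fp) {
        cand <- data.frame(gene1 = sample(seeds, n_fp, replace = TRUE),
                           gene2 = sample(others, n_fp, replace = TRUE),
                           stringsAsFactors = FALSE)
        cand <- cand[!(pair_key(cand$gene1, cand$gene2) %in% true_key), ]
        fp_rows <- unique(rbind(fp_rows, cand))
        guard <- guard + 1L
        if (guard > 100L) stopf("could not place false-positive pairs")
      }
      pairs <- rbind(pairs, fp_rows[seq_len(n_fp), ])
    }
    n_sent <- 1L + stats::rgeom(nrow(pairs), prob = 1 / mean_sentences)
    rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      k <- n_sent[i]
      data.frame(
        gene1 = pairs$gene1[i], gene2 = pairs$gene2[i],
        pmid = sample(1000000:30000000, k, replace = TRUE),
        sentence = sprintf(
          "Synthetic evidence sentence %d: %s interacts with %s.",
          seq_len(k), pairs$gene1[i], pairs$gene2[i]),
        confidence = round(stats::runif(k, 0.4, 1), 4),
        stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    attr(rows, "n_fp_pairs") <- n_fp
    rows
  })
}

#' Generate a circadian time course
#'
#' Rhythmic genes (per the truth) follow a unit-amplitude cosine of their
#' true period and phase sampled at the configured timepoints, plus Gaussian
#' noise; all other genes are pure noise.
#'
#' @param truth A `synthetic_truth`.
#' @param config A [synthetic_config()]; `timepoints` and `ts_noise_sd`
#'   apply.
#' @return Numeric matrix, genes by timepoints, hour-valued column names.
#' @export
generate_timeseries <- function(truth, config) {
  tp <- config$timepoints
  if (any(diff(tp) <= 0)) stopf("timepoints must be strictly increasing")
  if (length(tp) < 8L)
    warning("fewer than 8 timepoints: the rhythm scan will be underpowered",
            call. = FALSE)
  genes <- truth$genes
  with_seed(config$rng_seed + 404L, {
    m <- matrix(stats::rnorm(length(genes) * length(tp),
                             sd = max(config$ts_noise_sd, 1e-12)),
                nrow = length(genes),
                dimnames = list(genes, as.character(tp)))
    tr <- truth$true_rhythmic
    for (i in seq_len(nrow(tr)))
      m[tr$gene[i], ] <- m[tr$gene[i], ] +
        cos(2 * pi * (tp - tr$phase[i]) / tr$period[i])
    m
  })
}

#' Generate gene-set annotations (two namespaces)
#'
#' Builds an [annotation_catalog()] with a GO-like (`BP`) and a pathway-like
#' (`PW`) namespace over the whole synthetic universe: the truth's planted
#' term memberships (enriched in the planted target set by construction)
#' plus random background terms.
#'
#' @param truth A `synthetic_truth`.
#' @param config A [synthetic_config()].
#' @param n_random_terms Background terms per namespace (default 20).
#' @return An [annotation_catalog()] with namespaces `BP` and `PW` and the
#'   full gene universe.
#' @export
generate_annotations <- function(truth, config, n_random_terms = 20) {
  genes <- truth$genes
  with_seed(config$rng_seed + 505L, {
    ns <- list(BP = list(), PW = list())
    for (nm in names(truth$true_term_memberships)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      ns[[parts[1]]][[parts[2]]] <- truth$true_term_memberships[[nm]]
    }
    for (space in names(ns)) {
      for (i in seq_len(n_random_terms)) {
        size <- sample(10:60, 1)
        ns[[space]][[sprintf("%s_random_%02d", tolower(space), i)]] <-
          sort(sample(genes, size))
      }
    }
    annotation_catalog(ns, universes = list(BP = genes, PW = genes))
  })
}

#' Generate every synthetic pipeline input in memory
#'
#' @param config A [synthetic_config()].
#' @return List with `compendium`, `truth`, `gene_models`, `peaks` (named
#'   list per TF), `literature` (sentence table), `timeseries`, `catalog`.
#' @export
generate_all <- function(config = synthetic_config()) {
  gen <- generate_compendium(config)
  gm <- generate_gene_models(gen$truth)
  list(compendium = gen$compendium,
       truth = gen$truth,
       gene_models = gm,
       peaks = generate_peaks(gen$truth, gm, config),
       literature = generate_literature_table(gen$truth, config),
       timeseries = generate_timeseries(gen$truth, config),
       catalog = generate_annotations(gen$truth, config))
}

#' Write every synthetic input as plain-text files
#'
#' Materialises the generated inputs in their interchange formats:
#' expression TSV, evidence TSV, GMT per namespace, narrowPeak per factor,
#' gene-model BED, time-course TSV and a truth JSON. With a fixed config
#' seed the files are byte-identical across runs.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly; the
#'   generated objects as attribute `objects`.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- generate_all(config)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             evidence = file.path(dir, "evidence.tsv"),
             gene_models = file.path(dir, "gene_models.bed"),
             timeseries = file.path(dir, "timeseries.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(obj$compendium, paths[["expression"]])
  write_tsv_base(obj$literature, paths[["evidence"]])
  write_gene_models_bed(obj$gene_models, paths[["gene_models"]])
  ts <- data.frame(gene = rownames(obj$timeseries), obj$timeseries,
                   check.names = FALSE)
  write_tsv_base(ts, paths[["timeseries"]])
  for (ns in names(obj$catalog$namespaces)) {
    p <- file.path(dir, sprintf("annotations_%s.gmt", tolower(ns)))
    write_gmt(obj$catalog$namespaces[[ns]], p)
    paths[[paste0("gmt_", tolower(ns))]] <- p
  }
  for (tf in names(obj$peaks)) {
    p <- file.path(dir, sprintf("peaks_%s.narrowPeak", tf))
    write_narrowpeak(obj$peaks[[tf]], p)
    paths[[paste0("peaks_", tf)]] <- p
  }
  truth_json <- list(
    genes = obj$truth$genes,
    true_edges = obj$truth$true_edges,
    true_rhythmic = obj$truth$true_rhythmic,
    true_tf_targets = obj$truth$true_tf_targets,
    true_term_memberships = obj$truth$true_term_memberships)
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(paths, "objects") <- obj
  invisible(paths)
}
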