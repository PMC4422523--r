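#' Pipeline configuration
#'
#' Bundles every stage parameter with a single RNG seed. The defaults are
#' the reference analysis settings: top 10,000 co-expression pairs, minimum
#' tightness 2, 50 text-mining partners per seed gene, at most 5 supporting
#' sentences per pair, enrichment q-threshold 0.01, ChIP-seq log2 score
#' threshold 3 and rhythm significance levels 0.009 and 0.05.
#'
#' @param synthetic A [synthetic_config()] describing inputs to generate,
#'   or `NULL` when `inputs` is given.
#' @param inputs Optional named list of input file paths (`expression`,
#'   `evidence`, `gene_models`, `timeseries`, `peaks` (named vector),
#'   `gmt` (named vector)), as written by [write_synthetic_inputs()].
#' @param K Number of top co-expression pairs to select.
#' @param min_tightness Minimum distinct seed partners per candidate.
#' @param n_top_partners Text-mining partners kept per seed gene.
#' @param max_sentences Evidence sentence cap per pair.
#' @param q_threshold Enrichment significance threshold.
#' @param chip_log2_threshold ChIP-seq target-calling threshold (log2).
#' @param rhythm_alphas Rhythmicity significance levels.
#' @param rng_seed Integer seed threaded to every stochastic stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            inputs = NULL,
                            K = 10000,
                            min_tightness = 2,
                            n_top_partners = 50,
                            max_sentences = 5,
                            q_threshold = 0.01,
                            chip_log2_threshold = 3,
                            rhythm_alphas = c(0.009, 0.05),
                            rng_seed = 1L) {
  cfg <- structure(list(
    synthetic = synthetic, inputs = inputs, K = K,
    min_tightness = min_tightness, n_top_partners = n_top_partners,
    max_sentences = max_sentences, q_threshold = q_threshold,
    chip_log2_threshold = chip_log2_threshold,
    rhythm_alphas = rhythm_alphas, rng_seed = as.integer(rng_seed)),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$synthetic) && is.null(cfg$inputs))
    stopf("either synthetic config or input paths required")
  if (!is_count(cfg$K)) stopf("K must be >= 1")
  if (!is_count(cfg$min_tightness)) stopf("min_tightness must be >= 1")
  if (!is_count(cfg$n_top_partners)) stopf("n_top_partners must be >= 1")
  if (!is_count(cfg$max_sentences)) stopf("max_sentences must be >= 1")
  if (cfg$q_threshold <= 0 || cfg$q_threshold > 1)
    stopf("q_threshold must be in (0, 1]")
  if (!is.finite(cfg$chip_log2_threshold))
    stopf("chip_log2_threshold must be finite")
  if (any(cfg$rhythm_alphas < 0 | cfg$rhythm_alphas > 1))
    stopf("rhythm_alphas must be in [0, 1]")
  invisible(cfg)
}

pipeline_config_fields <- c("synthetic", "inputs", "K", "min_tightness",
                            "n_top_partners", "max_sentences", "q_threshold",
                            "chip_log2_threshold", "rhythm_alphas",
                            "rng_seed")

#' Serialise / restore a pipeline configuration
#'
#' JSON round-trip of the scalar configuration (the synthetic block included
#' as nested tables). Unknown keys in a restored file are rejected.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @name pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), pipeline_config_fields)
  if (length(unknown))
    stopf("unknown pipeline config key(s): %s", paste(unknown, collapse = ", "))
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    s <- raw$synthetic
    syn <- synthetic_config(
      n_samples = s$n_samples, n_background_genes = s$n_background_genes,
      clock_genes = as.data.frame(s$clock_genes),
      planted_edges = as.data.frame(s$planted_edges),
      noise_sd = s$noise_sd, literature_fp_rate = s$literature_fp_rate,
      rhythmic_fraction = s$rhythmic_fraction, timepoints = s$timepoints,
      ts_noise_sd = s$ts_noise_sd, n_tf_targets = s$n_tf_targets,
      rng_seed = s$rng_seed)
  }
  pipeline_config(
    synthetic = syn, inputs = raw$inputs, K = raw$K,
    min_tightness = raw$min_tightness, n_top_partners = raw$n_top_partners,
    max_sentences = raw$max_sentences, q_threshold = raw$q_threshold,
    chip_log2_threshold = raw$chip_log2_threshold,
    rhythm_alphas = raw$rhythm_alphas, rng_seed = raw$rng_seed)
}

#' K matching a target selection fraction
#'
#' The number of top pairs corresponding to a given percentage of the
#' seed-by-universe pair space — used to carry the reference selection
#' fraction (1.18%) to pair universes of any size.
#'
#' @param n_seed,n_universe Seed and universe gene counts.
#' @param fraction_pct Selection fraction in percent (default 1.18).
#' @return Integer K (at least 1).
#' @export
fraction_K <- function(n_seed, n_universe, fraction_pct = 1.18) {
  max(1L, as.integer(round(fraction_pct / 100 * n_seed * n_universe)))
}

#' Run the full multi-evidence pipeline
#'
#' Executes all stages against synthetic or file inputs: co-expression
#' correlation and target prediction with tightness filtering, enrichment of
#' the predicted set, text-mining evidence aggregation and top-partner
#' selection, intersection of the two streams, ChIP-seq target calling,
#' rhythmicity scanning, and assembly of the layered provenance network with
#' validation annotations. Artifacts are written to `out_dir` together with
#' a run manifest (package/R versions, seed, parameters, file digests);
#' identical config and seed give byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips artifact writing.
#' @param seed_network Seed network; defaults to the packaged fixture.
#' @return A `pipeline_result` list with each stage's objects.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         seed_network = read_seed_network()) {
  validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  data <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      sc$rng_seed <- config$rng_seed
      generate_all(sc)
    } else {
      inp <- config$inputs
      tmp_ev <- inp$evidence
      peaks <- lapply(inp$peaks, read_narrowpeak)
      list(compendium = read_expression_tsv(inp$expression),
           truth = NULL,
           gene_models = read_gene_models(inp$gene_models, format = "bed"),
           peaks = peaks,
           literature = NULL, evidence_path = tmp_ev,
           timeseries = {
             ts <- read_tsv_base(inp$timeseries)
             m <- as.matrix(ts[, -1]); rownames(m) <- ts[[1]]
             colnames(m) <- sub("^X", "", colnames(m))
             m
           },
           catalog = annotation_catalog(lapply(inp$gmt, read_gmt)))
    }
  })

  corr <- stage("coexpress", pearson_matrix(data$compendium))

  predicted <- stage("predict", {
    pairs <- select_top_pairs(corr, seed_network, K = config$K)
    cand <- compute_tightness(pairs, seed = seed_network)
    tight <- filter_tightness(cand, min_t = config$min_tightness,
                              pairs = pairs)
    list(pairs = pairs, candidates = cand, tight = tight,
         report = attr(pairs, "report"),
         genes = tight$gene)
  })

  enrich <- stage("enrich", {
    lapply(names(data$catalog$namespaces), function(ns) {
      res <- overrepresentation(predicted$genes, data$catalog, ns)
      res[res$q <= config$q_threshold, , drop = FALSE]
    }) |> stats::setNames(names(data$catalog$namespaces))
  })

  evidence <- stage("integrate", {
    path <- if (!is.null(data$literature)) {
      p <- tempfile(fileext = ".tsv")
      write_tsv_base(data$literature, p)
      p
    } else data$evidence_path
    ev <- load_interaction_table(path)
    ev <- cap_sentences(ev, max_sentences = config$max_sentences)
    partners <- top_partners(ev, seed_network,
                             n_top = config$n_top_partners)
    list(evidence = ev, partners = partners, genes = partners$genes)
  })

  consensus <- stage("intersect",
                     intersect_evidence(predicted$genes, evidence$genes))

  chip <- stage("chip", {
    lapply(names(data$peaks), function(tf) {
      sc <- closest_gene_scores(data$peaks[[tf]], data$gene_models, tf = tf)
      list(scores = sc,
           targets = call_targets(sc, config$chip_log2_threshold))
    }) |> stats::setNames(names(data$peaks))
  })

  rhythm <- stage("rhythm", {
    calls <- jtk_scan(data$timeseries)
    list(calls = calls,
         flags = classify_circadian(calls, alphas = config$rhythm_alphas))
  })

  network <- stage("assemble", {
    coexp_pairs <- attr(predicted$tight, "pairs")[, c("seed", "gene")]
    tm_tab <- evidence$partners$table
    tm_pairs <- data.frame(gene1 = tm_tab$seed, gene2 = tm_tab$partner,
                           stringsAsFactors = FALSE)
    edges <- classify_edges(coexp_pairs, tm_pairs, consensus$consensus)
    net <- assemble_ncrg(seed_network, consensus$consensus, edges)
    circadian_genes <- rhythm$calls$gene[
      rhythm$calls$p <= min(config$rhythm_alphas)]
    annotate_nodes(net,
                   tf_targets = lapply(chip, `[[`, "targets"),
                   circadian = circadian_genes)
  })

  result <- structure(list(
    config = config, data = data, corr = corr, predicted = predicted,
    enrichment = enrich, evidence = evidence, consensus = consensus,
    chip = chip, rhythm = rhythm, network = network$network,
    report = network$report), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_tsv_base(result$predicted$tight, fp("candidates.tsv"))
  write_tsv_base(as.data.frame(result$predicted$pairs), fp("pairs.tsv"))
  for (ns in names(result$enrichment))
    write_tsv_base(result$enrichment[[ns]],
                   fp(sprintf("enrichment_%s.tsv", tolower(ns))))
  write_tsv_base(data.frame(gene = result$consensus$consensus),
                 fp("consensus_genes.tsv"))
  for (tf in names(result$chip))
    write_tsv_base(as.data.frame(result$chip[[tf]]$scores),
                   fp(sprintf("chip_scores_%s.tsv", tf)))
  write_tsv_base(result$rhythm$calls, fp("rhythm_calls.tsv"))
  write_tsv_base(result$network$nodes, fp("network_nodes.tsv"))
  write_tsv_base(result$network$edges, fp("network_edges.tsv"))
  write_network_graphml(result$network, fp("network.graphml"))
  write_network_sif(result$network, fp("network.sif"))
  write_tsv_base(result$report, fp("report.tsv"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "circanet",
    package_version = as.character(utils::packageVersion("circanet")),
    r_version = R.version.string,
    rng_seed = result$config$rng_seed,
    parameters = unclass(result$config)[c(
      "K", "min_tightness", "n_top_partners", "max_sentences",
      "q_threshold", "chip_log2_threshold", "rhythm_alphas")],
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result: %d predicted coexpression genes, ",
                     "%d textmining genes, %d consensus; network %d nodes>\n"),
              length(x$predicted$genes), length(x$evidence$genes),
              x$consensus$n_consensus, nrow(x$network$nodes)))
  invisible(x)
}

#' Score pipeline recovery against the planted truth
#'
#' Precision and recall of the consensus gene set against the planted target
#' genes, plus per-factor ChIP-seq calling recall and false-call rate.
#'
#' @param result A `pipeline_result` from a synthetic run.
#' @param truth The `synthetic_truth` (defaults to the one in the result).
#' @return List with `precision`, `recall`, and `chip` (data frame `tf`,
#'   `recall`, `false_call_rate`).
#' @export
evaluate_recovery <- function(result, truth = result$data$truth) {
  if (is.null(truth)) stopf("no truth available")
  true_targets <- unique(truth$true_edges$target)
  cons <- result$consensus$consensus
  tp <- length(intersect(cons, true_targets))
  chip <- do.call(rbind, lapply(names(result$chip), function(tf) {
    called <- result$chip[[tf]]$targets
    tt <- truth$true_tf_targets[[tf]]
    data.frame(tf = tf,
               recall = length(intersect(called, tt)) / length(tt),
               false_call_rate = if (length(called))
                 length(setdiff(called, tt)) / length(called) else 0,
               stringsAsFactors = FALSE)
  }))
  list(precision = if (length(cons)) tp / length(cons) else NA_real_,
       recall = tp / length(true_targets),
       chip = chip)
}
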