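#' Default clock-gene parameters for the generator
#'
#' Assigns every seed-network gene a cosine amplitude and peak phase (hours).
#' Family phases follow the canonical oscillator geometry: PER peaks 9 h
#' before BMAL (so their profiles anti-correlate), CRY peaks shortly after
#' PER (positive PER-CRY correlation), and REV-ERB peaks 7 h before ROR.
#' Remaining curated-extension genes get phases spread evenly over the day.
#'
#' @param seed A `seed_network`; defaults to the packaged fixture.
#' @param amplitude Common cosine amplitude in expression units.
#' @return Data frame with columns `gene`, `amplitude`, `phase`.
#' @export
default_clock_genes <- function(seed = read_seed_network(), amplitude = 1) {
  genes <- seed$nodes$gene
  family_phase <- c(
    PER1 = 12, PER2 = 12, PER3 = 12, CRY1 = 13.5, CRY2 = 13.5,
    ARNTL = 21, ARNTL2 = 21, CLOCK = 21, NPAS2 = 21,
    NR1D1 = 5, NR1D2 = 5, RORA = 12, RORB = 12, RORC = 12)
  phase <- family_phase[genes]
  rest <- is.na(phase)
  # spread the remaining seed genes around the clock, deterministically
  phase[rest] <- (seq_len(sum(rest)) * 24 / sum(rest)) %% 24
  data.frame(gene = genes, amplitude = amplitude, phase = unname(phase),
             stringsAsFactors = FALSE)
}

#' Default planted seed-to-target edges
#'
#' Each planted target gene is driven by two seed genes (tightness 2 by
#' construction), cycling through the seed list so targets cover the whole
#' network.
#'
#' @param clock_genes Data frame from [default_clock_genes()].
#' @param n_targets Number of planted target genes (default 40).
#' @param effect Fraction of target variance driven by its seeds.
#' @return Data frame with columns `seed`, `target`, `effect`.
#' @export
default_planted_edges <- function(clock_genes, n_targets = 40, effect = 0.5) {
  sg <- clock_genes$gene
  do.call(rbind, lapply(seq_len(n_targets), function(i) {
    s1 <- sg[((2 * i - 2) %% length(sg)) + 1]
    s2 <- sg[((2 * i - 1) %% length(sg)) + 1]
    data.frame(seed = c(s1, s2), target = sprintf("T%03d", i),
               effect = effect, stringsAsFactors = FALSE)
  }))
}

#' Synthetic study configuration
#'
#' Fixes every parameter of the synthetic input generator. The defaults are
#' the package's reference study conditions: 200 unsynchronised samples, a
#' 43-gene seed clock module, 40 planted targets each driven by two seed
#' genes, unit-amplitude cosines with unit observation noise (attenuating
#' clock-pair correlations to about a third of their noiseless value), a 10%
#' false-positive rate in the literature table, and a 48 h two-hourly time
#' course.
#'
#' @param n_samples Number of compendium samples.
#' @param n_background_genes Independent background genes.
#' @param clock_genes Data frame `gene`, `amplitude`, `phase` (hours in
#'   `[0, 24)`).
#' @param planted_edges Data frame `seed`, `target`, `effect` (effect in
#'   `(0, 1)`: fraction of target variance driven by its seeds).
#' @param noise_sd Observation noise standard deviation (expression units).
#' @param literature_fp_rate Fraction of emitted literature pairs that are
#'   random non-edges, in `[0, 1]`.
#' @param rhythmic_fraction Fraction of planted targets that cycle in the
#'   time course (clock genes always cycle).
#' @param timepoints Time-course sampling times in hours, strictly
#'   increasing.
#' @param ts_noise_sd Time-course noise standard deviation.
#' @param n_tf_targets True targets per transcription factor for the peak
#'   generator.
#' @param rng_seed Integer seed; fixing it makes every generated artifact
#'   byte-identical.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 200,
                             n_background_genes = 1000,
                             clock_genes = default_clock_genes(),
                             planted_edges = default_planted_edges(clock_genes),
                             noise_sd = 1,
                             literature_fp_rate = 0.10,
                             rhythmic_fraction = 0.5,
                             timepoints = seq(0, 46, by = 2),
                             ts_noise_sd = 0.5,
                             n_tf_targets = 30,
                             rng_seed = 1L) {
  cfg <- structure(list(
    n_samples = n_samples, n_background_genes = n_background_genes,
    clock_genes = clock_genes, planted_edges = planted_edges,
    noise_sd = noise_sd, literature_fp_rate = literature_fp_rate,
    rhythmic_fraction = rhythmic_fraction, timepoints = timepoints,
    ts_noise_sd = ts_noise_sd, n_tf_targets = n_tf_targets,
    rng_seed = as.integer(rng_seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (!is_count(cfg$n_samples, min = 3)) stopf("n_samples must be >= 3")
  if (!is_count(cfg$n_background_genes, min = 0))
    stopf("n_background_genes must be a count")
  cg <- cfg$clock_genes
  if (anyDuplicated(cg$gene)) stopf("duplicate clock gene ids")
  if (any(cg$amplitude < 0)) stopf("amplitudes must be >= 0")
  if (any(cg$phase < 0 | cg$phase >= 24)) stopf("phases must be in [0, 24)")
  pe <- cfg$planted_edges
  if (nrow(pe)) {
    if (!all(pe$seed %in% cg$gene))
      stopf("planted edge seeds must be clock genes")
    if (any(pe$target %in% cg$gene))
      stopf("planted targets must not be clock genes")
    if (any(pe$effect <= 0 | pe$effect >= 1))
      stopf("effect sizes must be in (0, 1)")
    if (anyDuplicated(paste(pe$seed, pe$target)))
      stopf("duplicate planted edges")
  }
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (cfg$literature_fp_rate < 0 || cfg$literature_fp_rate > 1)
    stopf("literature_fp_rate must be in [0, 1]")
  if (cfg$rhythmic_fraction < 0 || cfg$rhythmic_fraction > 1)
    stopf("rhythmic_fraction must be in [0, 1]")
  if (any(diff(cfg$timepoints) <= 0))
    stopf("timepoints must be strictly increasing")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config: %d samples, %d clock genes, ",
                     "%d planted targets, %d background genes, seed %d>\n"),
              x$n_samples, nrow(x$clock_genes),
              length(unique(x$planted_edges$target)),
              x$n_background_genes, x$rng_seed))
  invisible(x)
}
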