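test_that("clock-pair correlations follow the phase-attenuation closed form", {
  two_gene_cfg <- function(dphi, noise, n = 2000) {
    synthetic_config(
      n_samples = n, n_background_genes = 0,
      clock_genes = data.frame(gene = c("ga", "gb"), amplitude = 1,
                               phase = c(0, dphi)),
      planted_edges = data.frame(seed = character(), target = character(),
                                 effect = numeric()),
      noise_sd = noise, rng_seed = 23L)
  }
  # noiseless identical phase -> correlation approaches 1
  gen0 <- generate_compendium(two_gene_cfg(0, 0))
  expect_gt(cor(gen0$compendium$values[1, ], gen0$compendium$values[2, ]),
            0.999)
  # antiphase with noise: expected rho = cos(pi)/(1 + 2*0.25) = -2/3
  gen12 <- generate_compendium(two_gene_cfg(12, 0.5))
  r <- cor(gen12$compendium$values[1, ], gen12$compendium$values[2, ])
  expect_lt(abs(r - (-2 / 3)), 0.05)
  # Monte-Carlo oracle computed independently of the generator
  set.seed(24)
  theta <- runif(5000, 0, 24)
  x <- cos(2 * pi * theta / 24) + rnorm(5000, sd = 0.5)
  y <- cos(2 * pi * (theta - 12) / 24) + rnorm(5000, sd = 0.5)
  expect_lt(abs(cor(x, y) - (-2 / 3)), 0.05)
})

test_that("clock-pair correlations converge at the 3/sqrt(n) rate", {
  cfg <- synthetic_config(n_samples = 2000, n_background_genes = 0,
                          rng_seed = 25L)
  gen <- generate_compendium(cfg)
  v <- gen$compendium$values
  cg <- cfg$clock_genes
  expected_rho <- function(g1, g2) {
    dphi <- cg$phase[cg$gene == g1] - cg$phase[cg$gene == g2]
    cos(2 * pi * dphi / 24) / (1 + 2 * cfg$noise_sd^2)
  }
  for (pair in list(c("PER1", "ARNTL"), c("PER2", "CRY2"),
                    c("NR1D1", "RORC"), c("CLOCK", "NPAS2"))) {
    r <- cor(v[pair[1], ], v[pair[2], ])
    expect_lt(abs(r - expected_rho(pair[1], pair[2])), 3 / sqrt(2000))
  }
})

test_that("the default phase geometry gives anti-correlated PER and BMAL", {
  gen <- generate_compendium(synthetic_config(rng_seed = 26L))
  v <- gen$compendium$values
  expect_lt(cor(v["ARNTL", ], v["PER3", ]), 0)   # 9 h apart
  expect_gt(cor(v["PER2", ], v["CRY2", ]), 0)    # near-synchronous
})

test_that("planted targets carry the configured seed-driven variance", {
  cfg <- tiny_config(seed = 27L)
  gen <- generate_compendium(cfg)
  v <- gen$compendium$values
  ed <- gen$truth$true_edges
  rhos <- mapply(function(s, t) abs(cor(v[s, ], v[t, ])), ed$seed, ed$target)
  expect_gt(median(rhos), 0.4)  # sqrt(e) * sqrt((1+rho12)/2) with e = 0.5
  expect_error(generate_compendium(
    synthetic_config(n_samples = 2)), "n_samples")
})

test_that("literature tables honor the false-positive rate", {
  cfg0 <- tiny_config(seed = 28L, literature_fp_rate = 0)
  gen <- generate_compendium(cfg0)
  lit0 <- generate_literature_table(gen$truth, cfg0)
  true_keys <- pair_key_test(as.matrix(gen$truth$true_edges))
  expect_true(all(pair_key_test(cbind(lit0$gene1, lit0$gene2)) %in% true_keys))

  # larger truth so the emitted pair count supports a tight check
  cg <- default_clock_genes()
  big <- synthetic_config(
    n_samples = 10, n_background_genes = 2000,
    clock_genes = cg,
    planted_edges = default_planted_edges(cg, n_targets = 450),
    literature_fp_rate = 0.10, rng_seed = 29L)
  genb <- generate_compendium(big)
  lit <- generate_literature_table(genb$truth, big)
  pairs <- unique(cbind(lit$gene1, lit$gene2))
  is_fp <- !(pair_key_test(pairs) %in%
               pair_key_test(as.matrix(genb$truth$true_edges)))
  n <- nrow(pairs)
  ci <- stats::binom.test(round(0.10 * n), n)$conf.int
  expect_gte(mean(is_fp), ci[1])
  expect_lte(mean(is_fp), ci[2])
  # heavy-tailed support: mean sentence count above the median
  counts <- table(pair_key_test(cbind(lit$gene1, lit$gene2)))
  expect_gt(mean(counts), stats::median(counts))
})

test_that("planted peaks recover the true TF targets", {
  cfg <- tiny_config(seed = 30L)
  gen <- generate_compendium(cfg)
  gm <- generate_gene_models(gen$truth)
  # zero background: every true target called, nothing else scores high
  peaks0 <- generate_peaks(gen$truth, gm, cfg, n_background_peaks = 0)
  for (tf in names(peaks0)) {
    called <- call_targets(closest_gene_scores(peaks0[[tf]], gm), 3)
    expect_true(all(gen$truth$true_tf_targets[[tf]] %in% called))
  }
  # halving all weights halves every gene score (linearity)
  pk <- peaks0[[1]]
  half <- pk; half$weight <- pk$weight / 2
  s1 <- closest_gene_scores(pk, gm)
  s2 <- closest_gene_scores(peak_set(half), gm)
  expect_equal(s2$score, s1$score / 2, tolerance = 1e-12)
})

test_that("gene scores are bimodal on the log2 scale with background peaks", {
  cfg <- tiny_config(seed = 31L)
  gen <- generate_compendium(cfg)
  gm <- generate_gene_models(gen$truth)
  peaks <- generate_peaks(gen$truth, gm, cfg, n_background_peaks = 200)
  sc <- closest_gene_scores(peaks[[1]], gm)
  x <- log2(sc$score[sc$score > 0])
  lo <- mean(x < 2); mid <- mean(x >= 2 & x < 3.5); hi <- mean(x >= 3.5)
  expect_gt(lo, mid)
  expect_gt(hi, mid)
})

test_that("time courses expose truth rhythm and an underpowered warning", {
  cfg <- tiny_config(seed = 32L, ts_noise_sd = 1e-9)
  gen <- generate_compendium(cfg)
  ts <- generate_timeseries(gen$truth, cfg)
  rhythmic <- gen$truth$true_rhythmic
  calls <- jtk_scan(ts[rhythmic$gene[1:5], ], periods = c(20, 24, 28),
                    null_draws = 200)
  expect_equal(calls$period, rhythmic$period[1:5])
  # true phases need not sit on the reference grid, so tau is near but not
  # necessarily exactly 1
  expect_true(all(calls$tau > 0.85))
  short <- tiny_config(seed = 32L, timepoints = seq(0, 24, by = 6))
  expect_warning(generate_timeseries(gen$truth, short), "underpowered")
})

test_that("planted annotation terms come out enriched, random terms do not", {
  cfg <- tiny_config(seed = 33L)
  gen <- generate_compendium(cfg)
  catalog <- generate_annotations(gen$truth, cfg)
  expect_setequal(names(catalog$namespaces), c("BP", "PW"))
  targets <- unique(gen$truth$true_edges$target)
  res <- overrepresentation(targets, catalog, "BP")
  expect_lt(res$q[res$term == "planted_target_program"], 0.01)
  # a term disjoint from the query stays at p ~ 1
  disjoint <- res[res$significant == 0, ]
  if (nrow(disjoint)) expect_true(all(disjoint$p == 1))
  # GMT round trip
  path <- tempfile(fileext = ".gmt")
  write_gmt(catalog$namespaces$BP, path)
  expect_equal(read_gmt(path)[], catalog$namespaces$BP[],
               ignore_attr = TRUE)
})

test_that("a fixed seed makes every written artifact byte-identical", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  p1 <- write_synthetic_inputs(tiny_config(seed = 34L), d1)
  p2 <- write_synthetic_inputs(tiny_config(seed = 34L), d2)
  p3 <- write_synthetic_inputs(tiny_config(seed = 35L), d3)
  md5 <- function(paths) unname(tools::md5sum(unlist(paths)))
  expect_equal(md5(p1), md5(p2))
  expect_false(all(md5(p1) == md5(p3)))
  expect_true(all(file.size(unlist(p1)) > 0))
})
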