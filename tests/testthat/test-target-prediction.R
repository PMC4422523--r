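toy_corr <- function() {
  # 3 seeds x 5 candidates with fixed correlations
  genes <- c("E1", "E2", "E3", "c1", "c2", "c3", "c4", "c5")
  rho <- diag(1, 8)
  dimnames(rho) <- list(genes, genes)
  vals <- rbind(
    c(0.90, -0.85, 0.40, 0.10, 0.05),
    c(0.70,  0.20, 0.60, 0.30, 0.02),
    c(0.10,  0.15, 0.25, 0.80, 0.01))
  for (i in 1:3) for (j in 1:5) {
    rho[i, j + 3] <- vals[i, j]
    rho[j + 3, i] <- vals[i, j]
  }
  rho
}

test_that("select_top_pairs returns the K largest |rho| seed pairs", {
  rho <- toy_corr()
  seeds <- c("E1", "E2", "E3")
  pairs <- select_top_pairs(rho, seeds, K = 4)
  # exhaustive sort oracle over all 15 seed x candidate values
  all_vals <- expand.grid(seed = seeds, gene = paste0("c", 1:5),
                          stringsAsFactors = FALSE)
  all_vals$rho <- rho[cbind(all_vals$seed, all_vals$gene)]
  expected <- all_vals[order(-abs(all_vals$rho)), ][1:4, ]
  expect_setequal(paste(pairs$seed, pairs$gene),
                  paste(expected$seed, expected$gene))
  expect_equal(nrow(pairs), 4)
  rep <- attr(pairs, "report")
  expect_equal(rep$implied_cutoff, min(abs(expected$rho)))
})

test_that("K beyond the pair universe returns everything with a warning", {
  rho <- toy_corr()
  expect_warning(pairs <- select_top_pairs(rho, c("E1", "E2", "E3"), K = 100),
                 "returning all")
  expect_equal(nrow(pairs), 15)
  expect_equal(attr(pairs, "report")$implied_cutoff, min(abs(pairs$rho)))
})

test_that("boundary ties are all retained", {
  genes <- c("E1", "a", "b", "c")
  rho <- diag(1, 4); dimnames(rho) <- list(genes, genes)
  rho["E1", c("a", "b", "c")] <- c(0.9, 0.5, 0.5)
  rho[c("a", "b", "c"), "E1"] <- c(0.9, 0.5, 0.5)
  expect_message(pairs <- select_top_pairs(rho, "E1", K = 2), "tie")
  expect_equal(nrow(pairs), 3)
})

test_that("selection is invariant to gene order and report self-consistent", {
  rho <- toy_corr()
  perm <- sample(nrow(rho))
  p1 <- select_top_pairs(rho, c("E1", "E2", "E3"), K = 6)
  p2 <- select_top_pairs(rho[perm, perm], c("E1", "E2", "E3"), K = 6)
  expect_setequal(paste(p1$seed, p1$gene), paste(p2$seed, p2$gene))
  rep <- attr(p1, "report")
  expect_equal(round(rep$fraction, 2),
               round(100 * rep$K / (rep$n_seed_genes * rep$n_universe_genes), 2))
})

test_that("signed ranking mode differs from absolute on anti-correlations", {
  rho <- toy_corr()
  abs_pairs <- select_top_pairs(rho, c("E1", "E2", "E3"), K = 3)
  sgn_pairs <- select_top_pairs(rho, c("E1", "E2", "E3"), K = 3,
                                ranking = "signed")
  expect_true("c2" %in% abs_pairs$gene[abs_pairs$seed == "E1"])  # rho -0.85
  expect_false("c2" %in% sgn_pairs$gene[sgn_pairs$seed == "E1"])
})

test_that("tightness counts distinct seed partners with set semantics", {
  pairs <- data.frame(seed = c("E1", "E2", "E1", "E1"),
                      gene = c("g", "g", "h", "g"))
  cand <- compute_tightness(pairs)
  expect_equal(cand$tightness[cand$gene == "g"], 2)  # duplicate (E1,g) ignored
  expect_equal(cand$tightness[cand$gene == "h"], 1)
  expect_equal(nrow(compute_tightness(pairs[0, ])), 0)
  # seed-seed pairs excluded with a message
  pairs2 <- rbind(pairs, data.frame(seed = "E1", gene = "E2"))
  expect_message(cand2 <- compute_tightness(pairs2, seed = c("E1", "E2")),
                 "excluded")
  expect_false("E2" %in% cand2$gene)
  # conservation: sum of tightness = number of distinct pairs
  expect_equal(sum(cand$tightness), 3)
})

test_that("tightness filtering nests and min_t = 1 is the identity", {
  set.seed(7)
  for (case in 1:5) {
    pairs <- data.frame(seed = sample(paste0("E", 1:6), 60, replace = TRUE),
                        gene = sample(paste0("g", 1:25), 60, replace = TRUE))
    cand <- compute_tightness(pairs)
    expect_equal(filter_tightness(cand, 1)$gene, cand$gene)
    for (t in 1:4) {
      hi <- filter_tightness(cand, t + 1)$gene
      lo <- filter_tightness(cand, t)$gene
      expect_true(all(hi %in% lo))
    }
  }
})

test_that("tightness sweep counts are non-increasing and q matches direct calls", {
  set.seed(8)
  pairs <- data.frame(seed = sample(paste0("E", 1:6), 80, replace = TRUE),
                      gene = sample(paste0("g", 1:30), 80, replace = TRUE))
  cand <- compute_tightness(pairs)
  universe <- paste0("g", 1:30)
  term <- paste0("g", 1:8)
  catalog <- annotation_catalog(list(NS = list(tm = term)),
                                universes = list(NS = universe))
  cb <- function(genes) {
    r <- overrepresentation(genes, catalog, "NS")
    data.frame(term = r$term, q = r$q)
  }
  sw <- tightness_sweep(cand, cb, t_range = 1:5)
  expect_true(all(diff(sw$counts$n_candidates) <= 0))
  for (t in 1:5) {
    genes <- filter_tightness(cand, t)$gene
    if (!length(genes)) next
    expect_equal(sw$trajectories$q[sw$trajectories$min_tightness == t],
                 cb(genes)$q)
  }
})

test_that("the candidate count drops hardest between tightness 1 and 2", {
  cfg <- synthetic_config(rng_seed = 12)
  gen <- generate_compendium(cfg)
  rho <- pearson_matrix(gen$compendium)
  seed <- read_seed_network()
  K <- fraction_K(43, length(gen$truth$genes))
  pairs <- select_top_pairs(rho, seed, K = K)
  cand <- compute_tightness(pairs, seed = seed)
  sw <- tightness_sweep(cand, t_range = 1:3)
  drops <- -diff(sw$counts$n_candidates)
  expect_gt(drops[1], drops[2])
})

test_that("the packaged seed network has the documented shape", {
  seed <- read_seed_network()
  expect_equal(nrow(seed$nodes), 43)
  expect_equal(sum(seed$nodes$layer == "CCN"), 14)
  expect_true(all(c(seed$edges$gene1, seed$edges$gene2) %in% seed$nodes$gene))
})
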