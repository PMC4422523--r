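toy_genes <- function() {
  gene_models(data.frame(gene = c("A", "B"), chrom = "chr1",
                         tss = c(1000L, 5000L), strand = "+"))
}

test_that("peaks are assigned to the nearest TSS and weights summed", {
  peaks <- peak_set(data.frame(chrom = "chr1",
                               start = c(1100L, 4000L),
                               end = c(1200L, 4100L),
                               weight = c(4, 6)))
  sc <- closest_gene_scores(peaks, toy_genes())
  expect_equal(sc$score[sc$gene == "A"], 4)  # midpoint 1150 nearest A
  expect_equal(sc$score[sc$gene == "B"], 6)  # midpoint 4050 nearest B
  expect_equal(sum(sc$score), sum(peaks$weight))
  expect_equal(attr(sc, "n_gene"), 2L)
})

test_that("no peaks gives all-zero scores", {
  sc <- closest_gene_scores(peak_set(data.frame(
    chrom = character(), start = integer(), end = integer(),
    weight = numeric())), toy_genes())
  expect_equal(sc$score, c(0, 0))
})

test_that("target calling applies the log2 threshold inclusively", {
  sc <- data.frame(gene = c("A", "B", "C"), score = c(8, 4, 6))
  expect_equal(call_targets(sc, 3), "A")          # log2(8) = 3 exactly
  expect_equal(call_targets(sc, 1), c("A", "B", "C"))
  expect_equal(call_targets(sc, -Inf), c("A", "B", "C"))
  sc0 <- data.frame(gene = "Z", score = 0)
  expect_length(call_targets(sc0, -Inf), 0)       # zero never called
})

test_that("score conservation and order invariance hold on random inputs", {
  set.seed(15)
  genes <- gene_models(data.frame(
    gene = sprintf("G%02d", 1:30),
    chrom = rep(c("chr1", "chr2"), 15),
    tss = sample(1000:200000, 30), strand = "+"))
  centers <- sample(1000:200000, 100)
  peaks <- peak_set(data.frame(
    chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
    start = centers, end = centers + 200L,
    weight = runif(100, 0.5, 10)))
  sc <- closest_gene_scores(peaks, genes)
  expect_equal(sum(sc$score), sum(peaks$weight), tolerance = 1e-9)
  perm <- peaks[sample(nrow(peaks)), ]
  expect_equal(closest_gene_scores(peak_set(perm), genes)$score, sc$score)
  # doubling weights shifts every positive log2 score by exactly 1
  peaks2 <- peaks; peaks2$weight <- 2 * peaks$weight
  sc2 <- closest_gene_scores(peak_set(peaks2), genes)
  pos <- sc$score > 0
  expect_equal(log2(sc2$score[pos]) - log2(sc$score[pos]),
               rep(1, sum(pos)), tolerance = 1e-12)
})

test_that("equidistant peaks go to the lexically smaller gene id", {
  genes <- gene_models(data.frame(gene = c("Zed", "Abe"), chrom = "chr1",
                                  tss = c(1000L, 3000L), strand = "+"))
  peaks <- peak_set(data.frame(chrom = "chr1", start = 1900L, end = 2100L,
                               weight = 5))
  sc <- closest_gene_scores(peaks, genes)  # midpoint 2000 equidistant
  expect_equal(sc$score[sc$gene == "Abe"], 5)
  expect_equal(sc$score[sc$gene == "Zed"], 0)
})

test_that("peaks on unknown chromosomes are counted as unassigned", {
  peaks <- peak_set(data.frame(chrom = c("chr1", "chrX"),
                               start = c(900L, 100L), end = c(1100L, 300L),
                               weight = c(2, 7)))
  expect_message(sc <- closest_gene_scores(peaks, toy_genes()),
                 "without gene models")
  expect_equal(attr(sc, "n_unassigned"), 1L)
  expect_equal(sum(sc$score), 2)
})

test_that("narrowPeak files round-trip with summit and signal honored", {
  peaks <- peak_set(data.frame(chrom = "chr1", start = c(100L, 500L),
                               end = c(400L, 900L), weight = c(3.5, 1.25),
                               pos = c(150L, 700L)))
  path <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(peaks, path)
  back <- read_narrowpeak(path)
  expect_equal(back$weight, peaks$weight)
  expect_equal(back$pos, peaks$pos)
  # BED3 input defaults to weight 1 and midpoint anchor
  bed3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t400", bed3)
  b <- read_narrowpeak(bed3)
  expect_equal(b$weight, 1)
  expect_equal(b$pos, 250)
})

test_that("gene models read from BED and minimal GTF with strand-aware TSS", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t900\tfw\t0\t+", "chr1\t2000\t2600\trv\t0\t-"), bed)
  gm <- read_gene_models(bed)
  expect_equal(gm$tss[gm$gene == "fw"], 100L)
  expect_equal(gm$tss[gm$gene == "rv"], 2599L)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t900\t.\t+\t.\tgene_id "fw";',
    'chr1\tsrc\tgene\t2001\t2600\t.\t-\t.\tgene_id "rv";'), gtf)
  gg <- read_gene_models(gtf, format = "gtf")
  expect_equal(gg$tss, gm$tss)
})

test_that("threshold suggestion lands in the valley of a bimodal mixture", {
  w <- c(0.6, 0.4); mu <- c(1, 4); sd_ <- c(0.5, 0.5)
  dens <- function(x) w[1] * dnorm(x, mu[1], sd_[1]) +
    w[2] * dnorm(x, mu[2], sd_[2])
  grid <- seq(mu[1], mu[2], length.out = 2000)
  analytic_valley <- grid[which.min(dens(grid))]
  errs <- vapply(1:20, function(s) {
    set.seed(400 + s)
    comp <- sample(1:2, 400, replace = TRUE, prob = w)
    x <- rnorm(400, mu[comp], sd_[comp])
    sug <- threshold_suggest(data.frame(gene = seq_along(x), score = 2^x))
    expect_false(sug$fallback)
    abs(sug$suggestion - analytic_valley)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
  expect_lt(max(errs), 1)
})

test_that("unimodal scores trigger the flagged fallback rule", {
  set.seed(16)
  x <- rnorm(300, 2, 0.7)
  sug <- threshold_suggest(data.frame(gene = seq_along(x), score = 2^x))
  expect_true(sug$fallback)
  expect_equal(sug$suggestion, mean(x) + sd(x), tolerance = 1e-9)
})

test_that("suggestion shifts with a global weight scaling", {
  set.seed(17)
  comp <- sample(1:2, 500, replace = TRUE)
  x <- rnorm(500, c(1, 4)[comp], 0.4)
  s1 <- threshold_suggest(data.frame(gene = seq_along(x), score = 2^x))
  s2 <- threshold_suggest(data.frame(gene = seq_along(x), score = 4 * 2^x))
  expect_equal(s2$suggestion - s1$suggestion, 2, tolerance = 0.1)
})

test_that("too few positive scores yields diagnostics but no suggestion", {
  expect_message(sug <- threshold_suggest(
    data.frame(gene = 1:10, score = c(rep(0, 5), 2^(1:5)))), "no suggestion")
  expect_true(is.na(sug$suggestion))
  expect_s3_class(sug$histogram, "histogram")
})
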