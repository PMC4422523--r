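test_that("evidence intersection is a plain set intersection with logging", {
  expect_message(res <- intersect_evidence(c("a", "b", "c"), c("b", "c", "d")),
                 "3 coexpression, 3 textmining -> 2 consensus")
  expect_equal(res$consensus, c("b", "c"))
  expect_warning(expect_message(empty <- intersect_evidence("a", "b")),
                 "empty consensus")
  expect_length(empty$consensus, 0)
})

test_that("edge provenance partitions evidence edges touching the consensus", {
  cx <- data.frame(g1 = c("E1", "E1", "E2"), g2 = c("a", "b", "a"))
  tm <- data.frame(g1 = c("a", "b", "E2"), g2 = c("E1", "E1", "c"))
  suppressMessages({
    ed <- classify_edges(cx, tm, consensus = c("a", "b", "c"))
  })
  counts <- attr(ed, "counts")
  expect_equal(unname(counts), c(2L, 1L, 1L))  # both, coexp-only, textmine-only
  expect_equal(sum(counts), nrow(ed))
  # identical pair sets -> all both; disjoint -> none
  suppressMessages({
    same <- classify_edges(cx, cx, consensus = c("a", "b"))
    expect_true(all(same$provenance == "both"))
    disj <- classify_edges(cx, data.frame(g1 = "E9", g2 = "a"),
                           consensus = "a")
    expect_equal(sum(disj$provenance == "both"), 0L)
  })
})

test_that("the assembled network layers partition the node set", {
  seed <- read_seed_network()
  suppressMessages({
    empty_net <- assemble_ncrg(seed, character())
  })
  expect_equal(nrow(empty_net$nodes), 43)
  consensus <- sprintf("N%03d", 1:20)
  net <- assemble_ncrg(seed, consensus)
  expect_equal(nrow(net$nodes), 63)
  expect_equal(sort(unique(net$nodes$layer)), c("CCN", "ECCN", "NCRG"))
  expect_equal(sum(table(net$nodes$layer)), nrow(net$nodes))
  expect_false(anyDuplicated(net$nodes$gene) > 0)
  # consensus genes already in the seed are dropped from the extension layer
  expect_message(net2 <- assemble_ncrg(seed, c("PER1", consensus)),
                 "already in the seed")
  expect_equal(nrow(net2$nodes), 63)
  expect_equal(net2$nodes$layer[net2$nodes$gene == "PER1"], "CCN")
})

test_that("node annotation flags feed a report of flagged extension genes", {
  seed <- read_seed_network()
  net <- assemble_ncrg(seed, c("n1", "n2", "n3"))
  expect_message(ann <- annotate_nodes(
    net,
    tf_targets = list(TFA = c("n1", "nope")),
    circadian = c("n1", "n2"),
    rnai = data.frame(gene = "n2", phenotype = "long-T"),
    disease = data.frame(gene = "n1", annotation = "some syndrome"),
    ml_similar = "zzz"), "not in the network")
  rep <- ann$report
  expect_setequal(rep$gene, c("n1", "n2"))  # n3 carries no flag
  n1 <- rep[rep$gene == "n1", ]
  expect_true(n1$target_TFA && n1$circadian)
  expect_equal(rep$long_T[rep$gene == "n2"], TRUE)
  expect_false("n3" %in% rep$gene)
  # seed-layer genes never enter the report even when flagged
  ann2 <- suppressMessages(annotate_nodes(net, circadian = "PER1"))
  expect_equal(nrow(ann2$report), 0)
})

test_that("GraphML export round-trips nodes, layers and edge provenance", {
  seed <- read_seed_network()
  suppressMessages({
    edges <- classify_edges(data.frame(g1 = c("PER1", "CLOCK"),
                                       g2 = c("n1", "n2")),
                            data.frame(g1 = "PER1", g2 = "n1"),
                            consensus = c("n1", "n2"))
  })
  net <- assemble_ncrg(seed, c("n1", "n2"), edges)
  ann <- suppressMessages(annotate_nodes(net, circadian = "n1"))
  path <- tempfile(fileext = ".graphml")
  write_network_graphml(ann$network, path)
  back <- read_network_graphml(path)
  expect_setequal(back$nodes$gene, ann$network$nodes$gene)
  m <- match(ann$network$nodes$gene, back$nodes$gene)
  expect_equal(back$nodes$layer[m], ann$network$nodes$layer)
  expect_equal(back$nodes$circadian[m], ann$network$nodes$circadian)
  expect_equal(sort(back$edges$provenance),
               sort(ann$network$edges$provenance))
  sif <- tempfile(fileext = ".sif")
  write_network_sif(ann$network, sif)
  expect_equal(length(readLines(sif)), nrow(ann$network$edges))
})

test_that("the consensus annotation fixture parses into annotation inputs", {
  ann <- read_consensus_annotations()
  expect_equal(nrow(ann$table), 77)
  expect_setequal(names(ann$tf_targets),
                  c("REV-ERBa", "REV-ERBb", "REV-ERBab", "RORa", "RORg",
                    "RORag", "BMAL1"))
  expect_true(all(ann$rnai$phenotype %in% c("high-A", "long-T", "short-T")))
  expect_true(all(unlist(ann$tf_targets) %in% ann$table$symbol))
})
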