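test_that("typed edge lists parse into validated networks", {
  path <- write_tmp(c("A\tB\tTF_gene", "A\tm1\tTF_miRNA", "m1\tB\tmiRNA_gene"))
  net <- read_network(path)
  expect_equal(n_nodes(net), 3)
  expect_equal(nrow(net$edges), 3)
  kinds <- setNames(net$nodes$kind, net$nodes$id)
  expect_equal(kinds[["A"]], "TF")
  expect_equal(kinds[["B"]], "gene")
  expect_equal(kinds[["m1"]], "miRNA")

  # duplicated rows collapse to the identical network
  path2 <- write_tmp(c("A\tB\tTF_gene", "A\tB\tTF_gene",
                       "A\tm1\tTF_miRNA", "m1\tB\tmiRNA_gene"))
  expect_identical(read_network(path2), net)

  # SIF dialect carries the type in the middle column
  sif <- write_tmp(c("A\tTF_gene\tB", "A\tTF_miRNA\tm1", "m1\tmiRNA_gene\tB"))
  expect_identical(read_network(sif, dialect = "sif"), net)
})

test_that("contradictory kind implications are a validation error", {
  # X is a miRNA (source of miRNA_gene) and a TF (source of TF_gene)
  path <- write_tmp(c("X\tG1\tmiRNA_gene", "X\tG2\tTF_gene"))
  expect_error(read_network(path), "contradictory")
})

test_that("malformed rows are reported with their line number", {
  path <- write_tmp(c("A\tB\tTF_gene", "brokenrow"))
  expect_error(read_network(path), "line 2")
  bad_type <- write_tmp(c("A\tB\tTF_gene", "A\tC\tactivates"))
  expect_error(read_network(bad_type), "line 2")
})

test_that("node kinds partition the node set", {
  net <- generate_toy_paper_network()
  expect_equal(sum(net$nodes$kind == "TF") + sum(net$nodes$kind == "gene") +
               sum(net$nodes$kind == "miRNA"), n_nodes(net))
  expect_false(anyDuplicated(net$nodes$id) > 0)
})

test_that("write/read round-trip and row order do not change the network", {
  net <- generate_toy_paper_network()
  path <- tempfile()
  write_network(net, path)
  expect_identical(read_network(path), net)

  # permuted rows give an identical network
  lines <- readLines(path)
  set.seed(7)
  path2 <- write_tmp(sample(lines))
  expect_identical(read_network(path2), net)

  # sif round-trip too
  write_network(net, path, dialect = "sif")
  expect_identical(read_network(path, dialect = "sif"), net)
})

test_that("expression tables parse values, absent LFC, and reject bad input", {
  path <- write_tmp(c("id\tlfc\tpadj", "E2F1\t3.76\t0.001",
                      "hsa-let-7b\t\t0.0005"))
  tab <- read_expression_table(path)
  expect_equal(tab$lfc[tab$id == "E2F1"], 3.76)
  expect_true(is.na(tab$lfc[tab$id == "hsa-let-7b"]))
  expect_equal(tab$padj[tab$id == "hsa-let-7b"], 5e-4)

  empty <- read_expression_table(write_tmp("id\tlfc\tpadj"))
  expect_equal(nrow(empty), 0)

  expect_error(read_expression_table(
    write_tmp(c("id\tlfc\tpadj", "A\t1\t0.1", "A\t2\t0.2"))), "duplicate")
  expect_error(read_expression_table(
    write_tmp(c("id\tlfc\tpadj", "A\t1\tlow"))), "padj")
})

test_that("annotation lists are trimmed, deduplicated and comment-aware", {
  ann <- read_annotation(write_tmp(c("FOS", "ESR1", "JUN")), "hcc")
  expect_equal(ann$members, c("ESR1", "FOS", "JUN"))
  expect_equal(ann$disease_name, "hcc")

  messy <- read_annotation(write_tmp(
    c("# disease genes", "FOS ", "", "FOS", "JUN # curated", "  ")), "x")
  expect_equal(messy$members, c("FOS", "JUN"))

  expect_warning(empty <- read_annotation(write_tmp("# nothing"), "x"),
                 "empty")
  expect_length(empty$members, 0)
})

test_that("priority tables are written in the canonical column layout", {
  tab <- structure(data.frame(
    node = c("E2F1", "hsa-let-7b"), kind = c("TF", "miRNA"),
    degree = c(25L, 47L), hub = c(1L, 1L), mds = c(1L, 1L),
    mcds = c(1L, 1L), score = c(3L, 3L), lfc = c(3.76, NA),
    layer = c(5L, 5L), rank = c(1L, 2L), stringsAsFactors = FALSE),
    class = c("priority_table", "data.frame"))
  path <- tempfile()
  write_priority_table(tab, path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_equal(lines[1], "gene\tD\thub\tmds\tmcds\tscore\tLFC\tlayer\trank")
  expect_equal(lines[2], "E2F1\t25\t1\t1\t1\t3\t3.76\t5\t1")
  expect_equal(lines[3], paste0("hsa-let-7b\t47\t1\t1\t1\t3\t", "\u2014", "\t5\t2"))

  write_priority_table(tab[0, ], path)
  expect_equal(readLines(path), lines[1])
})
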