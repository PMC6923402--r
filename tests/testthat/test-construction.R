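test_that("DE filtering is strict at the threshold", {
  tab <- expression_table(c("a", "b", "c"), c(1, 2, 3), c(0.01, 0.05, 0.049))
  expect_equal(filter_de_genes(tab, 0.05)$members, c("a", "c"))
  expect_length(filter_de_genes(tab, 0.01)$members, 0)
  expect_error(filter_de_genes(tab, 0), "alpha")
})

# catalog with a 100-node gene/TF universe: hub TF -> G001..G099
enrichment_catalog <- function(extra_edges = NULL) {
  genes <- sprintf("G%03d", 1:99)
  edges <- data.frame(source = "TFU", target = genes, type = "TF_gene",
                      stringsAsFactors = FALSE)
  if (!is.null(extra_edges)) edges <- rbind(edges, extra_edges)
  regulatory_network(edges)
}

test_that("miRNA enrichment reproduces the closed-form hypergeometric tail", {
  # miRNA m targets 5 genes, all DE; universe 100 with 10 DE
  cat5 <- enrichment_catalog(data.frame(
    source = "hsa-mir-1", target = sprintf("G%03d", 1:5),
    type = "miRNA_gene", stringsAsFactors = FALSE))
  de <- sprintf("G%03d", 1:10)
  res <- enrich_mirnas(cat5, de)
  expect_equal(res$raw_p, choose(10, 5) * choose(90, 0) / choose(100, 5))
  expect_equal(res$overlap, 5)
  expect_equal(res$partners, 5)

  # zero overlap: inclusive upper tail P(X >= 0) = 1
  cat0 <- enrichment_catalog(data.frame(
    source = "hsa-mir-1", target = sprintf("G%03d", 90:94),
    type = "miRNA_gene", stringsAsFactors = FALSE))
  expect_equal(enrich_mirnas(cat0, de)$raw_p, 1)

  # identical partner sets give identical raw and adjusted p
  cat2 <- enrichment_catalog(data.frame(
    source = rep(c("hsa-mir-1", "hsa-mir-2"), each = 5),
    target = rep(sprintf("G%03d", 1:5), 2),
    type = "miRNA_gene", stringsAsFactors = FALSE))
  res2 <- enrich_mirnas(cat2, de)
  expect_equal(res2$raw_p[1], res2$raw_p[2])
  expect_equal(res2$adj_p[1], res2$adj_p[2])
})

test_that("partner sets pool targets and TF regulators; separate mode needs both", {
  edges <- rbind(
    data.frame(source = "hsa-mir-1", target = sprintf("G%03d", 1:4),
               type = "miRNA_gene"),
    data.frame(source = "TFU", target = "hsa-mir-1", type = "TF_miRNA"))
  catalog <- enrichment_catalog(edges)
  de <- c(sprintf("G%03d", 1:9), "TFU")
  res <- enrich_mirnas(catalog, de)
  expect_equal(res$partners, 5)  # 4 targets + 1 regulator
  expect_equal(res$overlap, 5)

  sep <- enrich_mirnas(catalog, de, mode = "separate")
  expect_equal(sep$partners, 5)
  # the single-regulator test alone is weak, so the joint max p is larger
  expect_gte(sep$raw_p, res$raw_p)
})

test_that("enrichment with no DE overlap selects nothing", {
  cat0 <- enrichment_catalog(data.frame(
    source = "hsa-mir-1", target = sprintf("G%03d", 1:5),
    type = "miRNA_gene", stringsAsFactors = FALSE))
  res <- enrich_mirnas(cat0, character(0))
  expect_equal(res$raw_p, 1)
  expect_false(any(res$selected))
})

test_that("differential network keeps only fully DE/selected edges", {
  catalog <- net_from_edges(c("A", "A"), c("B", "C"))
  net <- build_differential_network(catalog, c("A", "B"))
  expect_equal(node_ids(net), c("A", "B"))
  expect_equal(nrow(net$edges), 1)

  cat2 <- regulatory_network(data.frame(
    source = c("T", "m"), target = c("m", "G"),
    type = c("TF_miRNA", "miRNA_gene"), stringsAsFactors = FALSE))
  net2 <- build_differential_network(cat2, c("T", "G"), "m")
  expect_equal(n_nodes(net2), 3)
  expect_equal(nrow(net2$edges), 2)

  # nothing selected: no miRNA nodes or miRNA-typed edges survive
  expect_warning(
    net3 <- build_differential_network(cat2, c("T", "G"), character()),
    "empty")
  expect_equal(n_nodes(net3), 0)

  expect_warning(build_differential_network(catalog, character()), "empty")
})

test_that("enlarging the DE set never removes edges (monotonicity)", {
  set.seed(42)
  for (rep in 1:10) {
    syn <- generate_synthetic(synthetic_spec(
      n_tfs = 8, n_genes = 40, n_mirnas = 4, seed = rep))
    all_ids <- c(node_ids(syn$catalog, "TF"), node_ids(syn$catalog, "gene"))
    de_small <- syn$truth$de_members
    de_big <- union(de_small, sample(all_ids, 10))
    mirnas <- syn$truth$enriched_mirnas
    suppressWarnings({
      small <- build_differential_network(syn$catalog, de_small, mirnas)
      big <- build_differential_network(syn$catalog, de_big, mirnas)
    })
    expect_true(all(apply(small$edges, 1, paste, collapse = "|") %in%
                    apply(big$edges, 1, paste, collapse = "|")))
    # every retained edge has both endpoints in the node set; no isolates
    expect_true(all(c(big$edges$source, big$edges$target) %in%
                    big$nodes$id))
    expect_true(all(big$nodes$id %in%
                    c(big$edges$source, big$edges$target)))
  }
})
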