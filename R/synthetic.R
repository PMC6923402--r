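#' Specification for the synthetic-data generator
#'
#' Defines the simulated study conditions: a tripartite catalog of
#' experimentally-validated-style regulations with hub-skewed TF
#' out-degrees, an expression table with a planted DE fraction, miRNAs with
#' planted enriched partner sets, and a disease annotation overlapping the
#' high-score nodes at a configured rate.
#'
#' @param n_tfs,n_genes,n_mirnas node counts of the background catalog
#' @param attachment_exponent preferential-attachment strength: TF i is
#'   chosen as a regulator with probability proportional to
#'   \code{i^-attachment_exponent}, producing a right-skewed (scale-free
#'   like) out-degree distribution
#' @param de_fraction fraction of genes/TFs planted as differentially
#'   expressed, in (0, 1)
#' @param lfc_scale scale (mean) of the exponential draw for absolute log2
#'   fold changes of DE nodes
#' @param planted_disease_overlap fraction of the layer-4 (high-score)
#'   nodes annotated as disease-associated, in [0, 1]; the remaining
#'   network nodes are annotated at a 5\% background rate
#' @param seed integer seed; the same spec and seed reproduce byte-identical
#'   outputs
#' @return a list of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(n_tfs = 40, n_genes = 800, n_mirnas = 10,
                           attachment_exponent = 1.0, de_fraction = 0.30,
                           lfc_scale = 1.5, planted_disease_overlap = 0.25,
                           seed = 1L) {
  if (n_tfs < 1 || n_genes < 1 || n_mirnas < 0)
    stop("node counts must be positive")
  if (de_fraction <= 0 || de_fraction >= 1)
    stop("de_fraction must lie in (0, 1); planted enrichment needs DE genes")
  if (planted_disease_overlap < 0 || planted_disease_overlap > 1)
    stop("planted_disease_overlap must lie in [0, 1]")
  structure(list(n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 attachment_exponent = attachment_exponent,
                 de_fraction = de_fraction, lfc_scale = lfc_scale,
                 planted_disease_overlap = planted_disease_overlap,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run expr under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic catalog, expression table and annotation
#'
#' Emits the three inputs of the workflow together with their ground
#' truth. TF-to-gene regulations are drawn with preferential attachment on
#' the TF side, so a few TFs regulate many genes. DE nodes get adjusted
#' p-values uniform on (0, 0.05) and signed-exponential log2 fold changes;
#' non-DE nodes get p-values uniform on (0.05, 1) and small fold changes.
#' A planted subset of miRNAs receives partner sets drawn entirely from
#' the DE nodes and sized so that the exact hypergeometric p-value falls
#' well below the BH-adjusted 0.001 selection cutoff; the remaining miRNAs
#' draw partners uniformly. The disease annotation samples the planted
#' overlap fraction from the layer-4 nodes of the planted differential
#' network and a 5\% background from the remaining network nodes.
#'
#' @param spec a \code{\link{synthetic_spec}}
#' @return list with components \code{catalog}
#'   (\code{\link{regulatory_network}}), \code{expression}
#'   (\code{\link{expression_table}}), \code{annotation}
#'   (\code{\link{disease_annotation}}), and \code{truth}: list with
#'   \code{de_members}, \code{enriched_mirnas}, \code{planted_subnetwork},
#'   \code{annotated}
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_private_rng(spec$seed, {
    tfs <- sprintf("TF%02d", seq_len(spec$n_tfs))
    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    mirnas <- if (spec$n_mirnas > 0)
      sprintf("hsa-mir-%03d", seq_len(spec$n_mirnas)) else character()
    w <- seq_len(spec$n_tfs)^(-spec$attachment_exponent)

    # TF -> gene edges: each gene draws 1 + Pois(1.5) regulators,
    # preferentially the high-weight TFs
    reg_counts <- 1L + stats::rpois(spec$n_genes, 1.5)
    reg_counts <- pmin(reg_counts, spec$n_tfs)
    src <- character(0); tgt <- character(0)
    for (i in seq_len(spec$n_genes)) {
      picked <- sample(tfs, reg_counts[i], prob = w)
      src <- c(src, picked)
      tgt <- c(tgt, rep(genes[i], reg_counts[i]))
    }
    edges <- data.frame(source = src, target = tgt, type = "TF_gene",
                        stringsAsFactors = FALSE)

    # DE status over genes and TFs
    regulated <- c(tfs, genes)
    n_de <- round(spec$de_fraction * length(regulated))
    de_ids <- sort_c(sample(regulated, n_de))
    is_de <- regulated %in% de_ids
    padj <- ifelse(is_de, stats::runif(length(regulated), 0, 0.05),
                   stats::runif(length(regulated), 0.05, 1))
    lfc <- ifelse(is_de,
                  sample(c(-1, 1), length(regulated), replace = TRUE) *
                    stats::rexp(length(regulated), rate = 1 / spec$lfc_scale),
                  stats::rnorm(length(regulated), 0, 0.25))
    expression <- expression_table(regulated, lfc, padj)

    # miRNA partner sets; planted miRNAs draw only DE partners, sized so
    # the exact hypergeometric tail is < 1e-5 (comfortably under BH/0.001)
    n_planted <- if (spec$n_mirnas > 0) max(1L, round(0.4 * spec$n_mirnas)) else 0L
    planted <- mirnas[seq_len(n_planted)]
    N_u <- length(regulated); K_u <- n_de
    psize <- 1L
    while (psize < min(15L, K_u) &&
           hypergeom_upper_tail(psize, N_u, K_u, psize) >= 1e-5)
      psize <- psize + 1L
    for (m in mirnas) {
      partners <- if (m %in% planted) sample(de_ids, min(psize, n_de))
                  else sample(regulated, min(psize, length(regulated)))
      for (p in partners) {
        if (p %in% tfs) {
          edges <- rbind(edges, data.frame(source = p, target = m,
                                           type = "TF_miRNA"))
        } else {
          edges <- rbind(edges, data.frame(source = m, target = p,
                                           type = "miRNA_gene"))
        }
      }
    }
    catalog <- regulatory_network(edges)

    # planted differential subnetwork: the generator knows the memberships
    e <- catalog$edges
    keep <- ifelse(e$type == "TF_gene",
                   e$source %in% de_ids & e$target %in% de_ids,
            ifelse(e$type == "TF_miRNA",
                   e$source %in% de_ids & e$target %in% planted,
                   e$source %in% planted & e$target %in% de_ids))
    planted_net <- if (any(keep)) regulatory_network(e[keep, , drop = FALSE])
                   else regulatory_network(NULL)

    # annotation: enriched among the high-score (layer-4) nodes of the
    # planted network, with a 5% background rate elsewhere
    annotated <- character()
    if (n_nodes(planted_net) > 0) {
      hub_set <- hubs(planted_net, 0.10)
      mds_set <- compute_mds(planted_net, mode = "greedy")
      mcds_set <- compute_mcds(planted_net)
      layer4 <- sort_c(unique(c(hub_set$members, mds_set$members,
                              mcds_set$members)))
      rest <- setdiff(planted_net$nodes$id, layer4)
      n_l4 <- round(spec$planted_disease_overlap * length(layer4))
      n_bg <- round(0.05 * length(rest))
      annotated <- sort_c(c(
        if (n_l4 > 0) sample(layer4, n_l4) else character(),
        if (n_bg > 0) sample(rest, n_bg) else character()))
    }
    list(catalog = catalog,
         expression = expression,
         annotation = disease_annotation("synthetic", annotated),
         truth = list(de_members = de_ids,
                      enriched_mirnas = planted,
                      planted_subnetwork = planted_net,
                      annotated = annotated))
  })
}

#' Write the synthetic inputs of a generated study to a directory
#' @param syn result of \code{\link{generate_synthetic}}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_synthetic <- function(syn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(catalog = file.path(dir, "catalog.tsv"),
             expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.txt"))
  write_network(syn$catalog, paths[["catalog"]])
  write_expression_table(syn$expression, paths[["expression"]])
  writeLines(syn$annotation$members, paths[["annotation"]])
  invisible(paths)
}

#' Fixed toy co-regulatory network
#'
#' A hand-coded 20-node typed network (3 TFs, 14 genes, 3 miRNAs) used as
#' a regression fixture: small enough that hubs, the exact MDS and the
#' MCDS heuristic output can be frozen and re-checked. It is a synthetic
#' illustration, not data from any study.
#'
#' @return a \code{\link{regulatory_network}}
#' @export
generate_toy_paper_network <- function() {
  edges <- rbind(
    data.frame(source = "TFA",
               target = c("G01", "G02", "G03", "G04", "G05", "G06"),
               type = "TF_gene"),
    data.frame(source = "TFB",
               target = c("G04", "G07", "G08", "G09"), type = "TF_gene"),
    data.frame(source = "TFC",
               target = c("G09", "G10", "G11"), type = "TF_gene"),
    data.frame(source = c("TFA", "TFB", "TFC"),
               target = c("mirX", "mirX", "mirY"), type = "TF_miRNA"),
    data.frame(source = "mirX",
               target = c("G02", "G12", "G13"), type = "miRNA_gene"),
    data.frame(source = "mirY",
               target = c("G10", "G14"), type = "miRNA_gene"),
    data.frame(source = "mirZ",
               target = c("G13", "G14"), type = "miRNA_gene"))
  regulatory_network(edges)
}
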