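#' Prioritize candidate disease genes from network controllability
#'
#' Runs the full layered workflow in memory: (2) keep genes with adjusted
#' p-value strictly below \code{de_alpha}; (3) select miRNAs whose partner
#' sets are enriched among the DE genes (BH-adjusted hypergeometric test,
#' cutoff \code{mirna_cutoff}) and assemble the differential co-regulatory
#' network from the catalog; (4) compute hub-degree nodes (top
#' \code{hub_fraction} of degree), a minimum dominating set, and a minimum
#' connected dominating set of the largest connected component; (5) score
#' every network node by the number of roles it carries and rank by score,
#' then absolute log2 fold change. When an annotation is supplied, the
#' layer-4 candidates are evaluated against it over the network background.
#'
#' Supply either \code{catalog} + \code{expression} (the network is built),
#' or a pre-built \code{network} (construction is skipped; \code{expression}
#' is then only used for fold changes and layers 1-2).
#'
#' @param expression an \code{\link{expression_table}} (id, lfc, padj)
#' @param catalog a background \code{\link{regulatory_network}} of
#'   experimentally validated interactions
#' @param network optional pre-built differential co-regulatory network
#' @param annotation optional \code{\link{disease_annotation}}
#' @param de_alpha adjusted p-value cutoff for DE genes, default 0.05
#' @param mirna_cutoff BH-adjusted cutoff for miRNA enrichment, default 0.001
#' @param hub_fraction fraction of top-degree nodes called hubs, default 0.10
#' @param mds_mode \code{"auto"}, \code{"exact"} or \code{"greedy"} (see
#'   \code{\link{compute_mds}})
#' @param size_limit auto-mode crossover for the exact MDS solver
#' @return object of class \code{topcontrol}: list with components
#'   \code{network}, \code{de}, \code{enrichment}, \code{hubs}, \code{mds},
#'   \code{mcds}, \code{priority} (ranked \code{priority_table}),
#'   \code{evaluation} (\code{topcontrol_eval} or NULL), \code{config} and
#'   \code{counts}
#' @export
#' @examples
#' syn <- generate_synthetic(synthetic_spec(seed = 1))
#' fit <- topcontrol(syn$expression, syn$catalog, annotation = syn$annotation)
#' head(as.data.frame(fit))
topcontrol <- function(expression = NULL, catalog = NULL, network = NULL,
                       annotation = NULL, de_alpha = 0.05,
                       mirna_cutoff = 0.001, hub_fraction = 0.10,
                       mds_mode = c("auto", "exact", "greedy"),
                       size_limit = 500) {
  mds_mode <- match.arg(mds_mode)
  if (is.null(network) && (is.null(catalog) || is.null(expression)))
    stop("supply either a pre-built network, or a catalog plus an ",
         "expression table")

  de <- NULL
  enrichment <- NULL
  if (!is.null(expression))
    de <- filter_de_genes(expression, de_alpha)
  if (is.null(network)) {
    enrichment <- enrich_mirnas(catalog, de, cutoff = mirna_cutoff)
    network <- build_differential_network(
      catalog, de, enrichment$mirna[enrichment$selected])
  }
  if (n_nodes(network) == 0)
    stop("stage 'network': differential network is empty")

  hub_set <- hubs(network, hub_fraction)
  mds_set <- compute_mds(network, mode = mds_mode, size_limit = size_limit)
  mcds_set <- compute_mcds(network)

  priority <- rank_candidates(
    assign_scores(network, hub_set, mds_set, mcds_set, expr = expression))

  evaluation <- NULL
  if (!is.null(annotation)) {
    layer4 <- layer_members(priority, 4L)
    evaluation <- evaluate_candidates(layer4, annotation, network$nodes$id)
  }

  counts <- c(nodes = n_nodes(network), edges = nrow(network$edges),
              de = if (is.null(de)) NA_integer_ else length(de$members),
              hub = length(hub_set$members), mds = length(mds_set$members),
              mcds = length(mcds_set$members),
              layer4 = sum(priority$score >= 1),
              layer5 = sum(priority$score == 3))
  structure(list(
    network = network, de = de, enrichment = enrichment,
    hubs = hub_set, mds = mds_set, mcds = mcds_set,
    priority = priority, evaluation = evaluation,
    config = list(de_alpha = de_alpha, mirna_cutoff = mirna_cutoff,
                  hub_fraction = hub_fraction, mds_mode = mds_mode,
                  size_limit = size_limit),
    counts = counts), class = "topcontrol")
}

#' @export
print.topcontrol <- function(x, ...) {
  cat("topcontrol prioritization\n")
  print(x$network)
  cat("  hubs ", x$counts[["hub"]], " | MDS ", x$counts[["mds"]],
      " (", x$mds$exactness, ") | MCDS ", x$counts[["mcds"]],
      " | layer 4: ", x$counts[["layer4"]],
      " | layer 5: ", x$counts[["layer5"]], "\n", sep = "")
  if (!is.null(x$evaluation))
    cat("  layer-4 overlap p = ", format(signif(x$evaluation$hyper_p, 3)),
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.topcontrol <- function(object, n = 10L, ...) {
  print(object)
  cat("\nTop-ranked candidates:\n")
  print(object$priority, n = n)
  if (!is.null(object$evaluation)) {
    cat("\n")
    print(object$evaluation)
  }
  invisible(object)
}

#' @export
as.data.frame.topcontrol <- function(x, ...) {
  as.data.frame(unclass(x$priority), stringsAsFactors = FALSE)
}

#' Degree-distribution summary plot
#' @param x a \code{topcontrol} object
#' @param ... passed to \code{hist}
#' @return invisibly, the histogram object
#' @export
plot.topcontrol <- function(x, ...) {
  d <- degrees(x$network)
  h <- graphics::hist(d$degree, breaks = "FD",
                      main = "Node degree distribution",
                      xlab = "degree (distinct interaction partners)", ...)
  graphics::abline(v = min(d$degree[d$node %in% x$hubs$members]),
                   lty = 2)
  invisible(h)
}

#' Run the full workflow from files to files
#'
#' Thin file-I/O wrapper around \code{\link{topcontrol}}: reads the inputs
#' named in \code{config}, runs the pipeline, writes the network, the
#' hub/MDS/MCDS node sets, the ranked priority table, an evaluation JSON
#' (when an annotation is given), a JSON summary with per-layer counts,
#' and a run log echoing every configuration value.
#'
#' @param config a list as produced by \code{\link{run_config}}
#' @return the \code{topcontrol} object, invisibly
#' @export
run_pipeline <- function(config) {
  cfg <- do.call(run_config, as.list(unclass(config)))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  cat("", file = log_path)
  logf("topcontrol ", as.character(utils::packageVersion("topcontrol")),
       " | R ", R.version.string)
  for (nm in setdiff(names(cfg), "out_dir"))
    logf("config ", nm, " = ",
         if (is.null(cfg[[nm]])) "NULL" else as.character(cfg[[nm]]))
  logf("config out_dir = ", cfg$out_dir)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  expression <- if (!is.null(cfg$de_path))
    stage("read-expression", read_expression_table(cfg$de_path))
  catalog <- if (!is.null(cfg$catalog_path))
    stage("read-catalog", read_network(cfg$catalog_path))
  network <- if (!is.null(cfg$network_path))
    stage("read-network", read_network(cfg$network_path))
  annotation <- if (!is.null(cfg$annotation_path))
    stage("read-annotation", read_annotation(cfg$annotation_path))

  fit <- stage("prioritize", topcontrol(
    expression = expression, catalog = catalog, network = network,
    annotation = annotation, de_alpha = cfg$de_alpha,
    mirna_cutoff = cfg$mirna_cutoff, hub_fraction = cfg$hub_fraction,
    mds_mode = cfg$mds_mode, size_limit = cfg$size_limit))

  stage("write-outputs", {
    write_network(fit$network, file.path(cfg$out_dir, "network.tsv"))
    sets <- rbind(
      data.frame(node = fit$hubs$members, method = "hub",
                 exactness = fit$hubs$exactness),
      data.frame(node = fit$mds$members, method = "MDS",
                 exactness = fit$mds$exactness),
      data.frame(node = fit$mcds$members, method = "MCDS",
                 exactness = fit$mcds$exactness))
    utils::write.table(sets, file.path(cfg$out_dir, "node_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_priority_table(fit$priority,
                         file.path(cfg$out_dir, "priority.tsv"))
    if (!is.null(fit$enrichment))
      utils::write.table(fit$enrichment,
                         file.path(cfg$out_dir, "mirna_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fit$evaluation))
      eval_to_json(fit$evaluation,
                   file.path(cfg$out_dir, "evaluation.json"))
    layers <- list(
      layer4 = layer_members(fit$priority, 4L),
      layer5 = layer_members(fit$priority, 5L),
      counts = as.list(fit$counts))
    writeLines(jsonlite::toJSON(layers, auto_unbox = TRUE, digits = NA,
                                na = "null"),
               file.path(cfg$out_dir, "summary.json"))
  })
  for (nm in names(fit$counts))
    logf("count ", nm, " = ", fit$counts[[nm]])
  invisible(fit)
}

#' Build a pipeline configuration
#'
#' @param de_path path to the expression table (optional when
#'   \code{network_path} is given)
#' @param catalog_path path to the background interaction catalog
#' @param network_path path to a pre-built differential network (skips
#'   construction)
#' @param annotation_path path to a disease annotation list
#' @param out_dir output directory
#' @param de_alpha,mirna_cutoff,hub_fraction,mds_mode,size_limit
#'   see \code{\link{topcontrol}}
#' @param seed integer seed recorded in the log (the deterministic pipeline
#'   itself draws no random numbers; the seed feeds the synthetic generator
#'   when used from the command line)
#' @return a named list of class \code{run_config}
#' @export
run_config <- function(de_path = NULL, catalog_path = NULL,
                       network_path = NULL, annotation_path = NULL,
                       out_dir = ".", de_alpha = 0.05,
                       mirna_cutoff = 0.001, hub_fraction = 0.10,
                       mds_mode = "auto", size_limit = 500, seed = 1L) {
  structure(list(de_path = de_path, catalog_path = catalog_path,
                 network_path = network_path,
                 annotation_path = annotation_path, out_dir = out_dir,
                 de_alpha = de_alpha, mirna_cutoff = mirna_cutoff,
                 hub_fraction = hub_fraction, mds_mode = mds_mode,
                 size_limit = size_limit, seed = as.integer(seed)),
            class = "run_config")
}
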