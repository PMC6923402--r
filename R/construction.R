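#' Select significant differentially expressed genes
#'
#' Keeps every record whose adjusted p-value is strictly below
#' \code{alpha}.
#'
#' @param table an \code{\link{expression_table}}
#' @param alpha adjusted p-value cutoff in (0, 1], default 0.05
#' @return object of class \code{de_gene_set}: list with \code{members}
#'   (character, sorted) and \code{alpha}
#' @export
filter_de_genes <- function(table, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  members <- sort_c(table$id[table$padj < alpha])
  structure(list(members = members, alpha = alpha), class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat("DE gene set: ", length(x$members), " members (padj < ", x$alpha,
      ")\n", sep = "")
  invisible(x)
}

de_members <- function(de) {
  if (inherits(de, "de_gene_set")) de$members else unique(as.character(de))
}

#' Test miRNAs for enrichment among DE genes
#'
#' For each miRNA in the catalog, its partner set is the union of its
#' target genes (via \code{miRNA_gene} edges) and its regulator TFs (via
#' \code{TF_miRNA} edges). The inclusive upper-tail hypergeometric test
#' asks whether the partner set is over-represented among the DE genes,
#' with all gene/TF nodes of the catalog as the universe, followed by
#' Benjamini-Hochberg adjustment across the tested miRNAs; a miRNA is
#' selected when its adjusted p-value is strictly below \code{cutoff}.
#'
#' \code{mode = "separate"} instead tests targets and regulators in two
#' separate hypergeometric tests (BH-adjusted jointly across all tests) and
#' selects a miRNA only when both pass; the reported \code{raw_p} and
#' \code{adj_p} are then the larger of the two.
#'
#' @param catalog a \code{\link{regulatory_network}} holding the background
#'   interaction catalog; must contain at least one miRNA-incident edge
#' @param de a \code{de_gene_set} (or character vector of DE node ids)
#' @param cutoff BH-adjusted significance cutoff, default 0.001
#' @param mode \code{"union"} (default) or \code{"separate"}
#' @return data.frame with columns \code{mirna}, \code{partners},
#'   \code{overlap}, \code{raw_p}, \code{adj_p}, \code{selected}, sorted by
#'   \code{adj_p} then \code{mirna}
#' @export
enrich_mirnas <- function(catalog, de, cutoff = 0.001,
                          mode = c("union", "separate")) {
  mode <- match.arg(mode)
  mirnas <- node_ids(catalog, "miRNA")
  if (!length(mirnas))
    stop("catalog contains no miRNA-incident edge")
  universe <- node_ids(catalog, c("TF", "gene"))
  de_ids <- intersect(de_members(de), universe)
  N <- length(universe)
  K <- length(de_ids)

  e <- catalog$edges
  partner_sets <- lapply(mirnas, function(m) {
    targets <- e$target[e$type == "miRNA_gene" & e$source == m]
    regulators <- e$source[e$type == "TF_miRNA" & e$target == m]
    list(targets = unique(targets), regulators = unique(regulators))
  })

  tail_p <- function(part) {
    n <- length(part)
    k <- length(intersect(part, de_ids))
    c(n = n, k = k, p = hypergeom_upper_tail(k, N, K, n))
  }

  if (mode == "union") {
    res <- t(vapply(partner_sets, function(ps)
      tail_p(union(ps$targets, ps$regulators)), c(n = 0, k = 0, p = 0)))
    adj <- bh_adjust(res[, "p"])
    out <- data.frame(mirna = mirnas, partners = as.integer(res[, "n"]),
                      overlap = as.integer(res[, "k"]),
                      raw_p = res[, "p"], adj_p = adj,
                      stringsAsFactors = FALSE)
  } else {
    pt <- t(vapply(partner_sets, function(ps) tail_p(ps$targets),
                   c(n = 0, k = 0, p = 0)))
    pr <- t(vapply(partner_sets, function(ps) tail_p(ps$regulators),
                   c(n = 0, k = 0, p = 0)))
    adj_all <- bh_adjust(c(pt[, "p"], pr[, "p"]))
    m <- length(mirnas)
    adj_t <- adj_all[seq_len(m)]
    adj_r <- adj_all[m + seq_len(m)]
    out <- data.frame(mirna = mirnas,
                      partners = as.integer(pt[, "n"] + pr[, "n"]),
                      overlap = as.integer(pt[, "k"] + pr[, "k"]),
                      raw_p = pmax(pt[, "p"], pr[, "p"]),
                      adj_p = pmax(adj_t, adj_r),
                      stringsAsFactors = FALSE)
  }
  out$selected <- out$adj_p < cutoff
  out <- out[order_c(out$adj_p, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the differential co-regulatory network
#'
#' Restricts the background catalog to the interactions among significant
#' DE genes/TFs and enrichment-selected miRNAs: an edge is retained when
#' every gene/TF endpoint is DE and every miRNA endpoint is selected.
#' Nodes that lose all incident edges are dropped (no isolated nodes).
#'
#' @param catalog a \code{\link{regulatory_network}} background catalog
#' @param de a \code{de_gene_set} or character vector of DE node ids
#' @param selected_mirnas character vector of selected miRNA ids (e.g.
#'   \code{mirna} column of \code{\link{enrich_mirnas}} rows with
#'   \code{selected == TRUE}); must be catalog miRNAs
#' @return a \code{\link{regulatory_network}}; empty (with a warning) when
#'   no edge survives
#' @export
build_differential_network <- function(catalog, de, selected_mirnas = character()) {
  de_ids <- de_members(de)
  selected_mirnas <- unique(as.character(selected_mirnas))
  extra <- setdiff(selected_mirnas, node_ids(catalog, "miRNA"))
  if (length(extra))
    stop("selected miRNAs not in catalog: ",
         paste(utils::head(extra, 5), collapse = ", "))
  e <- catalog$edges
  keep <- ifelse(e$type == "TF_gene",
                 e$source %in% de_ids & e$target %in% de_ids,
          ifelse(e$type == "TF_miRNA",
                 e$source %in% de_ids & e$target %in% selected_mirnas,
                 e$source %in% selected_mirnas & e$target %in% de_ids))
  retained <- e[keep, , drop = FALSE]
  if (!nrow(retained)) {
    warning("differential network is empty: no catalog edge connects the ",
            "DE set and the selected miRNAs")
    return(regulatory_network(NULL))
  }
  regulatory_network(retained)
}
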