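#' Assign controllability role flags and composite scores
#'
#' Each network node receives 0/1 flags for hub, MDS and MCDS membership;
#' its score is the number of roles it plays (0-3). Layer assignment: every
#' network node sits in layer 3; nodes with at least one role form layer 4;
#' nodes carrying all three roles form layer 5 (so layer 5 is a subset of
#' layer 4).
#'
#' @param network a \code{\link{regulatory_network}}
#' @param hubs,mds,mcds \code{\link{node_set}} results computed on this
#'   network (members must be network nodes)
#' @param expr optional \code{\link{expression_table}} supplying log2 fold
#'   changes; nodes without a record (or with an empty value, typically
#'   miRNAs) get \code{NA}
#' @return an unranked \code{priority_table}: data.frame with columns
#'   \code{node}, \code{kind}, \code{degree}, \code{hub}, \code{mds},
#'   \code{mcds}, \code{score}, \code{lfc}, \code{layer}, \code{rank}
#'   (\code{NA} until \code{\link{rank_candidates}})
#' @export
assign_scores <- function(network, hubs, mds, mcds, expr = NULL) {
  ids <- network$nodes$id
  sets <- list(hub = hubs, mds = mds, mcds = mcds)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    members <- if (inherits(s, "node_set")) s$members else as.character(s)
    stray <- setdiff(members, ids)
    if (length(stray))
      stop(nm, " set contains nodes outside the network: ",
           paste(utils::head(stray, 5), collapse = ", "))
    sets[[nm]] <- members
  }
  d <- degrees(network)
  lfc <- rep(NA_real_, length(ids))
  if (!is.null(expr)) lfc <- expr$lfc[match(ids, expr$id)]
  hub_flag <- as.integer(ids %in% sets$hub)
  mds_flag <- as.integer(ids %in% sets$mds)
  mcds_flag <- as.integer(ids %in% sets$mcds)
  score <- hub_flag + mds_flag + mcds_flag
  layer <- ifelse(score == 3L, 5L, ifelse(score >= 1L, 4L, 3L))
  structure(data.frame(
    node = ids, kind = network$nodes$kind, degree = d$degree,
    hub = hub_flag, mds = mds_flag, mcds = mcds_flag,
    score = score, lfc = lfc, layer = layer, rank = NA_integer_,
    stringsAsFactors = FALSE),
    class = c("priority_table", "data.frame"))
}

#' Rank a priority table
#'
#' Normative order: score descending; within equal score, absolute log2
#' fold change descending with LFC-less nodes (miRNAs) placed after all
#' LFC-bearing nodes of that score; residual ties by degree descending,
#' then node id ascending. Ranks are 1-based and contiguous.
#'
#' @param table a \code{priority_table} from \code{\link{assign_scores}}
#' @return the table reordered with \code{rank} filled in
#' @export
rank_candidates <- function(table) {
  if (!nrow(table)) return(table)
  abs_lfc <- abs(table$lfc)
  missing_lfc <- as.integer(is.na(abs_lfc))
  abs_lfc[is.na(abs_lfc)] <- -Inf
  o <- order_c(-table$score, missing_lfc, -abs_lfc, -table$degree, table$node)
  out <- table[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Members of a prioritization layer
#'
#' Layer 1 is every profiled node, layer 2 the significant DE nodes (both
#' require \code{expr}), layer 3 every network node, layer 4 the nodes
#' with at least one controllability role (score >= 1), layer 5 the nodes
#' selected by all three criteria (score = 3).
#'
#' @param table a \code{priority_table}
#' @param layer integer in 1..5
#' @param expr an \code{\link{expression_table}} (layers 1-2 only)
#' @param alpha DE cutoff for layer 2, default 0.05
#' @return character vector of node ids
#' @export
layer_members <- function(table, layer, expr = NULL, alpha = 0.05) {
  if (!is.numeric(layer) || length(layer) != 1 || layer < 1 || layer > 5 ||
      layer != as.integer(layer))
    stop("layer must be an integer in 1..5")
  layer <- as.integer(layer)
  if (layer <= 2L) {
    if (is.null(expr))
      stop("layers 1-2 are defined by the expression table; supply expr")
    if (layer == 1L) return(sort_c(expr$id))
    return(filter_de_genes(expr, alpha)$members)
  }
  if (layer == 3L) return(sort_c(table$node))
  if (layer == 4L) return(sort_c(table$node[table$score >= 1L]))
  sort_c(table$node[table$score == 3L])
}

#' @export
print.priority_table <- function(x, n = 10L, ...) {
  cat("Priority table: ", nrow(x), " nodes (",
      sum(x$score >= 1), " in layer 4, ", sum(x$score == 3),
      " in layer 5)\n", sep = "")
  if (nrow(x)) {
    shown <- utils::head(x, n)
    print.data.frame(shown, row.names = FALSE, digits = 4)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  }
  invisible(x)
}
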