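# Internal adjacency representation over DISTINCT (source, target) pairs:
# multi-typed duplicate edges collapse to one arc for degree, domination
# and connectivity purposes.
unique_arcs <- function(network) {
  e <- unique(network$edges[c("source", "target")])
  rownames(e) <- NULL
  e
}

# list(ids, out, inn, und): integer adjacency lists indexed by position in
# the lexicographically sorted id vector; `und` is the symmetrized
# neighborhood without self-loops (used for MCDS connectivity/bridging).
adjacency <- function(network) {
  ids <- network$nodes$id  # already lexicographically sorted
  n <- length(ids)
  arcs <- unique_arcs(network)
  si <- match(arcs$source, ids)
  ti <- match(arcs$target, ids)
  out <- lapply(seq_len(n), function(i) sort(ti[si == i]))
  inn <- lapply(seq_len(n), function(i) sort(si[ti == i]))
  und <- lapply(seq_len(n), function(i)
    setdiff(sort(unique(c(out[[i]], inn[[i]]))), i))
  list(ids = ids, n = n, out = out, inn = inn, und = und)
}

#' Node degrees
#'
#' Degree is in-degree plus out-degree over distinct (source, target)
#' pairs: a pair present with several edge types still counts once, and a
#' self-loop contributes 2 (once as source, once as target).
#'
#' @param network a \code{\link{regulatory_network}}
#' @return data.frame with columns \code{node}, \code{degree}, one row per
#'   node, in lexicographic node order
#' @export
degrees <- function(network) {
  ids <- network$nodes$id
  arcs <- unique_arcs(network)
  deg <- tabulate(match(arcs$source, ids), length(ids)) +
         tabulate(match(arcs$target, ids), length(ids))
  data.frame(node = ids, degree = deg, stringsAsFactors = FALSE)
}

#' Construct a node-set result
#' @param members character vector of node ids
#' @param method \code{"hub"}, \code{"MDS"} or \code{"MCDS"}
#' @param exactness \code{"exact"} or \code{"heuristic"}
#' @param domain node ids over which domination was required
#' @return object of class \code{node_set}
#' @export
node_set <- function(members, method, exactness, domain) {
  structure(list(members = sort_c(unique(as.character(members))),
                 method = method, exactness = exactness,
                 domain = sort_c(unique(as.character(domain)))),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat(x$method, " node set (", x$exactness, "): ", length(x$members),
      " of ", length(x$domain), " domain nodes\n", sep = "")
  invisible(x)
}

#' Hub-degree nodes (top fraction of degree)
#'
#' Returns exactly \code{ceiling(fraction * N)} nodes of highest degree.
#' Ties at the boundary degree are broken by lexicographic node id
#' (smallest kept), so the result is deterministic and size-exact.
#'
#' @param network a \code{\link{regulatory_network}}
#' @param fraction fraction of nodes to keep, in (0, 1]; default 0.10
#' @return a \code{\link{node_set}} with \code{method = "hub"}
#' @export
hubs <- function(network, fraction = 0.10) {
  stopifnot(is.numeric(fraction), length(fraction) == 1)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  d <- degrees(network)
  N <- nrow(d)
  if (N == 0) return(node_set(character(), "hub", "exact", character()))
  k <- ceiling(fraction * N)
  ord <- order_c(-d$degree, d$node)
  node_set(d$node[ord][seq_len(k)], "hub", "exact", d$node)
}

#' Nodes dominated by a node
#'
#' Directed domination: a node covers itself and its out-neighbors (a
#' regulator controls its targets). A self-loop is redundant with
#' self-domination.
#'
#' @param network a \code{\link{regulatory_network}}
#' @param node a node id present in the network
#' @return character vector: the node and its distinct out-neighbors
#' @export
dominated_by <- function(network, node) {
  ids <- network$nodes$id
  if (!node %in% ids) stop("unknown node: ", node)
  arcs <- unique_arcs(network)
  sort_c(unique(c(node, arcs$target[arcs$source == node])))
}

# closed out-neighborhood cover sets as integer vectors
cover_sets <- function(adj) {
  lapply(seq_len(adj$n), function(i) sort(unique(c(i, adj$out[[i]]))))
}

# dominator sets: who can cover node v (v itself plus in-neighbors)
dominator_sets <- function(adj) {
  lapply(seq_len(adj$n), function(i) sort(unique(c(i, adj$inn[[i]]))))
}

greedy_mds_idx <- function(adj, covers, deg, forced) {
  n <- adj$n
  S <- forced
  dominated <- rep(FALSE, n)
  for (s in S) dominated[covers[[s]]] <- TRUE
  while (!all(dominated)) {
    gain <- vapply(seq_len(n), function(u) sum(!dominated[covers[[u]]]), 0L)
    best <- which(gain == max(gain))
    if (length(best) > 1) {
      best <- best[deg[best] == max(deg[best])]
      best <- best[1]  # candidates are in ascending index = lexicographic id
    }
    S <- c(S, best)
    dominated[covers[[best]]] <- TRUE
  }
  sort(unique(S))
}

# lower bound on the number of extra sets needed to dominate `undom`:
# max of a coverage bound and a disjoint-element packing bound
mds_lower_bound <- function(undom, covers, dominators) {
  if (!length(undom)) return(0L)
  maxcov <- max(vapply(undom, function(v)
    max(vapply(dominators[[v]], function(u) length(intersect(covers[[u]], undom)), 0L)),
    0L))
  lb_cov <- as.integer(ceiling(length(undom) / maxcov))
  # packing: pick elements no single set can cover together
  blocked <- logical(max(undom))
  lb_pack <- 0L
  ord <- undom[order(vapply(undom, function(v) length(dominators[[v]]), 0L))]
  for (v in ord) {
    if (blocked[v]) next
    lb_pack <- lb_pack + 1L
    for (u in dominators[[v]]) {
      cv <- covers[[u]]
      blocked[cv[cv <= length(blocked)]] <- TRUE
    }
  }
  max(lb_cov, lb_pack)
}

exact_mds_idx <- function(adj, covers, dominators, deg, forced) {
  n <- adj$n
  dominated0 <- rep(FALSE, n)
  for (s in forced) dominated0[covers[[s]]] <- TRUE
  best <- greedy_mds_idx(adj, covers, deg, forced)

  search <- function(S, dominated) {
    undom <- which(!dominated)
    if (!length(undom)) {
      if (length(S) < length(best)) best <<- sort(S)
      return(invisible(NULL))
    }
    if (length(S) + mds_lower_bound(undom, covers, dominators) >= length(best))
      return(invisible(NULL))
    # branch on the hardest-to-cover undominated node
    ndom <- vapply(undom, function(v) length(dominators[[v]]), 0L)
    v <- undom[order(ndom, undom)][1]
    cand <- dominators[[v]]
    gain <- vapply(cand, function(u) sum(!dominated[covers[[u]]]), 0L)
    cand <- cand[order(-gain, cand)]
    for (u in cand) {
      d2 <- dominated
      d2[covers[[u]]] <- TRUE
      search(c(S, u), d2)
    }
    invisible(NULL)
  }
  search(forced, dominated0)
  best
}

#' Minimum dominating set
#'
#' A set S of nodes such that every node is in S or has an in-neighbor in
#' S (directed domination: regulators control their targets). Equivalent
#' binary program: minimize sum x_v subject to
#' x_v + sum over in-neighbors u of x_u >= 1 for all v.
#'
#' \code{mode = "exact"} runs a branch-and-bound over closed
#' out-neighborhood covers, seeded with the greedy solution as upper bound
#' and pruned with coverage and packing lower bounds; the returned size is
#' provably minimum. \code{mode = "greedy"} is classic greedy set cover
#' with a deterministic tie cascade (max new coverage, then max degree,
#' then lexicographic id). \code{mode = "auto"} (default) uses exact search
#' up to \code{size_limit} nodes and greedy beyond. Every node that no
#' other node can dominate (in-degree 0, ignoring self-loops) is forced
#' into S in all modes.
#'
#' @param network a non-empty \code{\link{regulatory_network}}
#' @param mode \code{"auto"}, \code{"exact"} or \code{"greedy"}
#' @param size_limit auto-mode crossover (node count), default 500
#' @return a \code{\link{node_set}} with \code{method = "MDS"} and
#'   \code{exactness} recording which solver produced it
#' @export
compute_mds <- function(network, mode = c("auto", "exact", "greedy"),
                        size_limit = 500) {
  mode <- match.arg(mode)
  if (n_nodes(network) == 0) stop("network is empty")
  adj <- adjacency(network)
  covers <- cover_sets(adj)
  dominators <- dominator_sets(adj)
  deg <- degrees(network)$degree
  # nodes no other node can dominate (in-degree 0 apart from self-loops)
  forced <- which(vapply(dominators, length, 0L) == 1L)
  use_exact <- mode == "exact" || (mode == "auto" && adj$n <= size_limit)
  S <- if (use_exact) {
    exact_mds_idx(adj, covers, dominators, deg, forced)
  } else {
    greedy_mds_idx(adj, covers, deg, forced)
  }
  members <- adj$ids[S]
  res <- node_set(members, "MDS",
                  if (use_exact) "exact" else "heuristic", adj$ids)
  assert_dominates(network, res$members, res$domain)
  res
}

# post-hoc validity check used by every solver path
assert_dominates <- function(network, members, domain) {
  covered <- unique(unlist(lapply(members, function(m)
    dominated_by(network, m)), use.names = FALSE))
  if (!all(domain %in% covered))
    stop("internal error: reported set does not dominate its domain")
  invisible(TRUE)
}

#' Largest (weakly) connected component
#'
#' Connectivity is judged on the underlying undirected graph. Ties in
#' component size are broken in favor of the component containing the
#' lexicographically smallest node id.
#'
#' @param network a \code{\link{regulatory_network}}
#' @return the induced subnetwork (all typed edges among the component's
#'   nodes); the empty network when the input is empty
#' @export
largest_connected_component <- function(network) {
  if (n_nodes(network) == 0) return(regulatory_network(NULL))
  g <- igraph::graph_from_data_frame(
    unique_arcs(network), directed = TRUE,
    vertices = data.frame(name = network$nodes$id))
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    # component whose smallest member id sorts first
    mins <- vapply(cand, function(ci)
      min(network$nodes$id[comp$membership == ci]), character(1))
    cand <- cand[order_c(mins)][1]
  }
  keep <- network$nodes$id[comp$membership == cand[1]]
  induced_subnetwork(network, keep)
}

#' Induced subnetwork on a node subset
#' @param network a \code{\link{regulatory_network}}
#' @param ids node ids to keep
#' @return the subnetwork with all typed edges among \code{ids}; nodes in
#'   \code{ids} are kept even if isolated
#' @export
induced_subnetwork <- function(network, ids) {
  ids <- intersect(network$nodes$id, ids)
  e <- network$edges
  e <- e[e$source %in% ids & e$target %in% ids, , drop = FALSE]
  nodes <- network$nodes[network$nodes$id %in% ids, , drop = FALSE]
  regulatory_network(e, nodes = nodes)
}

#' Minimum connected dominating set of the largest connected component
#'
#' Computes a connected dominating set of the network's largest weakly
#' connected component (LCC): the members dominate every LCC node under
#' directed domination and induce a connected subgraph of the underlying
#' undirected LCC (the "dominating pathway"). Growth-and-prune heuristic:
#' \enumerate{
#'   \item seed with the LCC node of maximum out-degree (ties: max total
#'     degree, then lexicographic id);
#'   \item while undominated nodes remain, add the node
#'     undirected-adjacent to the current set that covers the most
#'     undominated nodes (same tie cascade); when no adjacent node covers
#'     anything new, add the first node on a shortest undirected path from
#'     the set towards the nearest undominated node;
#'   \item prune: repeatedly remove any member whose removal preserves both
#'     domination and connectivity, scanning members in ascending coverage
#'     order, until a fixed point.
#' }
#'
#' @param network a non-empty \code{\link{regulatory_network}}
#' @return a \code{\link{node_set}} with \code{method = "MCDS"},
#'   \code{exactness = "heuristic"}, and the LCC node ids as domain
#' @export
compute_mcds <- function(network) {
  if (n_nodes(network) == 0) stop("network is empty")
  lcc <- largest_connected_component(network)
  adj <- adjacency(lcc)
  n <- adj$n
  covers <- cover_sets(adj)
  outdeg <- vapply(adj$out, length, 0L)
  deg <- degrees(lcc)$degree

  pick <- function(cand, gain) {
    # tie cascade: max gain, max out-degree, max total degree, smallest id
    o <- order(-gain, -outdeg[cand], -deg[cand], cand)
    cand[o][1]
  }

  seed <- pick(seq_len(n), outdeg)  # primary key collapses to out-degree
  S <- seed
  dominated <- rep(FALSE, n)
  dominated[covers[[seed]]] <- TRUE

  while (!all(dominated)) {
    frontier <- setdiff(sort(unique(unlist(adj$und[S]))), S)
    gain <- vapply(frontier, function(u) sum(!dominated[covers[[u]]]), 0L)
    if (length(frontier) && max(gain) > 0) {
      add <- pick(frontier, gain)
    } else {
      add <- bridge_node(adj, S, which(!dominated))
    }
    S <- c(S, add)
    dominated[covers[[add]]] <- TRUE
  }
  S <- prune_cds(adj, covers, sort(S))
  res <- node_set(adj$ids[S], "MCDS", "heuristic", adj$ids)
  assert_dominates(lcc, res$members, res$domain)
  if (!cds_connected(adj, S))
    stop("internal error: reported MCDS is not connected")
  res
}

# first node after leaving S on a shortest undirected path from S to the
# nearest undominated node; BFS with lexicographic (index-order) expansion
bridge_node <- function(adj, S, undominated) {
  n <- adj$n
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  queue <- sort(S)
  dist[queue] <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj$und[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  reach <- undominated[!is.na(dist[undominated])]
  if (!length(reach))
    stop("internal error: undominated node unreachable within the LCC")
  target <- reach[order(dist[reach], reach)][1]
  v <- target
  while (!is.na(parent[v]) && !(parent[v] %in% S)) v <- parent[v]
  v
}

cds_connected <- function(adj, S) {
  if (length(S) <= 1) return(TRUE)
  seen <- S[1]
  frontier <- S[1]
  while (length(frontier)) {
    nb <- intersect(unique(unlist(adj$und[frontier])), S)
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(S)
}

cds_dominates <- function(covers, S, n) {
  dominated <- rep(FALSE, n)
  for (s in S) dominated[covers[[s]]] <- TRUE
  all(dominated)
}

prune_cds <- function(adj, covers, S) {
  repeat {
    cov_size <- vapply(S, function(u) length(covers[[u]]), 0L)
    order_scan <- S[order(cov_size, S)]
    removed <- FALSE
    for (m in order_scan) {
      S2 <- setdiff(S, m)
      if (length(S2) &&
          cds_dominates(covers, S2, adj$n) && cds_connected(adj, S2)) {
        S <- S2
        removed <- TRUE
        break
      }
    }
    if (!removed) return(sort(S))
  }
}
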