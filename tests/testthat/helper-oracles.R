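# Independent brute-force oracles and fixture builders. These never call
# the solver code paths they are used to check.

net_from_edges <- function(source, target, type = "TF_gene") {
  regulatory_network(data.frame(source = source, target = target,
                                type = type, stringsAsFactors = FALSE))
}

# directed domination: S covers v iff v in S or some arc u->v with u in S
covers_all <- function(out_adj, S, n) {
  dominated <- rep(FALSE, n)
  dominated[S] <- TRUE
  for (u in S) dominated[out_adj[[u]]] <- TRUE
  all(dominated)
}

out_adjacency_idx <- function(network) {
  ids <- network$nodes$id
  arcs <- unique(network$edges[c("source", "target")])
  lapply(seq_along(ids), function(i)
    match(arcs$target[arcs$source == ids[i]], ids))
}

und_adjacency_idx <- function(network) {
  ids <- network$nodes$id
  arcs <- unique(network$edges[c("source", "target")])
  si <- match(arcs$source, ids); ti <- match(arcs$target, ids)
  lapply(seq_along(ids), function(i)
    setdiff(unique(c(ti[si == i], si[ti == i])), i))
}

subset_connected <- function(und_adj, S) {
  if (length(S) <= 1) return(TRUE)
  seen <- S[1]
  repeat {
    grow <- setdiff(intersect(unique(unlist(und_adj[seen])), S), seen)
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  length(seen) == length(S)
}

# exhaustive minimum dominating set size (directed domination)
brute_force_mds_size <- function(network) {
  n <- n_nodes(network)
  out_adj <- out_adjacency_idx(network)
  for (k in 1:n) {
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs)))
      if (covers_all(out_adj, combs[, j], n)) return(k)
  }
  n
}

# exhaustive minimum connected dominating set size on a (weakly)
# connected network; NA when none exists
brute_force_min_cds_size <- function(network) {
  n <- n_nodes(network)
  out_adj <- out_adjacency_idx(network)
  und_adj <- und_adjacency_idx(network)
  for (k in 1:n) {
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs))) {
      S <- combs[, j]
      if (covers_all(out_adj, S, n) && subset_connected(und_adj, S))
        return(k)
    }
  }
  NA_integer_
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
hyper_tail_enum <- function(k, N, K, n) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the successes
  mean(hits >= k)
}

# random typed digraph on `n` nodes with arc probability `p` (TF_gene
# arcs only, no self-loops); may be disconnected
random_digraph <- function(n, p) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
  pairs <- pairs[pairs$s != pairs$t, ]
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  regulatory_network(
    data.frame(source = ids[pairs$s[keep]], target = ids[pairs$t[keep]],
               type = "TF_gene", stringsAsFactors = FALSE),
    nodes = data.frame(id = ids,
                       kind = infer_kind_for_test(ids, pairs, keep),
                       stringsAsFactors = FALSE))
}

# kinds consistent with TF_gene arcs: sources are TFs, pure targets genes
infer_kind_for_test <- function(ids, pairs, keep) {
  is_src <- seq_along(ids) %in% pairs$s[keep]
  ifelse(is_src, "TF", "gene")
}

# random weakly connected digraph: a random spanning arborescence plus
# random extra arcs
random_connected_digraph <- function(n, p = 0.25) {
  ids <- sprintf("N%02d", seq_len(n))
  src <- integer(0); tgt <- integer(0)
  for (v in 2:n) {            # attach each node to an earlier one
    u <- sample.int(v - 1, 1)
    if (stats::runif(1) < 0.5) { src <- c(src, u); tgt <- c(tgt, v) }
    else                       { src <- c(src, v); tgt <- c(tgt, u) }
  }
  extra <- expand.grid(s = seq_len(n), t = seq_len(n))
  extra <- extra[extra$s != extra$t, ]
  keep <- stats::runif(nrow(extra)) < p
  src <- c(src, extra$s[keep]); tgt <- c(tgt, extra$t[keep])
  e <- unique(data.frame(s = src, t = tgt))
  nodes <- data.frame(id = ids,
                      kind = ifelse(seq_len(n) %in% e$s, "TF", "gene"),
                      stringsAsFactors = FALSE)
  regulatory_network(data.frame(source = ids[e$s], target = ids[e$t],
                                type = "TF_gene", stringsAsFactors = FALSE),
                     nodes = nodes)
}

write_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path, useBytes = TRUE)
  path
}
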