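#' @keywords internal
"_PACKAGE"

EDGE_TYPES <- c("TF_gene", "TF_miRNA", "miRNA_gene")
NODE_KINDS <- c("TF", "gene", "miRNA")

#' Construct a typed regulatory network
#'
#' A regulatory network is a directed graph whose nodes are transcription
#' factors (TFs), genes, or miRNAs and whose edges carry one of three
#' regulation types: \code{TF_gene}, \code{TF_miRNA}, \code{miRNA_gene}.
#' Exact duplicate edges (same source, target and type) are collapsed;
#' duplicate (source, target) pairs with *different* types are kept as
#' distinct edges but count once towards node degree (see
#' \code{\link{degrees}}).
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{type} (values in \code{TF_gene}, \code{TF_miRNA},
#'   \code{miRNA_gene}).
#' @param nodes optional data.frame with columns \code{id}, \code{kind}
#'   (\code{TF}, \code{gene} or \code{miRNA}). When omitted, node kinds are
#'   inferred from the edge types (see Details). Nodes listed here but
#'   absent from \code{edges} are kept as isolated nodes.
#'
#' @details Kind inference is a per-network property derived solely from the
#' supplied edges: a node acting as source of a \code{TF_gene} or
#' \code{TF_miRNA} edge is a TF; a node acting as source of a
#' \code{miRNA_gene} edge or as target of a \code{TF_miRNA} edge is a
#' miRNA; every other endpoint is a gene (so a node appearing only as a
#' \code{TF_gene} target has kind gene even if it is elsewhere known as a
#' TF). Contradictory implications (a node in both a TF role and a miRNA
#' role, or in both a gene-target role and a miRNA role) raise a validation
#' error. Identifier matching is exact, case-preserving and
#' whitespace-trimmed; no symbol aliasing is performed.
#'
#' @return An object of class \code{regulatory_network}: a list with
#'   data.frame components \code{nodes} (\code{id}, \code{kind}) and
#'   \code{edges} (\code{source}, \code{target}, \code{type}).
#' @export
#' @examples
#' net <- regulatory_network(data.frame(
#'   source = c("A", "A", "m1"),
#'   target = c("B", "m1", "B"),
#'   type   = c("TF_gene", "TF_miRNA", "miRNA_gene")))
#' net$nodes
regulatory_network <- function(edges, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "type") %in% names(edges)))
    stop("edges must have columns source, target, type")
  edges$source <- trimws(as.character(edges$source))
  edges$target <- trimws(as.character(edges$target))
  edges$type   <- trimws(as.character(edges$type))
  bad <- which(!edges$type %in% EDGE_TYPES)
  if (length(bad))
    stop("unknown edge type '", edges$type[bad[1]], "' (row ", bad[1], ")")
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target)))
    stop("empty node identifier in edge list")
  if (any(grepl("[[:space:]]", c(edges$source, edges$target))))
    stop("node identifiers must not contain whitespace")
  edges <- unique(edges)
  edges <- edges[order_c(edges$source, edges$target, edges$type), , drop = FALSE]
  rownames(edges) <- NULL

  inferred <- infer_node_kinds(edges)
  if (is.null(nodes)) {
    nodes <- inferred
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!all(c("id", "kind") %in% names(nodes)))
      stop("nodes must have columns id, kind")
    nodes$id <- trimws(as.character(nodes$id))
    nodes$kind <- as.character(nodes$kind)
    if (anyDuplicated(nodes$id))
      stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
    if (!all(nodes$kind %in% NODE_KINDS))
      stop("node kind must be one of: ", paste(NODE_KINDS, collapse = ", "))
    missing <- setdiff(inferred$id, nodes$id)
    if (length(missing))
      stop("edge endpoints not declared as nodes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    # declared kinds must be consistent with the edge types
    m <- match(inferred$id, nodes$id)
    clash <- inferred$id[nodes$kind[m] != inferred$kind]
    if (length(clash))
      stop("declared kind inconsistent with edge types for: ",
           paste(utils::head(clash, 5), collapse = ", "))
  }
  nodes <- nodes[order_c(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

# Derive node kinds from typed edges; error on contradictory roles.
infer_node_kinds <- function(edges) {
  ids <- sort_c(unique(c(edges$source, edges$target)))
  tf_role    <- ids %in% edges$source[edges$type %in% c("TF_gene", "TF_miRNA")]
  mirna_role <- ids %in% c(edges$source[edges$type == "miRNA_gene"],
                           edges$target[edges$type == "TF_miRNA"])
  gene_role  <- ids %in% c(edges$target[edges$type == "TF_gene"],
                           edges$target[edges$type == "miRNA_gene"])
  contra <- (tf_role & mirna_role) | (mirna_role & gene_role)
  if (any(contra))
    stop("contradictory kind inference for node(s): ",
         paste(utils::head(ids[contra], 5), collapse = ", "))
  kind <- ifelse(tf_role, "TF", ifelse(mirna_role, "miRNA", "gene"))
  data.frame(id = ids, kind = kind, stringsAsFactors = FALSE)
}

# Heuristic miRNA name recognition, used only when kind cannot be derived
# from any incident edge (isolated declared nodes).
looks_like_mirna <- function(id) grepl("mir|let-", id, ignore.case = TRUE)

#' Number of nodes in a network
#' @param network a \code{regulatory_network}
#' @return integer node count
#' @export
n_nodes <- function(network) nrow(network$nodes)

#' Node identifiers of a network
#' @inheritParams n_nodes
#' @param kind optional kind filter (\code{"TF"}, \code{"gene"}, \code{"miRNA"})
#' @return character vector of node ids (lexicographic order)
#' @export
node_ids <- function(network, kind = NULL) {
  if (is.null(kind)) return(network$nodes$id)
  network$nodes$id[network$nodes$kind %in% kind]
}

#' @export
print.regulatory_network <- function(x, ...) {
  kc <- table(factor(x$nodes$kind, levels = NODE_KINDS))
  cat("Regulatory network: ", nrow(x$nodes), " nodes (",
      kc[["TF"]], " TF, ", kc[["gene"]], " gene, ", kc[["miRNA"]],
      " miRNA), ", nrow(x$edges), " typed edges\n", sep = "")
  invisible(x)
}

#' Read a typed regulatory network from a file
#'
#' @param path path to a tab-separated edge list. The \code{"tsv"} dialect
#'   expects \code{source<TAB>target<TAB>edge_type}; the \code{"sif"}
#'   dialect expects \code{source<TAB>edge_type<TAB>target}. Edge types are
#'   \code{TF_gene}, \code{TF_miRNA}, \code{miRNA_gene}. A header line is
#'   tolerated and skipped. Duplicate rows are collapsed.
#' @param dialect \code{"tsv"} (default) or \code{"sif"}
#' @return a \code{\link{regulatory_network}}
#' @export
read_network <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  first <- TRUE
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    f <- trimws(parts[[i]])
    if (length(f) < 3)
      stop("malformed row at line ", keep[i], " of ", path,
           ": expected at least 3 tab-separated columns")
    rec <- if (dialect == "sif") c(f[1], f[3], f[2]) else f[1:3]
    if (first && !rec[3] %in% EDGE_TYPES &&
        tolower(rec[3]) %in% c("type", "edge_type", "interaction")) {
      first <- FALSE
      next  # header line
    }
    first <- FALSE
    if (!rec[3] %in% EDGE_TYPES)
      stop("unknown edge type '", rec[3], "' at line ", keep[i], " of ", path)
    rows[[i]] <- rec
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(regulatory_network(NULL))
  m <- do.call(rbind, rows)
  regulatory_network(data.frame(source = m[, 1], target = m[, 2],
                                type = m[, 3], stringsAsFactors = FALSE))
}

#' Write a network as a typed edge list
#' @param network a \code{regulatory_network}
#' @param path output path
#' @param dialect \code{"tsv"} or \code{"sif"} (see \code{\link{read_network}})
#' @return invisibly, \code{path}
#' @export
write_network <- function(network, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  e <- network$edges
  out <- if (dialect == "sif") {
    paste(e$source, e$type, e$target, sep = "\t")
  } else {
    paste(e$source, e$target, e$type, sep = "\t")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read an expression table (id, lfc, padj)
#'
#' @param path tab-separated file with header columns \code{id},
#'   \code{lfc}, \code{padj}. \code{lfc} cells may be empty (typically for
#'   miRNAs); they are stored as \code{NA}.
#' @return data.frame of class \code{expression_table} with columns
#'   \code{id} (character), \code{lfc} (numeric, NA when absent),
#'   \code{padj} (numeric in [0, 1])
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           strip.white = TRUE, stringsAsFactors = FALSE)
  need <- c("id", "lfc", "padj")
  if (!all(need %in% names(tab)))
    stop("expression table must have header columns id, lfc, padj")
  expression_table(id = tab$id, lfc = tab$lfc, padj = tab$padj)
}

#' Build an expression table from vectors
#' @param id node identifiers (unique)
#' @param lfc log2 fold changes; \code{NA} or \code{""} marks an absent value
#' @param padj adjusted p-values in [0, 1]
#' @return an \code{expression_table} data.frame
#' @export
expression_table <- function(id, lfc, padj) {
  id <- trimws(as.character(id))
  if (anyDuplicated(id))
    stop("duplicate id in expression table: ", id[duplicated(id)][1])
  lfc <- as.character(lfc)
  lfc[!nzchar(trimws(lfc)) | is.na(lfc)] <- NA_character_
  lfc_num <- suppressWarnings(as.numeric(lfc))
  if (any(!is.na(lfc) & is.na(lfc_num)))
    stop("non-numeric lfc for id: ", id[!is.na(lfc) & is.na(lfc_num)][1])
  padj_num <- suppressWarnings(as.numeric(as.character(padj)))
  if (any(is.na(padj_num)))
    stop("missing or non-numeric padj for id: ", id[is.na(padj_num)][1])
  if (any(padj_num < 0 | padj_num > 1))
    stop("padj outside [0, 1] for id: ", id[padj_num < 0 | padj_num > 1][1])
  structure(data.frame(id = id, lfc = lfc_num, padj = padj_num,
                       stringsAsFactors = FALSE),
            class = c("expression_table", "data.frame"))
}

#' Write an expression table
#' @param table an \code{expression_table}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_expression_table <- function(table, path) {
  lfc <- ifelse(is.na(table$lfc), "", format(table$lfc, trim = TRUE))
  writeLines(c("id\tlfc\tpadj",
               paste(table$id, lfc, format(table$padj, trim = TRUE),
                     sep = "\t")), path, useBytes = TRUE)
  invisible(path)
}

#' Read a disease annotation list
#'
#' Plain text, one identifier per line; \code{#} starts a comment; blank
#' lines are skipped; identifiers are trimmed and deduplicated. Membership
#' testing downstream is exact string match.
#'
#' @param path path to the list
#' @param disease_name label carried in the result
#' @return object of class \code{disease_annotation}: list with
#'   \code{disease_name} and character vector \code{members}
#' @export
read_annotation <- function(path, disease_name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  ids <- unique(trimws(lines))
  ids <- ids[nzchar(ids)]
  if (!length(ids))
    warning("annotation file is empty: ", path)
  disease_annotation(disease_name, ids)
}

#' Construct a disease annotation
#' @param disease_name label
#' @param members character vector of node ids
#' @return a \code{disease_annotation}
#' @export
disease_annotation <- function(disease_name, members) {
  structure(list(disease_name = as.character(disease_name),
                 members = sort_c(unique(trimws(as.character(members))))),
            class = "disease_annotation")
}

#' @export
print.disease_annotation <- function(x, ...) {
  cat("Disease annotation '", x$disease_name, "': ",
      length(x$members), " ids\n", sep = "")
  invisible(x)
}

#' Write a ranked priority table
#'
#' Columns: \code{gene, D, hub, mds, mcds, score, LFC, layer, rank}. Absent
#' LFC values (miRNAs) are rendered as an em dash.
#'
#' @param table a ranked \code{\link{priority_table}}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_priority_table <- function(table, path) {
  header <- "gene\tD\thub\tmds\tmcds\tscore\tLFC\tlayer\trank"
  if (!nrow(table)) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  lfc <- ifelse(is.na(table$lfc), "\u2014", format(table$lfc, trim = TRUE))
  rank <- ifelse(is.na(table$rank), "", as.character(table$rank))
  writeLines(c(header,
               paste(table$node, table$degree, table$hub, table$mds,
                     table$mcds, table$score, lfc, table$layer, rank,
                     sep = "\t")), path, useBytes = TRUE)
  invisible(path)
}
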