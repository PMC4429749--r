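# miRNA-centric network assembly: MTIs with expression correlation, DFS
# expansion to indirect targets, GO enrichment, Cytoscape-compatible export.

#' Expression correlation of miRNA-target interactions
#'
#' Adds the Pearson correlation between each miRNA's and its target's
#' expression profiles to an MTI table. Missing expression is a value, not an
#' error: such interactions keep `NA` and are flagged in `corr_missing`.
#'
#' @param mtis `data.frame` with columns `mirna`, `target` (and any others,
#'   carried through).
#' @param mirnaExpr,geneExpr expression matrices with identical condition
#'   columns.
#' @return the MTI table with columns `correlation` and `corr_missing`
#'   appended.
#' @export
mtiCorrelation <- function(mtis, mirnaExpr, geneExpr) {
  if (!identical(colnames(mirnaExpr), colnames(geneExpr)))
    stop("condition labels differ between matrices")
  corr <- vapply(seq_len(nrow(mtis)), function(i) {
    m <- mtis$mirna[i]; g <- mtis$target[i]
    if (!m %in% rownames(mirnaExpr) || !g %in% rownames(geneExpr))
      return(NA_real_)
    x <- mirnaExpr[m, ]; y <- geneExpr[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  mtis$correlation <- corr
  mtis$corr_missing <- is.na(corr)
  mtis
}

#' Adjacency matrix of a gene-gene interaction graph
#'
#' Entry `(i, j)` is 1 iff a directed edge i -> j exists, else 0; self-edges
#' sit on the diagonal.
#'
#' @param edges `data.frame` with columns `from`, `to`.
#' @param nodes optional node universe (default: all ids appearing in
#'   `edges`), row/column order of the matrix.
#' @return square 0/1 integer matrix with dimnames.
#' @export
geneGraphAdjacency <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges))
    A[cbind(match(edges$from, nodes), match(edges$to, nodes))] <- 1L
  A
}

#' Expand direct targets to indirect targets by depth-first search
#'
#' Starting from each direct target (roots processed in lexicographic
#' order), follows directed gene-gene edges depth-first, visiting children
#' in lexicographic id order, until no unvisited child remains. Every node is
#' visited once, so feedback loops and self-edges terminate. The indirect
#' targets are the reachable genes minus the direct targets.
#'
#' @param directTargets character vector of direct-target gene ids; ids
#'   absent from the graph are skipped with a warning.
#' @param edges `data.frame` with columns `from`, `to` (directed
#'   regulator -> regulatee).
#' @return list with `nodes` (`data.frame(node, depth, root)`; direct
#'   targets at depth 0), `edges` (the spanning-forest tree edges), and
#'   `indirect` (character vector).
#' @export
expandIndirectTargets <- function(directTargets, edges) {
  graphNodes <- unique(c(edges$from, edges$to))
  unknown <- setdiff(directTargets, graphNodes)
  if (length(unknown))
    warning("direct target(s) not in graph, skipped: ",
            paste(unknown, collapse = ", "))
  roots <- sort(intersect(unique(directTargets), graphNodes))
  adj <- split(edges$to, edges$from)
  adj <- lapply(adj, function(ch) sort(unique(ch)))
  visited <- character(0)
  nodeRows <- list()
  treeEdges <- list()
  visit <- function(node, depth, root) {
    visited <<- c(visited, node)
    nodeRows[[length(nodeRows) + 1L]] <<-
      data.frame(node = node, depth = depth, root = root,
                 stringsAsFactors = FALSE)
    for (ch in adj[[node]]) {
      if (!ch %in% visited) {
        treeEdges[[length(treeEdges) + 1L]] <<-
          data.frame(from = node, to = ch, stringsAsFactors = FALSE)
        visit(ch, depth + 1L, root)
      }
    }
  }
  for (r in roots) if (!r %in% visited) visit(r, 0L, r)
  nodes <- if (length(nodeRows)) do.call(rbind, nodeRows) else
    data.frame(node = character(), depth = integer(), root = character(),
               stringsAsFactors = FALSE)
  # direct targets reached from another root keep depth 0 semantics:
  nodes$depth[nodes$node %in% directTargets] <- 0L
  tEdges <- if (length(treeEdges)) do.call(rbind, treeEdges) else
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  list(nodes = nodes, edges = tEdges,
       indirect = setdiff(nodes$node, directTargets))
}

#' GO term enrichment by the hypergeometric distribution
#'
#' Upper-tail hypergeometric p-value per term for the over-representation of
#' the query gene set against the background (by default all genes bearing at
#' least one annotation), sharing the implementation of
#' [hypergeomPvalue()].
#'
#' @param queryGenes character vector of query gene ids; genes outside the
#'   background are dropped (empty intersection is an error).
#' @param annotations `data.frame` with columns `gene`, `term` (optional
#'   `term_name`, `namespace` carried through).
#' @param background optional background gene universe.
#' @param minTermSize smallest background term size tested (default 2).
#' @param adjust `"none"` (default; raw hypergeometric p is reported) or
#'   `"BH"`.
#' @return `data.frame` with columns `term`, (`term_name`, `namespace` if
#'   present), `k`, `n`, `K`, `N`, `p_value` (and `p_adjusted`), sorted by
#'   increasing p.
#' @export
goEnrichment <- function(queryGenes, annotations, background = NULL,
                         minTermSize = 2L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(background)) background <- unique(annotations$gene)
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  query <- intersect(unique(queryGenes), background)
  if (length(query) == 0L)
    stop("no query genes in the background universe")
  N <- length(unique(background))
  n <- length(query)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    genes <- unique(ann$gene[ann$term == tm])
    K <- length(genes)
    if (K < minTermSize) return(NULL)
    k <- length(intersect(genes, query))
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p_value = hypergeomPvalue(N, K, n, k, "upper"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if ("term_name" %in% names(ann))
    out$term_name <- ann$term_name[match(out$term, ann$term)]
  if ("namespace" %in% names(ann))
    out$namespace <- ann$namespace[match(out$term, ann$term)]
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a miRNA regulatory network
#'
#' Combines TF -> miRNA regulatory relations (with their coTFBS statistics),
#' direct miRNA -> target interactions (verified and putative, with
#' expression correlations) and the DFS spanning forest of indirect targets
#' into one typed directed graph. Duplicate (miRNA, target) interactions are
#' merged, `verified` evidence dominating `putative` and sources
#' concatenated.
#'
#' @param tfMirna optional `data.frame` with columns `tf`, `mirna` and
#'   optional statistic columns (`frequency`, `p_value`, ...).
#' @param mtis optional `data.frame` with columns `mirna`, `target`,
#'   `evidence`, `source`, optional `correlation`.
#' @param forest optional result of [expandIndirectTargets()].
#' @return a [RegulatoryNetwork-class].
#' @export
buildNetwork <- function(tfMirna = NULL, mtis = NULL, forest = NULL) {
  nodes <- list()
  edges <- list()
  addNodes <- function(ids, type)
    nodes[[length(nodes) + 1L]] <<-
      data.frame(id = ids, type = type, stringsAsFactors = FALSE)
  if (!is.null(mtis) && nrow(mtis)) {
    # merge duplicate (mirna, target) pairs; verified dominates putative
    key <- paste(mtis$mirna, mtis$target, sep = "\r")
    merged <- do.call(rbind, lapply(split(mtis, key), function(d) {
      out <- d[1, , drop = FALSE]
      out$evidence <- if (any(d$evidence == "verified")) "verified"
                      else "putative"
      if ("source" %in% names(d))
        out$source <- paste(sort(unique(d$source)), collapse = ";")
      if ("correlation" %in% names(d))
        out$correlation <- d$correlation[which(!is.na(d$correlation))[1]]
      out
    }))
    addNodes(unique(merged$mirna), "miRNA")
    addNodes(unique(merged$target), "direct_target")
    e <- data.frame(from = merged$mirna, to = merged$target,
                    type = "targets", evidence = merged$evidence,
                    stringsAsFactors = FALSE)
    if ("source" %in% names(merged)) e$source <- merged$source
    if ("correlation" %in% names(merged)) e$correlation <- merged$correlation
    edges[[length(edges) + 1L]] <- e
  }
  if (!is.null(tfMirna) && nrow(tfMirna)) {
    addNodes(unique(tfMirna$tf), "TF")
    addNodes(unique(tfMirna$mirna), "miRNA")
    e <- data.frame(from = tfMirna$tf, to = tfMirna$mirna,
                    type = "regulates", stringsAsFactors = FALSE)
    for (col in intersect(c("frequency", "p_value", "N", "K", "n", "k"),
                          names(tfMirna)))
      e[[col]] <- tfMirna[[col]]
    edges[[length(edges) + 1L]] <- e
  }
  if (!is.null(forest) && nrow(forest$nodes)) {
    indirect <- forest$indirect
    addNodes(forest$nodes$node[forest$nodes$node %in% indirect],
             "indirect_target")
    addNodes(forest$nodes$node[!forest$nodes$node %in% indirect],
             "direct_target")
    if (nrow(forest$edges))
      edges[[length(edges) + 1L]] <-
        data.frame(from = forest$edges$from, to = forest$edges$to,
                   type = "interacts", stringsAsFactors = FALSE)
  }
  nodeTab <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = character(), type = character(), stringsAsFactors = FALSE)
  # a node may be named by several layers; keep the most specific type
  prio <- c(TF = 1, miRNA = 2, direct_target = 3, indirect_target = 4,
            gene = 5)
  nodeTab <- nodeTab[order(nodeTab$id, prio[nodeTab$type]), , drop = FALSE]
  nodeTab <- nodeTab[!duplicated(nodeTab$id), , drop = FALSE]
  nodeTab <- nodeTab[order(nodeTab$id), , drop = FALSE]
  rownames(nodeTab) <- NULL
  edgeTab <- if (length(edges)) {
    cols <- unique(unlist(lapply(edges, names)))
    do.call(rbind, lapply(edges, function(e) {
      for (c0 in setdiff(cols, names(e))) e[[c0]] <- NA
      e[, cols, drop = FALSE]
    }))
  } else data.frame(from = character(), to = character(), type = character(),
                    stringsAsFactors = FALSE)
  edgeTab <- edgeTab[order(edgeTab$type, edgeTab$from, edgeTab$to), ,
                     drop = FALSE]
  rownames(edgeTab) <- NULL
  bad <- setdiff(c(edgeTab$from, edgeTab$to), nodeTab$id)
  if (length(bad))
    stop("dangling edge endpoint(s): ", paste(bad, collapse = ", "))
  new("RegulatoryNetwork", nodes = nodeTab, edges = edgeTab)
}

.asIgraph <- function(network) {
  nodes <- netNodes(network)
  edges <- netEdges(network)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Export a regulatory network
#'
#' Formats: `"sif"` (Cytoscape simple interaction format; interaction types
#' `regulates` for TF -> miRNA, `targets` for miRNA -> target, `interacts`
#' for gene -> gene), `"graphml"` (all node and edge attributes; re-import
#' with [importNetworkGraphML()] reproduces the graph), and `"cyjson"`
#' (Cytoscape.js-style JSON).
#'
#' @param network a [RegulatoryNetwork-class].
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"cyjson"`.
#' @return the path, invisibly; empty networks produce a valid empty document
#'   with a warning.
#' @export
exportNetwork <- function(network, path, format = c("sif", "graphml",
                                                    "cyjson")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown format '", format[1],
         "'; supported: sif, graphml, cyjson"))
  edges <- netEdges(network)
  nodes <- netNodes(network)
  if (nrow(nodes) == 0L) warning("exporting an empty network")
  if (format == "sif") {
    lines <- if (nrow(edges))
      paste(edges$from, edges$type, edges$to) else character(0)
    solo <- setdiff(nodes$id, c(edges$from, edges$to))
    writeLines(c(lines, solo), path)
  } else if (format == "graphml") {
    g <- .asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    cy <- list(elements = list(
      nodes = lapply(seq_len(nrow(nodes)), function(i)
        list(data = as.list(nodes[i, , drop = FALSE]))),
      edges = lapply(seq_len(nrow(edges)), function(i) {
        d <- as.list(edges[i, , drop = FALSE])
        names(d)[names(d) == "from"] <- "source"
        names(d)[names(d) == "to"] <- "target"
        list(data = d)
      })))
    jsonlite::write_json(cy, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Re-import a regulatory network from GraphML
#'
#' @param path a GraphML file written by [exportNetwork()].
#' @return a [RegulatoryNetwork-class] with identical nodes, edges and
#'   attributes.
#' @export
importNetworkGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  fixNa <- function(d) {
    for (j in seq_along(d))
      if (is.character(d[[j]])) d[[j]][d[[j]] == "NA"] <- NA_character_
    d
  }
  nodes <- igraph::as_data_frame(g, what = "vertices")
  names(nodes)[names(nodes) == "name"] <- "id"
  nodes <- fixNa(nodes[, c("id", setdiff(names(nodes), "id")), drop = FALSE])
  edges <- fixNa(igraph::as_data_frame(g, what = "edges"))
  names(edges)[names(edges) == "type"] <- "type"
  rownames(nodes) <- rownames(edges) <- NULL
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  new("RegulatoryNetwork", nodes = nodes, edges = edges)
}
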