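#' Construct a pathway graph
#'
#' A pathway is modeled as an undirected graph whose nodes (genes, enzyme
#' complexes, orthologs) carry sets of canonical gene identifiers. This is
#' the unit every enrichment computation runs over.
#'
#' @param pathway_id Short string key, unique within a universe.
#' @param name Free-text pathway name.
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column character matrix (or data.frame) of unordered
#'   node pairs. Self-loops and duplicate pairs are dropped.
#' @param node_genes Named list mapping node id to a character vector of
#'   canonical gene ids. Nodes absent from the list carry no genes.
#' @param is_disease_pathway,is_catchall Exclusion flags consulted by
#'   [filter_universe()].
#'
#' @return An object of class `pathway_graph`.
#' @seealso [read_kgml()], [read_pathway_tables()], [gene_count()]
#' @export
pathway_graph <- function(pathway_id, name = pathway_id, nodes = character(),
                          edges = NULL, node_genes = list(),
                          is_disease_pathway = FALSE, is_catchall = FALSE) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            nzchar(pathway_id))
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
    bad <- !(edges[, 1L] %in% nodes & edges[, 2L] %in% nodes)
    if (any(bad)) {
      stop(sprintf("pathway '%s': edge endpoint(s) not in node set: %s",
                   pathway_id,
                   paste(unique(c(edges[bad, ])), collapse = ", ")),
           call. = FALSE)
    }
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    # canonical unordered representation
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
    edges <- unique(edges)
  }
  if (length(node_genes) > 0) {
    unknown <- setdiff(names(node_genes), nodes)
    if (length(unknown) > 0) {
      stop(sprintf("pathway '%s': node_genes for unknown node(s): %s",
                   pathway_id, paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    node_genes <- lapply(node_genes, function(g) unique(as.character(g)))
  }
  structure(
    list(pathway_id = pathway_id, name = name, nodes = nodes, edges = edges,
         node_genes = node_genes,
         flags = c(is_disease_pathway = isTRUE(is_disease_pathway),
                   is_catchall = isTRUE(is_catchall))),
    class = "pathway_graph")
}

#' Number of distinct genes in a pathway
#'
#' @param graph A `pathway_graph`.
#' @return Integer count of the union of all node gene sets.
#' @export
gene_count <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  length(pathway_genes(graph))
}

#' Distinct genes of a pathway
#'
#' @param graph A `pathway_graph`.
#' @return Character vector, the union of all node gene sets.
#' @export
pathway_genes <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  unique(unlist(graph$node_genes, use.names = FALSE)) %||% character()
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s' (%s): %d nodes, %d edges, %d genes",
              x$pathway_id, x$name, length(x$nodes), nrow(x$edges),
              gene_count(x)))
  if (any(x$flags)) {
    cat(" [", paste(names(x$flags)[x$flags], collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Construct a pathway universe
#'
#' The universe is the ordered collection of pathways within which all
#' enrichment and overlap statistics are computed; its size `M` after
#' filtering is the `M` of the hypergeometric linkage test.
#'
#' @param pathways List of `pathway_graph` objects with unique ids.
#' @param filter_log Optional data.frame recording, per pathway, whether it
#'   was retained and the exclusion reason otherwise (set by
#'   [filter_universe()]).
#' @return An object of class `pathway_universe` with elements `pathways`
#'   (named list), `M` (number of pathways held) and `filter_log`.
#' @export
pathway_universe <- function(pathways, filter_log = NULL) {
  stopifnot(is.list(pathways))
  ok <- vapply(pathways, inherits, logical(1), "pathway_graph")
  if (!all(ok)) stop("all elements must be pathway_graph objects", call. = FALSE)
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate pathway id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(pathways) <- ids
  structure(list(pathways = pathways, M = length(pathways),
                 filter_log = filter_log),
            class = "pathway_universe")
}

#' @export
print.pathway_universe <- function(x, ...) {
  cat(sprintf("pathway_universe: M = %d pathway(s)%s\n", x$M,
              if (is.null(x$filter_log)) " (unfiltered)" else " (filtered)"))
  invisible(x)
}

#' Apply the pathway universe filter
#'
#' Excludes pathways with fewer than `min_genes` distinct genes, pathways
#' flagged as disease/health-condition pathways, and catch-all pathways.
#' The default `min_genes = 4` excludes pathways with 3 or fewer genes.
#' Each excluded pathway carries exactly one reason; gene count is checked
#' first, then the disease flag, then the catch-all flag.
#'
#' @param universe A `pathway_universe`.
#' @param min_genes Minimum number of distinct genes to retain (default 4).
#' @return A filtered `pathway_universe` whose `M` is the retained count
#'   and whose `filter_log` has columns `pathway_id`, `retained`, `reason`
#'   (one of `retained`, `too_few_genes`, `disease_pathway`, `catchall`).
#' @export
filter_universe <- function(universe, min_genes = 4L) {
  stopifnot(inherits(universe, "pathway_universe"), min_genes >= 0)
  reason <- vapply(universe$pathways, function(p) {
    if (gene_count(p) < min_genes) "too_few_genes"
    else if (p$flags[["is_disease_pathway"]]) "disease_pathway"
    else if (p$flags[["is_catchall"]]) "catchall"
    else "retained"
  }, character(1))
  log <- data.frame(pathway_id = names(universe$pathways),
                    retained = reason == "retained",
                    reason = reason, row.names = NULL,
                    stringsAsFactors = FALSE)
  kept <- universe$pathways[log$retained]
  if (length(kept) == 0L) message("filter_universe: no pathways retained")
  pathway_universe(kept, filter_log = log)
}

#' All-pairs node distances within a pathway
#'
#' Breadth-first shortest-path lengths (in edge steps) on the undirected
#' pathway graph. Used by the topology-weighted statistic to weight node
#' pairs by proximity.
#'
#' @param graph A `pathway_graph`.
#' @return A symmetric numeric matrix with node ids as dimnames; entries
#'   are path lengths, `0` on the diagonal, and `Inf` for node pairs in
#'   different components.
#' @export
node_distances <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  n <- length(graph$nodes)
  if (n == 0L) {
    return(matrix(numeric(), 0, 0))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$nodes)
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, t(graph$edges))
  }
  d <- igraph::distances(g, mode = "all")
  d[graph$nodes, graph$nodes, drop = FALSE]
}
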