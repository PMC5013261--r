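# Independent oracles and tiny fixtures used across the suite. These are
# deliberately naive (enumeration, brute force) and share no code with the
# implementation paths they check.

# Shortest path lengths by exhaustive enumeration of all simple paths.
# Only usable for graphs with <= ~7 nodes.
oracle_shortest_paths <- function(nodes, edges) {
  adj <- setNames(lapply(nodes, function(n) character()), nodes)
  if (NROW(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1]; v <- edges[i, 2]
      adj[[u]] <- union(adj[[u]], v)
      adj[[v]] <- union(adj[[v]], u)
    }
  }
  best <- matrix(Inf, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  diag(best) <- 0
  walk <- function(path) {
    tail <- path[length(path)]
    best[path[1], tail] <<- min(best[path[1], tail], length(path) - 1)
    for (nb in setdiff(adj[[tail]], path)) walk(c(path, nb))
  }
  for (n in nodes) walk(n)
  pmin(best, t(best))
}

# Upper-tail overlap probability by enumerating every K-subset of 1..M
# against the fixed disease subset 1..N.
oracle_link_probability <- function(X, M, K, N) {
  if (X == 0) return(1)
  if (K == 0 || N == 0) return(0)
  subsets <- utils::combn(M, K)
  mean(apply(subsets, 2, function(s) sum(s <= N) >= X))
}

# Pathway statistic by direct nested-loop evaluation of the formula.
oracle_pathway_statistic <- function(rho_node, dist, lambda, D) {
  nodes <- names(rho_node)
  s <- sum(rho_node)
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in (i + 1):length(nodes)) {
        d <- dist[nodes[i], nodes[j]]
        if (is.finite(d) && d >= 1 && d <= D) {
          s <- s + lambda^(d - 1) * rho_node[[i]] * rho_node[[j]]
        }
      }
    }
  }
  s
}

# A hand-written KGML document: two gene entries, one group entry with
# three genes via components, one relation (plus an optional bad one).
kgml_fixture <- function(bad_relation = FALSE) {
  rel_extra <- if (bad_relation)
    '<relation entry1="1" entry2="99" type="PPrel"/>' else ""
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:test01" org="hsa" number="00001" ',
    'title="Test pathway">\n',
    '  <entry id="1" name="hsa:111" type="gene"/>\n',
    '  <entry id="2" name="hsa:222 hsa:333" type="gene"/>\n',
    '  <entry id="3" name="undefined" type="group">\n',
    '    <component id="1"/>\n',
    '    <component id="2"/>\n',
    '  </entry>\n',
    '  <entry id="4" name="path:map00002" type="map"/>\n',
    '  <relation entry1="1" entry2="2" type="PPrel"/>\n',
    '  ', rel_extra, '\n',
    '</pathway>\n')
}

# A small five-pathway universe with known structure, built in code.
tiny_universe <- function() {
  mk <- function(id, genes, edges = NULL, dz = FALSE, ca = FALSE) {
    nodes <- paste0(id, "_n", seq_along(genes))
    ng <- as.list(genes)
    names(ng) <- nodes
    if (!is.null(edges)) {
      edges <- cbind(paste0(id, "_n", edges[, 1]),
                     paste0(id, "_n", edges[, 2]))
    }
    pathway_graph(id, nodes = nodes, edges = edges, node_genes = ng,
                  is_disease_pathway = dz, is_catchall = ca)
  }
  path4 <- cbind(1:3, 2:4)  # path graph on 4 nodes
  pathway_universe(list(
    mk("Q1", c("ga", "gb", "gc", "gd"), path4),
    mk("Q2", c("ge", "gf", "gg", "gh"), path4),
    mk("Q3", c("gi", "gj")),                      # too few genes
    mk("Q4", c("gk", "gl", "gm", "gn"), path4, dz = TRUE),
    mk("Q5", c("go", "gp", "gq", "gr"), path4, ca = TRUE)))
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
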