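#' Read a pathway from a KGML document
#'
#' Parses a KEGG Markup Language (KGML) XML file into a [pathway_graph()].
#' Entries of type `gene`, `ortholog` and `group` become nodes; every
#' `relation` between retained entries becomes one undirected edge. A
#' `group` entry becomes a single node carrying the union of its component
#' entries' genes (KEGG's enzyme-complex semantics). Gene identifiers of
#' the form `hsa:1234` (any organism prefix) are parsed to the canonical
#' integer part; bare identifiers are kept as-is.
#'
#' Relations naming an entry id that is not a retained node are skipped
#' with a warning rather than failing the whole document.
#'
#' @param path Path to a KGML file (or a literal XML string).
#' @return A `pathway_graph` with both exclusion flags `FALSE`.
#' @export
read_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop(sprintf("malformed KGML in '%s': %s",
                                 if (file.exists(path)) path else "<string>",
                                 conditionMessage(e)), call. = FALSE)
                  })
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("KGML document has no <pathway> root", call. = FALSE)
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- xml2::xml_attr(root, "number")
  if (is.na(pid)) pid <- "pathway"
  pname <- xml2::xml_attr(root, "title")
  if (is.na(pname)) pname <- pid

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  etype <- xml2::xml_attr(entries, "type")
  eid <- xml2::xml_attr(entries, "id")
  keep <- etype %in% c("gene", "ortholog", "group")
  entries <- entries[keep]
  eid <- eid[keep]
  etype <- etype[keep]

  parse_genes <- function(name_attr) {
    if (is.na(name_attr) || !nzchar(name_attr)) return(character())
    toks <- strsplit(trimws(name_attr), "\\s+")[[1]]
    toks <- toks[toks != "undefined"]
    sub("^[A-Za-z.]+:", "", toks)
  }
  genes_by_entry <- lapply(entries, function(e) {
    parse_genes(xml2::xml_attr(e, "name"))
  })
  names(genes_by_entry) <- eid

  # group entries: union of the genes of their component entries
  node_genes <- genes_by_entry
  for (i in which(etype == "group")) {
    comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "component"), "id")
    comp <- intersect(comp, eid)
    node_genes[[eid[i]]] <- unique(c(
      genes_by_entry[[eid[i]]],
      unlist(genes_by_entry[comp], use.names = FALSE)))
  }

  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  e1 <- xml2::xml_attr(rels, "entry1")
  e2 <- xml2::xml_attr(rels, "entry2")
  known <- e1 %in% eid & e2 %in% eid
  if (any(!known)) {
    warning(sprintf(
      "read_kgml('%s'): skipped %d relation(s) naming unknown entry id(s)",
      pid, sum(!known)), call. = FALSE)
  }
  edges <- cbind(e1[known], e2[known])

  node_genes <- node_genes[lengths(node_genes) > 0]
  pathway_graph(pathway_id = pid, name = pname, nodes = eid,
                edges = edges, node_genes = node_genes)
}

#' Read an unfiltered pathway universe from plain tables
#'
#' Plain-text alternative to KGML for pathway definitions. All three files
#' are UTF-8, tab-delimited, with a header row.
#'
#' @param nodes_file TSV with columns `pathway_id`, `node_id`, `gene_id`.
#'   Rows with a blank `gene_id` create gene-less nodes.
#' @param edges_file TSV with columns `pathway_id`, `node_u`, `node_v`.
#' @param flags_file Optional TSV with columns `pathway_id`,
#'   `is_disease_pathway`, `is_catchall` (values `0`/`1` or
#'   `TRUE`/`FALSE`). Pathways absent from the file carry `FALSE` flags.
#' @return An unfiltered `pathway_universe`, one `pathway_graph` per
#'   distinct `pathway_id`, in first-appearance order.
#' @export
read_pathway_tables <- function(nodes_file, edges_file, flags_file = NULL) {
  nd <- read_tsv_checked(nodes_file, c("pathway_id", "node_id", "gene_id"),
                         "nodes")
  ed <- read_tsv_checked(edges_file, c("pathway_id", "node_u", "node_v"),
                         "edges")
  flags <- NULL
  if (!is.null(flags_file)) {
    flags <- read_tsv_checked(
      flags_file, c("pathway_id", "is_disease_pathway", "is_catchall"),
      "flags")
  }

  bad_pw <- setdiff(unique(ed$pathway_id), unique(nd$pathway_id))
  if (length(bad_pw) > 0) {
    stop(sprintf("edges file references pathway(s) absent from nodes file: %s",
                 paste(bad_pw, collapse = ", ")), call. = FALSE)
  }

  as_flag <- function(x) {
    tolower(trimws(x)) %in% c("1", "true", "t", "yes")
  }
  pids <- unique(nd$pathway_id)
  graphs <- lapply(pids, function(pid) {
    nrows <- nd[nd$pathway_id == pid, , drop = FALSE]
    erows <- ed[ed$pathway_id == pid, , drop = FALSE]
    nodes <- unique(nrows$node_id)
    bad <- !(erows$node_u %in% nodes & erows$node_v %in% nodes)
    if (any(bad)) {
      stop(sprintf(
        "pathway '%s': edge row(s) %s name node(s) absent from nodes file",
        pid, paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    withg <- nrows[nzchar(trimws(nrows$gene_id)), , drop = FALSE]
    node_genes <- split(withg$gene_id, withg$node_id)
    dz <- FALSE; ca <- FALSE
    if (!is.null(flags)) {
      fr <- flags[flags$pathway_id == pid, , drop = FALSE]
      if (nrow(fr) > 0) {
        dz <- as_flag(fr$is_disease_pathway[1])
        ca <- as_flag(fr$is_catchall[1])
      }
    }
    pathway_graph(pathway_id = pid, nodes = nodes,
                  edges = erows[, c("node_u", "node_v"), drop = FALSE],
                  node_genes = node_genes,
                  is_disease_pathway = dz, is_catchall = ca)
  })
  pathway_universe(graphs)
}
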