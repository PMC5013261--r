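# Synthetic pathway universes, expression datasets and association tables
# with known planted structure. Every generator is a pure function of its
# seed, so fixtures are built in code at test time rather than shipped.

#' Parameters for a synthetic pathway universe
#'
#' @param n_pathways Number of clean (retainable) pathways.
#' @param gene_range Length-2 integer vector: min/max genes per clean
#'   pathway (one gene per node by default).
#' @param edge_density Probability of each extra edge beyond the spanning
#'   tree that keeps every pathway connected. Default 0.25.
#' @param n_too_small Pathways generated with 3 or fewer genes, which the
#'   universe filter must remove. Default 0.
#' @param n_flagged Pathways flagged as disease/catch-all (alternating),
#'   which the filter must remove. Default 0.
#' @param gene_pool Size of the gene identifier pool; must cover the
#'   total demand (genes are drawn without replacement, so synthetic
#'   pathways are gene-disjoint). Default 10000.
#' @param multi_gene_nodes If `TRUE`, roughly a quarter of nodes carry
#'   two genes, exercising the node projection. Default `FALSE`.
#' @return A list of class `universe_params`.
#' @export
universe_params <- function(n_pathways = 50L, gene_range = c(4L, 8L),
                            edge_density = 0.25, n_too_small = 0L,
                            n_flagged = 0L, gene_pool = 10000L,
                            multi_gene_nodes = FALSE) {
  stopifnot(n_pathways >= 1, length(gene_range) == 2,
            gene_range[1] >= 1, gene_range[2] >= gene_range[1],
            edge_density >= 0, edge_density <= 1,
            n_too_small >= 0, n_flagged >= 0, gene_pool >= 1)
  structure(list(n_pathways = as.integer(n_pathways),
                 gene_range = as.integer(gene_range),
                 edge_density = edge_density,
                 n_too_small = as.integer(n_too_small),
                 n_flagged = as.integer(n_flagged),
                 gene_pool = as.integer(gene_pool),
                 multi_gene_nodes = isTRUE(multi_gene_nodes)),
            class = "universe_params")
}

# Connected random graph: uniform random spanning tree (random attachment)
# plus independent extra edges at the stated density.
#' @keywords internal
random_connected_edges <- function(nodes, density) {
  n <- length(nodes)
  if (n < 2) return(matrix(character(), ncol = 2))
  to <- vapply(2:n, function(i) nodes[sample.int(i - 1L, 1L)], character(1))
  edges <- cbind(nodes[2:n], to)
  if (n > 2 && density > 0) {
    pairs <- t(utils::combn(nodes, 2))
    intree <- paste(pmin(pairs[, 1], pairs[, 2]),
                    pmax(pairs[, 1], pairs[, 2])) %in%
              paste(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]))
    extra <- pairs[!intree & stats::runif(nrow(pairs)) < density, ,
                   drop = FALSE]
    edges <- rbind(edges, extra)
  }
  edges
}

#' Generate a synthetic pathway universe
#'
#' Builds `n_pathways` clean connected pathways plus the demanded
#' too-small and flagged pathways, in that order, with ids `P01`, `P02`,
#' ... Genes are drawn from the pool without replacement, so distinct
#' pathways never share a gene and planted signals stay attributable.
#'
#' @param params A [universe_params()] list.
#' @param seed Integer seed; identical seeds give identical universes.
#' @return List with elements `universe` (unfiltered `pathway_universe`)
#'   and `catalog` (data.frame: `pathway_id`, `role` in
#'   clean/too_small/flagged, `n_genes`).
#' @export
make_universe <- function(params = universe_params(), seed = 1L) {
  stopifnot(inherits(params, "universe_params"))
  with_seed(seed, {
    total <- params$n_pathways + params$n_too_small + params$n_flagged
    roles <- c(rep("clean", params$n_pathways),
               rep("too_small", params$n_too_small),
               rep("flagged", params$n_flagged))
    sizes <- integer(total)
    for (i in seq_len(total)) {
      sizes[i] <- if (roles[i] == "too_small") sample(1:3, 1L)
                  else sample(params$gene_range[1]:params$gene_range[2], 1L)
    }
    extra_genes <- if (params$multi_gene_nodes) ceiling(sizes / 4L)
                   else integer(total)
    demand <- sum(sizes + extra_genes)
    if (demand > params$gene_pool) {
      stop(sprintf("gene pool of %d cannot supply %d genes",
                   params$gene_pool, demand), call. = FALSE)
    }
    pool <- sample(sprintf("g%05d", seq_len(params$gene_pool)), demand)
    used <- 0L
    width <- max(2L, nchar(as.character(total)))
    graphs <- vector("list", total)
    flag_disease <- TRUE
    for (i in seq_len(total)) {
      pid <- sprintf("P%0*d", width, i)
      n_nodes <- sizes[i]
      nodes <- sprintf("%s_n%d", pid, seq_len(n_nodes))
      n_genes <- sizes[i] + extra_genes[i]
      genes <- pool[used + seq_len(n_genes)]
      used <- used + n_genes
      node_genes <- as.list(genes[seq_len(n_nodes)])
      names(node_genes) <- nodes
      if (extra_genes[i] > 0L) {
        host <- sample.int(n_nodes, extra_genes[i],
                           replace = extra_genes[i] > n_nodes)
        for (k in seq_len(extra_genes[i])) {
          node_genes[[host[k]]] <- c(node_genes[[host[k]]],
                                     genes[n_nodes + k])
        }
      }
      dz <- ca <- FALSE
      if (roles[i] == "flagged") {
        if (flag_disease) dz <- TRUE else ca <- TRUE
        flag_disease <- !flag_disease
      }
      graphs[[i]] <- pathway_graph(
        pathway_id = pid, name = sprintf("synthetic pathway %d", i),
        nodes = nodes,
        edges = random_connected_edges(nodes, params$edge_density),
        node_genes = node_genes,
        is_disease_pathway = dz, is_catchall = ca)
    }
    catalog <- data.frame(
      pathway_id = vapply(graphs, function(g) g$pathway_id, character(1)),
      role = roles,
      n_genes = vapply(graphs, gene_count, integer(1)),
      stringsAsFactors = FALSE)
    list(universe = pathway_universe(graphs), catalog = catalog)
  })
}

#' Simulate an expression dataset with a planted pathway signal
#'
#' Background genes (the universe's genes plus `n_background_genes` extra
#' `bg...` genes) draw from a null distribution; genes of the planted
#' pathways draw from a shifted alternative with effect size `delta`:
#'
#' * `ONE_MINUS_P`: background Uniform(0, 1); planted
#'   Uniform(1 - delta, 1).
#' * `LOG2_RATIO`: background Normal(0, 1); planted
#'   (Normal(0, 1) + 3 * delta) with a random sign.
#' * `INDICATOR`: background Bernoulli(0.05); planted
#'   Bernoulli(min(1, 0.05 + delta)).
#'
#' At `delta = 0` planted genes are distributionally identical to
#' background.
#'
#' @param universe A `pathway_universe` (filtered or not).
#' @param planted_ids Pathway ids whose genes carry the signal.
#' @param delta Effect size in \[0, 1\].
#' @param measure_type Measure convention to emit.
#' @param n_background_genes Extra measured genes outside all pathways.
#' @param seed Integer seed.
#' @param code Dataset label.
#' @return An `expression_dataset`.
#' @export
simulate_dataset <- function(universe, planted_ids = character(),
                             delta = 0.2, measure_type = "ONE_MINUS_P",
                             n_background_genes = 2000L, seed = 1L,
                             code = "sim") {
  stopifnot(inherits(universe, "pathway_universe"),
            delta >= 0, delta <= 1)
  measure_type <- match.arg(measure_type, MEASURE_TYPES)
  stray <- setdiff(planted_ids, names(universe$pathways))
  if (length(stray) > 0) {
    stop(sprintf("planted pathway id(s) not in universe: %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  pw_genes <- unique(unlist(lapply(universe$pathways, pathway_genes)))
  planted <- unique(unlist(lapply(universe$pathways[planted_ids],
                                  pathway_genes))) %||% character()
  bg_extra <- if (n_background_genes > 0)
    sprintf("bg%05d", seq_len(n_background_genes)) else character()
  genes <- c(pw_genes, bg_extra)
  is_planted <- genes %in% planted
  n <- length(genes)
  with_seed(seed, {
    vals <- switch(measure_type,
      ONE_MINUS_P = {
        v <- stats::runif(n)
        # delta = 0 means no signal: planted genes keep their null draw
        # (Uniform(1 - 0, 1) would be a point mass, not the null)
        if (delta > 0) {
          v[is_planted] <- stats::runif(sum(is_planted), 1 - delta, 1)
        }
        v
      },
      LOG2_RATIO = {
        v <- stats::rnorm(n)
        k <- sum(is_planted)
        v[is_planted] <- (stats::rnorm(k) + 3 * delta) *
          sample(c(-1, 1), k, replace = TRUE)
        v
      },
      INDICATOR = {
        v <- as.numeric(stats::runif(n) < 0.05)
        k <- sum(is_planted)
        v[is_planted] <- as.numeric(stats::runif(k) < min(1, 0.05 + delta))
        v
      })
    expression_dataset(stats::setNames(vals, genes), measure_type,
                       code = code, field_type = "synthetic",
                       provenance = sprintf(
                         "simulated (delta=%g, %d planted gene(s), seed=%d)",
                         delta, sum(is_planted), seed))
  })
}

#' Simulate a gene-disease association table
#'
#' For each disease class, every gene of its planted pathways is recorded
#' as associated with probability `plant_prob`, and every other gene of
#' the universe with probability `background_rate`.
#'
#' @param universe A `pathway_universe`.
#' @param disease_plants Named list: disease class label -> character
#'   vector of planted pathway ids.
#' @param background_rate Association probability for non-planted genes.
#' @param seed Integer seed.
#' @param plant_prob Association probability for planted-pathway genes
#'   (default 0.8; set to 1 for a deterministic plant).
#' @return An `association_table`.
#' @export
simulate_associations <- function(universe, disease_plants,
                                  background_rate = 0.05, seed = 1L,
                                  plant_prob = 0.8) {
  stopifnot(inherits(universe, "pathway_universe"),
            is.list(disease_plants),
            background_rate >= 0, background_rate <= 1,
            plant_prob >= 0, plant_prob <= 1)
  all_genes <- unique(unlist(lapply(universe$pathways, pathway_genes)))
  with_seed(seed, {
    recs <- lapply(names(disease_plants), function(cls) {
      ids <- disease_plants[[cls]]
      stray <- setdiff(ids, names(universe$pathways))
      if (length(stray) > 0) {
        stop(sprintf("disease '%s' planted on unknown pathway(s): %s",
                     cls, paste(stray, collapse = ", ")), call. = FALSE)
      }
      planted <- unique(unlist(lapply(universe$pathways[ids],
                                      pathway_genes))) %||% character()
      pr <- ifelse(all_genes %in% planted, plant_prob, background_rate)
      hit <- all_genes[stats::runif(length(all_genes)) < pr]
      if (length(hit) == 0L) return(NULL)
      data.frame(gene_id = hit, disease_class = cls,
                 stringsAsFactors = FALSE)
    })
    recs <- recs[!vapply(recs, is.null, logical(1))]
    df <- if (length(recs) > 0) do.call(rbind, recs)
          else data.frame(gene_id = character(),
                          disease_class = character(),
                          stringsAsFactors = FALSE)
    association_table(df)
  })
}

#' The shipped default synthetic scenario
#'
#' A 50-pathway clean universe (plus 2 too-small and 2 flagged pathways
#' for the filter to remove), 2000 background genes, an exposure signal
#' of effect size `delta = 0.2` planted on 5 pathways, one disease
#' planted on the same 5 pathways (`matched`) and one on 5 disjoint
#' pathways (`control`), with background association rate 0.05 and
#' 999 permutations. The intended truth is one real exposure-disease
#' link (matched) and one null link (control).
#'
#' @param seed Integer seed driving every generator in the scenario.
#' @param delta Planted effect size.
#' @param permutations Permutation count for enrichment.
#' @return A list of class `synthetic_scenario` with fields `seed`,
#'   `params`, `planted_exposure`, `disease_plants`, `delta`,
#'   `measure_type`, `n_background_genes`, `background_rate`,
#'   `permutations`.
#' @export
default_scenario <- function(seed = 1L, delta = 0.2, permutations = 999L) {
  structure(list(
    seed = as.integer(seed),
    params = universe_params(n_pathways = 50L, gene_range = c(4L, 8L),
                             edge_density = 0.25, n_too_small = 2L,
                             n_flagged = 2L),
    planted_exposure = sprintf("P%02d", 1:5),
    disease_plants = list(matched = sprintf("P%02d", 1:5),
                          control = sprintf("P%02d", 6:10)),
    delta = delta,
    measure_type = "ONE_MINUS_P",
    n_background_genes = 2000L,
    background_rate = 0.05,
    permutations = as.integer(permutations)),
    class = "synthetic_scenario")
}

#' Expected linkage truth of a scenario
#'
#' @param scenario A `synthetic_scenario`.
#' @return Data.frame with one row per (dataset, disease) pair:
#'   `dataset`, `disease`, `expected_overlap` (the size of the
#'   intersection of the planted pathway sets).
#' @export
scenario_truth <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  do.call(rbind, lapply(names(scenario$disease_plants), function(cls) {
    data.frame(dataset = "sim", disease = cls,
               expected_overlap = length(intersect(
                 scenario$planted_exposure,
                 scenario$disease_plants[[cls]])),
               stringsAsFactors = FALSE)
  }))
}

#' Materialize a scenario's inputs
#'
#' Generates the universe, expression dataset and association table of a
#' scenario in memory (all derived deterministically from the scenario
#' seed).
#'
#' @param scenario A `synthetic_scenario`.
#' @return List with `universe` (unfiltered), `catalog`, `dataset`,
#'   `associations`, `truth`.
#' @export
realize_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  mu <- make_universe(scenario$params, seed = scenario$seed)
  ds <- simulate_dataset(mu$universe, scenario$planted_exposure,
                         delta = scenario$delta,
                         measure_type = scenario$measure_type,
                         n_background_genes = scenario$n_background_genes,
                         seed = scenario$seed + 1000L, code = "sim")
  assoc <- simulate_associations(mu$universe, scenario$disease_plants,
                                 background_rate = scenario$background_rate,
                                 seed = scenario$seed + 2000L)
  list(universe = mu$universe, catalog = mu$catalog, dataset = ds,
       associations = assoc, truth = scenario_truth(scenario))
}

#' Write a universe as plain pathway tables
#'
#' Emits the three TSV files read back by [read_pathway_tables()].
#'
#' @param universe A `pathway_universe`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_universe_tables <- function(universe, dir) {
  stopifnot(inherits(universe, "pathway_universe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- do.call(rbind, lapply(universe$pathways, function(p) {
    genes <- lapply(p$nodes, function(nd) {
      g <- p$node_genes[[nd]]
      if (is.null(g) || length(g) == 0L) "" else g
    })
    data.frame(pathway_id = p$pathway_id,
               node_id = rep(p$nodes, lengths(genes)),
               gene_id = unlist(genes), stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(universe$pathways, function(p) {
    if (nrow(p$edges) == 0L) return(NULL)
    data.frame(pathway_id = p$pathway_id, node_u = p$edges[, 1],
               node_v = p$edges[, 2], stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(pathway_id = character(), node_u = character(),
                        node_v = character(), stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, lapply(universe$pathways, function(p) {
    data.frame(pathway_id = p$pathway_id,
               is_disease_pathway = as.integer(p$flags[["is_disease_pathway"]]),
               is_catchall = as.integer(p$flags[["is_catchall"]]),
               stringsAsFactors = FALSE)
  }))
  paths <- c(nodes = file.path(dir, "pathway_nodes.tsv"),
             edges = file.path(dir, "pathway_edges.tsv"),
             flags = file.path(dir, "pathway_flags.tsv"))
  write_tsv_plain(nodes, paths[["nodes"]])
  write_tsv_plain(edges, paths[["edges"]])
  write_tsv_plain(flags, paths[["flags"]])
  invisible(paths)
}

#' Write an expression dataset as a scores TSV
#'
#' @param dataset An `expression_dataset`.
#' @param path Output file (columns `gene_id`, `value`).
#' @return The path, invisibly.
#' @export
write_scores <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  write_tsv_plain(data.frame(gene_id = names(dataset$values),
                             value = unname(dataset$values),
                             stringsAsFactors = FALSE), path)
}

#' Write an association table as TSV
#'
#' @param assoc An `association_table`.
#' @param path Output file (columns `gene_id`, `disease_class`).
#' @return The path, invisibly.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_table"))
  write_tsv_plain(as.data.frame(assoc), path)
}
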