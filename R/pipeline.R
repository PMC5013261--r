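# Orchestration: run the three linkage steps end to end from a
# configuration and emit the report bundle (filter log, per-dataset
# enrichment, disease-set table, linkage matrix, shared-pathway footnotes,
# machine-readable manifest).

RUN_CONFIG_KEYS <- c(
  "pathways_nodes", "pathways_edges", "pathways_flags", "kgml_dir",
  "scores", "assoc", "idmap", "out_dir",
  "alpha_disease", "alpha_exposure", "min_genes",
  "lambda_decay", "max_distance", "permutations", "seed", "statistic",
  "universe_m_policy")

#' Build a pipeline run configuration
#'
#' @param ... Configuration entries. Recognized keys: `pathways_nodes`,
#'   `pathways_edges`, `pathways_flags` (plain pathway tables) or
#'   `kgml_dir` (directory of KGML files); `scores` (named list:
#'   dataset code -> list(file=, measure_type=)); `assoc` (association
#'   TSV); `idmap` (optional identifier map applied to every scores
#'   file); `out_dir`; thresholds `alpha_disease` (default 0.01),
#'   `alpha_exposure` (default 0.05); `min_genes` (default 4);
#'   enrichment parameters `lambda_decay`, `max_distance`,
#'   `permutations`, `seed`, `statistic`; `universe_m_policy`
#'   (`"filtered"`, the default: one shared M; or `"evaluable"`:
#'   per-dataset M counting only evaluable pathways).
#'   Unknown keys are rejected.
#' @return A list of class `run_config` with all defaults resolved.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown run_config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults <- list(alpha_disease = 0.01, alpha_exposure = 0.05,
                   min_genes = 4L, lambda_decay = 0.5, max_distance = 3L,
                   permutations = 10000L, seed = 1L,
                   statistic = "topology_weighted",
                   universe_m_policy = "filtered")
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  stopifnot(cfg$universe_m_policy %in% c("filtered", "evaluable"))
  structure(cfg, class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. The `scores`
#' key may repeat, each value `CODE=FILE:MEASURE`.
#'
#' @param path Configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  scores <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("config line without '=': %s", ln),
                     call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (key == "scores") {
      scores <- c(scores, parse_scores_spec(val))
    } else {
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num) &&
                        key %in% c("alpha_disease", "alpha_exposure",
                                   "min_genes", "lambda_decay",
                                   "max_distance", "permutations",
                                   "seed")) num else val
    }
  }
  if (length(scores) > 0) cfg$scores <- scores
  do.call(run_config, cfg)
}

# "CODE=FILE:MEASURE" -> named list entry
#' @keywords internal
parse_scores_spec <- function(spec) {
  m <- regmatches(spec, regexec("^([^=]+)=(.+):([A-Z0-9_]+)$", spec))[[1]]
  if (length(m) != 4) {
    stop(sprintf("scores spec must be CODE=FILE:MEASURE, got '%s'", spec),
         call. = FALSE)
  }
  out <- list(list(file = m[3], measure_type = m[4]))
  names(out) <- m[2]
  out
}

#' Run the full exposure-disease linkage pipeline
#'
#' Executes the three steps — universe filtering plus per-dataset
#' enrichment, disease-class enrichment of the association table, and
#' hypergeometric overlap testing — and writes the report bundle into
#' `config$out_dir`:
#'
#' * `filter_log.tsv` — per-pathway retained/excluded + reason,
#' * `enrichment_<code>.tsv` — one per dataset,
#' * `disease_sets.tsv` — disease class, gene count, pathway count,
#' * `linkage_matrix.tsv` — datasets x disease classes, 4-decimal cells,
#'   zero-overlap cells rendered as a dash, trailing linked-pathway count,
#' * `linkage_long.tsv` — machine-readable rows with numeric p always,
#' * `shared_pathways.tsv` — the footnote analog per significant cell,
#' * `manifest.json` — seed, package version, effective configuration.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory objects: `universe`,
#'   `enrichments`, `exposure_sets`, `disease_sets`, `linkage`
#'   (long-format data.frame), `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out_dir <- config$out_dir %||% stop("run_config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    message(sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...)))
  }

  # -- step 0: pathway universe ------------------------------------------
  universe <- stage("read_pathways", {
    if (!is.null(config$kgml_dir)) {
      files <- list.files(config$kgml_dir, pattern = "\\.xml$",
                          full.names = TRUE)
      pathway_universe(lapply(sort(files), read_kgml))
    } else {
      read_pathway_tables(config$pathways_nodes, config$pathways_edges,
                          config$pathways_flags)
    }
  })
  universe <- stage("filter_universe",
                    filter_universe(universe, config$min_genes))
  files <- c(filter_log = file.path(out_dir, "filter_log.tsv"))
  write_tsv_plain(universe$filter_log, files[["filter_log"]])
  log_stage("universe filtered: M = %d", universe$M)

  idmap <- if (!is.null(config$idmap)) read_idmap(config$idmap) else NULL
  cfg_enr <- enrichment_config(
    lambda_decay = config$lambda_decay,
    max_distance = config$max_distance,
    permutations = config$permutations,
    seed = config$seed, statistic = config$statistic)

  # -- step 1: exposure datasets -> pathways -----------------------------
  stopifnot(!is.null(config$scores), length(config$scores) > 0)
  codes <- names(config$scores)
  enrichments <- list()
  exposure_sets <- list()
  for (i in seq_along(codes)) {
    code <- codes[i]
    sp <- config$scores[[i]]
    ds <- stage(paste0("read_scores:", code),
                read_scores(sp$file, sp$measure_type, code = code))
    if (!is.null(idmap)) ds <- map_ids(ds, idmap)$dataset
    cfg_i <- cfg_enr
    if (!is.null(cfg_i$seed)) cfg_i$seed <- cfg_i$seed + 10000L * i
    res <- stage(paste0("enrich:", code), enrich_all(universe, ds, cfg_i))
    enrichments[[code]] <- res
    exposure_sets[[code]] <-
      exposure_pathway_sets(res, owner = code,
                            alpha = config$alpha_exposure)
    f <- file.path(out_dir, sprintf("enrichment_%s.tsv", code))
    files[[paste0("enrichment_", code)]] <- f
    write_enrichment(res, f)
    log_stage("dataset %s enriched: K = %d", code,
              exposure_sets[[code]]$size)
  }

  # -- step 2: disease classes -> pathways -------------------------------
  disease_sets <- stage("disease_map", {
    assoc <- read_associations(config$assoc)
    cfg_d <- cfg_enr
    if (!is.null(cfg_d$seed)) cfg_d$seed <- cfg_d$seed + 500000L
    disease_pathway_sets(assoc, universe, cfg_d,
                         alpha = config$alpha_disease)
  })
  dtab <- data.frame(
    disease_class = names(disease_sets),
    n_genes = vapply(disease_sets,
                     function(s) attr(s, "n_genes") %||% 0L, numeric(1)),
    n_pathways = vapply(disease_sets, function(s) s$size, integer(1)),
    stringsAsFactors = FALSE)
  files[["disease_sets"]] <- file.path(out_dir, "disease_sets.tsv")
  write_tsv_plain(dtab, files[["disease_sets"]])
  log_stage("disease sets built: %d class(es)", length(disease_sets))

  # -- step 3: overlap test ----------------------------------------------
  linkage <- stage("linkage", {
    rows <- list()
    for (code in codes) {
      m_arg <- if (config$universe_m_policy == "evaluable") {
        sum(enrichments[[code]]$evaluable)
      } else universe
      for (cls in names(disease_sets)) {
        lr <- link_exposure_disease(exposure_sets[[code]],
                                    disease_sets[[cls]], m_arg)
        lr$shared_pathway_ids <-
          paste(attr(lr, "shared_pathway_ids"), collapse = ";")
        rows[[length(rows) + 1L]] <- as.data.frame(lr)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  files[["linkage_long"]] <- file.path(out_dir, "linkage_long.tsv")
  write_tsv_plain(linkage, files[["linkage_long"]])
  files[["linkage_matrix"]] <- file.path(out_dir, "linkage_matrix.tsv")
  write_linkage_table(linkage, files[["linkage_matrix"]],
                      alpha = config$alpha_disease)
  shared <- linkage[linkage$X > 0 & linkage$p_value < config$alpha_disease,
                    c("dataset", "disease", "p_value",
                      "shared_pathway_ids"), drop = FALSE]
  files[["shared_pathways"]] <- file.path(out_dir, "shared_pathways.tsv")
  write_tsv_plain(shared, files[["shared_pathways"]])
  log_stage("linkage computed: %d cell(s), %d significant", nrow(linkage),
            nrow(shared))

  # -- manifest -----------------------------------------------------------
  manifest <- list(
    package = "explinkr",
    version = as.character(utils::packageVersion("explinkr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    M = universe$M,
    config = unclass(config))
  files[["manifest"]] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(universe = universe, enrichments = enrichments,
                 exposure_sets = exposure_sets,
                 disease_sets = disease_sets, linkage = linkage,
                 files = files))
}

#' Write a linkage matrix in report style
#'
#' One row per dataset, one column per disease class; cells are p-values
#' formatted to 4 decimal places, with zero-overlap cells rendered as an
#' en dash ("no pathway in common"), a `*` mark on cells significant at
#' `alpha`, and a trailing `n_linked_pathways` column giving each
#' dataset's `K`. The machine-readable companion written by
#' [run_pipeline()] always carries the numeric p.
#'
#' @param linkage Long-format data.frame with columns `dataset`,
#'   `disease`, `X`, `K`, `p_value` (as produced by [run_pipeline()] or
#'   by stacking [link_exposure_disease()] rows).
#' @param path Output TSV.
#' @param alpha Threshold for the significance mark. Default 0.01.
#' @return The path, invisibly.
#' @export
write_linkage_table <- function(linkage, path, alpha = 0.01) {
  stopifnot(all(c("dataset", "disease", "X", "K", "p_value") %in%
                  names(linkage)))
  datasets <- unique(linkage$dataset)
  diseases <- unique(linkage$disease)
  cell <- function(row) {
    if (row$X == 0) return("–")
    p <- sprintf("%.4f", row$p_value)
    if (row$p_value < alpha) paste0(p, "*") else p
  }
  mat <- data.frame(dataset = datasets, stringsAsFactors = FALSE)
  for (cls in diseases) {
    mat[[cls]] <- vapply(datasets, function(code) {
      row <- linkage[linkage$dataset == code & linkage$disease == cls, ,
                     drop = FALSE]
      if (nrow(row) == 0) "" else cell(row[1, ])
    }, character(1))
  }
  mat$n_linked_pathways <- vapply(datasets, function(code) {
    linkage$K[linkage$dataset == code][1]
  }, numeric(1))
  write_tsv_plain(mat, path)
}
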