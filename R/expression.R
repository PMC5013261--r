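# Per-gene expression measures under the three source conventions:
# log2 exposed/control ratios, (1 - p) significance measures, and 0/1
# significance indicators.

MEASURE_TYPES <- c("LOG2_RATIO", "ONE_MINUS_P", "INDICATOR")

#' Construct an expression dataset
#'
#' One value per gene under a declared measure convention. The enrichment
#' statistic consumes a single strength-of-expression measure per gene,
#' so this container is deliberately minimal.
#'
#' @param values Named numeric vector, canonical gene id -> value. Names
#'   must be unique and non-blank.
#' @param measure_type One of `"LOG2_RATIO"` (finite reals, 0 = no
#'   change), `"ONE_MINUS_P"` (values in \[0, 1\]) or `"INDICATOR"`
#'   (values in \{0, 1\}).
#' @param code Short dataset label, e.g. `"B"`.
#' @param field_type Exposure field type: `"RF"`, `"LF"`, `"ELF"` or
#'   `"synthetic"`.
#' @param provenance Free-text note on where the values came from.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, measure_type, code = "X",
                               field_type = "synthetic", provenance = "") {
  measure_type <- match.arg(measure_type, MEASURE_TYPES)
  values <- unlist(values)
  if (length(values) > 0) {
    if (is.null(names(values)) || any(!nzchar(names(values)))) {
      stop("values must be named by gene id", call. = FALSE)
    }
    if (anyDuplicated(names(values))) {
      stop(sprintf("duplicate gene id(s): %s",
                   paste(unique(names(values)[duplicated(names(values))]),
                         collapse = ", ")), call. = FALSE)
    }
    check_measure_range(values, measure_type)
  }
  structure(list(code = code, field_type = field_type,
                 measure_type = measure_type,
                 values = values, provenance = provenance),
            class = "expression_dataset")
}

#' @keywords internal
check_measure_range <- function(values, measure_type) {
  bad <- switch(measure_type,
    LOG2_RATIO  = !is.finite(values),
    ONE_MINUS_P = !is.finite(values) | values < 0 | values > 1,
    INDICATOR   = !(values %in% c(0, 1)))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "value %s for gene '%s' is out of range for measure type %s",
      format(values[i]), names(values)[i], measure_type), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s' [%s, %s]: %d gene(s)\n",
              x$code, x$field_type, x$measure_type, length(x$values)))
  invisible(x)
}

#' Read per-gene scores from a TSV file
#'
#' @param path TSV with header columns `gene_id`, `value`.
#' @param measure_type Declared measure convention; values are validated
#'   against its range (see [expression_dataset()]). Out-of-range values
#'   and duplicate gene ids are hard errors naming the offending row.
#' @param code,field_type Dataset labels, passed through.
#' @return An `expression_dataset`.
#' @export
read_scores <- function(path, measure_type, code = "X",
                        field_type = "synthetic") {
  measure_type <- match.arg(measure_type, MEASURE_TYPES)
  df <- read_tsv_checked(path, c("gene_id", "value"), "scores")
  vals <- suppressWarnings(as.numeric(df$value))
  if (anyNA(vals)) {
    stop(sprintf("scores file %s row %d: non-numeric value '%s'",
                 path, which(is.na(vals))[1], df$value[which(is.na(vals))[1]]),
         call. = FALSE)
  }
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop(sprintf("scores file %s row %d: duplicate gene id '%s'",
                 path, which(dup)[1], df$gene_id[which(dup)[1]]),
         call. = FALSE)
  }
  names(vals) <- df$gene_id
  expression_dataset(vals, measure_type, code = code,
                     field_type = field_type,
                     provenance = sprintf("read_scores(%s)", path))
}

#' Average log2-ratio replicates gene-wise
#'
#' Per-gene arithmetic mean over the replicate datasets in which the gene
#' appears (gene universes may differ between chips). A single warning
#' reports how many genes were covered by only a subset of replicates.
#'
#' @param datasets List of `expression_dataset`s, all `LOG2_RATIO`.
#' @param code Label for the averaged dataset.
#' @return An `expression_dataset` of measure type `LOG2_RATIO`.
#' @export
replicate_mean <- function(datasets, code = "mean") {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  mt <- vapply(datasets, function(d) d$measure_type, character(1))
  if (any(mt != "LOG2_RATIO")) {
    stop("replicate_mean requires all datasets to be LOG2_RATIO", call. = FALSE)
  }
  genes <- unique(unlist(lapply(datasets, function(d) names(d$values))))
  sums <- counts <- stats::setNames(numeric(length(genes)), genes)
  for (d in datasets) {
    sums[names(d$values)] <- sums[names(d$values)] + d$values
    counts[names(d$values)] <- counts[names(d$values)] + 1
  }
  partial <- sum(counts < length(datasets))
  if (partial > 0) {
    warning(sprintf(
      "replicate_mean: %d gene(s) measured in only a subset of %d replicates",
      partial, length(datasets)), call. = FALSE)
  }
  expression_dataset(sums / counts, "LOG2_RATIO", code = code,
                     field_type = datasets[[1]]$field_type,
                     provenance = sprintf("mean of %d replicate(s)",
                                          length(datasets)))
}

#' Read an identifier map
#'
#' @param path TSV with header columns `source_id`, `canonical_id`.
#'   Many-to-one and one-to-many entries are permitted; blank keys or
#'   values are rejected.
#' @return A data.frame of class `id_map`.
#' @export
read_idmap <- function(path) {
  df <- read_tsv_checked(path, c("source_id", "canonical_id"), "id map")
  id_map(df)
}

#' @rdname read_idmap
#' @param df Data.frame with columns `source_id`, `canonical_id`.
#' @export
id_map <- function(df) {
  stopifnot(all(c("source_id", "canonical_id") %in% names(df)))
  df$source_id <- trimws(as.character(df$source_id))
  df$canonical_id <- trimws(as.character(df$canonical_id))
  if (any(!nzchar(df$source_id)) || any(!nzchar(df$canonical_id))) {
    stop("id map contains blank source or canonical id(s)", call. = FALSE)
  }
  df <- unique(df[, c("source_id", "canonical_id")])
  class(df) <- c("id_map", "data.frame")
  df
}

#' Re-key a dataset to canonical gene identifiers
#'
#' Probe- or symbol-keyed values are re-keyed through the map. When
#' several source ids map to one canonical id, the value with the largest
#' magnitude (per the dataset's measure convention, see [magnitude()]) is
#' kept — a conservative choice for enrichment detection. Sources with no
#' map entry are dropped.
#'
#' @param dataset An `expression_dataset` keyed by source identifiers.
#' @param idmap An `id_map` (see [read_idmap()]).
#' @return List with elements `dataset` (re-keyed `expression_dataset`)
#'   and `report` (counts: `mapped`, `collapsed`, `dropped`).
#' @export
map_ids <- function(dataset, idmap) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(idmap, "id_map"))
  src <- names(dataset$values)
  hit <- idmap[idmap$source_id %in% src, , drop = FALSE]
  dropped <- sum(!src %in% hit$source_id)
  if (nrow(hit) == 0L) {
    out <- expression_dataset(stats::setNames(numeric(0), character(0)),
                              dataset$measure_type, code = dataset$code,
                              field_type = dataset$field_type,
                              provenance = dataset$provenance)
    return(list(dataset = out,
                report = c(mapped = 0L, collapsed = 0L, dropped = dropped)))
  }
  vals <- dataset$values[hit$source_id]
  mags <- magnitude_values(vals, dataset$measure_type)
  # per canonical id keep the largest-magnitude candidate
  ord <- order(hit$canonical_id, -mags)
  first <- !duplicated(hit$canonical_id[ord])
  kept <- stats::setNames(vals[ord][first], hit$canonical_id[ord][first])
  collapsed <- length(vals) - length(kept)
  out <- expression_dataset(kept, dataset$measure_type, code = dataset$code,
                            field_type = dataset$field_type,
                            provenance = paste0(dataset$provenance,
                                                " | map_ids"))
  list(dataset = out,
       report = c(mapped = length(kept), collapsed = as.integer(collapsed),
                  dropped = as.integer(dropped)))
}

#' Pool significant-gene lists into an indicator dataset
#'
#' Emulates the construction of a pooled dataset from several studies that
#' report only their significantly altered genes: the indicator is 1 for
#' the union of the lists and 0 for every other gene of the measured
#' background universe.
#'
#' @param gene_lists List of character vectors of canonical gene ids.
#' @param background Character vector: the universe of measured genes.
#'   Significant genes absent from it are added with a warning.
#' @param code,field_type Dataset labels.
#' @return An `expression_dataset` of measure type `INDICATOR`.
#' @export
pool_indicator <- function(gene_lists, background, code = "pooled",
                           field_type = "synthetic") {
  stopifnot(is.list(gene_lists))
  sig <- unique(unlist(gene_lists, use.names = FALSE)) %||% character()
  background <- unique(as.character(background))
  missing <- setdiff(sig, background)
  if (length(missing) > 0) {
    warning(sprintf(
      "pool_indicator: %d significant gene(s) absent from background; added",
      length(missing)), call. = FALSE)
    background <- c(background, missing)
  }
  vals <- stats::setNames(as.numeric(background %in% sig), background)
  expression_dataset(vals, "INDICATOR", code = code, field_type = field_type,
                     provenance = sprintf("pooled indicator of %d list(s)",
                                          length(gene_lists)))
}

#' Pool heterogeneous measured datasets by mean normalized rank
#'
#' Datasets with different chips and measure conventions are made
#' commensurable by replacing each gene's value with its within-dataset
#' normalized rank of magnitude (see [rank_transform()]), then averaging
#' the ranks over the datasets containing the gene. Rank averaging is
#' scale-free: the result is invariant under any monotone transform of
#' each input's values, which is the only safe way to combine log-ratios,
#' (1 - p) measures and indicators into one dataset.
#'
#' @param datasets List of at least one `expression_dataset` (mixed
#'   measure types allowed).
#' @param code Label for the pooled dataset.
#' @return An `expression_dataset` of measure type `ONE_MINUS_P` with
#'   values in (0, 1\].
#' @export
pool_measured <- function(datasets, code = "pooled") {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  ranked <- lapply(datasets, function(d) rank_transform(magnitude(d)))
  genes <- unique(unlist(lapply(ranked, names)))
  sums <- counts <- stats::setNames(numeric(length(genes)), genes)
  for (r in ranked) {
    sums[names(r)] <- sums[names(r)] + r
    counts[names(r)] <- counts[names(r)] + 1
  }
  expression_dataset(sums / counts, "ONE_MINUS_P", code = code,
                     field_type = datasets[[1]]$field_type,
                     provenance = sprintf(
                       "mean normalized rank over %d dataset(s)",
                       length(datasets)))
}

#' Read a gene list file (one id per line)
#'
#' @param path Plain-text file, one gene id per line; blank lines ignored.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
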