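# Exposure-disease linkage: build the significant-pathway set of each
# disease class (alpha = 0.01) and each exposure dataset (alpha = 0.05),
# then test the overlap of the two sets with an exact hypergeometric
# upper-tail probability within the filtered pathway universe of size M.

#' Construct a gene-disease association table
#'
#' @param df Data.frame with columns `gene_id`, `disease_class`.
#' @param include_list Optional character vector of disease classes to
#'   analyze; records for other classes are dropped with a message giving
#'   the count (mirrors excluding sparse catch-all categories from a
#'   curated association database).
#' @return A data.frame of class `association_table`. The retained class
#'   labels, in first-appearance order, are in `attr(, "classes")`.
#' @export
association_table <- function(df, include_list = NULL) {
  stopifnot(all(c("gene_id", "disease_class") %in% names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$disease_class <- as.character(df$disease_class)
  if (!is.null(include_list)) {
    out <- !(df$disease_class %in% include_list)
    if (any(out)) {
      message(sprintf(
        "association_table: ignoring %d record(s) in %d excluded class(es)",
        sum(out), length(unique(df$disease_class[out]))))
    }
    df <- df[!out, , drop = FALSE]
  }
  df <- unique(df[, c("gene_id", "disease_class")])
  rownames(df) <- NULL
  structure(df, class = c("association_table", "data.frame"),
            classes = unique(df$disease_class))
}

#' Read a gene-disease association table from TSV
#'
#' @param path TSV with header columns `gene_id`, `disease_class`.
#' @inheritParams association_table
#' @return An `association_table`.
#' @export
read_associations <- function(path, include_list = NULL) {
  association_table(read_tsv_checked(path, c("gene_id", "disease_class"),
                                     "associations"),
                    include_list = include_list)
}

#' Construct a significant-pathway set
#'
#' Holds the pathways significant for one owner: a disease class (the `N`
#' of the linkage test, default alpha 0.01) or an exposure dataset (the
#' `K`, default alpha 0.05).
#'
#' @param owner Disease class label or dataset code.
#' @param kind `"disease"` or `"exposure"`.
#' @param pathway_ids Character vector of significant pathway ids.
#' @param alpha The significance threshold that produced the set.
#' @return An object of class `pathway_set` with a `size` field.
#' @export
pathway_set <- function(owner, kind = c("disease", "exposure"),
                        pathway_ids = character(), alpha = NULL) {
  kind <- match.arg(kind)
  if (is.null(alpha)) alpha <- if (kind == "disease") 0.01 else 0.05
  pathway_ids <- unique(as.character(pathway_ids))
  structure(list(owner = owner, kind = kind, pathway_ids = pathway_ids,
                 size = length(pathway_ids), alpha = alpha),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("pathway_set [%s] '%s': %d pathway(s) at alpha = %g\n",
              x$kind, x$owner, x$size, x$alpha))
  invisible(x)
}

#' Build per-disease significant-pathway sets
#'
#' For each disease class, the associated genes become an unweighted 0/1
#' indicator dataset over the genes appearing in the universe (1 =
#' associated, 0 = every other universe gene), which is enriched exactly
#' like an expression dataset; pathways with `p < alpha` form the
#' disease's set.
#'
#' @param assoc An `association_table`.
#' @param universe A filtered `pathway_universe`.
#' @param config An `enrichment_config`.
#' @param alpha Strict significance threshold, default 0.01.
#' @return Named list of `pathway_set`s (one per disease class, in table
#'   order), each carrying the full enrichment results in
#'   `attr(, "results")`.
#' @export
disease_pathway_sets <- function(assoc, universe,
                                 config = enrichment_config(),
                                 alpha = 0.01) {
  stopifnot(inherits(assoc, "association_table"),
            inherits(universe, "pathway_universe"))
  universe_genes <- unique(unlist(lapply(universe$pathways, pathway_genes)))
  classes <- attr(assoc, "classes")
  seeds <- if (is.null(config$seed)) rep(list(NULL), length(classes))
           else as.list(config$seed + seq_along(classes))
  sets <- vector("list", length(classes))
  names(sets) <- classes
  for (i in seq_along(classes)) {
    cls <- classes[i]
    genes <- intersect(assoc$gene_id[assoc$disease_class == cls],
                       universe_genes)
    if (length(genes) == 0L) {
      warning(sprintf(
        "disease class '%s' has no associated gene in the universe",
        cls), call. = FALSE)
      sets[[i]] <- pathway_set(cls, "disease", character(), alpha = alpha)
      next
    }
    ds <- expression_dataset(
      stats::setNames(as.numeric(universe_genes %in% genes), universe_genes),
      "INDICATOR", code = cls, field_type = "synthetic",
      provenance = sprintf("disease association indicator (%d genes)",
                           length(genes)))
    cfg <- config
    cfg$seed <- seeds[[i]]
    res <- enrich_all(universe, ds, cfg)
    sig <- res$pathway_id[res$evaluable & res$p_value < alpha]
    s <- pathway_set(cls, "disease", sig, alpha = alpha)
    attr(s, "results") <- res
    attr(s, "n_genes") <- length(genes)
    sets[[i]] <- s
  }
  sets
}

#' Build an exposure significant-pathway set from enrichment results
#'
#' @param results Data.frame from [enrich_all()] for one dataset.
#' @param owner Dataset code for the set.
#' @param alpha Strict significance threshold, default 0.05.
#' @return A `pathway_set` of kind `"exposure"` whose `size` is `K`.
#' @export
exposure_pathway_sets <- function(results, owner = "X", alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("pathway_id", "p_value", "evaluable") %in% names(results)))
  sig <- results$pathway_id[results$evaluable %in% TRUE &
                              results$p_value < alpha]
  s <- pathway_set(owner, "exposure", sig, alpha = alpha)
  attr(s, "results") <- results
  s
}

#' Exact hypergeometric CDF
#'
#' `H(x, M, K, N)`: the probability of at most `x` successes when drawing
#' `N` items without replacement from `M` objects of which `K` are
#' successes. Computed by summing exact log-gamma terms, so it is
#' accurate to near machine precision and symmetric in `K` and `N`.
#'
#' @param x Integer (may be negative: values below the support give 0,
#'   values at or above `min(K, N)` give 1).
#' @param M,K,N Nonnegative integers with `K <= M` and `N <= M`.
#' @return The CDF value in \[0, 1\].
#' @export
hypergeom_cdf <- function(x, M, K, N) {
  stopifnot(length(x) == 1, length(M) == 1, length(K) == 1, length(N) == 1)
  if (K < 0 || N < 0 || M < 0 || K > M || N > M) {
    stop(sprintf("invalid hypergeometric parameters M=%s K=%s N=%s",
                 M, K, N), call. = FALSE)
  }
  x <- floor(x)
  lo <- max(0, K + N - M)
  hi <- min(K, N)
  if (x < lo) return(0)
  if (x >= hi) return(1)
  i <- lo:x
  terms <- lchoose(K, i) + lchoose(M - K, N - i) - lchoose(M, N)
  min(1, sum(exp(terms)))
}

#' Upper-tail overlap probability
#'
#' The probability of observing at least `X` pathways in common between an
#' exposure set of size `K` and a disease set of size `N` drawn
#' independently at random in a universe of `M` pathways:
#' `p = 1 - H(X - 1, M, K, N)`. `X = 0` gives `p = 1` (at least zero in
#' common is certain).
#'
#' @param X Observed overlap, integer in `0..min(K, N)`.
#' @inheritParams hypergeom_cdf
#' @return The linkage p-value in (0, 1\].
#' @export
link_probability <- function(X, M, K, N) {
  stopifnot(length(X) == 1, X >= 0)
  if (X > min(K, N)) {
    stop(sprintf("overlap X=%s exceeds min(K=%s, N=%s)", X, K, N),
         call. = FALSE)
  }
  if (X == 0) return(1)
  # complement summed directly over the upper tail for accuracy at small p
  lo <- max(0, K + N - M)
  hi <- min(K, N)
  i <- max(X, lo):hi
  terms <- lchoose(K, i) + lchoose(M - K, N - i) - lchoose(M, N)
  min(1, sum(exp(terms)))
}

#' Test the overlap between an exposure set and a disease set
#'
#' @param exposure_set A `pathway_set` of kind `"exposure"` (its size is
#'   `K`).
#' @param disease_set A `pathway_set` of kind `"disease"` (its size is
#'   `N`).
#' @param universe Either a filtered `pathway_universe` (then `M` is its
#'   pathway count and both sets are checked to lie inside it — an id
#'   outside the universe is a hard error) or a single integer `M`.
#' @return A one-row data.frame of class `linkage_result` with columns
#'   `dataset`, `disease`, `X`, `M`, `K`, `N`, `p_value`; the shared
#'   pathway ids are in `attr(, "shared_pathway_ids")`.
#' @export
link_exposure_disease <- function(exposure_set, disease_set, universe) {
  stopifnot(inherits(exposure_set, "pathway_set"),
            inherits(disease_set, "pathway_set"))
  if (inherits(universe, "pathway_universe")) {
    M <- universe$M
    ids <- names(universe$pathways)
    stray <- setdiff(c(exposure_set$pathway_ids, disease_set$pathway_ids),
                     ids)
    if (length(stray) > 0) {
      stop(sprintf("pathway id(s) absent from the universe: %s",
                   paste(stray, collapse = ", ")), call. = FALSE)
    }
  } else {
    M <- as.integer(universe)
    stopifnot(length(M) == 1, M >= 0)
  }
  shared <- intersect(exposure_set$pathway_ids, disease_set$pathway_ids)
  K <- exposure_set$size
  N <- disease_set$size
  X <- length(shared)
  out <- data.frame(dataset = exposure_set$owner,
                    disease = disease_set$owner,
                    X = X, M = M, K = K, N = N,
                    p_value = link_probability(X, M, K, N),
                    stringsAsFactors = FALSE)
  class(out) <- c("linkage_result", "data.frame")
  attr(out, "shared_pathway_ids") <- shared
  out
}
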