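# Internal helpers shared across modules.

#' @keywords internal
read_tsv_checked <- function(path, required_cols, what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE, comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @keywords internal
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so package code never perturbs the user's stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
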