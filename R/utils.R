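# internal helpers shared across modules

## let data.table recognize this package as data.table-aware
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG state when a seed is supplied, leaving
## the caller's RNG untouched; with seed = NULL the expression runs as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Write a data frame as tab-separated values
#'
#' Plain TSV (no quoting, no row names) is the interchange format used for
#' every persisted pipeline intermediate, so stages stay diffable and
#' individually re-runnable.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
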