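# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' XORs a base seed with an integer stream id so that stochastic stages of a
#' run (one per signature length, one per perturbation, ...) are independent
#' but fully reproducible from the base seed alone.
#'
#' @param seed Base integer seed.
#' @param k Integer stream identifier (e.g. the signature length m).
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, k) {
  bitwXor(as.integer(seed), as.integer(k))
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
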