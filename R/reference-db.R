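# Reference database of compound-induced expression profiles.
#
# Each profile stores, for every gene of the universe, a signed rank: the
# magnitude is the gene's rank by differential-expression amplitude under
# the compound treatment (N = strongest, 1 = weakest) and the sign its
# regulation direction. A compound may have several replicate profiles.

#' Construct a reference profile database
#'
#' @param universe Character vector of gene ids (the shared universe).
#' @param ranks Integer matrix, genes x profiles: column j holds profile j's
#'   signed ranks; magnitudes of each column must be a permutation of
#'   `1..N` with no zeros.
#' @param profile_meta Data frame with columns `compound`, `replicate_id`
#'   (one row per profile column).
#' @return Object of class `reference_db` with fields `universe`, `ranks`,
#'   `profile_meta`, `compounds`, `Nc` (number of distinct compounds) and
#'   `N` (universe size).
#' @export
reference_db <- function(universe, ranks, profile_meta) {
  universe <- as.character(universe)
  N <- length(universe)
  if (N < 1L || anyDuplicated(universe)) {
    stop("universe must be a nonempty set of unique gene ids", call. = FALSE)
  }
  if (!is.matrix(ranks) || nrow(ranks) != N) {
    stop("'ranks' must be a genes x profiles matrix over the universe", call. = FALSE)
  }
  if (!all(c("compound", "replicate_id") %in% names(profile_meta)) ||
      nrow(profile_meta) != ncol(ranks)) {
    stop("'profile_meta' needs compound/replicate_id rows matching ranks columns",
         call. = FALSE)
  }
  mags <- abs(ranks)
  ok <- apply(mags, 2, function(col)
    identical(sort(unname(as.integer(col))), seq_len(N)))
  if (!all(ok)) {
    stop("each profile's rank magnitudes must be a permutation of 1..N (no zeros)",
         call. = FALSE)
  }
  rownames(ranks) <- universe
  compounds <- unique(profile_meta$compound)
  structure(
    list(universe = universe, ranks = ranks,
         profile_meta = as.data.frame(profile_meta, stringsAsFactors = FALSE),
         compounds = compounds, Nc = length(compounds), N = N),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d profiles / %d compounds over %d genes\n",
              ncol(x$ranks), x$Nc, x$N))
  invisible(x)
}

#' Subset a reference database to given compounds
#'
#' Keeps only the profiles of `compounds`. `Nc` of the returned object
#' reflects the subset; significance thresholds that depend on the full
#' database size must be computed from the original `Nc`.
#'
#' @param db A `reference_db`.
#' @param compounds Character vector of compound names present in `db`.
#' @return A `reference_db` restricted to those compounds.
#' @export
subset_reference_db <- function(db, compounds) {
  stopifnot(inherits(db, "reference_db"))
  missing <- setdiff(compounds, db$compounds)
  if (length(missing)) {
    stop("unknown compound(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- db$profile_meta$compound %in% compounds
  reference_db(db$universe, db$ranks[, keep, drop = FALSE],
               db$profile_meta[keep, , drop = FALSE])
}

#' Read / write a reference database as long-format TSV
#'
#' Columns: `compound`, `replicate_id`, `gene_id`, `signed_rank`; one row per
#' (profile, gene).
#'
#' @param path TSV path.
#' @param db A `reference_db`.
#' @return `read_reference_db`: a `reference_db`; `write_reference_db`:
#'   invisibly, `path`.
#' @export
read_reference_db <- function(path) {
  df <- .read_tsv(path)
  req <- c("compound", "replicate_id", "gene_id", "signed_rank")
  if (!all(req %in% names(df))) {
    stop("reference TSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  universe <- sort(unique(df$gene_id))
  key <- paste(df$compound, df$replicate_id, sep = "\r")
  profs <- unique(key)
  ranks <- matrix(0L, nrow = length(universe), ncol = length(profs),
                  dimnames = list(universe, NULL))
  ranks[cbind(match(df$gene_id, universe), match(key, profs))] <-
    as.integer(df$signed_rank)
  first <- match(profs, key)
  meta <- data.frame(compound = df$compound[first],
                     replicate_id = df$replicate_id[first],
                     stringsAsFactors = FALSE)
  reference_db(universe, ranks, meta)
}

#' @rdname read_reference_db
#' @export
write_reference_db <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  P <- ncol(db$ranks)
  out <- data.frame(
    compound = rep(db$profile_meta$compound, each = db$N),
    replicate_id = rep(db$profile_meta$replicate_id, each = db$N),
    gene_id = rep(db$universe, times = P),
    signed_rank = as.integer(db$ranks),
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}
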