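# Signed normalized-rank scoring and cross-dataset combination.
#
# Within one dataset the M statistically significant genes are ranked by
# significance (i = 1 is the most significant) and the i-th gene scores
# (M - i + 1) / M, signed + for up- and - for down-regulation; all other
# genes score 0. Dividing by M makes scores comparable between datasets with
# very different numbers of significant genes, so an under-powered study
# contributes little to the combined totals. Genes that are statistically
# significant but change less than 2-fold are reset to score 0 after rank
# assignment: surviving genes keep the score of their original position in
# the significance ordering (re-ranking would alter every published score
# below the first filtered gene).

#' Construct a per-dataset score vector
#'
#' Low-level constructor; most callers use [score_dataset()]. Scores must lie
#' in `[-1, 1]`; `M` is the dataset's significant-gene count.
#'
#' @param dataset_name Dataset name.
#' @param scores Named numeric vector over the gene universe (0 = not scored).
#' @param M Number of statistically significant genes.
#' @return Object of class `score_vector`.
#' @export
score_vector <- function(dataset_name, scores, M) {
  stopifnot(is.character(dataset_name), length(dataset_name) == 1L)
  if (is.null(names(scores))) stop("'scores' must be named by gene id", call. = FALSE)
  if (any(abs(scores) > 1 + 1e-12)) stop("scores must be in [-1, 1]", call. = FALSE)
  .assert_scalar_number(M, "M", lower = 0)
  structure(
    list(dataset_name = dataset_name, scores = scores, M = as.integer(M),
         nonzero_count = sum(scores != 0)),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector '%s': %d genes, M=%d, %d nonzero\n",
              x$dataset_name, length(x$scores), x$M, x$nonzero_count))
  invisible(x)
}

#' Signed normalized rank scores for one dataset
#'
#' Applies the ranking rules to a differential-expression result: the i-th
#' most significant of the M significant genes scores `(M - i + 1) / M`,
#' signed by its regulation direction; non-significant genes score 0; genes
#' failing the fold-change filter (default: less than 2-fold, i.e.
#' `|mean_log2_diff| < 1`) are zeroed after rank assignment, so they consume
#' a rank position but contribute nothing.
#'
#' @param de A `diffexp_result` from [run_diffexp()].
#' @param min_abs_log2_fc Fold-change filter on `|mean_log2_diff|`
#'   (default 1, i.e. 2-fold).
#' @return A [score_vector] over the dataset's gene universe.
#' @export
score_dataset <- function(de, min_abs_log2_fc = 1) {
  stopifnot(inherits(de, "diffexp_result"))
  res <- de$results
  scores <- stats::setNames(numeric(nrow(res)), res$gene_id)
  M <- de$M
  if (M > 0L) {
    i <- seq_len(M)
    raw <- (M - i + 1) / M
    idx <- match(de$significant_ids, res$gene_id)
    sgn <- sign(res$mean_log2_diff[idx])
    pass_fc <- abs(res$mean_log2_diff[idx]) >= min_abs_log2_fc
    scores[idx] <- ifelse(pass_fc, raw * sgn, 0)
  }
  score_vector(de$dataset_name, scores, M)
}

#' Combine per-dataset score vectors into an overall ranking
#'
#' Sums each gene's signed scores across datasets and sorts genes by the
#' absolute total in descending order. A gene regulated in opposite
#' directions in different datasets has its per-dataset scores cancel, so
#' only genes consistently significant in the same direction retain a large
#' total. Ties are broken by the number of datasets with a nonzero score
#' (descending), then gene id.
#'
#' @param score_vectors List of [score_vector] objects over the same universe.
#' @return Object of class `combined_signature`: a data frame `entries` with
#'   columns `gene_id`, one score column per dataset, `total_score`,
#'   `n_nonzero`, `overall_rank`, plus fields `D` (number of datasets) and
#'   `nonzero_total` (count of genes with total != 0).
#' @export
combine_scores <- function(score_vectors) {
  if (inherits(score_vectors, "score_vector")) score_vectors <- list(score_vectors)
  if (length(score_vectors) == 0L) stop("need at least one score vector", call. = FALSE)
  stopifnot(all(vapply(score_vectors, inherits, logical(1), "score_vector")))
  genes <- names(score_vectors[[1]]$scores)
  for (sv in score_vectors[-1]) {
    if (!identical(sort(names(sv$scores)), sort(genes))) {
      stop("score vectors are over different gene universes", call. = FALSE)
    }
  }
  mat <- vapply(score_vectors, function(sv) sv$scores[genes], numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, vapply(score_vectors, `[[`, "",
                                              "dataset_name")))
  total <- rowSums(mat)
  n_nonzero <- rowSums(mat != 0)
  ord <- order(-abs(total), -n_nonzero, genes)
  entries <- data.frame(gene_id = genes[ord], mat[ord, , drop = FALSE],
                        total_score = total[ord], n_nonzero = n_nonzero[ord],
                        overall_rank = seq_along(genes),
                        row.names = NULL, check.names = FALSE,
                        stringsAsFactors = FALSE)
  structure(
    list(entries = entries, D = length(score_vectors),
         dataset_names = colnames(mat),
         nonzero_total = sum(entries$total_score != 0)),
    class = "combined_signature"
  )
}

#' @export
print.combined_signature <- function(x, ...) {
  cat(sprintf("combined_signature: %d genes over %d datasets, %d with nonzero total\n",
              nrow(x$entries), x$D, x$nonzero_total))
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Query signature of the top m combined genes
#'
#' Takes the first `m` genes of the combined ranking, each carrying the sign
#' of its total score; genes with total exactly 0 carry no direction and are
#' never included.
#'
#' @param combined A `combined_signature`.
#' @param m Signature length, `1 <= m <=` number of nonzero-total genes.
#' @return Object of class `query_signature`: data frame with columns
#'   `gene_id` and `sign` (+1/-1), attribute `m`.
#' @export
take_top <- function(combined, m) {
  stopifnot(inherits(combined, "combined_signature"))
  .assert_scalar_number(m, "m", lower = 1)
  if (m > combined$nonzero_total) {
    stop(sprintf("m = %d exceeds the %d ranked genes with nonzero total score (exhausted)",
                 m, combined$nonzero_total), call. = FALSE)
  }
  top <- combined$entries[seq_len(m), ]
  query_signature(top$gene_id, sign(top$total_score))
}

#' Construct a query gene signature
#'
#' @param gene_ids Ordered character vector of unique gene ids.
#' @param signs Vector of +1/-1 regulation directions, one per gene.
#' @return Object of class `query_signature`.
#' @export
query_signature <- function(gene_ids, signs) {
  if (anyDuplicated(gene_ids)) stop("signature genes must be unique", call. = FALSE)
  if (length(gene_ids) == 0L) stop("signature must contain at least one gene", call. = FALSE)
  signs <- as.numeric(signs)
  if (length(signs) != length(gene_ids) || !all(signs %in% c(-1, 1))) {
    stop("'signs' must be +1/-1, one per gene", call. = FALSE)
  }
  structure(
    data.frame(gene_id = as.character(gene_ids), sign = signs,
               stringsAsFactors = FALSE),
    class = c("query_signature", "data.frame"),
    m = length(gene_ids)
  )
}

#' @export
print.query_signature <- function(x, ...) {
  cat(sprintf("query_signature: %d genes (%d up, %d down)\n",
              nrow(x), sum(x$sign > 0), sum(x$sign < 0)))
  invisible(x)
}

#' Write / read a combined signature table
#'
#' The TSV mirrors the published layout: `ProbeID`, one column per dataset
#' score, `TotalScore`, `OverallRank`.
#'
#' @param combined A `combined_signature`.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_combined_signature <- function(combined, path) {
  stopifnot(inherits(combined, "combined_signature"))
  e <- combined$entries
  out <- data.frame(ProbeID = e$gene_id,
                    e[, combined$dataset_names, drop = FALSE],
                    TotalScore = e$total_score, OverallRank = e$overall_rank,
                    check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(out, path)
}

#' Write a query signature as a two-column TSV (gene_id, sign)
#'
#' @param signature A `query_signature`.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "query_signature"))
  .write_tsv(data.frame(gene_id = signature$gene_id,
                        sign = ifelse(signature$sign > 0, "+1", "-1"),
                        stringsAsFactors = FALSE), path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- .read_tsv(path)
  query_signature(df$gene_id, as.numeric(df$sign))
}
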