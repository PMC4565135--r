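# Per-dataset paired differential expression.
#
# Each gene is tested with a classical paired t-test on the per-subject
# tumour - normal log2 differences. The significance cut-off is adaptive:
# p < 1 / (pi0 * N), where N is the number of genes analysed and pi0 the
# estimated proportion of non-differentially-expressed genes. With that
# threshold the expected number of false positives among N tests is about 1.

#' Paired t-test for every gene of a dataset
#'
#' Computes, per gene, the classical paired t statistic on tumour - normal
#' differences with `n_pairs - 1` degrees of freedom and a two-sided p-value.
#' Genes whose differences have zero variance get `t_stat = 0`, `p_value = 1`
#' and are flagged in the `degenerate` column.
#'
#' @param dataset A [paired_dataset] with at least 2 pairs.
#' @return Data frame with columns `gene_id`, `t_stat`, `p_value`,
#'   `mean_log2_diff`, `direction` (`up`/`down`/`flat`), `degenerate`.
#' @export
paired_t_test <- function(dataset) {
  stopifnot(inherits(dataset, "paired_dataset"))
  n <- dataset$n_pairs
  if (n < 2L) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  d <- .pair_differences(dataset)
  mu <- rowMeans(d)
  ss <- rowSums((d - mu)^2)
  sd_d <- sqrt(ss / (n - 1))
  degenerate <- sd_d == 0
  tstat <- ifelse(degenerate, 0, mu / (sd_d / sqrt(n)))
  pval <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df = n - 1))
  direction <- ifelse(mu > 0, "up", ifelse(mu < 0, "down", "flat"))
  data.frame(
    gene_id = rownames(d),
    t_stat = unname(tstat),
    p_value = unname(pval),
    mean_log2_diff = unname(mu),
    direction = direction,
    degenerate = unname(degenerate),
    stringsAsFactors = FALSE
  )
}

#' Estimate the proportion of non-differentially-expressed genes
#'
#' Estimates pi0, the proportion of true null hypotheses, from the p-value
#' distribution. The default delegates to [limma::propTrueNull()] (local-FDR
#' flavour); `method = "fixed"` returns a user-supplied value, which keeps
#' the downstream threshold formula exactly reproducible in tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"lfdr"`, `"mean"`, `"hist"`, `"convest"` (passed to limma)
#'   or `"fixed"`.
#' @param pi0 The value to return when `method = "fixed"`.
#' @return pi0 estimate, clamped to `(0, 1]`.
#' @export
estimate_pi0 <- function(p_values, method = c("lfdr", "mean", "hist",
                                              "convest", "fixed"),
                         pi0 = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    .assert_scalar_number(pi0, "pi0", lower = .Machine$double.eps, upper = 1)
    return(pi0)
  }
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  est <- limma::propTrueNull(p_values, method = method)
  min(max(est, 1 / length(p_values)), 1)
}

#' Adaptive significance threshold 1 / (pi0 * N)
#'
#' The p-value cut-off that controls the expected number of false positives
#' among `N` tests at about one.
#'
#' @param pi0 Estimated proportion of null genes, in `(0, 1]`.
#' @param N Total number of genes analysed.
#' @return The threshold `1 / (pi0 * N)`.
#' @export
significance_threshold <- function(pi0, N) {
  .assert_scalar_number(pi0, "pi0", lower = .Machine$double.eps, upper = 1)
  .assert_scalar_number(N, "N", lower = 1)
  1 / (pi0 * N)
}

#' Per-gene linear fold change
#'
#' Linear fold change `2^mean_log2_diff` from the mean of per-pair log2
#' differences (the paired geometric-mean ratio). The biological-significance
#' filter used downstream keeps genes with `|mean_log2_diff| >= 1`,
#' i.e. at least 2-fold change in either direction.
#'
#' @param dataset A [paired_dataset].
#' @return Named numeric vector of fold changes (tumour relative to normal).
#' @export
fold_change <- function(dataset) {
  stopifnot(inherits(dataset, "paired_dataset"))
  mu <- rowMeans(.pair_differences(dataset))
  2^mu
}

#' Full differential-expression analysis of one dataset
#'
#' Runs the paired t-test, estimates pi0, derives the adaptive threshold and
#' splits genes into the significant and non-significant groups. Significant
#' genes are ordered by ascending p-value (ties: larger `|t|` first, then
#' gene id), which fixes the significance rank `i` used for scoring.
#'
#' @param dataset A [paired_dataset].
#' @param pi0_method,pi0 Passed to [estimate_pi0()].
#' @return Object of class `diffexp_result`: fields `dataset_name`, `results`
#'   (per-gene table with `fold_change` and `significant` columns), `pi0`,
#'   `threshold`, `significant_ids` (p-ascending), `M`, `N`.
#' @export
run_diffexp <- function(dataset, pi0_method = "lfdr", pi0 = NULL) {
  res <- paired_t_test(dataset)
  res$fold_change <- 2^res$mean_log2_diff
  pi0_hat <- estimate_pi0(res$p_value, method = pi0_method, pi0 = pi0)
  thr <- significance_threshold(pi0_hat, nrow(res))
  res$significant <- res$p_value < thr
  ord <- order(res$p_value, -abs(res$t_stat), res$gene_id)
  sig_ids <- res$gene_id[ord][res$significant[ord]]
  structure(
    list(dataset_name = dataset$name, results = res, pi0 = pi0_hat,
         threshold = thr, significant_ids = sig_ids,
         M = length(sig_ids), N = nrow(res)),
    class = "diffexp_result"
  )
}

#' @export
print.diffexp_result <- function(x, ...) {
  cat(sprintf("diffexp_result '%s': N=%d genes, pi0=%.3f, threshold=%.3g, M=%d significant\n",
              x$dataset_name, x$N, x$pi0, x$threshold, x$M))
  invisible(x)
}

#' Write a per-dataset differential-expression table to TSV
#'
#' @param de A `diffexp_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diffexp <- function(de, path) {
  stopifnot(inherits(de, "diffexp_result"))
  out <- de$results[, c("gene_id", "t_stat", "p_value", "mean_log2_diff",
                        "fold_change")]
  out$significant <- as.integer(de$results$significant)
  .write_tsv(out, path)
}
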