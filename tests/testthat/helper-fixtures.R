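# Shared fixture builders and independent oracles for the test suite.

# Small paired dataset from an explicit matrix; stages default to II.
make_dataset <- function(values, name = "toy", stages = NULL) {
  np <- ncol(values) / 2
  subj <- paste0("s", seq_len(np))
  colnames(values) <- c(paste0(subj, "_T"), paste0(subj, "_N"))
  pairs <- data.frame(tumour = paste0(subj, "_T"), normal = paste0(subj, "_N"),
                      subject = subj,
                      stage = stages %||% rep("II", np),
                      stringsAsFactors = FALSE)
  paired_dataset(name, values, pairs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Dataset with fully controlled tumour - normal differences: normals are a
# constant baseline, tumours baseline + diffs (genes x pairs matrix).
dataset_from_diffs <- function(diffs, name = "toy") {
  if (is.null(rownames(diffs))) {
    rownames(diffs) <- sprintf("g%03d", seq_len(nrow(diffs)))
  }
  normal <- matrix(8, nrow(diffs), ncol(diffs), dimnames = dimnames(diffs))
  make_dataset(cbind(normal + diffs, normal), name = name)
}

# diffexp_result with explicit per-gene values; mirrors the ordering
# contract (p ascending, |t| descending, gene id) so score tests can pin
# down M and ranks exactly.
make_diffexp <- function(gene_id, p_value, mean_log2_diff, threshold,
                         t_stat = NULL, name = "toy") {
  t_stat <- t_stat %||% -stats::qnorm(p_value / 2) * sign(mean_log2_diff)
  res <- data.frame(gene_id = gene_id, t_stat = t_stat, p_value = p_value,
                    mean_log2_diff = mean_log2_diff,
                    direction = ifelse(mean_log2_diff > 0, "up",
                                       ifelse(mean_log2_diff < 0, "down", "flat")),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  res$fold_change <- 2^res$mean_log2_diff
  res$significant <- res$p_value < threshold
  ord <- order(res$p_value, -abs(res$t_stat), res$gene_id)
  sig_ids <- res$gene_id[ord][res$significant[ord]]
  structure(list(dataset_name = name, results = res, pi0 = 1,
                 threshold = threshold, significant_ids = sig_ids,
                 M = length(sig_ids), N = nrow(res)),
            class = "diffexp_result")
}

# --- independent oracles ----------------------------------------------------

# Plain-loop connection score: signed sum over signature genes divided by
# the sum of the m largest rank magnitudes.
naive_cscore <- function(genes, signs, profile) {
  total <- 0
  for (k in seq_along(genes)) total <- total + signs[k] * profile[[genes[k]]]
  N <- length(profile)
  m <- length(genes)
  total / sum(sort(seq_len(N), decreasing = TRUE)[seq_len(m)])
}

# Exact tail probability by full enumeration of every signed gene subset of
# size m (nested loops, no shared code with the package internals).
brute_force_p <- function(profile, m, obs, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  N <- length(profile)
  subsets <- utils::combn(N, m, simplify = FALSE)
  count <- 0L
  total <- 0L
  for (s in subsets) {
    for (mask in 0:(2^m - 1)) {
      sgn <- ifelse(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0, 1, -1)
      sc <- naive_cscore(names(profile)[s], sgn, profile)
      total <- total + 1L
      hit <- if (tail == "upper") sc >= obs - 1e-12 else sc <= obs + 1e-12
      if (hit) count <- count + 1L
    }
  }
  count / total
}

# Random signed-rank profile over n genes.
random_profile <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(sample(c(-1, 1), n, TRUE) * sample.int(n),
                  sprintf("g%03d", seq_len(n)))
}
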